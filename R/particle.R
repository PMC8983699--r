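#' Describe a model plastic particle
#'
#' A `particle_spec` carries the physical description of a monodisperse model
#' particle: its absolute diameter, bulk density, and the effective-diameter
#' inflation factor that accounts for the electrical double layer and
#' hydration shell in packing calculations.
#'
#' @param diameter_abs Absolute particle diameter in nm.
#' @param density Bulk density in g cm^-3. Polystyrene latex spheres are
#'   typically 1.05 g cm^-3.
#' @param eff_factor Dimensionless inflation factor applied to the diameter
#'   for packing geometry (default 1.1, i.e. a 100 nm particle packs as a
#'   110 nm disk).
#' @param label Free-text label.
#' @return An object of class `particle_spec`.
#' @examples
#' ps100 <- particle_spec(100, 1.05, label = "PS(ø100 nm)")
#' particle_mass(ps100)      # ~5.49e-7 ng
#' effective_area(ps100)     # ~9503 nm^2
#' @export
particle_spec <- function(diameter_abs, density, eff_factor = 1.1, label = "") {
  stopifnot(is.numeric(diameter_abs), length(diameter_abs) == 1L,
            is.numeric(density), length(density) == 1L,
            is.numeric(eff_factor), length(eff_factor) == 1L)
  if (diameter_abs <= 0) stop("`diameter_abs` must be positive", call. = FALSE)
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  if (eff_factor < 1) stop("`eff_factor` must be >= 1", call. = FALSE)
  structure(
    list(diameter_abs = diameter_abs, density = density,
         eff_factor = eff_factor, label = label),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  diameter  %g nm (effective %g nm)\n",
              x$diameter_abs, x$diameter_abs * x$eff_factor))
  cat(sprintf("  density   %g g cm^-3\n", x$density))
  cat(sprintf("  mass      %.3g ng\n", particle_mass(x)))
  invisible(x)
}

#' Single-particle mass
#'
#' Mass of one particle treated as a solid sphere of the spec's absolute
#' diameter and density, returned in ng. A 100 nm sphere at 1.05 g cm^-3
#' weighs 5.49e-7 ng.
#'
#' @param spec A [particle_spec()].
#' @return Mass in ng.
#' @export
particle_mass <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  r_cm <- spec$diameter_abs / 2 * 1e-7          # nm -> cm
  vol_cm3 <- 4 / 3 * pi * r_cm^3
  spec$density * vol_cm3 * 1e9                  # g -> ng
}

#' Effective cross-sectional area of one particle
#'
#' The footprint used in packing calculations, `pi * (d_eff / 2)^2` with
#' `d_eff = eff_factor * diameter_abs`, in nm^2.
#'
#' @inheritParams particle_mass
#' @return Area in nm^2.
#' @export
effective_area <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  d_eff <- spec$eff_factor * spec$diameter_abs
  pi * (d_eff / 2)^2
}

#' Maximum number of particles an area can hold at the jamming limit
#'
#' For random sequential adsorption of equal disks the surface saturates at
#' coverage `theta_inf` (0.547 for disks), so an area `A` holds at most
#' `theta_inf * A / A_particle` disks. Returned as a real number; callers may
#' floor it.
#'
#' @param area_mm2 Available area in mm^2.
#' @param spec A [particle_spec()].
#' @param theta_inf Jamming coverage (default 0.547).
#' @return Expected maximum particle count (real-valued).
#' @export
max_packing_count <- function(area_mm2, spec, theta_inf = 0.547) {
  stopifnot(is.numeric(area_mm2), all(area_mm2 > 0))
  a_nm2 <- effective_area(spec)
  area_nm2 <- area_mm2 * 1e12
  theta_inf * area_nm2 / a_nm2
}

#' Equivalent diameter of an occupied area
#'
#' Diameter of the circle with area `a`: `2 * sqrt(a / pi)`. Used to express
#' the fitted per-particle occupied area (particle plus its strongly coupled
#' water) as a length.
#'
#' @param a_nm2 Occupied area per particle in nm^2.
#' @return Diameter in nm.
#' @export
d_rsa_from_area <- function(a_nm2) {
  stopifnot(is.numeric(a_nm2), all(a_nm2 > 0))
  2 * sqrt(a_nm2 / pi)
}
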