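# Fluorescence-depletion quantification: calibration curves, before/after
# concentrations, captured particle counts (or mass only, for heterogeneous
# size distributions), and film-area extrapolation.

#' Fit a fluorescence calibration curve
#'
#' Ordinary least-squares line through (concentration, intensity) standards,
#' with intercept (a blank at zero concentration is a standard). The default
#' standard set is five concentrations: 0, 0.025, 0.05, 0.075 and
#' 0.1 g L^-1.
#'
#' @param standards A data frame with columns `concentration` (g L^-1) and
#'   `intensity` (arbitrary units); at least 3 rows.
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "intensity") %in% names(standards)))
  if (nrow(standards) < 3) {
    stop("need at least 3 calibration standards", call. = FALSE)
  }
  if (stats::var(standards$concentration) == 0) {
    stop("calibration standards have zero concentration variance", call. = FALSE)
  }
  fit <- stats::lm(intensity ~ concentration, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    warning("non-positive calibration slope; the curve cannot be inverted",
            call. = FALSE)
  }
  # direct r^2 (avoids summary.lm's perfect-fit warning on exact standards)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$intensity - mean(standards$intensity))^2)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, fit = fit,
         standards = tibble::as_tibble(standards)),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> I = %.4g * c + %.4g  (r^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  out <- tibble::as_tibble(summary(x$fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = nrow(x$standards))
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$concentration, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(x = expression(concentration ~ (g ~ L^-1)),
                  y = "fluorescence intensity (a.u.)",
                  title = sprintf("Calibration: slope %.3g, r^2 = %.4f",
                                  object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Invert a calibration curve
#'
#' `c = (I - intercept) / slope`; negative results are clipped to zero with
#' a warning (readings below the blank).
#'
#' @param curve A [fit_calibration()] result.
#' @param intensity Intensity reading(s).
#' @return Concentration(s) in g L^-1.
#' @export
concentration_from_intensity <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope is not positive", call. = FALSE)
  conc <- (intensity - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative concentration(s) clipped to 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Particles captured by a film, from fluorescence depletion
#'
#' Triplicate before/after intensity readings are averaged, converted to
#' concentrations through the calibration curve, and the depleted mass
#' `m_Tot = (c_before - c_after) * V` is divided by the single-particle
#' mass. The standard deviation of the count is propagated from the
#' triplicate spread of the concentration difference
#' (`SD(N) = V / m_particle * SD(delta c)`).
#'
#' @param intensity_before,intensity_after Intensity readings (vectors;
#'   triplicates in the standard protocol).
#' @param volume_ml Immersion volume in mL.
#' @param curve A [fit_calibration()] result.
#' @param spec A [particle_spec()]; the particle mass is computed from it
#'   (for 100 nm polystyrene at 1.05 g cm^-3, 5.49e-7 ng).
#' @param tol_negative Tolerated negative depletion, as a fraction of the
#'   before-concentration (default 0.05); beyond it an error is raised.
#' @return A list of class `capture_result`: `n_particles`, `sd_particles`,
#'   `mass_ng`, `sd_mass_ng`, `c_before`, `c_after` (g L^-1).
#' @export
captured_particles <- function(intensity_before, intensity_after, volume_ml,
                               curve, spec, tol_negative = 0.05) {
  res <- captured_mass(intensity_before, intensity_after, volume_ml, curve,
                       tol_negative = tol_negative)
  m_p <- particle_mass(spec)
  res$n_particles <- res$mass_ng / m_p
  res$sd_particles <- res$sd_mass_ng / m_p
  res
}

#' Mass captured by a film, from fluorescence depletion
#'
#' Mass-only quantification, `m_Tot = (c_before - c_after) * V`: the mode
#' used for heterogeneous particle populations (e.g. polyethylene with a
#' broad size distribution) where a single-particle mass is undefined and
#' particle counts are never reported.
#'
#' @inheritParams captured_particles
#' @return A list of class `capture_result` with `mass_ng`, `sd_mass_ng`,
#'   `c_before`, `c_after`.
#' @export
captured_mass <- function(intensity_before, intensity_after, volume_ml,
                          curve, tol_negative = 0.05) {
  stopifnot(is.numeric(intensity_before), is.numeric(intensity_after),
            volume_ml > 0, inherits(curve, "calibration_curve"))
  cb <- concentration_from_intensity(curve, intensity_before)
  ca <- concentration_from_intensity(curve, intensity_after)
  c_before <- mean(cb)
  c_after <- mean(ca)
  dc <- c_before - c_after
  if (dc < -tol_negative * max(c_before, .Machine$double.eps)) {
    stop("negative depletion beyond tolerance: after-concentration exceeds before",
         call. = FALSE)
  }
  dc <- max(dc, 0)
  # SD of the difference from the paired/unpaired triplicate spread
  sd_dc <- sqrt(stats::var(cb) / length(cb) + stats::var(ca) / length(ca))
  # g/L * mL = mg; -> ng
  mass_ng <- dc * volume_ml * 1e6
  sd_mass_ng <- sd_dc * volume_ml * 1e6
  structure(list(mass_ng = mass_ng, sd_mass_ng = sd_mass_ng,
                 c_before = c_before, c_after = c_after,
                 volume_ml = volume_ml),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat("<capture_result>\n")
  cat(sprintf("  c: %.4g -> %.4g g/L in %g mL\n", x$c_before, x$c_after,
              x$volume_ml))
  cat(sprintf("  mass captured: %.4g +/- %.2g ng\n", x$mass_ng, x$sd_mass_ng))
  if (!is.null(x$n_particles)) {
    cat(sprintf("  particles:     %.4g +/- %.2g\n", x$n_particles,
                x$sd_particles))
  }
  invisible(x)
}

#' Film area needed to remove everything from a dispersion
#'
#' Divides the total amount (particles or mass) by the per-area capture
#' rate and rounds up to whole cm^2.
#'
#' @param total Total particles (or mass) to remove.
#' @param capture_per_area Capture rate per cm^2 of film, same unit as
#'   `total`.
#' @return Required area in whole cm^2 (ceiling, minimum 1).
#' @export
area_to_remove_all <- function(total, capture_per_area) {
  stopifnot(is.numeric(total), is.numeric(capture_per_area))
  if (any(capture_per_area <= 0)) {
    stop("`capture_per_area` must be positive", call. = FALSE)
  }
  pmax(ceiling(total / capture_per_area), 1)
}

#' Full fluorescence-depletion workflow on tabular input
#'
#' Fits the calibration, converts before/after readings, and reports the
#' captured amount; with a [particle_spec()] the particle count is included,
#' otherwise the report is mass-only.
#'
#' @param standards Data frame with `concentration`, `intensity`.
#' @param readings Data frame with columns `when` (`"before"`/`"after"`)
#'   and `intensity`.
#' @param volume_ml Immersion volume, mL.
#' @param spec Optional [particle_spec()] for particle counts.
#' @return A `capture_result` with the calibration attached as
#'   `attr(, "calibration")`.
#' @export
quantify_fluorescence <- function(standards, readings, volume_ml, spec = NULL) {
  stopifnot(is.data.frame(readings),
            all(c("when", "intensity") %in% names(readings)))
  curve <- fit_calibration(standards)
  before <- readings$intensity[readings$when == "before"]
  after <- readings$intensity[readings$when == "after"]
  if (length(before) == 0 || length(after) == 0) {
    stop("`readings` must contain both 'before' and 'after' rows", call. = FALSE)
  }
  res <- if (is.null(spec)) {
    captured_mass(before, after, volume_ml, curve)
  } else {
    captured_particles(before, after, volume_ml, curve, spec)
  }
  attr(res, "calibration") <- curve
  res
}
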