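# QCM-D trace handling: Sauerbrey conversion, dissipation validity check,
# rescaling against image-analysis dry mass, coupled-water factors and the
# assembly of per-system coverage summaries.

#' QCM-D sensor description
#'
#' @param sauerbrey_C Mass-sensitivity constant in ng cm^-2 Hz^-1
#'   (17.7 for a 5 MHz AT-cut crystal).
#' @param sensor_diameter Active sensor diameter in mm (default 9).
#' @param fundamental Fundamental frequency in MHz (default 5).
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(sauerbrey_C = 17.7, sensor_diameter = 9, fundamental = 5) {
  stopifnot(sauerbrey_C > 0, sensor_diameter > 0, fundamental > 0)
  structure(list(sauerbrey_C = sauerbrey_C, sensor_diameter = sensor_diameter,
                 fundamental = fundamental),
            class = "sensor_spec")
}

.check_overtone <- function(n) {
  if (length(n) != 1 || n %% 2 == 0 || n < 1) {
    stop("overtone `n` must be a single odd positive integer", call. = FALSE)
  }
}

#' Sauerbrey mass from a frequency shift
#'
#' Converts a frequency shift at overtone `n` to an areal mass,
#' `delta_m = -(C / n) * delta_f` for a raw shift, or `-C * delta_f` for a
#' shift already divided by the overtone number. The normalization
#' convention must be declared; it is never guessed from magnitudes.
#'
#' @param delta_f Frequency shift(s) in Hz; negative for mass uptake.
#' @param n Odd overtone number (default 5, the analysis overtone).
#' @param sensor A [sensor_spec()].
#' @param normalization `"raw"` or `"normalized_by_n"` — whether `delta_f`
#'   is the raw shift or the shift divided by `n`.
#' @return Areal mass in ng cm^-2, vectorised over `delta_f`.
#' @export
sauerbrey_mass <- function(delta_f, n = 5, sensor = sensor_spec(),
                           normalization = c("raw", "normalized_by_n")) {
  normalization <- match.arg(normalization)
  .check_overtone(n)
  stopifnot(inherits(sensor, "sensor_spec"))
  if (normalization == "raw") {
    -(sensor$sauerbrey_C / n) * delta_f
  } else {
    -sensor$sauerbrey_C * delta_f
  }
}

#' Does a dissipation channel satisfy the Sauerbrey validity bound?
#'
#' The Sauerbrey relation holds for rigid films where dissipation changes
#' stay below 1e-5 (i.e. 10 in the conventional 1e-6 units). Particle
#' layers with substantial coupled water typically violate this, which is
#' why the hydrated mass must be rescaled against an independent dry mass.
#'
#' @param delta_D Dissipation shift(s) in units of 1e-6.
#' @param limit Validity bound in the same units (default 10).
#' @return `TRUE` if `max(abs(delta_D)) < limit`.
#' @export
dissipation_ok <- function(delta_D, limit = 10) {
  stopifnot(is.numeric(delta_D), length(delta_D) >= 1)
  max(abs(delta_D)) < limit
}

#' Rescale an acoustic mass trace to the dry mass
#'
#' The acoustic (hydrated) mass trace `m(t)` is rescaled so its maximum
#' equals the dry surface mass density determined by image analysis:
#' `Gamma(t) = m(t) * Gamma_max_IA / max(m(t))`. This removes the coupled
#' water from the trace under the assumption that hydration is proportional
#' to the adsorbed amount.
#'
#' @param mass Hydrated areal mass series in ng cm^-2.
#' @param gamma_max_ia Dry surface mass density at the end of adsorption
#'   from image analysis, ng cm^-2.
#' @return Rescaled dry-mass series; its maximum equals `gamma_max_ia`.
#' @export
rescale_to_dry_mass <- function(mass, gamma_max_ia) {
  stopifnot(is.numeric(mass), length(mass) >= 1, gamma_max_ia >= 0)
  m_max <- max(mass)
  if (m_max <= 0) stop("mass trace has no positive maximum", call. = FALSE)
  mass * gamma_max_ia / m_max
}

#' Coupled-water factor from QCM-D vs image-analysis frequency shifts
#'
#' The dry mass from image analysis is translated into the frequency shift
#' it would have produced, `delta_f(IA) = -Gamma_IA * n / C`, and compared
#' with the measured shift: `factor = delta_f(QCM) / delta_f(IA)`. A factor
#' of 3.2 means the acoustically sensed mass is 3.2x the dry particle mass,
#' i.e. roughly 2/3 of the sensed mass is coupled water.
#'
#' @param delta_f_qcm Measured frequency shift at overtone `n`, Hz.
#' @param gamma_ia Dry surface mass density from image analysis, ng cm^-2.
#' @param n Odd overtone number (default 5).
#' @param sensor A [sensor_spec()].
#' @param normalization Convention of `delta_f_qcm` (`"raw"` default).
#' @return A list with `factor` (unrounded), `factor_reported` (1 decimal)
#'   and `delta_f_ia` (the theoretical raw shift in Hz).
#' @export
coupled_water_factor <- function(delta_f_qcm, gamma_ia, n = 5,
                                 sensor = sensor_spec(),
                                 normalization = c("raw", "normalized_by_n")) {
  normalization <- match.arg(normalization)
  .check_overtone(n)
  if (gamma_ia <= 0) stop("`gamma_ia` must be positive", call. = FALSE)
  f_qcm_raw <- if (normalization == "raw") delta_f_qcm else delta_f_qcm * n
  f_ia <- -gamma_ia * n / sensor$sauerbrey_C
  if (sign(f_qcm_raw) != sign(f_ia)) {
    stop("QCM and image-analysis frequency shifts have opposite signs",
         call. = FALSE)
  }
  fac <- f_qcm_raw / f_ia
  list(factor = fac, factor_reported = round(fac, 1), delta_f_ia = f_ia)
}

#' Solid/air surface coverage from the dry mass
#'
#' Coverage at the solid/gas interface at the end of adsorption:
#' the particle number density `Gamma_IA / m` times the effective
#' cross-section `pi (d_eff/2)^2`.
#'
#' @param gamma_ia Dry surface mass density, ng cm^-2.
#' @param m Single-particle mass, ng.
#' @param spec A [particle_spec()] supplying the effective diameter.
#' @return Dimensionless coverage.
#' @export
coverage_solid_air <- function(gamma_ia, m, spec) {
  stopifnot(gamma_ia >= 0, m > 0, inherits(spec, "particle_spec"))
  a_eff_cm2 <- effective_area(spec) * NM2_TO_CM2
  (gamma_ia / m) * a_eff_cm2
}

#' Fractional surface coverage relative to the jamming limit
#'
#' @param theta_air Solid/air coverage.
#' @param theta_inf Jamming coverage (default 0.547).
#' @return `theta_air / theta_inf`.
#' @export
fractional_coverage <- function(theta_air, theta_inf = 0.547) {
  stopifnot(theta_inf > 0)
  theta_air / theta_inf
}

#' Total adsorbed mass on the sensor
#'
#' @param gamma Surface mass density, ng cm^-2.
#' @param sensor A [sensor_spec()]; the 9 mm active diameter gives an area
#'   of ~0.64 cm^2.
#' @return Mass in ng.
#' @export
sensor_total_mass <- function(gamma, sensor = sensor_spec()) {
  stopifnot(is.numeric(gamma), all(gamma >= 0), inherits(sensor, "sensor_spec"))
  d_cm <- sensor$sensor_diameter / 10
  gamma * pi * (d_cm / 2)^2
}

#' Read a QCM-D trace from delimited text
#'
#' Expects a CSV with a `time_s` column and per-overtone columns `f1..f11`
#' and `D1..D11` (missing overtones allowed). The normalization convention
#' of the frequency columns must be declared explicitly; files of unknown
#' origin carry no reliable convention.
#'
#' @param path CSV file path.
#' @param normalization `"raw"` or `"normalized_by_n"`.
#' @return A tibble with attribute `normalization`; class `qcmd_trace`.
#' @export
read_qcmd <- function(path, normalization = c("raw", "normalized_by_n")) {
  normalization <- match.arg(normalization)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing `time_s` column", call. = FALSE)
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "normalization") <- normalization
  class(out) <- c("qcmd_trace", class(out))
  message("QCM-D trace read with normalization = '", normalization,
          "' (declared, not inferred)")
  out
}

#' Write a QCM-D trace as CSV
#'
#' @param trace A data frame with `time_s` and channel columns.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_qcmd <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Endpoint of a trace after the rinse
#'
#' The endpoint value of a channel is the mean over the final `window`
#' seconds, which is robust to spikes at the very end of the record.
#'
#' @param time_s Time vector, s.
#' @param values Channel values.
#' @param window Averaging window in s (default 60).
#' @return Scalar endpoint value.
#' @export
trace_endpoint <- function(time_s, values, window = 60) {
  stopifnot(length(time_s) == length(values), length(time_s) >= 1)
  sel <- time_s >= max(time_s) - window
  mean(values[sel])
}

#' Assemble a coverage summary for one substrate/particle system
#'
#' Combines the QCM-D endpoint, the image-analysis dry mass and the fitted
#' kinetic parameters into one record of derived quantities: the
#' coupled-water factor, solid/air and solid/liquid coverages, the occupied
#' area and its equivalent diameter, and the fractional coverage relative
#' to the jamming limit. Presentation rounding (coverages and d_RSA to 2
#' significant figures, water factor to 1 decimal) applies only in
#' `print()`; the stored values are unrounded.
#'
#' @param substrate,particle Labels.
#' @param delta_f5 Frequency-shift endpoint at the 5th overtone, Hz.
#' @param delta_D5 Dissipation endpoint, 1e-6 units.
#' @param gamma_max_ia Dry surface mass density from image analysis, ng cm^-2.
#' @param a_nm2 Fitted occupied area per particle, nm^2.
#' @param k_a Fitted adsorption rate coefficient, cm s^-1.
#' @param m Single-particle mass, ng.
#' @param spec A [particle_spec()].
#' @param sensor A [sensor_spec()].
#' @param theta_inf Jamming coverage (default 0.547).
#' @param normalization Convention of `delta_f5`.
#' @return A one-row tibble of class `coverage_summary`.
#' @export
coverage_summary <- function(substrate, particle, delta_f5, delta_D5,
                             gamma_max_ia, a_nm2, k_a, m, spec,
                             sensor = sensor_spec(), theta_inf = 0.547,
                             normalization = c("raw", "normalized_by_n")) {
  normalization <- match.arg(normalization)
  if (gamma_max_ia == 0) {
    wf <- list(factor = NA_real_, factor_reported = NA_real_)
    theta_air <- 0
    theta_liq <- 0
  } else {
    wf <- coupled_water_factor(delta_f5, gamma_max_ia, n = 5, sensor = sensor,
                               normalization = normalization)
    theta_air <- coverage_solid_air(gamma_max_ia, m, spec)
    theta_liq <- suppressWarnings(surface_coverage(gamma_max_ia, a_nm2, m))
  }
  out <- tibble::tibble(
    substrate = substrate, particle = particle,
    delta_f5 = delta_f5, delta_D5 = delta_D5,
    water_factor = wf$factor,
    gamma_max = gamma_max_ia,
    theta_air = theta_air,
    theta_liquid = theta_liq,
    a_nm2 = a_nm2,
    d_rsa = d_rsa_from_area(a_nm2),
    k_a = k_a,
    fractional_coverage = fractional_coverage(theta_air, theta_inf)
  )
  class(out) <- c("coverage_summary", class(out))
  out
}

#' @export
print.coverage_summary <- function(x, ...) {
  y <- dplyr::mutate(
    tibble::as_tibble(x),
    water_factor = round(.data$water_factor, 1),
    theta_air = signif(.data$theta_air, 2),
    theta_liquid = signif(.data$theta_liquid, 2),
    d_rsa = signif(.data$d_rsa, 2),
    fractional_coverage = signif(.data$fractional_coverage, 2)
  )
  print(y)
  invisible(x)
}
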