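# End-to-end plumbing: dataset synthesis to disk, and the full
# QCM-D + image-analysis + RSA-fit pipeline that assembles a coverage
# summary for one substrate/particle system.

#' Write a complete synthetic dataset to a directory
#'
#' Generates a QCM-D trace, `n_images` SEM-like images and a fluorescence
#' dataset from one scenario and writes them in the formats the readers
#' consume (CSV and PNG), together with the ground truth and a scenario
#' echo. Deterministic for a fixed scenario seed (per-image seeds are
#' derived as `seed + image index`).
#'
#' @param scn A [scenario()].
#' @param dir Output directory (created if missing).
#' @param target_coverage Coverage for the SEM images (default: the
#'   coverage implied by the scenario's kinetics endpoint, capped at 0.45).
#' @param n_images Number of SEM fields (default 3, the usual replication).
#' @param capture_fraction Capture fraction for the fluorescence dataset
#'   (default 0.5).
#' @return `dir`, invisibly. Side effect: files `qcmd.csv`,
#'   `sem_<i>.png`, `sem_truth.csv`, `fluor_standards.csv`,
#'   `fluor_readings.csv`, `scenario.txt`, `truth.txt`.
#' @export
synthesize_dataset <- function(scn, dir, target_coverage = NULL,
                               n_images = 3, capture_fraction = 0.5) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  q <- generate_qcmd_trace(scn)
  write_qcmd(q$trace, file.path(dir, "qcmd.csv"))

  if (is.null(target_coverage)) {
    gam_end <- q$truth$gamma$gamma[nrow(q$truth$gamma)]
    target_coverage <- min(coverage_solid_air(gam_end, scn$m, scn$particle), 0.45)
  }
  truth_rows <- list()
  for (i in seq_len(n_images)) {
    scn_i <- scn
    scn_i$seed <- scn$seed + i
    g <- generate_sem_image(scn_i, target_coverage)
    write_sem_image(g$image, file.path(dir, sprintf("sem_%d.png", i)))
    truth_rows[[i]] <- tibble::tibble(image = i, n_total = g$truth$n_total,
                                      coverage = g$truth$coverage,
                                      seed = scn_i$seed)
  }
  utils::write.csv(dplyr::bind_rows(truth_rows),
                   file.path(dir, "sem_truth.csv"), row.names = FALSE)

  fl <- generate_fluorescence_dataset(scn, capture_fraction)
  utils::write.csv(fl$standards, file.path(dir, "fluor_standards.csv"),
                   row.names = FALSE)
  utils::write.csv(fl$readings, file.path(dir, "fluor_readings.csv"),
                   row.names = FALSE)

  scn_flat <- scn
  scn_flat$particle <- NULL
  writeLines(c(
    sprintf("%s: %s", names(scn_flat), vapply(scn_flat, format, "")),
    sprintf("particle_diameter_nm: %g", scn$particle$diameter_abs),
    sprintf("particle_density: %g", scn$particle$density),
    sprintf("particle_eff_factor: %g", scn$particle$eff_factor)
  ), file.path(dir, "scenario.txt"))
  writeLines(c(
    sprintf("water_factor: %g", scn$water_factor),
    sprintf("gamma_end_dry: %.6g", q$truth$gamma$gamma[nrow(q$truth$gamma)]),
    sprintf("capture_fraction: %g", capture_fraction),
    sprintf("target_coverage: %.6g", target_coverage)
  ), file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Count particles across SEM fields and convert to a dry mass
#'
#' Runs threshold + detection on each image, averages the number density
#' over fields, and converts to a surface mass density with the
#' single-particle mass.
#'
#' @param images A list of [image_record()]s (or a single one).
#' @param spec A [particle_spec()] giving the expected diameter.
#' @param m Single-particle mass, ng (default 5.26e-7, the image-analysis
#'   value for 100 nm polystyrene).
#' @param mode Cluster handling mode, see [detect_particles()].
#' @return A list: `gamma` (ng cm^-2), `density_mm2` (mean over fields),
#'   and a tibble `per_image` (counts, density and threshold per field).
#' @export
analyze_images <- function(images, spec, m = 5.26e-7, mode = "auto") {
  if (inherits(images, "image_record")) images <- list(images)
  stopifnot(length(images) >= 1, inherits(spec, "particle_spec"))
  per_image <- purrr::imap_dfr(images, function(img, i) {
    thr <- histogram_threshold(img)
    mask <- threshold_mask(img, threshold = thr)
    d_px <- spec$diameter_abs * spec$eff_factor / img$nm_per_px
    counts <- detect_particles(mask, d_px, mode = mode)
    tibble::tibble(image = i, threshold = thr,
                   n_singles = counts$n_singles,
                   particles_total = counts$particles_total,
                   mode = counts$mode,
                   density_mm2 = particle_density(counts, img))
  })
  density <- mean(per_image$density_mm2)
  list(gamma = surface_mass_density(density, m),
       density_mm2 = density, per_image = per_image)
}

#' Full capture analysis for one substrate/particle system
#'
#' The complete chain: image analysis gives the dry surface mass density;
#' the QCM-D trace endpoint gives the hydrated frequency shift and hence
#' the coupled-water factor; the acoustic mass trace is rescaled to the dry
#' mass and the RSA rate equation is fitted to recover the adsorption
#' coefficient and the occupied area per particle; all derived coverage
#' quantities are assembled into a [coverage_summary()] row.
#'
#' @param trace A QCM-D trace tibble with `time_s`, `f5`, `D5` (as from
#'   [read_qcmd()] or [generate_qcmd_trace()]).
#' @param images List of [image_record()]s (or a pre-computed
#'   [analyze_images()] result).
#' @param spec A [particle_spec()].
#' @param c Bulk concentration, ng cm^-3.
#' @param m Single-particle mass, ng.
#' @param substrate,particle_label Labels for the summary row.
#' @param sensor A [sensor_spec()].
#' @param normalization Frequency normalization of the trace; defaults to
#'   the trace's declared attribute.
#' @param fit_until_s Fit the kinetics only up to this time (default: the
#'   whole trace; pass the adsorption duration to exclude a rinse plateau).
#' @param mode Cluster handling for the image analysis.
#' @param multistart Number of fit starts (default 5).
#' @return A list with `summary` (a [coverage_summary()] row), `fit` (the
#'   [fit_rsa()] object), `image_analysis`, `sauerbrey_valid` and the
#'   rescaled dry-mass trace `gamma_trace`.
#' @export
analyze_capture <- function(trace, images, spec, c, m,
                            substrate = "substrate", particle_label = "particle",
                            sensor = sensor_spec(), normalization = NULL,
                            fit_until_s = NULL, mode = "auto", multistart = 5) {
  stopifnot(all(c("time_s", "f5") %in% names(trace)))
  if (is.null(normalization)) {
    normalization <- attr(trace, "normalization")
    if (is.null(normalization)) {
      stop("trace carries no normalization attribute; declare `normalization`",
           call. = FALSE)
    }
  }

  ia <- if (is.list(images) && !is.null(images$gamma)) images
        else analyze_images(images, spec, m = m, mode = mode)

  f5_end <- trace_endpoint(trace$time_s, trace$f5)
  d5_end <- if ("D5" %in% names(trace)) {
    trace_endpoint(trace$time_s, trace$D5)
  } else NA_real_
  valid <- if (is.na(d5_end)) NA else dissipation_ok(trace$D5)

  wf <- coupled_water_factor(f5_end, ia$gamma, n = 5, sensor = sensor,
                             normalization = normalization)

  mass_t <- sauerbrey_mass(trace$f5, n = 5, sensor = sensor,
                           normalization = normalization)
  gamma_t <- rescale_to_dry_mass(mass_t, ia$gamma)
  fit_df <- tibble::tibble(time_s = trace$time_s, gamma = gamma_t)
  if (!is.null(fit_until_s)) {
    fit_df <- dplyr::filter(fit_df, .data$time_s <= fit_until_s)
  }
  fit <- fit_rsa(fit_df, c = c, m = m, multistart = multistart)

  summary <- coverage_summary(
    substrate = substrate, particle = particle_label,
    delta_f5 = f5_end, delta_D5 = d5_end,
    gamma_max_ia = ia$gamma, a_nm2 = fit$a_nm2, k_a = fit$k_a,
    m = m, spec = spec, sensor = sensor,
    normalization = normalization)

  list(summary = summary, fit = fit, image_analysis = ia,
       sauerbrey_valid = valid, gamma_trace = fit_df)
}
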