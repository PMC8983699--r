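# Synthetic-data generators: every input the pipeline consumes, produced
# from a declared scenario with the ground truth emitted alongside.
# The generators emulate (i) hydrated QCM-D traces driven by RSA kinetics,
# (ii) SEM-like images of bright disks placed by hard-disk RSA on a noisy
# dark background, and (iii) linear fluorescence-concentration responses.

#' Declare a synthetic experiment scenario
#'
#' Bundles the particle, kinetics, hydration and noise settings that define
#' one synthetic experiment. Defaults mirror the reference adsorption
#' experiment: a 0.1 g L^-1 (1e5 ng cm^-3) dispersion of 100 nm polystyrene
#' flowed for ~1 h, adsorbing with k_a = 1e-5 cm s^-1 onto an area of
#' 6e4 nm^2 per particle, sensed with a coupled-water factor of 3.2.
#'
#' @param seed Integer seed; recorded in every output.
#' @param particle A [particle_spec()] (default 100 nm PS at 1.05 g cm^-3).
#' @param k_a Adsorption rate coefficient, cm s^-1.
#' @param a_nm2 Occupied area per particle, nm^2.
#' @param m Single-particle mass, ng (default: the image-analysis value
#'   5.26e-7 ng for 100 nm PS).
#' @param c Bulk concentration, ng cm^-3.
#' @param water_factor Hydrated/dry mass ratio sensed acoustically
#'   (default 3.2).
#' @param qcmd_noise_rel Relative (multiplicative) noise on the frequency
#'   trace (default 0.02).
#' @param duration_s Adsorption duration, s (default 3600).
#' @param dt_s Sampling interval, s (default 10).
#' @param delta_D5_end Dissipation endpoint in 1e-6 units for the
#'   proportional placeholder dissipation channel (default 21).
#' @param image_width_px,image_height_px Synthetic image geometry
#'   (defaults 2048 x 1536).
#' @param nm_per_px Image calibration (default 2 nm/px).
#' @param background_mean,background_sd Gaussian background of the image on
#'   the 8-bit scale (defaults 30 and 8).
#' @param particle_level Gray level of particle interiors (default 220).
#' @param fluor_slope,fluor_intercept Calibration line of the synthetic
#'   fluorophore (intensity = slope * c + intercept).
#' @param fluor_sigma Additive intensity noise, a.u. (default 5).
#' @param volume_ml Immersion volume for depletion experiments (default 20).
#' @return An object of class `synthetic_scenario`.
#' @export
scenario <- function(seed = 1L,
                     particle = particle_spec(100, 1.05, label = "PS(100 nm)"),
                     k_a = 1e-5, a_nm2 = 6e4, m = 5.26e-7, c = 1e5,
                     water_factor = 3.2, qcmd_noise_rel = 0.02,
                     duration_s = 3600, dt_s = 10, delta_D5_end = 21,
                     image_width_px = 2048, image_height_px = 1536,
                     nm_per_px = 2, background_mean = 30, background_sd = 8,
                     particle_level = 220,
                     fluor_slope = 1e4, fluor_intercept = 50, fluor_sigma = 5,
                     volume_ml = 20) {
  stopifnot(inherits(particle, "particle_spec"), water_factor >= 1,
            qcmd_noise_rel >= 0, duration_s > 0, dt_s > 0)
  structure(
    list(seed = as.integer(seed), particle = particle,
         k_a = k_a, a_nm2 = a_nm2, m = m, c = c,
         water_factor = water_factor, qcmd_noise_rel = qcmd_noise_rel,
         duration_s = duration_s, dt_s = dt_s, delta_D5_end = delta_D5_end,
         image_width_px = image_width_px, image_height_px = image_height_px,
         nm_per_px = nm_per_px, background_mean = background_mean,
         background_sd = background_sd, particle_level = particle_level,
         fluor_slope = fluor_slope, fluor_intercept = fluor_intercept,
         fluor_sigma = fluor_sigma, volume_ml = volume_ml),
    class = "synthetic_scenario")
}

#' Generate a hydrated QCM-D trace with known ground truth
#'
#' Integrates the RSA rate equation for the scenario's kinetics, multiplies
#' by the coupled-water factor to obtain the acoustically sensed hydrated
#' mass, converts it to a raw 5th-overtone frequency shift through the
#' Sauerbrey relation, and adds multiplicative Gaussian noise. A noiseless
#' 10-minute rinse plateau is appended. The dissipation channel is a
#' proportional placeholder (scaled to reach `delta_D5_end` at the
#' endpoint); it carries no viscoelastic physics and is meant only to
#' exercise the validity flag.
#'
#' @param scn A [scenario()].
#' @param sensor A [sensor_spec()].
#' @return A list with `trace` (tibble `time_s`, `f5`, `D5`, raw
#'   normalization, class `qcmd_trace`) and `truth` (the noiseless dry
#'   `gamma` series, the kinetics, water factor and seed).
#' @export
generate_qcmd_trace <- function(scn, sensor = sensor_spec()) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  kin <- rsa_kinetics(scn$k_a, scn$a_nm2, scn$m, scn$c)
  times <- seq(0, scn$duration_s, by = scn$dt_s)
  dry <- integrate_rsa(kin, times)
  hydrated <- dry$gamma * scn$water_factor
  f5_clean <- -hydrated * 5 / sensor$sauerbrey_C
  noise <- stats::rnorm(length(f5_clean), 0, scn$qcmd_noise_rel)
  f5 <- f5_clean * (1 + noise)
  D5 <- scn$delta_D5_end * hydrated / max(hydrated)

  rinse_t <- seq(scn$duration_s + scn$dt_s, scn$duration_s + 600,
                 by = scn$dt_s)
  trace <- tibble::tibble(
    time_s = c(times, rinse_t),
    f5 = c(f5, rep(f5_clean[length(f5_clean)], length(rinse_t))),
    D5 = c(D5, rep(D5[length(D5)], length(rinse_t)))
  )
  attr(trace, "normalization") <- "raw"
  class(trace) <- c("qcmd_trace", class(trace))
  list(trace = trace,
       truth = list(gamma = dry, kinetics = kin,
                    water_factor = scn$water_factor, seed = scn$seed))
}

# sequential hard-disk insertion against an existing center set; R-level,
# used for image generation where counts are modest
.place_disks <- function(n_new, existing, diameter, xlim, ylim,
                         max_tries = 2e5) {
  xs <- existing$x
  ys <- existing$y
  out_x <- numeric(0)
  out_y <- numeric(0)
  d2 <- diameter^2
  tries <- 0
  while (length(out_x) < n_new && tries < max_tries) {
    tries <- tries + 1
    x <- stats::runif(1, xlim[1], xlim[2])
    y <- stats::runif(1, ylim[1], ylim[2])
    if (length(xs) == 0 || all((x - xs)^2 + (y - ys)^2 >= d2)) {
      xs <- c(xs, x); ys <- c(ys, y)
      out_x <- c(out_x, x); out_y <- c(out_y, y)
    }
  }
  if (length(out_x) < n_new) {
    stop("unreachable coverage target: could not place all disks", call. = FALSE)
  }
  tibble::tibble(x = out_x, y = out_y)
}

#' Generate an SEM-like image of RSA-deposited particles
#'
#' Places non-overlapping disks of the particle's effective diameter by
#' random sequential adsorption to the requested coverage (centers confined
#' one radius from the image edges, so no particle is clipped), optionally
#' injects touching triplet clusters, and renders bright anti-aliased disks
#' (Gaussian point-spread blur, sigma 1 px) on a noisy dark background.
#'
#' @param scn A [scenario()].
#' @param target_coverage Fractional area coverage to plant (<= 0.45).
#' @param cluster_fraction Fraction of particles placed as touching
#'   triplets (default 0).
#' @return A list with `image` (an [image_record()]) and `truth` (planted
#'   centers in nm, counts of singles and triplets, total count, disk
#'   diameter, seed).
#' @export
generate_sem_image <- function(scn, target_coverage, cluster_fraction = 0) {
  stopifnot(inherits(scn, "synthetic_scenario"),
            target_coverage >= 0, cluster_fraction >= 0, cluster_fraction <= 1)
  if (target_coverage > 0.45) {
    stop("`target_coverage` above 0.45 is not reachable by sequential insertion",
         call. = FALSE)
  }
  set.seed(scn$seed)
  W <- scn$image_width_px * scn$nm_per_px
  H <- scn$image_height_px * scn$nm_per_px
  d <- scn$particle$diameter_abs * scn$particle$eff_factor
  r <- d / 2
  disk_area <- pi * r^2
  n_total <- round(target_coverage * W * H / disk_area)
  n_trip <- floor(cluster_fraction * n_total / 3)
  n_single <- n_total - 3 * n_trip

  centers <- tibble::tibble(x = numeric(0), y = numeric(0))
  # triplets first: three mutually touching disks in an equilateral triangle
  if (n_trip > 0) {
    offs <- rbind(c(0, 0), c(d, 0), c(d / 2, d * sqrt(3) / 2))
    placed <- 0
    tries <- 0
    while (placed < n_trip && tries < 1e5) {
      tries <- tries + 1
      cx <- stats::runif(1, r, W - r - d)
      cy <- stats::runif(1, r, H - r - d)
      xs <- cx + offs[, 1]
      ys <- cy + offs[, 2]
      ok <- TRUE
      if (nrow(centers) > 0) {
        for (k in 1:3) {
          if (any((xs[k] - centers$x)^2 + (ys[k] - centers$y)^2 < d^2 * 0.999)) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) {
        centers <- dplyr::bind_rows(centers, tibble::tibble(x = xs, y = ys))
        placed <- placed + 1
      }
    }
    if (placed < n_trip) {
      stop("unreachable coverage target: could not place all clusters",
           call. = FALSE)
    }
  }
  if (n_single > 0) {
    singles <- .place_disks(n_single, centers, d, c(r, W - r), c(r, H - r))
    centers <- dplyr::bind_rows(centers, singles)
  }

  # render: anti-aliased disks + Gaussian PSF blur + Gaussian background
  nr <- scn$image_height_px
  nc <- scn$image_width_px
  fg <- matrix(0, nr, nc)
  r_px <- r / scn$nm_per_px
  if (nrow(centers) > 0) {
    cx_px <- centers$x / scn$nm_per_px + 0.5
    cy_px <- centers$y / scn$nm_per_px + 0.5
    pad <- ceiling(r_px) + 2
    for (i in seq_len(nrow(centers))) {
      cols <- max(1, floor(cx_px[i] - pad)):min(nc, ceiling(cx_px[i] + pad))
      rows <- max(1, floor(cy_px[i] - pad)):min(nr, ceiling(cy_px[i] + pad))
      dist <- sqrt(outer((rows - cy_px[i])^2, (cols - cx_px[i])^2, "+"))
      cover <- pmin(pmax(r_px - dist + 0.5, 0), 1)   # anti-aliased edge
      fg[rows, cols] <- pmax(fg[rows, cols], cover * scn$particle_level)
    }
    fg <- EBImage::gblur(fg, sigma = 1)
  }
  bg <- matrix(stats::rnorm(nr * nc, scn$background_mean, scn$background_sd),
               nr, nc)
  px <- pmin(pmax(round(pmax(fg, 0) + bg), 0), 255)

  list(
    image = image_record(px, scn$nm_per_px,
                         provenance = sprintf("synthetic seed %d", scn$seed)),
    truth = list(centers = centers, n_total = nrow(centers),
                 n_singles = n_single, n_triplets = n_trip,
                 disk_diameter_nm = d, seed = scn$seed,
                 coverage = nrow(centers) * disk_area / (W * H))
  )
}

#' Generate a fluorescence calibration/depletion dataset
#'
#' Standards at the five calibration concentrations (0, 0.025, 0.05, 0.075,
#' 0.1 g L^-1) and triplicate before/after readings for a depletion
#' experiment in which the film captures `true_capture_fraction` of the
#' particles, all through a linear intensity model with additive Gaussian
#' noise.
#'
#' @param scn A [scenario()].
#' @param true_capture_fraction Fraction of the dispersed mass captured,
#'   in `[0, 1]`.
#' @param c0 Starting concentration, g L^-1 (default 0.1).
#' @param n_replicates Readings per condition (default 3).
#' @return A list with `standards` (tibble), `readings` (tibble with
#'   `when`, `intensity`) and `truth` (capture fraction, concentrations,
#'   captured mass in ng, volume, seed).
#' @export
generate_fluorescence_dataset <- function(scn, true_capture_fraction,
                                          c0 = 0.1, n_replicates = 3) {
  stopifnot(inherits(scn, "synthetic_scenario"),
            true_capture_fraction >= 0, true_capture_fraction <= 1)
  set.seed(scn$seed)
  conc <- c(0, 0.025, 0.05, 0.075, 0.1)
  standards <- tibble::tibble(
    concentration = conc,
    intensity = scn$fluor_intercept + scn$fluor_slope * conc +
      stats::rnorm(length(conc), 0, scn$fluor_sigma)
  )
  c_after <- c0 * (1 - true_capture_fraction)
  mk <- function(cc) {
    scn$fluor_intercept + scn$fluor_slope * cc +
      stats::rnorm(n_replicates, 0, scn$fluor_sigma)
  }
  readings <- tibble::tibble(
    when = rep(c("before", "after"), each = n_replicates),
    intensity = c(mk(c0), mk(c_after))
  )
  list(standards = standards, readings = readings,
       truth = list(capture_fraction = true_capture_fraction,
                    c_before = c0, c_after = c_after,
                    mass_captured_ng = (c0 - c_after) * scn$volume_ml * 1e6,
                    volume_ml = scn$volume_ml, seed = scn$seed))
}
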