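# Monte Carlo random sequential adsorption of equal hard disks on a square
# domain. Verifies the cited jamming coverage for disks (0.547) and supplies
# ground-truth configurations to the synthetic image generator.

#' Simulate random sequential adsorption of equal disks
#'
#' Sequential uniform-random insertion attempts in a square box; an attempt
#' is accepted iff the disk overlaps no previously accepted disk. With
#' periodic boundaries distances are minimum-image; in a hard-walled box
#' centers are confined to at least one radius from the walls
#' (minus-sampling of positions) so bulk coverage is unbiased. Deterministic
#' for a fixed seed.
#'
#' @param box_size Side length of the square box (nm, or any unit consistent
#'   with `disk_diameter`).
#' @param disk_diameter Disk diameter, same unit as `box_size`.
#' @param max_attempts Number of insertion attempts. Defaults to the number
#'   needed to reach dimensionless time `tau = 200` (see Details).
#' @param periodic Use periodic boundary conditions (default `TRUE`).
#' @param seed Integer seed recorded in the configuration.
#' @param record_every Record the accepted-disk count every this many
#'   attempts (default: 200 history points over the run).
#' @param tau_max If `max_attempts` is `NULL`, run until dimensionless time
#'   `tau = attempts * disk area / box area` reaches this value (default 200).
#' @return An object of class `rsa_deposition`: a list with `centers`
#'   (tibble of x, y), `box_size`, `disk_diameter`, `periodic`, `seed`,
#'   `attempts_made` and `history` (tibble of attempts, tau, n, coverage).
#' @export
simulate_rsa <- function(box_size, disk_diameter, max_attempts = NULL,
                         periodic = TRUE, seed = 1L, record_every = NULL,
                         tau_max = 200) {
  stopifnot(box_size > 0, disk_diameter > 0)
  if (periodic && box_size < disk_diameter) {
    stop("periodic box must be at least one disk diameter wide", call. = FALSE)
  }
  disk_area <- pi * (disk_diameter / 2)^2
  box_area <- box_size^2
  if (is.null(max_attempts)) {
    max_attempts <- ceiling(tau_max * box_area / disk_area)
  }
  stopifnot(max_attempts > 0)
  if (!periodic && box_size < disk_diameter) {
    warning("box smaller than one disk; returning an empty configuration",
            call. = FALSE)
  }
  if (is.null(record_every)) record_every <- max(1, floor(max_attempts / 200))

  set.seed(seed)
  raw <- rsa_deposit_cpp(box_size, disk_diameter, max_attempts,
                         periodic, record_every)
  history <- tibble::tibble(
    attempts = raw$rec_attempts,
    tau = raw$rec_attempts * disk_area / box_area,
    n = raw$rec_n,
    coverage = raw$rec_n * disk_area / box_area
  )
  structure(
    list(centers = tibble::tibble(x = raw$x, y = raw$y),
         box_size = box_size, disk_diameter = disk_diameter,
         periodic = periodic, seed = seed,
         attempts_made = raw$attempts, history = history),
    class = "rsa_deposition"
  )
}

#' @export
print.rsa_deposition <- function(x, ...) {
  cat(sprintf("<rsa_deposition> %d disks of d = %g in a %g x %g box (%s, seed %d)\n",
              nrow(x$centers), x$disk_diameter, x$box_size, x$box_size,
              if (x$periodic) "periodic" else "hard walls", x$seed))
  cat(sprintf("  attempts %g, coverage %.4f\n", x$attempts_made, coverage_of(x)))
  invisible(x)
}

#' Coverage of a deposition configuration
#'
#' Fraction of the box area occupied: `n * pi * (d/2)^2 / box^2`. Disk area
#' is not clipped at hard walls; centers are already confined to the bulk,
#' so the bulk coverage is unbiased.
#'
#' @param config An [simulate_rsa()] result.
#' @return Dimensionless coverage.
#' @export
coverage_of <- function(config) {
  stopifnot(inherits(config, "rsa_deposition"))
  nrow(config$centers) * pi * (config$disk_diameter / 2)^2 / config$box_size^2
}

#' Extrapolate the jamming coverage from a finite run
#'
#' Fits the late-time approach to jamming for disks,
#' `theta(tau) = theta_inf - b * tau^(-1/2)`, over the window
#' `tau >= tau_min` and returns the extrapolated saturation coverage with
#' its standard error.
#'
#' @param history A tibble with columns `tau` and `coverage` (as produced by
#'   [simulate_rsa()]), or an `rsa_deposition` object.
#' @param tau_min Lower edge of the late-time fitting window (default 50).
#' @return A list with `theta_inf`, `se`, `b`, `n_points` and the `fit` lm
#'   object.
#' @export
estimate_jamming <- function(history, tau_min = 50) {
  if (inherits(history, "rsa_deposition")) history <- history$history
  stopifnot(is.data.frame(history), all(c("tau", "coverage") %in% names(history)))
  late <- history[history$tau >= tau_min, , drop = FALSE]
  if (nrow(late) < 3) {
    stop("need at least 3 history points with tau >= ", tau_min, call. = FALSE)
  }
  fit <- stats::lm(coverage ~ I(tau^(-0.5)), data = late)
  co <- summary(fit)$coefficients
  list(theta_inf = unname(co[1, 1]), se = unname(co[1, 2]),
       b = -unname(co[2, 1]), n_points = nrow(late), fit = fit)
}

#' Verify the hard-core constraint of a configuration
#'
#' Pairwise check that no two centers are closer than one diameter
#' (minimum-image if periodic). Intended for post-hoc validation.
#'
#' @param config An [simulate_rsa()] result.
#' @return `TRUE` invisibly, or an error naming the violating pair.
#' @export
check_hard_core <- function(config) {
  stopifnot(inherits(config, "rsa_deposition"))
  cc <- config$centers
  n <- nrow(cc)
  if (n < 2) return(invisible(TRUE))
  dx <- outer(cc$x, cc$x, "-")
  dy <- outer(cc$y, cc$y, "-")
  if (config$periodic) {
    L <- config$box_size
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
  }
  dist2 <- dx^2 + dy^2
  diag(dist2) <- Inf
  bad <- which(dist2 < config$disk_diameter^2 * (1 - 1e-12), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("hard-core violation between disks %d and %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a deposition configuration as delimited text
#'
#' Serialises the center list with a `#`-prefixed header carrying box size,
#' diameter, boundary type and seed, one `x,y` pair per line.
#'
#' @param config An [simulate_rsa()] result.
#' @param path Output file path.
#' @return `path` invisibly ([write_deposition()]); an `rsa_deposition`
#'   ([read_deposition()]) with an empty history.
#' @export
write_deposition <- function(config, path) {
  stopifnot(inherits(config, "rsa_deposition"))
  header <- sprintf("# box_size=%.17g diameter=%.17g periodic=%d seed=%d attempts=%g",
                    config$box_size, config$disk_diameter,
                    as.integer(config$periodic), config$seed,
                    config$attempts_made)
  lines <- c(header, "x,y",
             sprintf("%.17g,%.17g", config$centers$x, config$centers$y))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_deposition
#' @export
read_deposition <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.e+]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  body <- utils::read.csv(text = lines[-1])
  structure(
    list(centers = tibble::as_tibble(body),
         box_size = get("box_size"), disk_diameter = get("diameter"),
         periodic = get("periodic") == 1, seed = as.integer(get("seed")),
         attempts_made = get("attempts"),
         history = tibble::tibble(attempts = numeric(), tau = numeric(),
                                  n = numeric(), coverage = numeric())),
    class = "rsa_deposition"
  )
}

#' Pooled jamming estimate across seeds
#'
#' Runs [simulate_rsa()] for each seed, extrapolates each run with
#' [estimate_jamming()] and pools the per-seed estimates (mean and standard
#' error of the mean).
#'
#' @param seeds Integer vector of seeds.
#' @param box_diameters Box side in units of the disk diameter (default 50).
#' @param tau_max Dimensionless attempt budget per run (default 200).
#' @param tau_min Late-time window edge for extrapolation (default 50).
#' @return A list with `theta_inf`, `se`, and a tibble `per_seed`.
#' @export
simulate_jamming <- function(seeds = 1:10, box_diameters = 50,
                             tau_max = 200, tau_min = 50) {
  per_seed <- purrr::map_dfr(seeds, function(s) {
    cfg <- simulate_rsa(box_size = box_diameters, disk_diameter = 1,
                        seed = s, tau_max = tau_max)
    est <- estimate_jamming(cfg, tau_min = tau_min)
    tibble::tibble(seed = s, theta_inf = est$theta_inf, b = est$b,
                   final_coverage = coverage_of(cfg))
  })
  list(theta_inf = mean(per_seed$theta_inf),
       se = stats::sd(per_seed$theta_inf) / sqrt(nrow(per_seed)),
       per_seed = per_seed)
}

#' Plot a deposition configuration
#'
#' @param object An `rsa_deposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_deposition <- function(object, ...) {
  ggplot2::ggplot(object$centers, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::coord_fixed(xlim = c(0, object$box_size),
                         ylim = c(0, object$box_size)) +
    ggplot2::labs(
      title = sprintf("RSA deposition: %d disks, coverage %.3f",
                      nrow(object$centers), coverage_of(object)),
      x = "x", y = "y") +
    ggplot2::theme_minimal()
}
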