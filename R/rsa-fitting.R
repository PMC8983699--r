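# Nonlinear least-squares fitting of the RSA adsorption rate equation to a
# rescaled dry-mass trace Gamma(t). The two free composites are
# ka_c = k_a * c (ng cm^-2 s^-1) and a_over_m = a / m (cm^2 ng^-1); k_a and
# a are decomposed afterwards from the known concentration and particle
# mass. The objective integrates the ODE at every evaluation rather than
# differentiating the noisy trace.

.integrate_composites <- function(ka_c, a_over_m, times, regime,
                                  theta_inf = 0.547, k0 = 8.98) {
  # composite-parameter forward model; same solver settings as integrate_rsa
  kin <- list(k_a = ka_c, c = 1, a_cm2 = a_over_m, m = 1,
              theta_inf = theta_inf, k0 = k0, regime = regime,
              crossover = if (regime == "blended") blocking_crossover(theta_inf, k0) else NA_real_)
  class(kin) <- "rsa_kinetics"
  rhs <- function(t, y, parms) {
    theta <- y[1] * kin$a_cm2
    list(kin$k_a * .blocking_for(theta, kin))
  }
  sol <- deSolve::lsoda(y = c(gamma = 0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  as.numeric(sol[, "gamma"])
}

#' Fit the RSA rate equation to an adsorption trace
#'
#' Least-squares fit of the integrated rate equation
#' `dGamma/dt = ka_c * B(Gamma * a_over_m)` to a dry-mass trace, using a
#' bounded trust-region-based Levenberg-Marquardt optimiser. Both composite
#' coefficients start at 0.1 with bounds `[0, 10]` (in the internal
#' ng/cm/s unit system); a multistart with a data-driven second start
#' guards against the flat near-jamming likelihood. The physical parameters
#' are decomposed as `k_a = ka_c / c` and `a = a_over_m * m`.
#'
#' @param data A data frame with columns `time_s` (s, starting near 0) and
#'   `gamma` (ng cm^-2, rescaled to dry mass).
#' @param c Bulk mass concentration, ng cm^-3.
#' @param m Single-particle mass, ng.
#' @param regime Blocking-function regime, see [rsa_kinetics()].
#' @param start Starting value for both composites (default 0.1).
#' @param lower,upper Box bounds for both composites (defaults 0 and 10).
#' @param multistart Number of starts (default 5): the canonical
#'   `(0.1, 0.1)` start, a data-driven start (initial slope for `ka_c`,
#'   jamming coverage over the trace maximum for `a_over_m`), and
#'   log-spaced perturbations of the latter. The flat near-jamming
#'   likelihood makes a single start unreliable for fast kinetics.
#' @param theta_inf,k0 Blocking-function constants.
#' @return An object of class `rsa_fit` with elements `ka_c`, `a_over_m`,
#'   `k_a`, `a_nm2`, `fitted`, `residuals`, `adjusted_r2`, `converged`,
#'   `bounds_hit`, `data` and the optimiser report.
#' @export
fit_rsa <- function(data, c, m,
                    regime = c("blended", "low_coverage_polynomial", "near_jamming"),
                    start = 0.1, lower = 0, upper = 10, multistart = 5,
                    theta_inf = 0.547, k0 = 8.98) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(data), all(c("time_s", "gamma") %in% names(data)),
            c > 0, m > 0, multistart >= 1)
  times <- data$time_s
  obs <- data$gamma
  if (times[1] > 1e-9) {
    times <- c(0, times)
    pad <- TRUE
  } else pad <- FALSE

  resid_fun <- function(p) {
    pred <- .integrate_composites(p[1], p[2], times, regime, theta_inf, k0)
    if (pad) pred <- pred[-1]
    pred - obs
  }

  clamp <- function(x) pmin(pmax(x, max(lower, 1e-6)), upper)
  starts <- matrix(c(start, start), ncol = 2)
  if (multistart >= 2) {
    # Data-driven start: the initial slope of the trace estimates ka_c
    # (B(0) = 1), and the jamming coverage over the trace maximum bounds
    # a_over_m from below.
    i0 <- which(obs > 0.05 * max(obs))[1]
    ka_c0 <- if (!is.na(i0) && data$time_s[i0] > 0) {
      obs[i0] / data$time_s[i0]
    } else start
    aom0 <- if (max(obs) > 0) theta_inf / max(obs) else start
    ds <- clamp(c(ka_c0, aom0))
    starts <- rbind(starts, ds)
    if (multistart > 2) {
      fac <- 10^seq(-1, 1, length.out = multistart - 2)
      starts <- rbind(starts, clamp(cbind(ds[1] * fac, ds[2] * rev(fac))))
    }
  }
  starts <- unique(starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit_i <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = rep(lower, 2),
                         upper = rep(upper, 2), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit_i)) next
    if (is.null(best) || fit_i$deviance < best$deviance) best <- fit_i
  }
  if (is.null(best)) stop("RSA fit failed from every start", call. = FALSE)

  ka_c <- best$par[1]
  a_over_m <- best$par[2]
  fitted <- .integrate_composites(ka_c, a_over_m, times, regime, theta_inf, k0)
  if (pad) fitted <- fitted[-1]
  res <- obs - fitted
  bounds_hit <- any(abs(best$par - lower) < 1e-12) ||
    any(abs(upper - best$par) < 1e-12)

  structure(
    list(ka_c = ka_c, a_over_m = a_over_m,
         k_a = ka_c / c, a_nm2 = a_over_m * m / NM2_TO_CM2,
         c = c, m = m, regime = regime,
         theta_inf = theta_inf, k0 = k0,
         fitted = fitted, residuals = res,
         adjusted_r2 = adjusted_r_squared(obs, fitted, 2),
         converged = best$info %in% 1:4,
         iterations = best$niter,
         bounds_hit = bounds_hit,
         deviance = best$deviance,
         data = tibble::tibble(time_s = data$time_s, gamma = obs),
         optim = best),
    class = "rsa_fit"
  )
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat("<rsa_fit>\n")
  cat(sprintf("  ka_c = %.4g ng cm^-2 s^-1, a/m = %.4g cm^2 ng^-1\n",
              x$ka_c, x$a_over_m))
  cat(sprintf("  k_a = %.4g cm s^-1, a = %.4g nm^2 (c = %.3g, m = %.3g)\n",
              x$k_a, x$a_nm2, x$c, x$m))
  cat(sprintf("  adjusted R^2 = %.4f, regime = %s, converged = %s%s\n",
              x$adjusted_r2, x$regime, x$converged,
              if (x$bounds_hit) " [bounds hit]" else ""))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (N - 1) / (N - p - 1)` for `N` observations and `p`
#' fitted parameters.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param n_params Number of fitted parameters.
#' @return Adjusted R-squared (scalar, at most 1).
#' @export
adjusted_r_squared <- function(observed, fitted, n_params) {
  stopifnot(length(observed) == length(fitted),
            length(observed) >= n_params + 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observations have zero variance", call. = FALSE)
  r2 <- 1 - sum((observed - fitted)^2) / ss_tot
  n <- length(observed)
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Evaluate a fitted RSA model on a time grid
#'
#' @param object An [fit_rsa()] result.
#' @param times Time grid in s (default: the training grid).
#' @param ... Unused.
#' @return A tibble `time_s`, `gamma`.
#' @export
predict.rsa_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_s
  tt <- if (times[1] > 1e-9) c(0, times) else times
  g <- .integrate_composites(object$ka_c, object$a_over_m, tt,
                             object$regime, object$theta_inf, object$k0)
  if (length(tt) > length(times)) g <- g[-1]
  tibble::tibble(time_s = times, gamma = g)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of an RSA fit
#'
#' @param x An `rsa_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (composites and decomposed
#'   physical parameters).
#' @export
tidy.rsa_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka_c", "a_over_m", "k_a", "a_nm2"),
    estimate = c(x$ka_c, x$a_over_m, x$k_a, x$a_nm2),
    unit = c("ng cm-2 s-1", "cm2 ng-1", "cm s-1", "nm2")
  )
}

#' One-row summary of an RSA fit
#'
#' @param x An `rsa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit diagnostics.
#' @export
glance.rsa_fit <- function(x, ...) {
  tibble::tibble(
    adjusted_r2 = x$adjusted_r2,
    deviance = x$deviance,
    iterations = x$iterations,
    converged = x$converged,
    bounds_hit = x$bounds_hit,
    regime = x$regime,
    nobs = nrow(x$data)
  )
}

#' Plot an RSA fit overlay
#'
#' Observed dry-mass trace (points) with the fitted integrated model
#' (line).
#'
#' @param object An `rsa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$gamma), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(Gamma ~ (ng ~ cm^-2)),
                  title = sprintf("RSA fit: k[a] = %.2g cm/s, a = %.2g nm^2, adj. R^2 = %.2f",
                                  object$k_a, object$a_nm2, object$adjusted_r2)) +
    ggplot2::theme_minimal()
}
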