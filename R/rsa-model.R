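# Closed-form RSA mathematics: blocking functions, coverage relations, and
# forward integration of the adsorption ODE
#   dGamma/dt = k_a * c * B(Gamma * a / m),        k_d = 0 (irreversible)
# Internal unit system: ng, cm, s, Hz. Areas in nm^2 are converted at the
# boundary (1 nm^2 = 1e-14 cm^2).

NM2_TO_CM2 <- 1e-14

# coefficients of the low-coverage cubic expansion of the disk RSA
# blocking function (Schaaf-Talbot)
.B2 <- 6 * sqrt(3) / pi
.B3 <- 40 / (pi * sqrt(3)) - 176 / (3 * pi^2)

#' RSA blocking function (low-coverage cubic)
#'
#' Probability that a random insertion attempt is accepted at coverage
#' `theta`, third-order expansion for equal hard disks:
#' `B(theta) = 1 - 4 theta + (6 sqrt(3)/pi) theta^2 + (40/(pi sqrt(3)) -
#' 176/(3 pi^2)) theta^3`. The expansion is quantitatively accurate for
#' `theta < 0.3`; it does not vanish at the jamming coverage, which is why
#' the near-jamming form [rsa_blocking_jamming()] takes over at high
#' coverage.
#'
#' @param theta Surface coverage, in `[0, 0.547]`. Values outside this range
#'   are an error (the cubic turns unphysical), not an extrapolation.
#' @return Acceptance probability (dimensionless), vectorised over `theta`.
#' @export
rsa_blocking <- function(theta) {
  stopifnot(is.numeric(theta))
  if (any(theta < 0)) stop("`theta` must be non-negative", call. = FALSE)
  if (any(theta > 0.547)) {
    stop("`theta` beyond the jamming coverage 0.547; the cubic expansion is unphysical there",
         call. = FALSE)
  }
  1 - 4 * theta + .B2 * theta^2 + .B3 * theta^3
}

#' RSA blocking function near the jamming limit
#'
#' Asymptotic form `B(theta) = K0 * (theta_inf - theta)^3`, valid close to
#' the jamming coverage; exactly zero at `theta = theta_inf`. For equal
#' disks `theta_inf = 0.547` and `K0` is about 8.98.
#'
#' @param theta Surface coverage, must not exceed `theta_inf`.
#' @param theta_inf Jamming coverage (default 0.547).
#' @param k0 Near-jamming amplitude (default 8.98).
#' @return Acceptance probability, vectorised over `theta`.
#' @export
rsa_blocking_jamming <- function(theta, theta_inf = 0.547, k0 = 8.98) {
  stopifnot(is.numeric(theta), theta_inf > 0, theta_inf <= 1, k0 > 0)
  if (any(theta < 0)) stop("`theta` must be non-negative", call. = FALSE)
  if (any(theta > theta_inf)) {
    stop("`theta` exceeds the jamming coverage `theta_inf`", call. = FALSE)
  }
  k0 * (theta_inf - theta)^3
}

#' Crossover coverage between the two blocking-function forms
#'
#' The coverage in (0.25, theta_inf) where the low-coverage cubic and the
#' near-jamming cube intersect for a given `K0`; used by the `blended`
#' kinetics regime to switch forms with a continuous right-hand side.
#'
#' @inheritParams rsa_blocking_jamming
#' @return The crossover coverage (scalar).
#' @keywords internal
blocking_crossover <- function(theta_inf = 0.547, k0 = 8.98) {
  f <- function(th) {
    (1 - 4 * th + .B2 * th^2 + .B3 * th^3) - k0 * (theta_inf - th)^3
  }
  stats::uniroot(f, c(0.25, theta_inf - 1e-6), tol = 1e-10)$root
}

#' Surface coverage from areal mass
#'
#' `theta = Gamma * a / m`: the fraction of the surface occupied when a mass
#' `Gamma` per unit area is made of particles of mass `m` each occupying
#' area `a`. The identity is used for coverage bookkeeping at any coverage;
#' as the driver of the cubic blocking function it is quantitatively valid
#' only below 0.3, and a warning is emitted above that.
#'
#' @param gamma Surface mass density in ng cm^-2.
#' @param a_nm2 Occupied area per particle in nm^2.
#' @param m Single-particle mass in ng.
#' @return Dimensionless coverage, vectorised over `gamma`.
#' @export
surface_coverage <- function(gamma, a_nm2, m) {
  stopifnot(is.numeric(gamma), is.numeric(a_nm2), is.numeric(m))
  if (any(a_nm2 <= 0)) stop("`a_nm2` must be positive", call. = FALSE)
  if (any(m <= 0)) stop("`m` must be positive", call. = FALSE)
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  theta <- gamma * (a_nm2 * NM2_TO_CM2) / m
  if (any(theta > 0.3)) {
    warning("coverage exceeds 0.3; the low-coverage kinetic expansion is not quantitative there",
            call. = FALSE)
  }
  theta
}

#' RSA kinetics parameter set
#'
#' Bundles the parameters of the irreversible adsorption rate equation
#' `dGamma/dt = k_a * c * B(Gamma a / m)` (desorption fixed to zero).
#'
#' @param k_a Adsorption rate coefficient in cm s^-1.
#' @param a_nm2 Occupied area per adsorbed particle in nm^2 (converted to
#'   cm^2 internally).
#' @param m Single-particle mass in ng.
#' @param c Bulk mass concentration in ng cm^-3.
#' @param theta_inf Jamming coverage (default 0.547).
#' @param k0 Near-jamming blocking amplitude (default 8.98).
#' @param regime Which blocking function drives the kinetics:
#'   `"blended"` (default) uses the cubic below the crossover coverage and
#'   the near-jamming cube above it, giving a continuous right-hand side;
#'   `"low_coverage_polynomial"` and `"near_jamming"` use one form
#'   throughout.
#' @return An object of class `rsa_kinetics`.
#' @export
rsa_kinetics <- function(k_a, a_nm2, m, c,
                         theta_inf = 0.547, k0 = 8.98,
                         regime = c("blended", "low_coverage_polynomial", "near_jamming")) {
  regime <- match.arg(regime)
  stopifnot(k_a >= 0, a_nm2 > 0, m > 0, c >= 0,
            theta_inf > 0, theta_inf <= 1, k0 > 0)
  crossover <- if (regime == "blended") blocking_crossover(theta_inf, k0) else NA_real_
  structure(
    list(k_a = k_a, a_nm2 = a_nm2, a_cm2 = a_nm2 * NM2_TO_CM2, m = m, c = c,
         theta_inf = theta_inf, k0 = k0, regime = regime, crossover = crossover),
    class = "rsa_kinetics"
  )
}

#' @export
print.rsa_kinetics <- function(x, ...) {
  cat("<rsa_kinetics>\n")
  cat(sprintf("  k_a = %.3g cm s^-1, a = %.3g nm^2, m = %.3g ng, c = %.3g ng cm^-3\n",
              x$k_a, x$a_nm2, x$m, x$c))
  cat(sprintf("  theta_inf = %.3f, K0 = %.3g, regime = %s", x$theta_inf, x$k0, x$regime))
  if (!is.na(x$crossover)) cat(sprintf(" (crossover at theta = %.4f)", x$crossover))
  cat("\n")
  invisible(x)
}

# blocking function for a kinetics object, safe at/above jamming
.blocking_for <- function(theta, kin) {
  theta <- min(max(theta, 0), kin$theta_inf)
  switch(kin$regime,
    low_coverage_polynomial = 1 - 4 * theta + .B2 * theta^2 + .B3 * theta^3,
    near_jamming = kin$k0 * (kin$theta_inf - theta)^3,
    blended = if (theta < kin$crossover) {
      1 - 4 * theta + .B2 * theta^2 + .B3 * theta^3
    } else {
      kin$k0 * (kin$theta_inf - theta)^3
    }
  )
}

#' Integrate the RSA adsorption rate equation
#'
#' Forward-integrates `dGamma/dt = k_a c B(Gamma a / m)` from `Gamma(0) = 0`
#' on the supplied time grid with an adaptive stiff-capable solver
#' (relative tolerance 1e-8, absolute tolerance 1e-10 ng cm^-2). The
#' trajectory is monotone non-decreasing and the coverage never exceeds the
#' jamming value.
#'
#' @param kinetics An [rsa_kinetics()] parameter set.
#' @param times Monotone time grid in s, starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time_s`, `gamma` (ng cm^-2) and `theta`.
#' @export
integrate_rsa <- function(kinetics, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(kinetics, "rsa_kinetics"), is.numeric(times))
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  kin <- kinetics
  rhs <- function(t, y, parms) {
    theta <- y[1] * kin$a_cm2 / kin$m
    list(kin$k_a * kin$c * .blocking_for(theta, kin))
  }
  sol <- deSolve::lsoda(y = c(gamma = 0), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge: istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  }
  gamma <- pmin(cummax(sol[, "gamma"]), kin$theta_inf * kin$m / kin$a_cm2)
  tibble::tibble(time_s = times, gamma = as.numeric(gamma),
                 theta = as.numeric(gamma) * kin$a_cm2 / kin$m)
}
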