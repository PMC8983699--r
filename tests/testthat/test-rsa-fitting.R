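make_trace <- function(k_a, a_nm2, m = 5.26e-7, c = 1e5,
                       duration = 3600, dt = 10) {
  kin <- rsa_kinetics(k_a, a_nm2, m, c)
  integrate_rsa(kin, seq(0, duration, by = dt))
}

test_that("noiseless traces return the generating parameters", {
  tr <- make_trace(1e-5, 6e4)
  fit <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7)
  expect_equal(fit$k_a, 1e-5, tolerance = 1e-4)
  expect_equal(fit$a_nm2, 6e4, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_false(fit$bounds_hit)
  expect_gt(fit$adjusted_r2, 0.9999)
})

test_that("recovery is unbiased across the studied parameter range", {
  # property: 2% multiplicative noise on the dry trace; the fitted
  # parameters show < 2% bias and < 8% RMSE over the kinetic range
  cells <- expand.grid(ka = c(0.5, 1, 2, 5) * 1e-5,
                       a = c(1, 3, 6, 24) * 1e4)
  errs <- purrr::pmap_dfr(cells, function(ka, a) {
    set.seed(7 + round(ka * 1e6 + a))
    tr <- make_trace(ka, a)
    noisy <- tr$gamma * (1 + stats::rnorm(nrow(tr), 0, 0.02))
    noisy[1] <- 0
    fit <- fit_rsa(tibble::tibble(time_s = tr$time_s, gamma = noisy),
                   c = 1e5, m = 5.26e-7)
    tibble::tibble(rka = fit$k_a / ka - 1, ra = fit$a_nm2 / a - 1)
  })
  expect_lt(abs(mean(errs$rka)), 0.02)
  expect_lt(abs(mean(errs$ra)), 0.02)
  expect_lt(sqrt(mean(errs$rka^2)), 0.08)
  expect_lt(sqrt(mean(errs$ra^2)), 0.08)
})

test_that("the fit is invariant to a change of time unit", {
  tr <- make_trace(1e-5, 6e4)
  fit_s <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7)
  # the same data on a 60x finer time unit with the concentration scaled
  # down by 60 describes identical physics
  tr_min <- tibble::tibble(time_s = tr$time_s * 60, gamma = tr$gamma)
  fit_min <- fit_rsa(tr_min, c = 1e5 / 60, m = 5.26e-7)
  expect_equal(fit_min$k_a, fit_s$k_a, tolerance = 1e-4)
  expect_equal(fit_min$a_nm2, fit_s$a_nm2, tolerance = 1e-4)
})

test_that("regime choice is immaterial below the crossover coverage", {
  # short run: final theta ~ 0.23 < 0.29
  tr <- make_trace(1e-5, 6e4, duration = 900)
  f_b <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7,
                 regime = "blended")
  f_p <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7,
                 regime = "low_coverage_polynomial")
  expect_equal(f_b$k_a, f_p$k_a, tolerance = 5e-3)
  expect_equal(f_b$a_nm2, f_p$a_nm2, tolerance = 5e-3)
})

test_that("fitting on noisy data yields the expected goodness of fit", {
  set.seed(41)
  tr <- make_trace(1e-5, 6e4)
  noisy <- tr$gamma * (1 + stats::rnorm(nrow(tr), 0, 0.02))
  noisy[1] <- 0
  fit <- fit_rsa(tibble::tibble(time_s = tr$time_s, gamma = noisy),
                 c = 1e5, m = 5.26e-7)
  expect_gt(fit$adjusted_r2, 0.85)
  expect_lt(fit$adjusted_r2, 0.9999)
})

test_that("predict round-trips through a second fit", {
  tr <- make_trace(2e-5, 3e4)
  fit <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7)
  pred <- predict(fit)
  refit <- fit_rsa(pred[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7)
  expect_equal(refit$k_a, fit$k_a, tolerance = 1e-4)
  expect_equal(refit$a_nm2, fit$a_nm2, tolerance = 1e-4)
})

test_that("adjusted R-squared matches its textbook definition", {
  obs <- c(1, 2, 3, 4, 5, 6)
  fitted <- c(1.1, 1.9, 3.2, 3.8, 5.1, 6.0)
  r2 <- 1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
  expect_equal(adjusted_r_squared(obs, fitted, 2),
               1 - (1 - r2) * 5 / 3)
  expect_equal(adjusted_r_squared(obs, obs, 2), 1)
  expect_error(adjusted_r_squared(rep(1, 6), rep(1, 6), 2), "zero variance")
})

test_that("tidy and glance expose the fit in broom shape", {
  tr <- make_trace(1e-5, 6e4, duration = 1200)
  fit <- fit_rsa(tr[, c("time_s", "gamma")], c = 1e5, m = 5.26e-7)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("ka_c", "a_over_m", "k_a", "a_nm2"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("adjusted_r2", "converged", "nobs") %in% names(gl)))
  expect_equal(gl$nobs, nrow(tr))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("malformed fitting input is rejected", {
  expect_error(fit_rsa(data.frame(t = 1, g = 1), c = 1e5, m = 5.26e-7))
  tr <- make_trace(1e-5, 6e4, duration = 300)
  expect_error(fit_rsa(tr[, c("time_s", "gamma")], c = -1, m = 5.26e-7))
})
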