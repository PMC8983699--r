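test_that("the blocking function starts at 1 and decreases with crowding", {
  expect_equal(rsa_blocking(0), 1)
  th <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(rsa_blocking(th)) < 0))
  expect_true(all(rsa_blocking(th) > 0))
})

test_that("the cubic expansion matches its hand-evaluated coefficients", {
  # oracle: term-by-term evaluation at theta = 0.1 with independently
  # written constants
  b2 <- 6 * sqrt(3) / pi
  b3 <- 40 / (pi * sqrt(3)) - 176 / (3 * pi^2)
  expect_equal(rsa_blocking(0.1), 1 - 0.4 + b2 * 0.01 + b3 * 0.001)
  expect_equal(rsa_blocking(c(0.05, 0.2)),
               1 - 4 * c(0.05, 0.2) + b2 * c(0.05, 0.2)^2 + b3 * c(0.05, 0.2)^3)
})

test_that("coverages beyond jamming are an error, not an extrapolation", {
  expect_error(rsa_blocking(0.6), "jamming")
  expect_error(rsa_blocking(-0.01), "non-negative")
  expect_error(rsa_blocking_jamming(0.56), "exceeds")
})

test_that("the near-jamming form vanishes exactly at the jamming coverage", {
  expect_equal(rsa_blocking_jamming(0.547), 0)
  expect_equal(rsa_blocking_jamming(0.5), 8.98 * (0.547 - 0.5)^3)
  th <- seq(0.3, 0.547, by = 0.01)
  expect_true(all(diff(rsa_blocking_jamming(th)) < 0))
})

test_that("the two blocking forms intersect where the blended regime switches", {
  cross <- nanocapture:::blocking_crossover()
  expect_gt(cross, 0.25)
  expect_lt(cross, 0.547)
  expect_equal(rsa_blocking(cross), rsa_blocking_jamming(cross),
               tolerance = 1e-8)
})

test_that("coverage bookkeeping follows theta = Gamma a / m", {
  # 419 ng/cm2 of 5.26e-7 ng particles at 6e4 nm2 each
  th <- suppressWarnings(surface_coverage(419, 6e4, 5.26e-7))
  expect_equal(th, 419 * 6e4 * 1e-14 / 5.26e-7)
  expect_warning(surface_coverage(419, 6e4, 5.26e-7), "0.3")
  expect_silent(surface_coverage(100, 6e4, 5.26e-7))
  expect_error(surface_coverage(-1, 6e4, 5.26e-7))
})

test_that("the integrated trajectory is monotone and capped at jamming", {
  kin <- rsa_kinetics(k_a = 1e-5, a_nm2 = 6e4, m = 5.26e-7, c = 1e5)
  tr <- integrate_rsa(kin, seq(0, 36000, by = 60))
  expect_true(all(diff(tr$gamma) >= 0))
  expect_true(all(tr$theta <= 0.547 + 1e-12))
  # the approach to jamming is t^(-1/2)-slow; extrapolating the tail
  # recovers the jamming mass
  gamma_jam <- 0.547 * 5.26e-7 / (6e4 * 1e-14)
  tail_idx <- tr$time_s >= 18000
  ext <- stats::lm(gamma ~ I(time_s^(-0.5)), data = tr[tail_idx, ])
  expect_equal(unname(coef(ext)[1]), gamma_jam, tolerance = 0.005)
  expect_lt(tr$gamma[nrow(tr)], gamma_jam)
})

test_that("the initial adsorption rate is k_a * c", {
  kin <- rsa_kinetics(k_a = 1e-5, a_nm2 = 6e4, m = 5.26e-7, c = 1e5)
  tr <- integrate_rsa(kin, c(0, 0.1, 0.2))
  expect_equal(tr$gamma[2] / 0.1, 1e-5 * 1e5, tolerance = 1e-3)
})

test_that("nothing adsorbs from a particle-free solution", {
  kin <- rsa_kinetics(k_a = 1e-5, a_nm2 = 6e4, m = 5.26e-7, c = 0)
  tr <- integrate_rsa(kin, seq(0, 1000, by = 100))
  expect_true(all(tr$gamma == 0))
})

test_that("regimes agree while the coverage stays below the crossover", {
  kin_b <- rsa_kinetics(1e-5, 6e4, 5.26e-7, 1e5, regime = "blended")
  kin_p <- rsa_kinetics(1e-5, 6e4, 5.26e-7, 1e5,
                        regime = "low_coverage_polynomial")
  times <- seq(0, 300, by = 10)   # endpoint theta well below 0.29
  tr_b <- integrate_rsa(kin_b, times)
  tr_p <- integrate_rsa(kin_p, times)
  expect_lt(max(tr_b$theta), nanocapture:::blocking_crossover())
  expect_equal(tr_b$gamma, tr_p$gamma, tolerance = 1e-7)
})

test_that("time grids must start at zero and increase", {
  kin <- rsa_kinetics(1e-5, 6e4, 5.26e-7, 1e5)
  expect_error(integrate_rsa(kin, c(10, 20)), "start at 0")
  expect_error(integrate_rsa(kin, c(0, 10, 10)), "increasing")
})
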