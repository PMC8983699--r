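exact_standards <- function(slope = 1e4, intercept = 50) {
  conc <- c(0, 0.025, 0.05, 0.075, 0.1)
  tibble::tibble(concentration = conc, intensity = intercept + slope * conc)
}

test_that("a noiseless calibration is recovered exactly", {
  cal <- fit_calibration(exact_standards())
  expect_equal(cal$slope, 1e4)
  expect_equal(cal$intercept, 50)
  expect_equal(cal$r_squared, 1)
  expect_error(fit_calibration(exact_standards()[1:2, ]), "at least 3")
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 1, 1),
                                              intensity = c(1, 2, 3))),
               "variance")
})

test_that("curve inversion returns the generating concentrations", {
  cal <- fit_calibration(exact_standards())
  expect_equal(concentration_from_intensity(cal, 50 + 1e4 * 0.08), 0.08)
  expect_warning(c0 <- concentration_from_intensity(cal, 40), "clipped")
  expect_equal(c0, 0)
})

test_that("depletion mass is concentration drop times volume", {
  cal <- fit_calibration(exact_standards())
  before <- rep(50 + 1e4 * 0.1, 3)
  after <- rep(50 + 1e4 * 0.04, 3)
  res <- captured_mass(before, after, volume_ml = 20, cal)
  # 0.06 g/L * 20 mL = 1.2 mg = 1.2e6 ng
  expect_equal(res$mass_ng, 1.2e6)
  expect_equal(res$sd_mass_ng, 0)
  expect_equal(res$c_before, 0.1)
  expect_equal(res$c_after, 0.04)
})

test_that("particle counts are the captured mass over one particle mass", {
  cal <- fit_calibration(exact_standards())
  ps <- particle_spec(100, 1.05)
  res <- captured_particles(rep(50 + 1e4 * 0.1, 3), rep(50 + 1e4 * 0.05, 3),
                            volume_ml = 20, cal, ps)
  expect_equal(res$n_particles * particle_mass(ps), res$mass_ng)
})

test_that("triplicate scatter propagates into the reported SD", {
  cal <- fit_calibration(exact_standards())
  before <- 50 + 1e4 * c(0.099, 0.100, 0.101)
  after <- 50 + 1e4 * c(0.049, 0.050, 0.051)
  res <- captured_mass(before, after, volume_ml = 20, cal)
  cb <- c(0.099, 0.100, 0.101); ca <- c(0.049, 0.050, 0.051)
  sd_dc <- sqrt(stats::var(cb) / 3 + stats::var(ca) / 3)
  expect_equal(res$sd_mass_ng, sd_dc * 20 * 1e6)
})

test_that("apparent mass creation is rejected beyond tolerance", {
  cal <- fit_calibration(exact_standards())
  expect_error(
    captured_mass(rep(50 + 1e4 * 0.05, 3), rep(50 + 1e4 * 0.10, 3), 20, cal),
    "negative depletion")
  # tiny negative depletion within tolerance clips to zero
  res <- captured_mass(rep(50 + 1e4 * 0.0500, 3), rep(50 + 1e4 * 0.0501, 3),
                       20, cal)
  expect_equal(res$mass_ng, 0)
})

test_that("estimates are invariant to the detector gain", {
  set.seed(8)
  conc <- c(0, 0.025, 0.05, 0.075, 0.1)
  base_i <- 50 + 1e4 * conc + stats::rnorm(5, 0, 3)
  before <- 50 + 1e4 * 0.1 + stats::rnorm(3, 0, 3)
  after <- 50 + 1e4 * 0.05 + stats::rnorm(3, 0, 3)
  run <- function(gain) {
    cal <- fit_calibration(tibble::tibble(concentration = conc,
                                          intensity = gain * base_i))
    captured_mass(gain * before, gain * after, 20, cal)$mass_ng
  }
  expect_equal(run(1), run(7.3), tolerance = 1e-10)
})

test_that("required film area rounds up and shrinks with better films", {
  expect_equal(area_to_remove_all(1e12, 4e11), 3)
  expect_equal(area_to_remove_all(1e12, 1e12), 1)
  expect_equal(area_to_remove_all(1, 1e12), 1)   # floor of one piece
  a <- area_to_remove_all(1e12, c(1e11, 2e11, 4e11))
  expect_true(all(diff(a) <= 0))
  expect_error(area_to_remove_all(1, 0), "positive")
})

test_that("the tabular workflow ties calibration and depletion together", {
  scn <- scenario(seed = 5)
  fl <- generate_fluorescence_dataset(scn, true_capture_fraction = 0.5)
  res <- quantify_fluorescence(fl$standards, fl$readings,
                               volume_ml = scn$volume_ml,
                               spec = scn$particle)
  expect_s3_class(res, "capture_result")
  expect_equal(res$mass_ng, fl$truth$mass_captured_ng, tolerance = 0.05)
  expect_s3_class(attr(res, "calibration"), "calibration_curve")
  # mass-only mode for heterogeneous particles reports no count
  res2 <- quantify_fluorescence(fl$standards, fl$readings,
                                volume_ml = scn$volume_ml)
  expect_null(res2$n_particles)
  expect_error(quantify_fluorescence(fl$standards,
                                     data.frame(when = "before",
                                                intensity = 1),
                                     20),
               "before.*after|'before' and 'after'")
})

test_that("calibration objects support the tidy accessors", {
  cal <- fit_calibration(exact_standards())
  # exact standards provoke lm's perfect-fit warning inside summary()
  td <- suppressWarnings(tidy(cal))
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(cal)
  expect_equal(gl$r_squared, 1)
  p <- ggplot2::autoplot(cal)
  expect_s3_class(p, "ggplot")
})
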