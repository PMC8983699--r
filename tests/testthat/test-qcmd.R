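test_that("Sauerbrey conversion respects the declared normalization", {
  # oracle: -C/n * raw shift
  expect_equal(sauerbrey_mass(-100, n = 5, normalization = "raw"),
               17.7 / 5 * 100)
  # a shift already divided by n needs no further division
  expect_equal(sauerbrey_mass(-20, n = 5, normalization = "normalized_by_n"),
               17.7 * 20)
  # the two conventions describe the same physical shift
  expect_equal(sauerbrey_mass(-100, n = 5, normalization = "raw"),
               sauerbrey_mass(-100 / 5, n = 5,
                              normalization = "normalized_by_n"))
  expect_error(sauerbrey_mass(-100, n = 4), "odd")
})

test_that("the Sauerbrey validity flag trips on soft layers", {
  expect_false(dissipation_ok(21))
  expect_true(dissipation_ok(rep(0, 10)))
  expect_true(dissipation_ok(9.9))
  expect_false(dissipation_ok(c(1, 2, 15)))
})

test_that("rescaling pins the trace maximum to the image-analysis dry mass", {
  m_t <- c(0, 40, 100, 130, 132)
  g <- rescale_to_dry_mass(m_t, 419)
  expect_equal(max(g), 419)
  expect_equal(g, m_t * 419 / 132)
  expect_equal(rescale_to_dry_mass(c(1, 2), 2), c(1, 2))
  expect_error(rescale_to_dry_mass(c(0, 0), 419), "positive maximum")
})

test_that("the worked coupled-water example yields a factor of 3.2", {
  wf <- coupled_water_factor(-373.5, 419, n = 5)
  expect_equal(wf$delta_f_ia, -419 * 5 / 17.7)
  expect_equal(wf$delta_f_ia, -118.4, tolerance = 1e-3)
  expect_equal(wf$factor_reported, 3.2)
  expect_error(coupled_water_factor(373.5, 419), "opposite signs")
})

test_that("the coverage chain reproduces the stabile-particle film numbers", {
  ps <- particle_spec(100, 1.05)
  theta_liq <- suppressWarnings(surface_coverage(419, 6e4, 5.26e-7))
  expect_equal(signif(theta_liq, 2), 0.48)
  theta_air <- coverage_solid_air(419, 5.26e-7, ps)
  expect_equal(signif(theta_air, 2), 0.076)
  expect_equal(signif(fractional_coverage(theta_air), 2), 0.14)
  expect_equal(signif(d_rsa_from_area(6e4), 2), 280)
})

test_that("the high-uptake film numbers follow from the same chain", {
  ps <- particle_spec(100, 1.005)
  theta_air <- coverage_solid_air(1890, 5.26e-7, ps)
  expect_equal(signif(fractional_coverage(theta_air), 2), 0.62)
  total <- sensor_total_mass(1890)
  expect_equal(signif(total, 3), 1200)
  # 1 h at 0.1 mL/min of a 1e5 ng/cm3 dispersion supplies 6e5 ng
  expect_equal(signif(total / 6e5, 1), 0.002)
})

test_that("trace endpoints average the final window", {
  t <- seq(0, 600, by = 10)
  v <- c(rep(0, 54), rep(10, 7))   # last 60 s (times 540..600) at 10
  expect_equal(trace_endpoint(t, v), 10)
  expect_equal(trace_endpoint(t, seq_along(t)), mean(55:61))
})

test_that("QCM-D traces survive a CSV round trip with declared convention", {
  tr <- tibble::tibble(time_s = seq(0, 100, by = 10),
                       f5 = -seq(0, 100, by = 10) / 3,
                       D5 = seq(0, 100, by = 10) / 50)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_qcmd(tr, path)
  expect_message(rd <- read_qcmd(path, normalization = "raw"), "declared")
  expect_equal(rd$f5, tr$f5)
  expect_identical(attr(rd, "normalization"), "raw")
  # a file without time cannot be a trace
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  utils::write.csv(data.frame(f5 = 1:3), path2, row.names = FALSE)
  expect_error(suppressMessages(read_qcmd(path2, "raw")), "time_s")
})

test_that("a coverage summary stores unrounded values and rounds on print", {
  ps <- particle_spec(100, 1.05)
  cs <- coverage_summary(
    substrate = "film", particle = "PS(100 nm)",
    delta_f5 = -373.5, delta_D5 = 21,
    gamma_max_ia = 419, a_nm2 = 6e4, k_a = 1.4e-5,
    m = 5.26e-7, spec = ps, normalization = "raw")
  expect_s3_class(cs, "coverage_summary")
  expect_equal(nrow(cs), 1)
  expect_gt(cs$theta_liquid, 0.47)   # unrounded 0.4779...
  expect_lt(cs$theta_liquid, 0.48)
  out <- capture.output(print(cs))
  expect_true(any(grepl("3.2", out)))
})
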