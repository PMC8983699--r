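# paints filled disks into a matrix; independent of the package's renderer
paint_disks <- function(nr, nc, cx, cy, r, level = 255, background = 0) {
  m <- matrix(background, nr, nc)
  for (k in seq_along(cx)) {
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if ((i - cy[k])^2 + (j - cx[k])^2 <= r^2) m[i, j] <- level
      }
    }
  }
  m
}

test_that("scale calibration is a simple ratio with guarded inputs", {
  expect_equal(calibrate_scale(500, 1000), 2)
  expect_error(calibrate_scale(0, 1000), "positive")
  expect_error(calibrate_scale(500, -1), "positive")
})

test_that("field area follows from the pixel grid and calibration", {
  img <- image_record(matrix(0, 1536, 2048), nm_per_px = 2)
  expect_equal(field_area_mm2(img), 1536 * 2048 * (2e-6)^2)
})

test_that("the histogram threshold sits on the background peak's bright flank", {
  set.seed(1)
  bg <- matrix(pmax(stats::rnorm(400 * 400, 30, 8), 0), 400, 400)
  px <- bg
  px[100:140, 100:140] <- 220    # one bright square
  thr <- histogram_threshold(px)
  expect_gt(thr, 30)     # above the background mean
  expect_lt(thr, 220)    # below the particle level
  mask <- threshold_mask(px, threshold = thr)
  expect_true(all(mask[110:130, 110:130]))
  # unblurred Gaussian noise leaves only isolated speckles above the cut
  expect_lt(mean(mask[200:400, 200:400]), 0.01)
  expect_error(histogram_threshold(matrix(5, 10, 10)), "degenerate")
})

test_that("well-separated equal disks are counted as singles", {
  d <- 20
  m <- paint_disks(300, 300, cx = c(50, 150, 250), cy = c(60, 160, 60),
                   r = d / 2)
  counts <- detect_particles(m > 0, expected_diameter_px = d)
  expect_equal(counts$n_singles, 3)
  expect_equal(counts$particles_total, 3)
  expect_true(all(counts$components$class == "single"))
  expect_true(all(counts$components$circularity > 0.75))
})

test_that("a triplet-sized blob counts as exactly three detached particles", {
  d <- 25
  r <- d / 2
  # three mutually touching disks (equilateral arrangement)
  m <- paint_disks(200, 200, cx = c(80, 105, 92.5),
                   cy = c(100, 100, 100 + d * sqrt(3) / 2), r = r)
  counts <- detect_particles(m > 0, expected_diameter_px = d,
                             mode = "detached")
  expect_equal(counts$particles_total, 3)
  expect_equal(counts$n_small_clusters, 1)
})

test_that("area division resolves a large aggregate", {
  d <- 20
  # a 3x2 block of touching disks merges into one component of ~6 A1
  cx <- rep(c(60, 80, 100), 2)
  cy <- rep(c(60, 80), each = 3)
  m <- paint_disks(160, 160, cx, cy, r = d / 2)
  counts <- detect_particles(m > 0, expected_diameter_px = d,
                             mode = "clustered")
  expect_true(counts$particles_total %in% 5:7)
  expect_equal(counts$n_singles, 0)
})

test_that("sub-particle specks are discarded as noise", {
  d <- 20
  m <- paint_disks(100, 100, cx = 50, cy = 50, r = 3)  # ~9% of A1
  counts <- detect_particles(m > 0, expected_diameter_px = d)
  expect_equal(counts$particles_total, 0)
})

test_that("an empty mask yields an empty count", {
  counts <- detect_particles(matrix(FALSE, 50, 50), expected_diameter_px = 10)
  expect_equal(counts$particles_total, 0)
  expect_equal(nrow(counts$components), 0)
})

test_that("counts convert to number density and surface mass density", {
  img <- image_record(matrix(0, 1000, 1000), nm_per_px = 10)  # 1e-4 mm2
  expect_equal(particle_density(50, img), 50 / 1e-4)
  # Gamma = density per mm2 * 100 * m  (per-cm2 conversion)
  expect_equal(surface_mass_density(5e5, 5.26e-7), 5e5 * 100 * 5.26e-7)
  expect_equal(surface_mass_density(0, 5.26e-7), 0)
})

test_that("profile areas integrate a peak-normalised trapezoid", {
  prof <- c(0, 1, 2, 1, 0)
  # oracle: peak 2, normalised 0,.5,1,.5,0 on a 400 nm grid
  expect_equal(normalized_profile_auc(prof), 800)
  expect_error(normalized_profile_auc(c(0, 0)), "positive peak")
})

test_that("images survive a PNG round trip", {
  set.seed(2)
  px <- matrix(sample(0:255, 60 * 40, replace = TRUE), 60, 40)
  img <- image_record(px, nm_per_px = 2)
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path), add = TRUE)
  write_sem_image(img, path)
  rd <- read_sem_image(path, nm_per_px = 2)
  expect_equal(rd$pixels, px)
  expect_error(read_sem_image("foo.bmp", 2), "unsupported")
})
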