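test_that("forward projection is linear and nonnegative", {
  set.seed(1)
  acq <- small_acq(psf = 3)
  g <- grid_geometry(c(32, 32, 2), c(2.73, 2.73, 2.8))
  a <- random_volume(c(32, 32, 2), c(2.73, 2.73, 2.8))
  b <- random_volume(c(32, 32, 2), c(2.73, 2.73, 2.8))
  zero <- activity_volume(g, array(0, c(32, 32, 2)))
  expect_true(all(forward_project(zero, acq)$values == 0))
  ab <- activity_volume(g, a$values + b$values)
  expect_equal(forward_project(ab, acq)$values,
               forward_project(a, acq)$values +
                 forward_project(b, acq)$values,
               tolerance = 1e-12)
  expect_true(all(forward_project(a, acq)$values >= 0))
})

test_that("disc projection matches the analytic chord-length profile", {
  g <- grid_geometry(c(128, 128, 1), c(1, 1, 1))
  spec <- phantom_spec(list(), background_activity = 1,
                       body = list(center = c(0, 0), semi_axes = c(40, 40)))
  vol <- build_phantom(spec, g, subsample = 3)
  acq <- acquisition_model(n_angles = 4, n_radial_bins = 160,
                           radial_bin_size = 1, psf_fwhm = 0,
                           count_scale = 1)
  prof <- forward_project(vol, acq)$values[, 1, 1]
  s <- (seq_len(160) - (160 + 1) / 2) * 1
  chord <- ifelse(abs(s) < 40, 2 * sqrt(pmax(40^2 - s^2, 0)), 0)
  expect_lt(max(abs(prof - chord)) / max(chord), 0.02)
})

test_that("Poisson sampling honors seed, zero-mean bins and moments", {
  g <- grid_geometry(c(100, 100, 1), c(1, 1, 1))
  acq <- acquisition_model(n_angles = 100, n_radial_bins = 100,
                           radial_bin_size = 1, psf_fwhm = 0,
                           count_scale = 1)
  expd <- projection_data(array(50, c(100, 100, 1)), acq, g, "expected")
  s1 <- sample_counts(expd, 42)
  s2 <- sample_counts(expd, 42)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, sample_counts(expd, 43)$values))
  # 10,000 bins of expectation 50: mean within 3 standard errors
  expect_lt(abs(mean(s1$values) - 50), 3 * sqrt(50 / 10000))
  expect_lt(abs(stats::var(as.vector(s1$values)) - 50), 5 * 50 / sqrt(10000))
  zero <- projection_data(array(0, c(100, 100, 1)), acq, g, "expected")
  expect_true(all(sample_counts(zero, 1)$values == 0))
})

test_that("projection container validates geometry and count types", {
  g <- grid_geometry(c(16, 16, 2))
  acq <- acquisition_model(n_angles = 8, n_radial_bins = 24)
  expect_error(projection_data(array(1, c(10, 8, 2)), acq, g, "expected"),
               "does not match")
  expect_error(projection_data(array(0.5, c(24, 8, 2)), acq, g, "sampled"),
               "integers")
  expect_error(projection_data(array(-1, c(24, 8, 2)), acq, g, "expected"),
               "nonnegative")
  ok <- projection_data(array(1, c(24, 8, 2)), acq, g, "expected")
  expect_error(sample_counts(sample_counts(ok, 1), 1), "expected")
})

test_that("PSF blur preserves total activity away from edges", {
  g <- grid_geometry(c(48, 48, 16), c(2.73, 2.73, 2.8))
  vals <- array(0, c(48, 48, 16)); vals[24, 24, 8] <- 100
  blurred <- gaussian_blur(activity_volume(g, vals), 6)
  expect_equal(sum(blurred$values), 100, tolerance = 1e-6)
  expect_lt(max(blurred$values), 100)
  expect_identical(gaussian_blur(activity_volume(g, vals), 0)$values, vals)
})
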