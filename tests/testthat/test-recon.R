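test_that("poisson_loglik agrees with the direct formula and guards edges", {
  set.seed(5)
  g <- grid_geometry(c(16, 16, 1), c(2, 2, 2))
  acq <- acquisition_model(n_angles = 12, n_radial_bins = 24,
                           radial_bin_size = 2, psf_fwhm = 0,
                           count_scale = 1)
  vol <- activity_volume(g, array(stats::runif(256, 0.5, 3), c(16, 16, 1)))
  expd <- forward_project(vol, acq)
  y <- sample_counts(expd, 9)
  yhat <- expd$values
  pos <- y$values > 0
  manual <- sum(y$values[pos] * log(yhat[pos])) - sum(yhat)
  expect_equal(poisson_loglik(vol, y, acq), manual, tolerance = 1e-12)
  # zero counts + zero volume: empty-data convention gives 0
  zerov <- activity_volume(g, array(0, c(16, 16, 1)))
  zeroy <- projection_data(array(0, c(24, 12, 1)), acq, g, "sampled")
  expect_equal(poisson_loglik(zerov, zeroy, acq), 0)
  # positive counts where the model predicts nothing is -Inf -> error
  onecount <- projection_data(array(1, c(24, 12, 1)), acq, g, "sampled")
  expect_error(poisson_loglik(zerov, onecount, acq), "-Inf")
})

test_that("the truth maximizes the likelihood of its own expectation data", {
  set.seed(6)
  g <- grid_geometry(c(16, 16, 1), c(2, 2, 2))
  acq <- acquisition_model(n_angles = 16, n_radial_bins = 24,
                           radial_bin_size = 2, psf_fwhm = 0,
                           count_scale = 1)
  truth <- activity_volume(g, array(stats::runif(256, 0.5, 4), c(16, 16, 1)))
  expd <- forward_project(truth, acq)
  ll_truth <- poisson_loglik(truth, expd, acq)
  for (i in 1:100) {
    pert <- activity_volume(g, pmax(truth$values *
      array(stats::runif(256, 0.7, 1.3), c(16, 16, 1)), 1e-9))
    expect_gte(ll_truth, poisson_loglik(pert, expd, acq))
  }
})

test_that("ML-EM recovers a point source and preserves total counts", {
  g <- grid_geometry(c(32, 32, 1), c(2, 2, 2))
  acq <- acquisition_model(n_angles = 32, n_radial_bins = 48,
                           radial_bin_size = 2, psf_fwhm = 0,
                           count_scale = 1)
  truth <- array(0, c(32, 32, 1)); truth[20, 14, 1] <- 10
  expd <- forward_project(activity_volume(g, truth), acq)
  fit <- reconstruct(expd, recon_params(n_iterations = 200, stop_tol = 0))
  expect_equal(which.max(fit$volume$values), which.max(truth))
  # EM count preservation: sensitivity-weighted total = measured total
  # at every iteration, well within 0.1%
  rel <- abs(fit$trace$sens_total[-1] - fit$measured_total) /
    fit$measured_total
  expect_true(all(rel < 1e-3))
})

test_that("an EM fixed point is left unchanged by one more update", {
  set.seed(7)
  g <- grid_geometry(c(16, 16, 1), c(2, 2, 2))
  acq <- acquisition_model(n_angles = 16, n_radial_bins = 24,
                           radial_bin_size = 2, psf_fwhm = 0,
                           count_scale = 1)
  truth <- activity_volume(g, array(stats::runif(256, 1, 4), c(16, 16, 1)))
  expd <- forward_project(truth, acq)
  # the truth is an exact ML fixed point of its own expectation data
  # (yhat = y makes the EM ratio 1 everywhere): one update leaves it
  # unchanged to float precision
  again <- reconstruct(expd, recon_params(n_iterations = 1, stop_tol = 0),
                       init = truth)
  delta <- max(abs(again$volume$values - truth$values)) / max(truth$values)
  expect_lt(delta, 1e-10)
  # whereas one update from the uniform start is still far away
  cold <- reconstruct(expd, recon_params(n_iterations = 1, stop_tol = 0))
  expect_gt(max(abs(cold$volume$values - truth$values)) /
              max(truth$values), 1e-3)
})

test_that("penalized objective is monotone over full 1-subset iterations", {
  set.seed(8)
  g <- grid_geometry(c(24, 24, 1), c(2.73, 2.73, 2.8))
  acq <- acquisition_model(n_angles = 24, n_radial_bins = 32,
                           radial_bin_size = 2.73, psf_fwhm = 3,
                           count_scale = 0.5)
  for (seed in 1:5) {
    vol <- activity_volume(g, array(stats::runif(576, 0, 10), c(24, 24, 1)))
    counts <- sample_counts(forward_project(vol, acq), seed)
    fit <- reconstruct(counts, recon_params(
      penalty_params(350, beta_scale = 3e-4),
      n_iterations = 15, stop_tol = 0))
    expect_true(all(diff(fit$trace$objective) >= -1e-7 *
                      abs(fit$trace$objective[-1])))
    expect_true(fit$status == "ok")
  }
})

test_that("stronger regularization yields smoother converged images", {
  set.seed(9)
  ph <- small_hot_phantom()
  g <- grid_geometry(c(64, 64, 3), c(2.73, 2.73, 2.8))
  truth <- build_phantom(ph, g)
  acq <- small_acq()
  counts <- sample_counts(forward_project(truth, acq), 21)
  pen_vals <- sapply(c(100, 350, 700, 1000), function(beta) {
    fit <- reconstruct(counts, recon_params(
      penalty_params(beta, beta_scale = 3e-4), n_iterations = 30))
    # noise in a background patch away from both spheres
    patch <- bplquant:::sphere_mask(g, c(0, 40, 0), 16)
    c(rdp_value(fit$volume, penalty_params(1)),
      stats::sd(fit$volume$values[patch]))
  })
  expect_true(all(diff(pen_vals[1, ]) < 0))  # rdp_value strictly decreases
  expect_lt(pen_vals[2, 4], pen_vals[2, 1])  # background SD shrinks
})

test_that("geometry mismatches and bad subset counts are rejected", {
  g <- grid_geometry(c(16, 16, 1), c(2, 2, 2))
  acq <- acquisition_model(n_angles = 12, n_radial_bins = 24,
                           radial_bin_size = 2)
  counts <- projection_data(array(1, c(24, 12, 1)), acq, g, "sampled")
  other <- acquisition_model(n_angles = 10, n_radial_bins = 24,
                             radial_bin_size = 2)
  expect_error(reconstruct(counts, recon_params(), acq = other),
               "does not match")
  expect_error(reconstruct(counts, recon_params(n_subsets = 5)),
               "divide")
})
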