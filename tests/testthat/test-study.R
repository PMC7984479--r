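# a deliberately small sweep configuration to keep unit runtimes short;
# full-size sweeps are exercised by the acceptance suite
mini_nema_cfg <- function(noiseless = FALSE, replicates = 2L, seeds = NULL) {
  sweep_config(mode = "nema", betas = c(200, 350, 800),
               reference_beta = 350, replicates = replicates,
               seeds = seeds, noiseless = noiseless,
               grid = grid_geometry(c(96, 96, 15)),
               n_iterations = 6L, n_subsets = 4L)
}

test_that("sweep configuration validates the beta grid", {
  expect_error(sweep_config(betas = c(100, 100, 200)), "increasing")
  expect_error(sweep_config(betas = c(-1, 100)), "increasing")
  expect_error(sweep_config(betas = c(100, 200), reference_beta = 350),
               "reference_beta")
  expect_error(sweep_config(replicates = 2, seeds = 1:3), "one entry")
})

test_that("a NEMA sweep yields one row per sphere x beta x replicate", {
  metrics <- run_sweep(mini_nema_cfg(noiseless = TRUE))
  expect_equal(nrow(metrics), 6 * 3 * 1)
  expect_setequal(unique(metrics$diameter_mm), c(10, 13, 17, 22, 28, 37))
  expect_true(all(is.finite(metrics$rc_pct)))
  expect_true(all(is.na(metrics$suv_mean)))
})

test_that("identical seeds reproduce an identical metrics table", {
  m1 <- run_sweep(mini_nema_cfg(replicates = 1L, seeds = 5L))
  m2 <- run_sweep(mini_nema_cfg(replicates = 1L, seeds = 5L))
  attr(m1, "phantom") <- attr(m2, "phantom") <- NULL
  expect_identical(m1, m2)
})

test_that("RC models fit per beta on replicate-averaged sweep points", {
  metrics <- data.frame(
    object_id = rep(1:6, 2), group = "sphere",
    diameter_mm = rep(c(10, 13, 17, 22, 28, 37), 2),
    beta = rep(c(100, 1000), each = 6), replicate = 1L,
    rc_pct = c(2 * c(10, 13, 17, 22, 28, 37) + 10,
               1.5 * c(10, 13, 17, 22, 28, 37) + 5))
  models <- fit_rc_models(metrics)
  expect_named(models, c("100", "1000"))
  expect_equal(models[["100"]]$slope, 2)
  expect_equal(models[["1000"]]$intercept, 5)
  expect_equal(models[["100"]]$diameter_range, c(10, 37))
})

test_that("metric-table PVC adds corrected columns dividing by the RC", {
  metrics <- data.frame(
    object_id = 1:2, group = c("<10 mm", "10-30 mm"),
    diameter_mm = c(8, 20), beta = 350, replicate = 1L,
    suv_mean = c(1, 1.5), suv_max = c(2, 2.5), suv_peak = c(1.5, 2))
  models <- list("350" = fit_rc_regression(c(10, 20, 30),
                                           c(50, 60, 70), beta = 350))
  out <- apply_pvc_to_metrics(metrics, models)
  expect_equal(out$estimated_rc[2], 0.6)
  expect_equal(out$suv_max_pvc[2], 2.5 / 0.6)
  expect_true(out$extrapolated[1])
  expect_false(out$extrapolated[2])
  expect_error(apply_pvc_to_metrics(metrics, models["-1"]), "no RC model")
})

test_that("group-mean SUV correlation is computed over per-beta averages", {
  metrics <- data.frame(
    object_id = rep(1:2, 3), group = "<10 mm",
    diameter_mm = 8, beta = rep(c(100, 550, 1000), each = 2),
    replicate = 1L,
    suv_max = c(2.0, 2.2, 1.5, 1.7, 1.0, 1.2))
  ct <- suv_beta_correlation(metrics, "suv_max", "<10 mm")
  expect_equal(ct$r, -1, tolerance = 1e-9)
  expect_error(suv_beta_correlation(metrics, "suv_max", "none"), "no rows")
})
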