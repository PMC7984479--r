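test_that("thresholding a binary sphere recovers exactly its voxel set", {
  g <- grid_geometry(c(32, 32, 32), c(2, 2, 2))
  m <- bplquant:::sphere_mask(g, c(0, 0, 0), 24)
  img <- activity_volume(g, array(ifelse(m, 10, 0), dim(m)))
  voi <- segment_voi(img, c(16, 16, 16), fraction = 0.42)
  expect_identical(voi$mask, m)
  expect_equal(voi$provenance$fraction, 0.42)
})

test_that("42% isocontour of a Gaussian blob matches the analytic radius", {
  g <- grid_geometry(c(41, 41, 41), c(1, 1, 1))
  sigma <- 4
  cx <- voxel_centers(g, 1)
  d2 <- outer(outer(cx^2, cx^2, "+"), cx^2, "+")
  img <- activity_volume(g, 10 * exp(-d2 / (2 * sigma^2)))
  voi <- segment_voi(img, c(21, 21, 21), fraction = 0.42)
  r_analytic <- sigma * sqrt(2 * log(1 / 0.42))
  r_measured <- max(sqrt(d2[voi$mask]))
  expect_lt(abs(r_measured - r_analytic), 1)
})

test_that("a near-unity threshold keeps only the maximum voxel", {
  g <- grid_geometry(c(21, 21, 1), c(1, 1, 1))
  cx <- voxel_centers(g, 1)
  img <- activity_volume(g, array(10 * exp(-outer(cx^2, cx^2, "+") / 50),
                                  c(21, 21, 1)))
  voi <- segment_voi(img, c(11, 11, 1), fraction = 0.999)
  expect_equal(sum(voi$mask), 1L)
  expect_true(voi$mask[11, 11, 1])
})

test_that("segmentation fails cleanly on empty neighborhoods", {
  g <- tiny_grid(c(8, 8, 1))
  img <- activity_volume(g, array(0, c(8, 8, 1)))
  expect_error(segment_voi(img, c(4, 4, 1)), "segmentation failure")
  expect_error(segment_voi(img, c(99, 4, 1)), "inside the grid")
})

test_that("VOI propagation copies the voxel set and records provenance", {
  g <- grid_geometry(c(16, 16, 4), c(2, 2, 2))
  m <- bplquant:::sphere_mask(g, c(0, 0, 0), 10)
  img <- activity_volume(g, array(ifelse(m, 5, 0), dim(m)))
  voi <- segment_voi(img, round(world_to_voxel(g, c(0, 0, 0))), 0.42,
                     reference_beta = 350)
  tgt <- activity_volume(g, array(1, c(16, 16, 4)))
  moved <- propagate_voi(voi, tgt, target_beta = 900)
  expect_identical(moved$mask, voi$mask)
  expect_equal(moved$provenance$target_beta, 900)
  other <- activity_volume(grid_geometry(c(16, 16, 5), c(2, 2, 2)),
                           array(1, c(16, 16, 5)))
  expect_error(propagate_voi(voi, other), "grid mismatch")
})

test_that("RC, CR and BV implement their closed forms and guard domains", {
  expect_equal(recovery_coefficient(13.2, 13.2), 100)
  expect_equal(recovery_coefficient(6.6, 13.2), 50)
  expect_error(recovery_coefficient(1, 0), "a_k")
  expect_equal(contrast_recovery(4, 1, 4), 100)
  expect_equal(contrast_recovery(1, 1, 4), 0)
  expect_equal(contrast_recovery(2.5, 1, 4), 50)
  expect_error(contrast_recovery(1, 1, 1), "contrast")
  expect_error(contrast_recovery(1, 0, 4), "a_b")
  expect_equal(background_variability(0, 5), 0)
  expect_equal(background_variability(5, 5), 100)
  expect_error(background_variability(1, 0), "c_b")
})

test_that("NEMA background ROI set has 60 disjoint sphere-free members", {
  g <- grid_geometry(c(96, 96, 32))
  ph <- nema_phantom_spec()
  truth <- build_phantom(ph, g)
  roi <- place_background_rois(truth, ph, 37)
  expect_length(roi$means, 60L)
  expect_equal(nrow(roi$centers), 12L)
  # pairwise non-overlap
  dd <- as.matrix(stats::dist(roi$centers))
  expect_true(all(dd[upper.tri(dd)] >= 37))
  # clearance from every sphere
  for (s in ph$spheres) {
    d <- sqrt((roi$centers[, 1] - s$center[1])^2 +
                (roi$centers[, 2] - s$center[2])^2)
    expect_true(all(d >= 37 / 2 + s$diameter / 2))
  }
  # constant background field: every ROI mean equals the background value
  expect_true(all(abs(roi$means - 3.3) < 1e-12))
  expect_error(place_background_rois(truth, ph, 150),
               "too small|could only place")
})

test_that("SUV conversion is the dose-normalized concentration", {
  ctx <- suv_context(300000, 60000)
  expect_equal(suv(5, ctx), 1)
  expect_equal(suv(0, ctx), 0)
  expect_equal(suv(10, ctx), 2 * suv(5, ctx))
  expect_equal(suv(5, suv_context(600000, 60000)), 0.5)
  expect_error(suv_context(0, 60000), "injected_dose")
})

test_that("suv_peak equals exhaustive search and is bounded by the max", {
  set.seed(10)
  ctx <- suv_context(300000, 60000)
  g <- grid_geometry(c(24, 24, 24), c(3, 3, 3))
  kd <- 2 * (3 * 1000 / (4 * pi))^(1 / 3)
  noff <- floor(kd / 2 / g$voxel_size)
  offs <- as.matrix(expand.grid(-noff[1]:noff[1], -noff[2]:noff[2],
                                -noff[3]:noff[3]))
  offs <- offs[rowSums(sweep(offs, 2, g$voxel_size, "*")^2) <= (kd / 2)^2, ]
  for (rep in 1:5) {
    base <- array(stats::runif(24^3, 0, 2), c(24, 24, 24))
    img <- gaussian_blur(activity_volume(g, base), 5)
    whole <- voi_mask(g, array(TRUE, c(24, 24, 24)))
    got <- suv_peak(img, whole, ctx)
    # naive exhaustive scan over every voxel center
    best <- -Inf
    for (q in seq_len(24^3)) {
      ijk <- arrayInd(q, c(24, 24, 24))
      nb <- sweep(offs, 2, as.vector(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= 24 & nb[, 2] >= 1 & nb[, 2] <= 24 &
        nb[, 3] >= 1 & nb[, 3] <= 24
      best <- max(best, mean(img$values[nb[ok, , drop = FALSE]]))
    }
    expect_equal(got, suv(best, ctx), tolerance = 1e-12)
    expect_lte(got, suv(max(img$values), ctx))
  }
  # uniform field: peak equals the constant
  u <- activity_volume(g, array(2.5, c(24, 24, 24)))
  expect_equal(suv_peak(u, voi_mask(g, array(TRUE, c(24, 24, 24))), ctx),
               suv(2.5, ctx))
  coarse <- activity_volume(grid_geometry(c(4, 4, 4), c(8, 8, 8)),
                            array(1, c(4, 4, 4)))
  expect_error(
    suv_peak(coarse, voi_mask(coarse$grid, array(TRUE, c(4, 4, 4))), ctx),
    "finer grid")
})

test_that("SNR and CNR are the stated ratios with guarded denominators", {
  expect_equal(snr(8, 2), 4)
  expect_gt(snr(8, 1), snr(8, 2))
  expect_error(snr(8, 0), "reference_sd")
  expect_equal(cnr(6, 2, 1), 4)
  expect_equal(cnr(3, 3, 2), 0)
  expect_lt(cnr(1, 2, 1), 0)
  expect_error(cnr(6, 2, 0), "sd_bg")
})

test_that("the CNR annulus sits between 1.5x and 2.5x the VOI radius", {
  g <- grid_geometry(c(48, 48, 48), c(2, 2, 2))
  m <- bplquant:::sphere_mask(g, c(0, 0, 0), 20)
  voi <- voi_mask(g, m)
  allowed <- array(TRUE, c(48, 48, 48))
  ann <- lesion_background_annulus(voi, c(0, 0, 0), allowed)
  r_eq <- ann$provenance$r_eq
  cx <- voxel_centers(g, 1)
  d <- sqrt(outer(outer(cx^2, cx^2, "+"), cx^2, "+"))
  expect_true(all(d[ann$mask] >= 1.5 * r_eq - 1e-9))
  expect_true(all(d[ann$mask] <= 2.5 * r_eq + 1e-9))
  expect_false(any(ann$mask & m))
})
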