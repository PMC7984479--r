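test_that("NEMA phantom voxelizes at exactly 4:1 sphere-to-background", {
  g <- grid_geometry(c(96, 96, 32))
  spec <- nema_phantom_spec()
  vol <- build_phantom(spec, g)
  # interior sphere voxels (eroded by one voxel diagonal) vs deep background
  s <- spec$spheres[[6]]
  interior <- bplquant:::sphere_mask(g, s$center, s$diameter - 2 * 4)
  expect_true(all(vol$values[interior] == 13.2))
  far_bg <- bplquant:::sphere_mask(g, c(0, 0, -30), 10)
  expect_true(all(vol$values[far_bg] == 3.3))
  expect_equal(max(vol$values[interior]) / vol$values[far_bg][1], 4.0)
})

test_that("empty phantom gives an all-zero volume", {
  g <- tiny_grid(c(8, 8, 8))
  spec <- phantom_spec(list(), background_activity = 0,
                       body = list(center = c(0, 0), semi_axes = c(3, 3)))
  expect_true(all(build_phantom(spec, g)$values == 0))
})

test_that("voxelized sphere volume matches the analytic value and improves
           with subsampling", {
  g <- grid_geometry(c(48, 48, 48), c(1, 1, 1))
  spec <- phantom_spec(list(sphere_spec(c(0, 0, 0), 37, 1)),
                       background_activity = 0,
                       body = list(center = c(0, 0), semi_axes = c(23, 23)))
  analytic <- pi / 6 * 37^3
  errs <- sapply(c(1, 3, 5), function(s) {
    v <- build_phantom(spec, g, subsample = s)
    abs(sum(v$values) - analytic) / analytic
  })
  expect_lt(errs[2], 0.01)        # 3x corner subsampling within 1%
  expect_true(all(diff(errs) < 0))  # error shrinks monotonically 1 -> 3 -> 5
})

test_that("invalid geometry is rejected with a geometry error", {
  g <- grid_geometry(c(96, 96, 32))
  overlapping <- phantom_spec(
    list(sphere_spec(c(0, 0, 0), 20, 1), sphere_spec(c(10, 0, 0), 20, 1)),
    background_activity = 0,
    body = list(center = c(0, 0), semi_axes = c(100, 100)))
  expect_error(build_phantom(overlapping, g), "overlap")
  outside <- phantom_spec(
    list(sphere_spec(c(95, 0, 0), 20, 1)),
    background_activity = 0,
    body = list(center = c(0, 0), semi_axes = c(100, 100)))
  expect_error(build_phantom(outside, g), "outside the body")
})

test_that("clinical phantom catalog honors size groups, contrast and seed", {
  g <- grid_geometry(c(96, 96, 32))
  ph <- build_clinical_phantom(c(5.7, 15, 29.4), 4, g, seed = 3)
  expect_equal(sum(ph$catalog$group == "<10 mm"), 1L)
  expect_equal(sum(ph$catalog$group == "10-30 mm"), 2L)
  expect_equal(ph$catalog$activity / ph$lung_activity, rep(4, 3))
  ph2 <- build_clinical_phantom(c(5.7, 15, 29.4), 4, g, seed = 3)
  expect_identical(ph$volume$values, ph2$volume$values)
  # 1:1 contrast: lesion voxels indistinguishable from lung background
  ph1 <- build_clinical_phantom(15, 1, g, seed = 3)
  expect_true(all(ph1$volume$values[ph1$lung_mask] == ph1$lung_activity))
  expect_error(build_clinical_phantom(2, 4, g), "diameters")
})
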