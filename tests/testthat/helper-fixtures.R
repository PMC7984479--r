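# Small construction helpers shared across test files.

tiny_grid <- function(shape = c(4, 4, 4), voxel = c(1, 1, 1)) {
  grid_geometry(shape, voxel)
}

random_volume <- function(shape = c(4, 4, 4), voxel = c(1, 1, 1),
                          max_val = 10) {
  activity_volume(tiny_grid(shape, voxel),
                  array(stats::runif(prod(shape), 0, max_val), shape))
}

# Pure-R brute-force relative difference penalty over all ordered neighbor
# pairs; the independent oracle for the compiled implementation.
brute_rdp <- function(vals, voxel, gamma, neighborhood) {
  shape <- dim(vals)
  nb <- bplquant:::neighbor_offsets(neighborhood, voxel)
  offs <- rbind(nb$offsets, -nb$offsets)
  w <- c(nb$weights, nb$weights)
  total <- 0
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      for (m in seq_len(nrow(offs))) {
        p <- c(i, j, k) + offs[m, ]
        if (any(p < 1) || any(p > shape)) next
        a <- vals[i, j, k]; b <- vals[p[1], p[2], p[3]]
        s <- a + b + gamma * abs(a - b)
        if (s > 0) total <- total + w[m] * (a - b)^2 / s
      }
    }
  total
}

# two-sphere phantom inside a small disc body, for recon trend tests on
# grids too small to host the full six-sphere ring
small_hot_phantom <- function() {
  spheres <- list(sphere_spec(c(-25, 0, 0), 14, 13.2),
                  sphere_spec(c(25, 0, 0), 26, 13.2))
  # explicit axial range so the spheres may be truncated by thin test grids
  phantom_spec(spheres, background_activity = 3.3,
               body = list(center = c(0, 0), semi_axes = c(60, 60),
                           z_range = c(-50, 50)))
}

small_acq <- function(psf = 4.5, n_angles = 48L) {
  acquisition_model(n_angles = n_angles, n_radial_bins = 64L,
                    radial_bin_size = 2.73, psf_fwhm = psf,
                    count_scale = 0.05)
}
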