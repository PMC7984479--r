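#' Acquisition model
#'
#' Parallel-beam acquisition geometry plus the simulation's resolution and
#' count-level settings.  Together with [forward_project()] this realizes the
#' system matrix of the reconstruction problem: slice-by-slice 2-D parallel
#' projections of the (optionally PSF-blurred) activity volume, scaled to
#' expected coincidence counts.
#'
#' @param n_angles number of projection angles over 180 degrees.
#' @param n_radial_bins number of radial bins per projection.
#' @param radial_bin_size radial sampling pitch in mm.
#' @param psf_fwhm image-space Gaussian PSF FWHM in mm applied before
#'   projection (the resolution of the simulated scanner).  The
#'   reconstruction omits this blur from its own system model by default, so
#'   small objects are reconstructed with partial-volume losses.
#' @param count_scale expected counts per mm of line integral at 1 kBq/mL;
#'   controls the Poisson noise level.
#' @return A list of class `acquisition_model`.
#' @export
acquisition_model <- function(n_angles = 96L,
                              n_radial_bins = 128L,
                              radial_bin_size = 2.73,
                              psf_fwhm = 4.5,
                              count_scale = 0.05) {
  n_angles <- as.integer(n_angles); n_radial_bins <- as.integer(n_radial_bins)
  if (n_angles < 1L) stop("`n_angles` must be >= 1")
  if (n_radial_bins < 2L) stop("`n_radial_bins` must be >= 2")
  if (radial_bin_size <= 0) stop("`radial_bin_size` must be > 0")
  if (psf_fwhm < 0) stop("`psf_fwhm` must be >= 0")
  if (count_scale <= 0) stop("`count_scale` must be > 0")
  structure(list(n_angles = n_angles, n_radial_bins = n_radial_bins,
                 radial_bin_size = radial_bin_size, psf_fwhm = psf_fwhm,
                 count_scale = count_scale),
            class = "acquisition_model")
}

#' @export
print.acquisition_model <- function(x, ...) {
  cat(sprintf(
    "acquisition_model: %d angles x %d radial bins (%g mm), PSF %g mm FWHM\n",
    x$n_angles, x$n_radial_bins, x$radial_bin_size, x$psf_fwhm))
  invisible(x)
}

# cache of sparse system matrices keyed by in-plane geometry
.proj_cache <- new.env(parent = emptyenv())

# Sparse (n_radial * n_angles) x (nx * ny) parallel-beam matrix: pixel-driven
# with linear interpolation onto radial bins.  Entries carry pixel_area /
# bin_size so that A %*% x approximates the line integral (value * mm).
system_matrix <- function(grid, acq) {
  key <- paste(grid$shape[1], grid$shape[2],
               grid$voxel_size[1], grid$voxel_size[2],
               grid$origin[1], grid$origin[2],
               acq$n_angles, acq$n_radial_bins, acq$radial_bin_size,
               sep = "|")
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cx <- voxel_centers(grid, 1); cy <- voxel_centers(grid, 2)
  px <- rep(cx, times = ny); py <- rep(cy, each = nx)
  nr <- acq$n_radial_bins
  area <- grid$voxel_size[1] * grid$voxel_size[2]
  th <- (seq_len(acq$n_angles) - 1L) * pi / acq$n_angles
  ii <- jj <- ww <- vector("list", acq$n_angles)
  for (t in seq_along(th)) {
    s <- px * cos(th[t]) + py * sin(th[t])
    u <- s / acq$radial_bin_size + (nr + 1) / 2  # fractional bin index
    i0 <- floor(u); w1 <- i0 + 1 - u
    pix <- seq_len(nx * ny)
    row0 <- (t - 1L) * nr
    keep0 <- i0 >= 1 & i0 <= nr
    keep1 <- i0 + 1 >= 1 & i0 + 1 <= nr
    ii[[t]] <- c(row0 + i0[keep0], row0 + i0[keep1] + 1)
    jj[[t]] <- c(pix[keep0], pix[keep1])
    ww[[t]] <- c(w1[keep0], 1 - w1[keep1])
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(nr * acq$n_angles, nx * ny))
  A <- A * (area / acq$radial_bin_size)
  A <- methods::as(A, "CsparseMatrix")
  .proj_cache[[key]] <- A
  A
}

#' Projection data (sinograms)
#'
#' Expected or Poisson-sampled coincidence counts for every slice of a
#' volume, stored as an array with axes (radial bin, angle, slice).  The
#' generating [acquisition_model()] and [grid_geometry()] travel with the
#' data so that reconstruction needs no extra geometry arguments.
#'
#' @param values numeric array `(n_radial, n_angles, n_slices)`, >= 0.
#' @param acq the [acquisition_model()].
#' @param grid the image [grid_geometry()].
#' @param kind `"expected"` (real-valued means) or `"sampled"`
#'   (integer Poisson counts).
#' @return A list of class `projection_data`.
#' @export
projection_data <- function(values, acq, grid, kind = c("expected", "sampled")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  expect_dim <- c(acq$n_radial_bins, acq$n_angles, grid$shape[3])
  if (!identical(dim(values), as.integer(expect_dim)))
    stop(sprintf("projection dim (%s) does not match geometry (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  if (any(!is.finite(values)) || any(values < 0))
    stop("projection values must be finite and nonnegative")
  if (kind == "sampled" && any(values != round(values)))
    stop("sampled projection values must be integers")
  structure(list(values = values, acq = acq, grid = grid, kind = kind),
            class = "projection_data")
}

#' @export
print.projection_data <- function(x, ...) {
  cat(sprintf("projection_data (%s): %s bins, total counts %.4g\n",
              x$kind, paste(dim(x$values), collapse = " x "),
              sum(x$values)))
  invisible(x)
}

#' Forward-project a volume into expected counts
#'
#' Applies the acquisition PSF blur (if `acq$psf_fwhm > 0` and
#' `apply_psf = TRUE`), then computes slice-by-slice parallel-beam line
#' integrals scaled by `count_scale`.  The operation is linear in the input
#' volume.
#'
#' @param volume an [activity_volume()].
#' @param acq an [acquisition_model()].
#' @param apply_psf whether to apply the acquisition PSF; the reconstruction
#'   system model calls this with `FALSE`.
#' @return A [projection_data()] of kind `"expected"`.
#' @export
forward_project <- function(volume, acq, apply_psf = TRUE) {
  stopifnot(inherits(volume, "activity_volume"),
            inherits(acq, "acquisition_model"))
  v <- if (apply_psf && acq$psf_fwhm > 0)
    gaussian_blur(volume, acq$psf_fwhm) else volume
  A <- system_matrix(volume$grid, acq)
  nxy <- volume$grid$shape[1] * volume$grid$shape[2]
  X <- matrix(v$values, nxy, volume$grid$shape[3])
  Y <- as.matrix(A %*% X) * acq$count_scale
  projection_data(array(Y, c(acq$n_radial_bins, acq$n_angles,
                             volume$grid$shape[3])),
                  acq, volume$grid, kind = "expected")
}

#' Draw Poisson counts from expected projections
#'
#' Independent Poisson draws per sinogram bin; the same seed reproduces the
#' same counts bitwise.
#'
#' @param expected a [projection_data()] of kind `"expected"`.
#' @param seed integer RNG seed.
#' @return A [projection_data()] of kind `"sampled"`.
#' @export
sample_counts <- function(expected, seed) {
  stopifnot(inherits(expected, "projection_data"))
  if (expected$kind != "expected")
    stop("`expected` must be projection_data of kind 'expected'")
  if (any(expected$values < 0)) stop("expected counts must be >= 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  y <- stats::rpois(length(expected$values), expected$values)
  projection_data(array(as.numeric(y), dim(expected$values)),
                  expected$acq, expected$grid, kind = "sampled")
}
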