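#' Gaussian resolution blur in image space
#'
#' Separable 3-D Gaussian convolution used as the acquisition resolution
#' model: the phantom truth is blurred by the point-spread function before
#' projection, which is what induces the partial-volume effect that the
#' recovery-coefficient analysis measures.  The kernel is integrated over
#' voxel extents and truncated at 3 sigma; boundaries use zero padding
#' (activity blurring out of the field is lost, as in a real acquisition).
#'
#' @param volume an [activity_volume()].
#' @param fwhm full width at half maximum of the PSF in mm (scalar, applied
#'   isotropically in world units).  `fwhm = 0` returns the input unchanged.
#' @return A blurred [activity_volume()].
#' @export
gaussian_blur <- function(volume, fwhm) {
  stopifnot(inherits(volume, "activity_volume"), fwhm >= 0)
  if (fwhm == 0) return(volume)
  v <- gaussian_blur_array(volume$values, volume$grid, fwhm)
  activity_volume(volume$grid, pmax(v, 0))
}

# unvalidated separable blur on a raw array (also used on signed gradients
# inside the reconstruction; the blur kernel is symmetric, so this is its
# own adjoint)
gaussian_blur_array <- function(v, grid, fwhm) {
  if (fwhm == 0) return(v)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    h <- grid$voxel_size[ax]
    m <- max(1L, ceiling(3 * sigma / h))
    off <- (-m):m
    k <- stats::pnorm((off + 0.5) * h, sd = sigma) -
      stats::pnorm((off - 0.5) * h, sd = sigma)
    k <- k / sum(k)
    n <- dim(v)[ax]
    # band matrix acting along axis `ax`
    K <- matrix(0, n, n)
    for (i in seq_along(off)) {
      j <- seq_len(n) + off[i]
      ok <- j >= 1L & j <= n
      K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[i]
    }
    perm <- c(ax, setdiff(1:3, ax))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    vp <- K %*% matrix(vp, dp[1], dp[2] * dp[3])
    dim(vp) <- dp
    v <- aperm(vp, order(perm))
  }
  v
}
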