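#' Relative difference penalty parameters
#'
#' The penalty weight `beta` is the single user-facing regularization knob of
#' penalized-likelihood reconstruction; `gamma` controls edge preservation
#' (larger gamma penalizes large voxel differences less, keeping edges
#' sharper).  Neighbor weights are the inverse Euclidean center distance in
#' mm, normalized so the nearest neighbor has weight 1.
#'
#' `beta_scale` maps the conventional clinical beta magnitudes (hundreds)
#' onto this simulator's count level: the objective uses
#' `beta * beta_scale` as the effective penalty weight.  Trends across a
#' beta sweep, not absolute beta correspondence with any vendor
#' implementation, are the quantity of interest.
#'
#' @param beta nonnegative penalty weight.
#' @param gamma nonnegative edge-preservation parameter (default 2, the
#'   conventional choice for this penalty family).
#' @param neighborhood 3-D connectivity: 6, 18 or 26.  On single-slice
#'   volumes the in-plane restriction applies (18 and 26 give the 8-neighbor
#'   2-D system).
#' @param beta_scale multiplier converting `beta` to the effective penalty
#'   weight for this simulator's count level.
#' @return A list of class `penalty_params`.
#' @export
penalty_params <- function(beta, gamma = 2, neighborhood = 18L,
                           beta_scale = 1) {
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0")
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be >= 0")
  if (!neighborhood %in% c(6L, 18L, 26L))
    stop("`neighborhood` must be 6, 18 or 26")
  if (!is.finite(beta_scale) || beta_scale < 0)
    stop("`beta_scale` must be >= 0")
  structure(list(beta = beta, gamma = gamma,
                 neighborhood = as.integer(neighborhood),
                 beta_scale = beta_scale),
            class = "penalty_params")
}

# Half-set of neighbor offsets (each unordered pair represented once) and
# inverse-distance weights in mm, nearest neighbor normalized to 1.
neighbor_offsets <- function(neighborhood, voxel_size) {
  base6 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  base18 <- rbind(base6,
                  c(1, 1, 0), c(1, -1, 0),
                  c(1, 0, 1), c(1, 0, -1),
                  c(0, 1, 1), c(0, 1, -1))
  base26 <- rbind(base18,
                  c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))
  off <- switch(as.character(neighborhood),
                "6" = base6, "18" = base18, "26" = base26)
  d <- sqrt(colSums((t(off) * voxel_size)^2))
  list(offsets = off, weights = min(d) / d)
}

check_penalty_input <- function(volume, penalty) {
  stopifnot(inherits(volume, "activity_volume"),
            inherits(penalty, "penalty_params"))
  if (any(volume$values < 0))
    stop("the relative difference penalty is defined on nonnegative images")
}

#' Relative difference penalty value
#'
#' Computes `sum_j sum_{k in N_j} w_jk (x_j - x_k)^2 /
#' (x_j + x_k + gamma |x_j - x_k|)` over ordered neighbor pairs.  Pairs with
#' a zero denominator (both voxels zero) contribute 0.  The penalty is
#' positively homogeneous of degree 1: scaling the image by `a > 0` scales
#' the penalty by `a`.
#'
#' @param volume a nonnegative [activity_volume()].
#' @param penalty a [penalty_params()] (only `gamma` and the neighborhood
#'   affect the value; `beta` weights it inside the objective).
#' @return Scalar penalty value.
#' @export
rdp_value <- function(volume, penalty) {
  check_penalty_input(volume, penalty)
  nb <- neighbor_offsets(penalty$neighborhood, volume$grid$voxel_size)
  .rdp_value_cpp(as.numeric(volume$values), volume$grid$shape,
                 nb$offsets, nb$weights, penalty$gamma)
}

#' Gradient of the relative difference penalty
#'
#' Analytic partial derivatives of [rdp_value()] with respect to each voxel,
#' returned as a volume-shaped array.
#'
#' @inheritParams rdp_value
#' @return Numeric array with the same dim as `volume$values`.
#' @export
rdp_gradient <- function(volume, penalty) {
  check_penalty_input(volume, penalty)
  nb <- neighbor_offsets(penalty$neighborhood, volume$grid$voxel_size)
  g <- .rdp_gradient_cpp(as.numeric(volume$values), volume$grid$shape,
                         nb$offsets, nb$weights, penalty$gamma)
  array(g, volume$grid$shape)
}
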