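#' Volume-of-interest mask
#'
#' Boolean voxel mask with provenance: the threshold fraction it was drawn
#' at, the reference image (beta) it was segmented on, and the seed object.
#'
#' @param grid a [grid_geometry()].
#' @param mask logical array with `dim == grid$shape`.
#' @param provenance named list (threshold fraction, reference beta, seed).
#' @return A list of class `voi_mask`.
#' @export
voi_mask <- function(grid, mask, provenance = list()) {
  stopifnot(inherits(grid, "grid_geometry"), is.logical(mask))
  if (!identical(dim(mask), grid$shape)) stop("mask dim must match grid")
  if (!any(mask)) stop("VOI mask is empty")
  structure(list(grid = grid, mask = mask, provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask: %d voxels (%.2f mL)%s\n", sum(x$mask),
              sum(x$mask) * prod(x$grid$voxel_size) / 1000,
              if (!is.null(x$provenance$fraction))
                sprintf(", %g%% threshold", 100 * x$provenance$fraction)
              else ""))
  invisible(x)
}

# 26-connected neighbors of a voxel index triple, clipped to the grid
.neighbors26 <- function(ijk, shape) {
  nb <- sweep(.delta26, 2, ijk, "+")
  nb[nb[, 1] >= 1 & nb[, 1] <= shape[1] &
     nb[, 2] >= 1 & nb[, 2] <= shape[2] &
     nb[, 3] >= 1 & nb[, 3] <= shape[3], , drop = FALSE]
}

#' Threshold-based VOI segmentation
#'
#' Hill-climbs from `seed_point` to the nearest local maximum, thresholds
#' the image at `fraction` times that maximum, and returns the 26-connected
#' component of suprathreshold voxels containing the maximum.  This is the
#' isocontour VOI tool used with the conventional 42%-of-maximum threshold.
#'
#' @param image an [activity_volume()].
#' @param seed_point integer voxel index triple near the object.
#' @param fraction threshold fraction of the local maximum, in (0, 1).
#' @param reference_beta optional beta value of the image, recorded in the
#'   mask provenance (VOIs are conventionally drawn once on a reference-beta
#'   image and propagated to the others).
#' @param max_radius_mm growth bound: the component is not allowed to extend
#'   further than this from the local maximum, which keeps the VOI from
#'   leaking through suprathreshold noise into neighboring structures.  The
#'   default comfortably contains the largest (37 mm) phantom sphere.
#' @return A [voi_mask()].
#' @export
segment_voi <- function(image, seed_point, fraction = 0.42,
                        reference_beta = NULL, max_radius_mm = 30) {
  stopifnot(inherits(image, "activity_volume"))
  seed_point <- as.integer(seed_point)
  shape <- image$grid$shape
  if (length(seed_point) != 3L || any(seed_point < 1L) ||
      any(seed_point > shape))
    stop("`seed_point` must be a voxel index inside the grid")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)")
  v <- image$values
  # hill climb to the local maximum nearest the seed
  cur <- seed_point
  for (step in 1:10000) {
    nb <- .neighbors26(cur, shape)
    vals <- v[nb]
    best <- which.max(vals)
    if (vals[best] > v[cur[1], cur[2], cur[3]]) cur <- nb[best, ]
    else break
  }
  peak <- v[cur[1], cur[2], cur[3]]
  if (peak <= 0)
    stop("segmentation failure: no voxel above threshold near the seed")
  thr <- fraction * peak
  supra <- v >= thr
  if (is.finite(max_radius_mm)) {
    peak_world <- voxel_to_world(image$grid, as.numeric(cur))
    supra <- supra & sphere_mask(image$grid, peak_world, 2 * max_radius_mm)
  }
  # BFS for the 26-connected component containing the peak
  mask <- array(FALSE, shape)
  lin <- function(ijk) ijk[1] + (ijk[2] - 1L) * shape[1] +
    (ijk[3] - 1L) * shape[1] * shape[2]
  queue <- matrix(cur, 1)
  mask[lin(cur)] <- TRUE
  while (nrow(queue)) {
    nxt <- vector("list", nrow(queue))
    for (q in seq_len(nrow(queue))) {
      nb <- .neighbors26(queue[q, ], shape)
      li <- nb[, 1] + (nb[, 2] - 1L) * shape[1] +
        (nb[, 3] - 1L) * shape[1] * shape[2]
      new <- supra[li] & !mask[li]
      mask[li[new]] <- TRUE
      nxt[[q]] <- nb[new, , drop = FALSE]
    }
    queue <- do.call(rbind, nxt)
  }
  voi_mask(image$grid, mask,
           provenance = list(fraction = fraction,
                             reference_beta = reference_beta,
                             seed_point = seed_point,
                             peak_value = peak))
}

#' Propagate a VOI mask onto another image
#'
#' Copies the voxel set unchanged (as when a VOI drawn on the reference-beta
#' image is applied to reconstructions at other beta values) and records the
#' target beta in the provenance.
#'
#' @param mask a [voi_mask()].
#' @param target an [activity_volume()] on the same grid.
#' @param target_beta optional beta value of the target image.
#' @return A [voi_mask()] with identical voxels.
#' @export
propagate_voi <- function(mask, target, target_beta = NULL) {
  stopifnot(inherits(mask, "voi_mask"), inherits(target, "activity_volume"))
  if (!grids_equal(mask$grid, target$grid))
    stop("grid mismatch between VOI mask and target image")
  prov <- mask$provenance
  prov$target_beta <- target_beta
  voi_mask(mask$grid, mask$mask, prov)
}

#' Spherical VOI at a known center
#'
#' Voxels whose centers lie within `diameter / 2` of `center` (world mm).
#' Used for the 1.0-cm reference-region VOI and for kernel construction.
#'
#' @param grid a [grid_geometry()].
#' @param center world coordinates (mm).
#' @param diameter sphere diameter (mm).
#' @return A [voi_mask()].
#' @export
spherical_voi <- function(grid, center, diameter) {
  m <- sphere_mask(grid, center, diameter)
  if (!any(m))
    stop("spherical VOI contains no voxel centers; grid too coarse")
  voi_mask(grid, m, provenance = list(center = center, diameter = diameter))
}

#' Recovery coefficient (percent)
#'
#' `RC = 100 * A_M / A_K`: measured mean concentration in a hot object
#' relative to its known filled concentration.  Below 100% for small objects
#' because of partial-volume losses.
#'
#' @param a_m measured mean activity concentration, kBq/mL (>= 0).
#' @param a_k known activity concentration, kBq/mL (> 0).
#' @return RC in percent.
#' @export
recovery_coefficient <- function(a_m, a_k) {
  if (any(!is.finite(a_k)) || any(a_k <= 0)) stop("`a_k` must be > 0")
  if (any(!is.finite(a_m)) || any(a_m < 0)) stop("`a_m` must be >= 0")
  100 * a_m / a_k
}

#' Contrast recovery (percent)
#'
#' `CR = 100 * (A_M / A_B - 1) / (C - 1)`: the measured hot-sphere contrast
#' over background relative to the known filled contrast `C`.
#'
#' @param a_m measured mean sphere concentration, kBq/mL.
#' @param a_b measured mean background concentration, kBq/mL (> 0).
#' @param contrast known sphere-to-background ratio `C` (> 1).
#' @return CR in percent.
#' @export
contrast_recovery <- function(a_m, a_b, contrast) {
  if (any(!is.finite(a_b)) || any(a_b <= 0)) stop("`a_b` must be > 0")
  if (any(!is.finite(contrast)) || any(contrast <= 1))
    stop("`contrast` must be > 1")
  100 * (a_m / a_b - 1) / (contrast - 1)
}

#' Background variability (percent)
#'
#' `BV = 100 * SD_B / C_B` where `SD_B` and `C_B` are the standard deviation
#' and mean of the background ROI means: the image's noise metric.
#'
#' @param sd_b standard deviation of background ROI means, kBq/mL.
#' @param c_b mean of background ROI means, kBq/mL (> 0).
#' @return BV in percent.
#' @export
background_variability <- function(sd_b, c_b) {
  if (any(!is.finite(c_b)) || any(c_b <= 0)) stop("`c_b` must be > 0")
  if (any(!is.finite(sd_b)) || any(sd_b < 0)) stop("`sd_b` must be >= 0")
  100 * sd_b / c_b
}

#' Place the NEMA background ROI set
#'
#' Places 12 non-overlapping circular ROIs of diameter `sphere_diameter` in
#' the background compartment -- clear of all spheres by `margin` mm and of
#' the body edge by `edge_margin` mm -- on the central sphere slice, then
#' replicates them on the slices at `slice_offsets`, giving
#' `12 * length(slice_offsets)` ROIs (60 with the default two slices above
#' and two below).  Placement is deterministic: candidate centers on a 2 mm
#' lattice are taken greedily from the periphery inward.
#'
#' @param image an [activity_volume()] to measure ROI means on.
#' @param phantom the [phantom_spec()] that generated the image (supplies
#'   sphere positions and the body outline).
#' @param sphere_diameter ROI diameter in mm (matched to the sphere under
#'   analysis, per the NEMA scheme).
#' @param n_rois number of in-plane ROI positions (12).
#' @param slice_offsets slice offsets around the central sphere slice.
#' @param margin clearance (mm) between ROI edge and sphere surface.
#' @param edge_margin clearance (mm) between ROI edge and body edge.
#' @return An object of class `background_roi_set`: list with `centers`
#'   (n_rois x 2 matrix, mm), `slices` (indices), `diameter`, and `means`
#'   (vector of all ROI means, length `n_rois * length(slice_offsets)`).
#' @export
place_background_rois <- function(image, phantom, sphere_diameter,
                                  n_rois = 12L, slice_offsets = -2:2,
                                  margin = 4, edge_margin = 8) {
  stopifnot(inherits(image, "activity_volume"),
            inherits(phantom, "phantom_spec"))
  grid <- image$grid
  rr <- sphere_diameter / 2
  body <- phantom$body
  a <- body$semi_axes[1] - rr - edge_margin
  b <- body$semi_axes[2] - rr - edge_margin
  if (a <= 0 || b <= 0)
    stop("background region too small for the requested ROI diameter")
  sx <- vapply(phantom$spheres, function(s) s$center[1], 0)
  sy <- vapply(phantom$spheres, function(s) s$center[2], 0)
  sr <- vapply(phantom$spheres, function(s) s$diameter / 2, 0)
  gx <- seq(-body$semi_axes[1], body$semi_axes[1], by = 2) + body$center[1]
  gy <- seq(-body$semi_axes[2], body$semi_axes[2], by = 2) + body$center[2]
  cand <- expand.grid(x = gx, y = gy)
  keep <- ((cand$x - body$center[1]) / a)^2 +
    ((cand$y - body$center[2]) / b)^2 <= 1
  cand <- cand[keep, ]
  for (i in seq_along(sx)) {
    d <- sqrt((cand$x - sx[i])^2 + (cand$y - sy[i])^2)
    cand <- cand[d >= rr + sr[i] + margin, ]
  }
  ord <- order(-(((cand$x - body$center[1]) / body$semi_axes[1])^2 +
                   ((cand$y - body$center[2]) / body$semi_axes[2])^2),
               atan2(cand$y - body$center[2], cand$x - body$center[1]))
  cand <- cand[ord, ]
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- c(cand$x[i], cand$y[i])
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >=
              2 * rr + 1)) {
      centers <- rbind(centers, p)
      if (nrow(centers) >= n_rois) break
    }
  }
  if (nrow(centers) < n_rois)
    stop(sprintf("could only place %d of %d background ROIs of %g mm",
                 nrow(centers), n_rois, sphere_diameter))
  zc <- mean(vapply(phantom$spheres, function(s) s$center[3], 0))
  central <- which.min(abs(voxel_centers(grid, 3) - zc))
  slices <- central + slice_offsets
  if (any(slices < 1L) || any(slices > grid$shape[3]))
    stop("background ROI slices fall outside the grid")
  cx <- voxel_centers(grid, 1); cy <- voxel_centers(grid, 2)
  means <- numeric(0)
  for (sl in slices) {
    plane <- image$values[, , sl]
    for (i in seq_len(n_rois)) {
      m <- outer((cx - centers[i, 1])^2, (cy - centers[i, 2])^2, "+") <= rr^2
      means <- c(means, mean(plane[m]))
    }
  }
  structure(list(centers = centers, slices = slices,
                 diameter = sphere_diameter, means = means,
                 margin = margin, edge_margin = edge_margin),
            class = "background_roi_set")
}

#' @export
print.background_roi_set <- function(x, ...) {
  cat(sprintf(
    "background_roi_set: %d ROIs of %g mm on %d slices, mean %.4g kBq/mL\n",
    length(x$means), x$diameter, length(x$slices), mean(x$means)))
  invisible(x)
}

#' SUV conversion context
#'
#' Decay-corrected injected dose and body weight for body-weight SUV:
#' `SUV = r / (dose / weight)` with concentration `r` in kBq/mL, dose in kBq
#' and weight in g (the usual 1 g ~ 1 mL density convention makes the
#' result dimensionless).
#'
#' @param injected_dose decay-corrected injected dose, kBq (> 0).
#' @param body_weight body weight, g (> 0).
#' @return A list of class `suv_context`.
#' @export
suv_context <- function(injected_dose, body_weight) {
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("`injected_dose` must be > 0")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("`body_weight` must be > 0")
  structure(list(injected_dose = injected_dose, body_weight = body_weight),
            class = "suv_context")
}

#' Standardized uptake value
#'
#' @param r activity concentration, kBq/mL.
#' @param ctx a [suv_context()].
#' @return Dimensionless SUV (same shape as `r`).
#' @export
suv <- function(r, ctx) {
  stopifnot(inherits(ctx, "suv_context"))
  r / (ctx$injected_dose / ctx$body_weight)
}

#' SUVpeak: highest-mean 1 mL spherical kernel inside a VOI
#'
#' Moves a fixed 1 mL spherical kernel (diameter about 12.4 mm) over all
#' voxel centers of the VOI and reports the maximum kernel mean, converted
#' to SUV.  Kernel voxels falling outside the grid are dropped from the
#' mean.  Ties are broken by the smallest center index in scan order.
#'
#' @param image an [activity_volume()].
#' @param voi a [voi_mask()] of candidate kernel centers.
#' @param ctx a [suv_context()].
#' @param kernel_volume_ml kernel volume in mL (default 1).
#' @return Scalar SUVpeak.
#' @export
suv_peak <- function(image, voi, ctx, kernel_volume_ml = 1) {
  stopifnot(inherits(image, "activity_volume"), inherits(voi, "voi_mask"))
  if (!grids_equal(image$grid, voi$grid))
    stop("grid mismatch between image and VOI")
  grid <- image$grid
  kd <- 2 * (3 * kernel_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  if (any(kd / grid$voxel_size < 2))
    stop("grid too coarse for the SUVpeak kernel; use a finer grid")
  # kernel as integer index offsets whose center offsets lie in the sphere
  noff <- floor(kd / 2 / grid$voxel_size)
  offs <- as.matrix(expand.grid(-noff[1]:noff[1], -noff[2]:noff[2],
                                -noff[3]:noff[3]))
  mm <- sweep(offs, 2, grid$voxel_size, "*")
  offs <- offs[rowSums(mm^2) <= (kd / 2)^2, , drop = FALSE]
  shape <- grid$shape
  centers <- which(voi$mask)  # ascending linear index = scan order
  ijk <- arrayInd(centers, shape)
  interior <- ijk[, 1] > noff[1] & ijk[, 1] <= shape[1] - noff[1] &
    ijk[, 2] > noff[2] & ijk[, 2] <= shape[2] - noff[2] &
    ijk[, 3] > noff[3] & ijk[, 3] <= shape[3] - noff[3]
  best <- -Inf
  if (any(interior)) {
    # vectorized kernel means: all kernel voxels in bounds, no index wrap
    off_lin <- offs[, 1] + offs[, 2] * shape[1] +
      offs[, 3] * shape[1] * shape[2]
    base <- centers[interior]
    lin <- outer(base, off_lin, "+")
    best <- max(rowMeans(matrix(image$values[lin], nrow = length(base))))
  }
  for (q in which(!interior)) {
    nb <- sweep(offs, 2, ijk[q, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    m <- mean(image$values[nb[ok, , drop = FALSE]])
    if (m > best) best <- m
  }
  suv(best, ctx)
}

#' Mean and maximum SUV over a VOI
#'
#' @inheritParams suv_peak
#' @return Named list with `suv_mean` and `suv_max`.
#' @export
suv_mean_max <- function(image, voi, ctx) {
  stopifnot(inherits(image, "activity_volume"), inherits(voi, "voi_mask"))
  if (!grids_equal(image$grid, voi$grid))
    stop("grid mismatch between image and VOI")
  vals <- image$values[voi$mask]
  list(suv_mean = suv(mean(vals), ctx), suv_max = suv(max(vals), ctx))
}

#' Signal-to-noise ratio of a lesion
#'
#' Lesion SUVmax divided by the SUV standard deviation of a uniform
#' reference region (measured over a 1.0 cm spherical VOI, typically in a
#' liver-like compartment).
#'
#' @param lesion_suv_max lesion SUVmax.
#' @param reference_sd SUV standard deviation of the reference VOI (> 0).
#' @return Scalar SNR.
#' @export
snr <- function(lesion_suv_max, reference_sd) {
  if (any(!is.finite(reference_sd)) || any(reference_sd <= 0))
    stop("`reference_sd` must be > 0 (degenerate reference region)")
  lesion_suv_max / reference_sd
}

#' Contrast-to-noise ratio of a lesion
#'
#' `(mean_lesion - mean_background) / sd_background`, with the background
#' taken from the lesion's neighboring low-uptake (lung-like) tissue.
#' Negative for cold lesions.
#'
#' @param mean_lesion lesion mean SUV.
#' @param mean_bg background mean SUV.
#' @param sd_bg background SUV standard deviation (> 0).
#' @return Scalar CNR.
#' @export
cnr <- function(mean_lesion, mean_bg, sd_bg) {
  if (any(!is.finite(sd_bg)) || any(sd_bg <= 0))
    stop("`sd_bg` must be > 0")
  (mean_lesion - mean_bg) / sd_bg
}

#' Shell annulus around a lesion VOI for CNR background sampling
#'
#' Voxels between 1.5 and 2.5 times the VOI-equivalent radius from the
#' lesion center, intersected with an allowed-region mask (the lung
#' compartment) and cleared of any exclusion mask (other lesions).
#'
#' @param voi the lesion [voi_mask()].
#' @param center lesion center, world mm.
#' @param allowed logical array: where background tissue may be sampled.
#' @param exclude optional logical array of voxels to exclude.
#' @param inner,outer annulus radii as multiples of the equivalent radius.
#' @return A [voi_mask()] of the annulus.
#' @export
lesion_background_annulus <- function(voi, center, allowed, exclude = NULL,
                                      inner = 1.5, outer = 2.5) {
  stopifnot(inherits(voi, "voi_mask"))
  grid <- voi$grid
  v_ml <- sum(voi$mask) * prod(grid$voxel_size) / 1000
  r_eq <- (3 * v_ml * 1000 / (4 * pi))^(1 / 3)
  m <- sphere_mask(grid, center, 2 * outer * r_eq) &
    !sphere_mask(grid, center, 2 * inner * r_eq) & allowed
  if (!is.null(exclude)) m <- m & !exclude
  if (!any(m)) stop("empty background annulus around lesion")
  voi_mask(grid, m, provenance = list(center = center, inner = inner,
                                      outer = outer, r_eq = r_eq))
}
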