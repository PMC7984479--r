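#' Synthetic clinical lesion phantom
#'
#' Builds a thorax-like truth volume: an elliptical soft-tissue body
#' containing two low-uptake lung-field compartments, a uniform liver-like
#' reference region (for noise measurement), and hot spherical lesions
#' placed inside the lung fields at a fixed lesion-to-lung-background
#' contrast.  Lesions are labeled by size group: sub-centimeter (< 10 mm)
#' versus medium (10-30 mm).
#'
#' Default activities are on the absolute scale of an FDG patient study
#' (a few kBq/mL): with the default [suv_context()] of a 300 MBq dose in a
#' 60 kg patient (dose/weight 5 kBq/g), the liver-like reference sits at
#' SUV 1 and lung tissue at SUV 0.5, emulating typical uptake, and the
#' simulated count level matches the image-quality phantom arm.
#'
#' @param lesion_diameters lesion diameters in mm, each in (3, 40).
#' @param lesion_to_background lesion-to-lung activity ratio (default 4, the
#'   assumed tumor-to-background ratio of small pulmonary nodules).
#' @param grid a [grid_geometry()].
#' @param seed integer seed for the rejection-sampled lesion placement.
#' @param lung_activity,body_activity,liver_activity compartment activity
#'   concentrations, kBq/mL.
#' @param clearance minimum surface-to-surface gap between lesions and
#'   between a lesion and the lung boundary, mm.
#' @param max_tries placement attempts per lesion before giving up.
#' @return An object of class `clinical_phantom`: list with
#'   `volume` (truth [activity_volume()]), `catalog` (data frame: id, x, y,
#'   z, diameter_mm, activity, group), `reference_mask` (logical array of
#'   the liver-like region), `lung_mask` (logical array), `liver_center`
#'   (mm), `lung_activity`, and `lesion_to_background`.
#' @export
build_clinical_phantom <- function(lesion_diameters,
                                   lesion_to_background = 4,
                                   grid = grid_geometry(c(96, 96, 32)),
                                   seed = 1L,
                                   lung_activity = 2.5,
                                   body_activity = 5,
                                   liver_activity = 5,
                                   clearance = 5,
                                   max_tries = 4000L) {
  lesion_diameters <- as.numeric(lesion_diameters)
  if (any(lesion_diameters <= 3) || any(lesion_diameters >= 40))
    stop("lesion diameters must lie in (3, 40) mm")
  if (lesion_to_background <= 0) stop("`lesion_to_background` must be > 0")
  stopifnot(inherits(grid, "grid_geometry"))

  zc <- voxel_centers(grid, 3)
  zspan <- range(zc) + c(-0.5, 0.5) * grid$voxel_size[3]
  # compartment layout (mm), scaled to the default thorax body
  body <- list(center = c(0, 0), semi_axes = c(125, 100), z_range = NULL)
  lung_z <- c(zspan[1] + 0.35 * diff(zspan), zspan[2] - 2)
  lungs <- list(list(center = c(-58, 0), semi_axes = c(45, 58)),
                list(center = c(58, 0), semi_axes = c(45, 58)))
  liver_d <- 26
  liver_center <- c(50, 0, lung_z[1] - 3 - liver_d / 2)
  if (liver_center[3] - liver_d / 2 < zspan[1])
    stop("grid too short axially for the liver reference region")

  vals <- array(0, grid$shape)
  vals[body_mask(grid, body)] <- body_activity
  lung_mask <- array(FALSE, grid$shape)
  for (lg in lungs) {
    m <- body_mask(grid, list(center = lg$center, semi_axes = lg$semi_axes,
                              z_range = lung_z))
    lung_mask <- lung_mask | m
  }
  vals[lung_mask] <- lung_activity
  reference_mask <- sphere_mask(grid, liver_center, liver_d)
  vals[reference_mask] <- liver_activity

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  ord <- order(-lesion_diameters)  # place the big ones first
  placed <- matrix(numeric(0), 0, 4)  # x, y, z, r
  centers <- matrix(NA_real_, length(lesion_diameters), 3)
  for (i in ord) {
    r <- lesion_diameters[i] / 2
    done <- FALSE
    for (try in seq_len(max_tries)) {
      lg <- lungs[[sample.int(2L, 1L)]]
      a <- lg$semi_axes[1] - r - clearance
      b <- lg$semi_axes[2] - r - clearance
      if (a <= 0 || b <= 0) next
      u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
      if (u^2 + v^2 > 1) next
      x <- lg$center[1] + u * a
      y <- lg$center[2] + v * b
      z <- stats::runif(1, lung_z[1] + r + clearance,
                        lung_z[2] - r - clearance)
      if (nrow(placed)) {
        d <- sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2 +
                    (placed[, 3] - z)^2)
        if (any(d < placed[, 4] + r + clearance)) next
      }
      placed <- rbind(placed, c(x, y, z, r))
      centers[i, ] <- c(x, y, z)
      done <- TRUE
      break
    }
    if (!done)
      stop(sprintf(
        "placement error: could not place lesion %d (d = %g mm) after %d tries",
        i, lesion_diameters[i], max_tries))
  }

  lesion_activity <- lung_activity * lesion_to_background
  for (i in seq_along(lesion_diameters)) {
    sp <- sphere_spec(centers[i, ], lesion_diameters[i], lesion_activity)
    ff <- sphere_fill_fraction(grid, sp, 3L)
    block <- vals[ff$index[[1]], ff$index[[2]], ff$index[[3]], drop = FALSE]
    vals[ff$index[[1]], ff$index[[2]], ff$index[[3]]] <-
      block + ff$frac * (lesion_activity - lung_activity)
  }

  catalog <- data.frame(
    id = seq_along(lesion_diameters),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    diameter_mm = lesion_diameters,
    activity = lesion_activity,
    group = ifelse(lesion_diameters < 10, "<10 mm", "10-30 mm"),
    stringsAsFactors = FALSE)

  structure(list(volume = activity_volume(grid, vals),
                 catalog = catalog,
                 reference_mask = reference_mask,
                 lung_mask = lung_mask,
                 liver_center = liver_center,
                 lung_activity = lung_activity,
                 lesion_to_background = lesion_to_background),
            class = "clinical_phantom")
}

#' @export
print.clinical_phantom <- function(x, ...) {
  cat(sprintf(
    "clinical_phantom: %d lesions (%d sub-centimeter, %d medium), contrast %g:1\n",
    nrow(x$catalog), sum(x$catalog$group == "<10 mm"),
    sum(x$catalog$group == "10-30 mm"), x$lesion_to_background))
  invisible(x)
}

#' Default study lesion diameters
#'
#' Draws the study's lesion-size mix: `n_sub` sub-centimeter diameters
#' uniform in [5.7, 10) mm and `n_medium` medium diameters uniform in
#' [10, 29.4] mm (the observed clinical range), under a fixed seed.
#'
#' @param n_sub number of sub-centimeter lesions (default 7).
#' @param n_medium number of medium lesions (default 16).
#' @param seed integer RNG seed.
#' @return Numeric vector of diameters, sub-centimeter first.
#' @export
study_lesion_diameters <- function(n_sub = 7L, n_medium = 16L, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  c(stats::runif(n_sub, 5.7, 9.9), stats::runif(n_medium, 10, 29.4))
}
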