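#' Voxel grid geometry
#'
#' Describes a 3-D voxel lattice in world (mm) coordinates.  Axes are ordered
#' (x, y, z) = (columns, rows, slices) in world space; the `values` array of an
#' [activity_volume()] built on a grid has `dim = shape` with the same axis
#' order.  A voxel's value is attributed to its center; `origin` is the world
#' position (mm) of the center of voxel `(1, 1, 1)`.
#'
#' @param shape integer vector of length 3: number of voxels along (x, y, z).
#' @param voxel_size numeric vector of length 3: voxel pitch in mm along
#'   (x, y, z).  The default mirrors a clinical PET raster: 2.73 mm in-plane,
#'   2.8 mm slice thickness.
#' @param origin world coordinates (mm) of the first voxel center.  The
#'   default centers the grid on the world origin.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(96, 96, 32))
#' voxel_centers(g, axis = 1)[1:3]
#' @export
grid_geometry <- function(shape,
                          voxel_size = c(2.73, 2.73, 2.8),
                          origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)")
  if (is.null(origin)) {
    # centered grid: world origin at geometric center of the lattice
    origin <- -voxel_size * (shape - 1L) / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' World coordinates of voxel centers along one axis
#'
#' @param grid a [grid_geometry()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of world coordinates (mm).
#' @export
voxel_centers <- function(grid, axis) {
  stopifnot(inherits(grid, "grid_geometry"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1L) * grid$voxel_size[axis]
}

#' Convert world coordinates (mm) to fractional voxel indices (1-based)
#'
#' @param grid a [grid_geometry()].
#' @param xyz numeric vector of length 3 or matrix with 3 columns.
#' @return Fractional indices with the same shape as `xyz`.
#' @export
world_to_voxel <- function(grid, xyz) {
  if (is.matrix(xyz)) {
    sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
  } else {
    (xyz - grid$origin) / grid$voxel_size + 1
  }
}

#' Convert (1-based) voxel indices to world coordinates of voxel centers
#'
#' @inheritParams world_to_voxel
#' @param ijk indices, vector of length 3 or matrix with 3 columns.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.matrix(ijk)) {
    sweep(sweep(ijk - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
  } else {
    grid$origin + (ijk - 1) * grid$voxel_size
  }
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Activity volume
#'
#' A 3-D voxel image of activity concentration (kBq/mL) on a
#' [grid_geometry()].  This is the common container for phantom truth images
#' and reconstructions.
#'
#' @param grid a [grid_geometry()].
#' @param values numeric array with `dim == grid$shape`, all finite and
#'   nonnegative, in kBq/mL.
#' @return An object of class `activity_volume` with elements `grid` and
#'   `values`.
#' @export
activity_volume <- function(grid, values) {
  stopifnot(inherits(grid, "grid_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), grid$shape))
    stop(sprintf("values dim (%s) does not match grid shape (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  if (any(!is.finite(values))) stop("activity values must be finite")
  if (any(values < 0)) stop("activity values must be nonnegative")
  structure(list(grid = grid, values = values), class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "activity_volume: %s voxels, range [%.4g, %.4g] kBq/mL, mean %.4g\n",
    paste(dim(v), collapse = " x "), min(v), max(v), mean(v)))
  invisible(x)
}

#' Total activity (kBq) in a volume
#'
#' Sum of voxel values times voxel volume (mL); used for count-preservation
#' checks.
#' @param volume an [activity_volume()].
#' @export
total_activity <- function(volume) {
  stopifnot(inherits(volume, "activity_volume"))
  sum(volume$values) * prod(volume$grid$voxel_size) / 1000
}

# Logical mask of voxel centers inside a sphere (center mm, diameter mm).
sphere_mask <- function(grid, center, diameter) {
  cx <- voxel_centers(grid, 1); cy <- voxel_centers(grid, 2)
  cz <- voxel_centers(grid, 3)
  r2 <- (diameter / 2)^2
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
}
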