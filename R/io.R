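#' Write an activity volume as NIfTI-1
#'
#' Stores the concentration array (float32) with the voxel size in the
#' header and the world origin in the sform; [read_volume()] restores the
#' geometry exactly.
#'
#' @param volume an [activity_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "activity_volume"))
  img <- RNifti::asNifti(volume$values, datatype = "float")
  aff <- diag(c(volume$grid$voxel_size, 1))
  aff[1:3, 4] <- volume$grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an activity volume from NIfTI-1
#'
#' @param path a NIfTI file with 3-D data and positive voxel sizes.
#' @return An [activity_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected 3-D volume, got %d-D (field: dim)", length(d)))
  aff <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(aff, "try-error") &&
      all(is.finite(aff)) && any(aff[1:3, 1:3] != 0)) {
    # spacing from the affine column norms, origin from its translation
    pd <- sqrt(colSums(aff[1:3, 1:3]^2))
    origin <- aff[1:3, 4]
  } else {
    pd <- RNifti::pixdim(img)[1:3]
    origin <- NULL
  }
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("missing or nonpositive voxel spacing (field: pixdim)")
  grid <- grid_geometry(d, pd, origin = origin)
  activity_volume(grid, array(pmax(as.numeric(img), 0), d))
}

#' Write projection data (sinograms) with a YAML sidecar
#'
#' The counts array is stored as NIfTI with axes (radial, angle, slice);
#' acquisition and grid geometry go to `<path>.yaml`.
#'
#' @param proj a [projection_data()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(proj, path) {
  stopifnot(inherits(proj, "projection_data"))
  img <- RNifti::asNifti(proj$values, datatype = "double")
  RNifti::writeNifti(img, path)
  meta <- list(format = "bplquant-projections-v1",
               kind = proj$kind,
               acq = unclass(proj$acq),
               grid = list(shape = as.integer(proj$grid$shape),
                           voxel_size = proj$grid$voxel_size,
                           origin = proj$grid$origin))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read projection data written by [write_projections()]
#'
#' @param path the NIfTI path (expects `<path>.yaml` alongside).
#' @return A [projection_data()].
#' @export
read_projections <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(path) || !file.exists(side))
    stop(sprintf("projection file or sidecar missing: %s", path))
  meta <- yaml::read_yaml(side)
  if (!identical(meta$format, "bplquant-projections-v1"))
    stop("unrecognized projection sidecar format")
  acq <- do.call(acquisition_model, meta$acq)
  grid <- grid_geometry(meta$grid$shape, meta$grid$voxel_size,
                        meta$grid$origin)
  vals <- as.numeric(RNifti::readNifti(path))
  projection_data(array(vals, c(acq$n_radial_bins, acq$n_angles,
                                grid$shape[3])),
                  acq, grid, kind = meta$kind)
}

table_schemas <- list(
  metrics = c("object_id", "group", "diameter_mm", "beta", "replicate",
              "rc_pct", "cr_pct", "bv_pct", "suv_mean", "suv_max",
              "suv_peak", "snr", "cnr"),
  rc_models = c("beta", "slope", "intercept", "r2", "dmin", "dmax"),
  scores = c("group", "beta", "reader", "general", "sharpness",
             "conspicuity", "overall")
)

#' Write a pipeline table as versioned CSV
#'
#' RFC-4180 CSV (UTF-8, "." decimal) with a leading
#' `# bplquant-table-v1 <type>` format line.  Numeric columns round trip
#' through [read_table()] at full double precision.
#'
#' @param df data frame matching the schema of `type`.
#' @param path output path.
#' @param type one of `"metrics"`, `"rc_models"`, `"scores"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, type = c("metrics", "rc_models", "scores")) {
  type <- match.arg(type)
  schema <- table_schemas[[type]]
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s) %s (expected: %s)",
                 paste(missing, collapse = ", "),
                 paste(schema, collapse = ", ")))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# bplquant-table-v1 %s", type), con)
  utils::write.csv(df[schema], con, row.names = FALSE)
  invisible(path)
}

#' Read a versioned pipeline CSV table
#'
#' Validates the format line and the column schema; the `scores` type also
#' checks score ranges and that `overall` equals the component sum.
#'
#' @param path CSV path.
#' @param type one of `"metrics"`, `"rc_models"`, `"scores"`.
#' @return A data frame.
#' @export
read_table <- function(path, type = c("metrics", "rc_models", "scores")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1], "# bplquant-table-v1"))
    stop("schema error: missing '# bplquant-table-v1' format line")
  df <- utils::read.csv(text = paste(lines[-1], collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  schema <- table_schemas[[type]]
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s) %s (expected: %s)",
                 paste(missing, collapse = ", "),
                 paste(schema, collapse = ", ")))
  if (type == "scores") {
    comp <- df$general + df$sharpness + df$conspicuity
    if (any(abs(comp - df$overall) > 1e-9))
      stop("validation error: overall score is not the sum of components")
    rng <- c(df$general, df$sharpness, df$conspicuity)
    if (any(rng < 1 | rng > 5))
      stop("validation error: component scores must lie in [1, 5]")
  }
  df
}

#' Read and validate a pipeline configuration file
#'
#' YAML schema with optional blocks `grid` (shape, voxel_size), `acq`
#' (arguments of [acquisition_model()]), `sweep` (arguments of
#' [sweep_config()] except grid/acq) and `seed`.  Unknown top-level keys
#' are rejected.
#'
#' @param path YAML file.
#' @return A list of class `pipeline_config` with `grid`, `acq`, `sweep`
#'   (a ready [sweep_config()]) and `seed`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("schema error: config must be a YAML mapping")
  known <- c("grid", "acq", "sweep", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("schema error: unknown config key(s): %s",
                 paste(extra, collapse = ", ")))
  grid <- if (is.null(cfg$grid)) grid_geometry(c(96, 96, 32))
          else grid_geometry(cfg$grid$shape %||% c(96, 96, 32),
                             cfg$grid$voxel_size %||% c(2.73, 2.73, 2.8))
  acq <- if (is.null(cfg$acq)) acquisition_model()
         else do.call(acquisition_model, cfg$acq)
  sweep_args <- cfg$sweep %||% list()
  sweep_args$grid <- grid
  sweep_args$acq <- acq
  sw <- do.call(sweep_config, sweep_args)
  structure(list(grid = grid, acq = acq, sweep = sw,
                 seed = cfg$seed %||% 1L),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
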