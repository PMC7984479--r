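#' Beta-sweep configuration
#'
#' Describes one full experiment: phantom mode, beta grid, penalty and
#' optimizer settings, replicate noise seeds, and the acquisition model.
#' Defaults follow the study design: 19 beta values from 100 to 1000 in
#' steps of 50, three replicates, VOIs drawn at the reference beta of 350,
#' and a 4:1 object-to-background contrast.
#'
#' @param mode `"nema"` (image-quality phantom) or `"clinical"`
#'   (lesion phantom).
#' @param betas strictly increasing positive beta grid.
#' @param gamma edge-preservation parameter of the penalty.
#' @param beta_scale mapping from nominal beta to the effective penalty
#'   weight at this simulator's count level (see [penalty_params()]).
#' @param reference_beta beta of the image VOIs are segmented on; must be
#'   in `betas`.
#' @param replicates number of independent noise realizations.
#' @param seeds integer noise seeds, one per replicate.
#' @param noiseless use expected (Poisson-mean) counts instead of sampled
#'   counts; replicates then collapse to one.
#' @param grid image [grid_geometry()].
#' @param acq [acquisition_model()].
#' @param n_iterations,n_subsets optimizer settings per reconstruction
#'   (default 12 full iterations of 4-subset BSREM, which matches the
#'   1-subset/40-iteration objective to ~1e-5 relative at a fraction of
#'   the cost).
#' @param neighborhood penalty neighborhood (6, 18 or 26).
#' @param lesion_diameters clinical mode: lesion diameters, mm.
#' @param lesion_contrast clinical mode: lesion-to-lung activity ratio.
#' @param placement_seed clinical mode: seed of the lesion placement
#'   (kept fixed across replicates, which vary only the Poisson noise).
#' @param suv_ctx clinical mode: [suv_context()] for SUV conversion.
#' @param model_psf include the acquisition PSF in the reconstruction
#'   system model (optional resolution modelling; off by default so
#'   recovery coefficients fall below 1 and the partial-volume correction
#'   has something to correct).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(mode = c("nema", "clinical"),
                         betas = seq(100, 1000, by = 50),
                         gamma = 2,
                         beta_scale = 3e-4,
                         reference_beta = 350,
                         replicates = 3L,
                         seeds = NULL,
                         noiseless = FALSE,
                         grid = grid_geometry(c(96, 96, 32)),
                         acq = acquisition_model(),
                         n_iterations = 12L,
                         n_subsets = 4L,
                         neighborhood = 18L,
                         lesion_diameters = study_lesion_diameters(),
                         lesion_contrast = 4,
                         placement_seed = 7L,
                         suv_ctx = suv_context(300000, 60000),
                         model_psf = FALSE) {
  mode <- match.arg(mode)
  betas <- as.numeric(betas)
  if (any(betas <= 0) || any(diff(betas) <= 0))
    stop("`betas` must be strictly increasing and positive")
  if (!reference_beta %in% betas)
    stop("`reference_beta` must be one of `betas`")
  replicates <- as.integer(replicates)
  if (noiseless) replicates <- 1L
  if (is.null(seeds)) seeds <- seq_len(replicates)
  if (length(seeds) != replicates)
    stop("`seeds` must have one entry per replicate")
  structure(list(mode = mode, betas = betas, gamma = gamma,
                 beta_scale = beta_scale, reference_beta = reference_beta,
                 replicates = replicates, seeds = as.integer(seeds),
                 noiseless = noiseless, grid = grid, acq = acq,
                 n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 neighborhood = as.integer(neighborhood),
                 lesion_diameters = lesion_diameters,
                 lesion_contrast = lesion_contrast,
                 placement_seed = as.integer(placement_seed),
                 suv_ctx = suv_ctx, model_psf = isTRUE(model_psf)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "sweep_config (%s): %d betas in [%g, %g], %d replicate(s)%s\n",
    x$mode, length(x$betas), min(x$betas), max(x$betas), x$replicates,
    if (x$noiseless) ", noiseless" else ""))
  invisible(x)
}

recon_for_beta <- function(counts, config, beta) {
  pen <- penalty_params(beta = beta, gamma = config$gamma,
                        neighborhood = config$neighborhood,
                        beta_scale = config$beta_scale)
  reconstruct(counts, recon_params(penalty = pen,
                                   n_iterations = config$n_iterations,
                                   n_subsets = config$n_subsets,
                                   model_psf = config$model_psf))
}

# reconstruct one sinogram at every beta of the sweep; returns list of
# activity_volume keyed by beta
reconstruct_sweep <- function(counts, config) {
  out <- vector("list", length(config$betas))
  names(out) <- as.character(config$betas)
  for (i in seq_along(config$betas)) {
    out[[i]] <- recon_for_beta(counts, config, config$betas[i])$volume
  }
  out
}

nema_replicate_metrics <- function(images, phantom, config, replicate) {
  grid <- config$grid
  spheres <- phantom$spheres
  # A_M is measured in the sphere's physical volume (the CT-delineated VOI
  # of the image-quality protocol): voxel centers inside the known sphere
  vois <- lapply(spheres, function(s) {
    voi_mask(grid, sphere_mask(grid, s$center, s$diameter),
             provenance = list(source = "ct", diameter = s$diameter))
  })
  rows <- list()
  for (b in names(images)) {
    img <- images[[b]]
    for (k in seq_along(spheres)) {
      s <- spheres[[k]]
      voi <- propagate_voi(vois[[k]], img, target_beta = as.numeric(b))
      a_m <- mean(img$values[voi$mask])
      roi <- place_background_rois(img, phantom, s$diameter)
      a_b <- mean(roi$means)
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = k, group = "sphere", diameter_mm = s$diameter,
        beta = as.numeric(b), replicate = replicate,
        rc_pct = recovery_coefficient(a_m, s$activity),
        cr_pct = contrast_recovery(a_m, a_b, phantom$contrast),
        bv_pct = background_variability(stats::sd(roi$means), a_b),
        suv_mean = NA_real_, suv_max = NA_real_, suv_peak = NA_real_,
        snr = NA_real_, cnr = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

clinical_replicate_metrics <- function(images, phantom, config, replicate) {
  grid <- config$grid
  ctx <- config$suv_ctx
  cat_df <- phantom$catalog
  ref_img <- images[[as.character(config$reference_beta)]]
  vois <- lapply(seq_len(nrow(cat_df)), function(i) {
    seedv <- round(world_to_voxel(
      grid, c(cat_df$x[i], cat_df$y[i], cat_df$z[i])))
    segment_voi(ref_img, seedv, fraction = 0.42,
                reference_beta = config$reference_beta)
  })
  # all-lesion exclusion mask (truth spheres dilated by 4 mm) for CNR
  lesion_excl <- array(FALSE, grid$shape)
  for (i in seq_len(nrow(cat_df))) {
    lesion_excl <- lesion_excl |
      sphere_mask(grid, c(cat_df$x[i], cat_df$y[i], cat_df$z[i]),
                  cat_df$diameter_mm[i] + 8)
  }
  ref_voi <- spherical_voi(grid, phantom$liver_center, 10)
  # annuli depend only on the (propagated) VOI geometry: compute once
  annuli <- lapply(seq_len(nrow(cat_df)), function(i) {
    lesion_background_annulus(
      vois[[i]], c(cat_df$x[i], cat_df$y[i], cat_df$z[i]),
      allowed = phantom$lung_mask,
      exclude = lesion_excl &
        !sphere_mask(grid, c(cat_df$x[i], cat_df$y[i], cat_df$z[i]),
                     cat_df$diameter_mm[i] + 8))
  })
  rows <- list()
  for (b in names(images)) {
    img <- images[[b]]
    ref_sd <- stats::sd(suv(img$values[ref_voi$mask], ctx))
    for (i in seq_len(nrow(cat_df))) {
      voi <- propagate_voi(vois[[i]], img, target_beta = as.numeric(b))
      mm <- suv_mean_max(img, voi, ctx)
      sp <- suv_peak(img, voi, ctx)
      bg <- suv(img$values[annuli[[i]]$mask], ctx)
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = cat_df$id[i], group = cat_df$group[i],
        diameter_mm = cat_df$diameter_mm[i], beta = as.numeric(b),
        replicate = replicate,
        rc_pct = NA_real_, cr_pct = NA_real_, bv_pct = NA_real_,
        suv_mean = mm$suv_mean, suv_max = mm$suv_max, suv_peak = sp,
        snr = snr(mm$suv_max, ref_sd),
        cnr = cnr(mm$suv_mean, mean(bg), stats::sd(bg)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a full beta-sweep experiment
#'
#' For each replicate, simulates one acquisition of the configured phantom
#' (one Poisson noise realization, shared by all betas, or the noiseless
#' expectation), reconstructs it at every beta of the sweep, and quantifies
#' every object.  NEMA mode reports RC/CR/BV per sphere (concentration
#' domain); clinical mode reports SUVmean/SUVmax/SUVpeak, SNR and CNR per
#' lesion.
#'
#' @param config a [sweep_config()].
#' @return A data frame (tidy metrics table) with columns `object_id`,
#'   `group`, `diameter_mm`, `beta`, `replicate`, `rc_pct`, `cr_pct`,
#'   `bv_pct`, `suv_mean`, `suv_max`, `suv_peak`, `snr`, `cnr`; inapplicable
#'   metrics are `NA`.  The generating phantom is attached as attribute
#'   `"phantom"`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$mode == "nema") {
    phantom <- nema_phantom_spec()
    truth <- build_phantom(phantom, config$grid)
  } else {
    phantom <- build_clinical_phantom(
      lesion_diameters = config$lesion_diameters,
      lesion_to_background = config$lesion_contrast,
      grid = config$grid, seed = config$placement_seed)
    truth <- phantom$volume
  }
  expected <- forward_project(truth, config$acq)
  rows <- list()
  for (r in seq_len(config$replicates)) {
    counts <- if (config$noiseless) expected
              else sample_counts(expected, config$seeds[r])
    images <- reconstruct_sweep(counts, config)
    rows[[r]] <- if (config$mode == "nema")
      nema_replicate_metrics(images, phantom, config, r)
    else
      clinical_replicate_metrics(images, phantom, config, r)
  }
  out <- do.call(rbind, rows)
  attr(out, "phantom") <- phantom
  out
}

#' Fit per-beta RC regressions from a NEMA sweep
#'
#' Averages RC over replicates per sphere and beta, then fits the
#' RC-versus-diameter line for every beta ([fit_rc_regression()]).
#'
#' @param metrics a NEMA metrics table from [run_sweep()].
#' @param contrast contrast the phantom was filled at.
#' @return Named list of `rc_regression` objects, keyed by beta.
#' @export
fit_rc_models <- function(metrics, contrast = 4) {
  stopifnot(all(c("diameter_mm", "beta", "rc_pct") %in% names(metrics)))
  betas <- sort(unique(metrics$beta))
  models <- lapply(betas, function(b) {
    sub <- metrics[metrics$beta == b, ]
    agg <- stats::aggregate(rc_pct ~ diameter_mm, data = sub, FUN = mean)
    fit_rc_regression(agg$diameter_mm, agg$rc_pct, beta = b,
                      contrast = contrast)
  })
  names(models) <- as.character(betas)
  models
}

#' Apply the phantom-derived partial-volume correction to clinical metrics
#'
#' For every lesion row, predicts the recovery coefficient from the lesion's
#' truth diameter using the RC regression of the row's beta and divides the
#' SUVs by it.
#'
#' @param metrics clinical metrics table from [run_sweep()].
#' @param models named list of `rc_regression` per beta
#'   (from [fit_rc_models()]).
#' @return The metrics table with added columns `estimated_rc`,
#'   `extrapolated`, `suv_mean_pvc`, `suv_max_pvc`, `suv_peak_pvc`.
#' @export
apply_pvc_to_metrics <- function(metrics, models) {
  need <- c("beta", "diameter_mm", "suv_mean", "suv_max", "suv_peak")
  stopifnot(all(need %in% names(metrics)))
  rc <- numeric(nrow(metrics)); ex <- logical(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    m <- models[[as.character(metrics$beta[i])]]
    if (is.null(m))
      stop(sprintf("no RC model for beta %g", metrics$beta[i]))
    p <- suppressWarnings(predict(m, metrics$diameter_mm[i]))
    rc[i] <- p$rc; ex[i] <- p$extrapolated
  }
  metrics$estimated_rc <- rc
  metrics$extrapolated <- ex
  metrics$suv_mean_pvc <- metrics$suv_mean / rc
  metrics$suv_max_pvc <- metrics$suv_max / rc
  metrics$suv_peak_pvc <- metrics$suv_peak / rc
  metrics
}

#' Correlation of group-mean SUV with beta
#'
#' Averages an SUV column over lesions and replicates per beta within a
#' size group, then computes the Pearson correlation of the per-beta means
#' with beta.
#'
#' @param metrics clinical metrics table.
#' @param column SUV column name (e.g. `"suv_max"`, `"suv_peak_pvc"`).
#' @param group size-group label (`"<10 mm"` or `"10-30 mm"`).
#' @return A list with `r` and `p` (see [pearson_correlation()]).
#' @export
suv_beta_correlation <- function(metrics, column, group) {
  sub <- metrics[metrics$group == group, ]
  if (!nrow(sub)) stop(sprintf("no rows for group '%s'", group))
  agg <- stats::aggregate(sub[[column]], by = list(beta = sub$beta),
                          FUN = mean)
  pearson_correlation(agg$beta, agg$x)
}
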