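#' Reconstruction parameters
#'
#' Settings for the BSREM-style penalized maximum-likelihood reconstruction.
#' The optimizer is preconditioned gradient ascent with the classic EM
#' preconditioner `x / sensitivity` and relaxation schedule
#' `alpha_n = alpha0 / (1 + decay * n)`; with one subset, `beta = 0` and the
#' default `alpha0 = 1`, `decay = 0`, one update is exactly one ML-EM
#' iteration.  A monotone safeguard halves the step whenever a full
#' iteration would decrease the penalized objective.
#'
#' @param penalty a [penalty_params()].
#' @param n_iterations number of full iterations.
#' @param n_subsets number of angular subsets (must divide `n_angles`).
#' @param alpha0,decay relaxation schedule parameters.
#' @param epsilon nonnegativity floor (kBq/mL) applied after every update;
#'   keeps the penalty denominator and the log-likelihood defined.
#' @param stop_tol relative objective change below which iteration stops.
#' @param model_psf include the acquisition PSF in the reconstruction's own
#'   system model (default `FALSE`: resolution losses stay in the image, as
#'   for a reconstruction without resolution modelling).
#' @return A list of class `recon_params`.
#' @export
recon_params <- function(penalty = penalty_params(beta = 0),
                         n_iterations = 50L,
                         n_subsets = 1L,
                         alpha0 = 1,
                         decay = 0,
                         epsilon = 1e-9,
                         stop_tol = 1e-6,
                         model_psf = FALSE) {
  stopifnot(inherits(penalty, "penalty_params"))
  n_iterations <- as.integer(n_iterations)
  n_subsets <- as.integer(n_subsets)
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1")
  if (n_subsets < 1L) stop("`n_subsets` must be >= 1")
  if (epsilon <= 0) stop("`epsilon` must be > 0")
  if (alpha0 <= 0) stop("`alpha0` must be > 0")
  if (decay < 0) stop("`decay` must be >= 0")
  structure(list(penalty = penalty, n_iterations = n_iterations,
                 n_subsets = n_subsets, alpha0 = alpha0, decay = decay,
                 epsilon = epsilon, stop_tol = stop_tol,
                 model_psf = model_psf),
            class = "recon_params")
}

#' Poisson log-likelihood of a volume given measured counts
#'
#' `sum_i y_i log(yhat_i) - yhat_i` with `yhat` the forward projection of
#' the volume under the reconstruction system model (no PSF unless
#' `apply_psf = TRUE`).  Bins with `yhat = 0` and `y = 0` contribute 0; a
#' bin with `yhat = 0` but `y > 0` makes the likelihood `-Inf` and raises an
#' error.
#'
#' @param volume an [activity_volume()].
#' @param counts a [projection_data()].
#' @param acq an [acquisition_model()]; defaults to the one stored in
#'   `counts`.
#' @param apply_psf include the acquisition PSF in the projection.
#' @return Scalar log-likelihood (data-dependent constant omitted).
#' @export
poisson_loglik <- function(volume, counts, acq = counts$acq,
                           apply_psf = FALSE) {
  stopifnot(inherits(volume, "activity_volume"),
            inherits(counts, "projection_data"))
  if (any(counts$values < 0)) stop("counts must be nonnegative")
  yhat <- forward_project(volume, acq, apply_psf = apply_psf)$values
  y <- counts$values
  pos <- y > 0
  if (any(pos & yhat == 0))
    stop("zero expected count where measured count > 0: log-likelihood is -Inf")
  sum(y[pos] * log(yhat[pos])) - sum(yhat)
}

# loglik from precomputed yhat matrix; yhat floored to keep logs finite
loglik_from_proj <- function(y, yhat) {
  pos <- y > 0
  sum(y[pos] * log(pmax(yhat[pos], 1e-300))) - sum(yhat)
}

#' Penalized-likelihood (BSREM-style) reconstruction
#'
#' Maximizes `poisson_loglik(x) - beta_eff * rdp_value(x)` over nonnegative
#' images, where `beta_eff = beta * beta_scale`, by subsetized preconditioned
#' gradient ascent with the EM preconditioner.  With `n_subsets = 1` and
#' `beta = 0` the update is exactly ML-EM.  The per-iteration objective
#' (log-likelihood, penalty and their combination) is returned as a trace;
#' an objective decrease that the step-halving safeguard cannot repair is
#' flagged in `status` rather than silently accepted.
#'
#' @param counts a [projection_data()] (sampled counts, or expected counts
#'   for noiseless studies).
#' @param params a [recon_params()].
#' @param acq acquisition model; defaults to the one stored in `counts`.
#' @param grid image grid; defaults to the one stored in `counts`.
#' @param init optional [activity_volume()] to warm-start from; the default
#'   is a uniform image matched to the measured total counts.
#' @return An object of class `bpl_recon`: list with `volume`
#'   ([activity_volume()]), `trace` (data frame with columns `iteration`,
#'   `loglik`, `penalty`, `objective`, `step`, `sens_total`), `params`,
#'   `converged`, `status`.
#' @export
reconstruct <- function(counts, params, acq = counts$acq,
                        grid = counts$grid, init = NULL) {
  stopifnot(inherits(counts, "projection_data"),
            inherits(params, "recon_params"),
            inherits(acq, "acquisition_model"),
            inherits(grid, "grid_geometry"))
  dy <- dim(counts$values)
  if (dy[1] != acq$n_radial_bins || dy[2] != acq$n_angles ||
      dy[3] != grid$shape[3])
    stop(sprintf("counts dim (%s) does not match acquisition/grid (%s)",
                 paste(dy, collapse = "x"),
                 paste(c(acq$n_radial_bins, acq$n_angles, grid$shape[3]),
                       collapse = "x")))
  if (acq$n_angles %% params$n_subsets != 0L)
    stop("`n_subsets` must divide `n_angles`")

  pen <- params$penalty
  beta_eff <- pen$beta * pen$beta_scale
  nb <- neighbor_offsets(pen$neighborhood, grid$voxel_size)
  nxy <- grid$shape[1] * grid$shape[2]
  nz <- grid$shape[3]
  cs <- acq$count_scale
  A <- system_matrix(grid, acq)
  At <- Matrix::t(A)
  nr <- acq$n_radial_bins

  S <- params$n_subsets
  sub_rows <- lapply(seq_len(S), function(s) {
    ang <- seq(s, acq$n_angles, by = S)
    as.vector(outer(seq_len(nr), (ang - 1L) * nr, "+"))
  })
  if (S == 1L) {
    subA <- list(A); subAt <- list(At)
  } else {
    sub_key <- paste("subsets", S, grid$shape[1], grid$shape[2],
                     acq$n_angles, nr, acq$radial_bin_size, sep = "|")
    if (is.null(.proj_cache[[sub_key]])) {
      subA <- lapply(sub_rows, function(r) A[r, ])
      .proj_cache[[sub_key]] <- list(A = subA,
                                     At = lapply(subA, Matrix::t))
    }
    subA <- .proj_cache[[sub_key]]$A
    subAt <- .proj_cache[[sub_key]]$At
  }
  sens <- lapply(subA, function(M) cs * Matrix::colSums(M))
  sens_tot <- Reduce(`+`, sens)
  support <- sens_tot > 0

  blur3 <- function(X) {
    matrix(gaussian_blur_array(array(X, grid$shape), grid, acq$psf_fwhm),
           nxy, nz)
  }
  fw <- function(X) {
    # expected counts for all slices, (nr*na) x nz
    Xe <- if (params$model_psf && acq$psf_fwhm > 0) blur3(X) else X
    as.matrix(A %*% Xe) * cs
  }
  rdp_val <- function(X) {
    if (beta_eff == 0) return(0)
    .rdp_value_cpp(as.numeric(X), grid$shape, nb$offsets, nb$weights,
                   pen$gamma)
  }
  rdp_grad <- function(X) {
    matrix(.rdp_gradient_cpp(as.numeric(X), grid$shape, nb$offsets,
                             nb$weights, pen$gamma), nxy, nz)
  }

  y <- matrix(counts$values, nr * acq$n_angles, nz)
  X <- matrix(0, nxy, nz)
  if (is.null(init)) {
    # uniform initialization matched in total projected counts
    x0 <- sum(y) / max(sum(sens_tot), .Machine$double.eps)
    X[support, ] <- max(x0, params$epsilon)
  } else {
    stopifnot(inherits(init, "activity_volume"))
    if (!grids_equal(init$grid, grid))
      stop("`init` grid does not match the reconstruction grid")
    Xi <- matrix(init$values, nxy, nz)
    X[support, ] <- pmax(Xi[support, ], params$epsilon)
  }

  yhat <- fw(X)
  ll <- loglik_from_proj(y, yhat)
  rv <- rdp_val(X)
  obj <- ll - beta_eff * rv
  trace <- data.frame(iteration = 0L, loglik = ll, penalty = rv,
                      objective = obj, step = NA_real_,
                      sens_total = sum(sweep(X, 1, sens_tot, "*")))
  converged <- FALSE
  status <- "ok"

  # with subsets the full objective is not guaranteed monotone per subset
  # pass, so the step-halving safeguard applies only to the S = 1 path
  max_halvings <- if (S == 1L) 12L else 0L
  for (it in seq_len(params$n_iterations)) {
    alpha_it <- params$alpha0 / (1 + params$decay * (it - 1))
    accepted <- FALSE
    for (half in 0:max_halvings) {
      alpha <- alpha_it / 2^half
      Xc <- X
      yh <- yhat
      for (s in seq_len(S)) {
        ys <- if (S == 1L) y else y[sub_rows[[s]], , drop = FALSE]
        yhs <- if (s == 1L) {
          if (S == 1L) yh else yh[sub_rows[[s]], , drop = FALSE]
        } else {
          Xe <- if (params$model_psf && acq$psf_fwhm > 0) blur3(Xc) else Xc
          as.matrix(subA[[s]] %*% Xe) * cs
        }
        ratio <- ifelse(yhs > 0, ys / yhs, 0)
        gl <- cs * as.matrix(subAt[[s]] %*% (ratio - 1))
        if (params$model_psf && acq$psf_fwhm > 0) gl <- blur3(gl)
        if (beta_eff > 0) gl <- gl - (beta_eff / S) * rdp_grad(Xc)
        pre <- matrix(0, nxy, nz)
        pre[support, ] <- Xc[support, ] / sens[[s]][support]
        Xc <- Xc + alpha * pre * gl
        Xc[support, ] <- pmax(Xc[support, ], params$epsilon)
        Xc[!support, ] <- 0
      }
      yhat_c <- fw(Xc)
      ll_c <- loglik_from_proj(y, yhat_c)
      rv_c <- rdp_val(Xc)
      obj_c <- ll_c - beta_eff * rv_c
      tol_dec <- 1e-9 * (abs(obj) + 1)
      if (obj_c >= obj - tol_dec || beta_eff == 0 || S > 1L) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) status <- "convergence failure: objective decreased"
    rel_change <- abs(obj_c - obj) / (abs(obj) + .Machine$double.eps)
    X <- Xc; yhat <- yhat_c; ll <- ll_c; rv <- rv_c; obj <- obj_c
    trace <- rbind(trace, data.frame(
      iteration = it, loglik = ll, penalty = rv, objective = obj,
      step = alpha, sens_total = sum(sweep(X, 1, sens_tot, "*"))))
    if (accepted && rel_change < params$stop_tol) {
      converged <- TRUE
      break
    }
  }
  vol <- activity_volume(grid, array(pmax(X, 0), grid$shape))
  structure(list(volume = vol, trace = trace, params = params, acq = acq,
                 converged = converged, status = status,
                 measured_total = sum(y)),
            class = "bpl_recon")
}

#' @export
print.bpl_recon <- function(x, ...) {
  n <- nrow(x$trace) - 1L
  cat(sprintf(
    "bpl_recon: beta = %g, %d iterations, objective %.6g (%s)\n",
    x$params$penalty$beta, n, x$trace$objective[n + 1L],
    if (x$converged) "converged" else x$status))
  invisible(x)
}
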