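#' Fit the recovery-coefficient regression for one beta
#'
#' Ordinary least squares of RC (percent) on sphere diameter (mm) over the
#' phantom spheres reconstructed at one beta value.  The fitted line
#' predicts the recovery coefficient of a lesion of known diameter at the
#' same contrast, which is the basis of the regional partial-volume
#' correction.
#'
#' @param diameters sphere diameters, mm (>= 2 distinct values).
#' @param rc recovery coefficients, percent.
#' @param beta the beta value the spheres were reconstructed at.
#' @param contrast sphere-to-background contrast the model was fit at.
#' @return An object of class `rc_regression` with elements `beta`, `slope`
#'   (%/mm), `intercept` (%), `r_squared`, `diameter_range`, `contrast`,
#'   `fitted`, `residuals` and the underlying `lm` fit.
#' @seealso [predict.rc_regression()], [apply_pvc()]
#' @export
fit_rc_regression <- function(diameters, rc, beta, contrast = 4) {
  diameters <- as.numeric(diameters); rc <- as.numeric(rc)
  if (length(diameters) != length(rc) || length(diameters) < 2L)
    stop("need >= 2 (diameter, RC) points")
  if (length(unique(diameters)) < 2L)
    stop("all diameters identical: regression undefined")
  fit <- stats::lm(rc ~ diameters)
  sst <- sum((rc - mean(rc))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(beta = beta,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 diameter_range = range(diameters),
                 contrast = contrast,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 fit = fit),
            class = "rc_regression")
}

#' @export
print.rc_regression <- function(x, ...) {
  cat(sprintf(
    "rc_regression (beta = %s): RC%% = %.4g * d + %.4g, R^2 = %.4f, d in [%g, %g] mm\n",
    format(x$beta), x$slope, x$intercept, x$r_squared,
    x$diameter_range[1], x$diameter_range[2]))
  invisible(x)
}

#' @export
coef.rc_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict a recovery coefficient from lesion diameter
#'
#' Evaluates the fitted line and returns the RC as a fraction clamped to
#' (0.05, 1]; predictions outside the fitted diameter range (notably below
#' 10 mm, which the phantom spheres do not cover) are flagged as
#' extrapolated.
#'
#' @param object an `rc_regression` from [fit_rc_regression()].
#' @param diameter lesion diameter, mm (> 0).
#' @param ... unused.
#' @return A list with `rc` (fraction in (0.05, 1]), `extrapolated`
#'   (logical) and `clamped` (logical).
#' @export
predict.rc_regression <- function(object, diameter, ...) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`diameter` must be > 0")
  raw <- (object$slope * diameter + object$intercept) / 100
  rc <- pmin(pmax(raw, 0.05), 1)
  clamped <- rc != raw
  if (any(clamped))
    warning(sprintf("predicted RC clamped to (0.05, 1] for %d diameter(s)",
                    sum(clamped)))
  list(rc = rc,
       extrapolated = diameter < object$diameter_range[1] |
         diameter > object$diameter_range[2],
       clamped = clamped)
}

#' Alias of [predict.rc_regression()] with the operation's plain name
#'
#' @inheritParams predict.rc_regression
#' @param model an `rc_regression`.
#' @export
predict_rc <- function(model, diameter) {
  stopifnot(inherits(model, "rc_regression"))
  predict(model, diameter)
}

#' SUV record for one lesion at one beta
#'
#' @param lesion_id identifier.
#' @param beta reconstruction beta.
#' @param suv_mean,suv_max,suv_peak SUV values (suv_peak <= suv_max).
#' @param pvc_applied whether a partial-volume correction has been applied.
#' @param rc_used RC used by the correction, if any.
#' @return A list of class `suv_record`.
#' @export
suv_record <- function(lesion_id, beta, suv_mean, suv_max, suv_peak,
                       pvc_applied = FALSE, rc_used = NA_real_) {
  vals <- c(suv_mean, suv_max, suv_peak)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("SUVs must be finite and >= 0")
  structure(list(lesion_id = lesion_id, beta = beta, suv_mean = suv_mean,
                 suv_max = suv_max, suv_peak = suv_peak,
                 pvc_applied = pvc_applied, rc_used = rc_used),
            class = "suv_record")
}

#' Apply the regional partial-volume correction to an SUV record
#'
#' Divides SUVmean, SUVmax and SUVpeak by the estimated recovery
#' coefficient (a fraction in (0, 1]), marks the record as corrected and
#' retains the RC used.  Since `rc <= 1`, the correction never decreases an
#' SUV.
#'
#' @param record a [suv_record()].
#' @param rc estimated recovery coefficient, fraction in (0, 1].
#' @return The corrected [suv_record()].
#' @export
apply_pvc <- function(record, rc) {
  stopifnot(inherits(record, "suv_record"))
  if (!is.finite(rc) || rc <= 0) stop("`rc` must be in (0, 1]")
  if (rc > 1) stop("`rc` must be in (0, 1]")
  suv_record(record$lesion_id, record$beta,
             record$suv_mean / rc, record$suv_max / rc,
             record$suv_peak / rc,
             pvc_applied = TRUE, rc_used = rc)
}
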