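#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two equally long, non-constant
#' vectors, with the two-sided p-value from the t transform
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test
#'
#' Two-sided paired t statistic and p-value (via [stats::t.test()]);
#' errors when the pairwise differences have zero variance.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return A list with `t` and `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (stats::var(a - b) == 0)
    stop("zero variance of paired differences: t statistic undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` from the joint contingency
#' table of two categorical rating vectors; ratings (such as 1-5 scores
#' with halves) are treated as nominal categories.
#'
#' @param r1,r2 rating vectors of equal length (coerced to factors over the
#'   union of observed categories).
#' @return Scalar kappa.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("ratings must have equal length")
  if (!length(r1)) stop("empty ratings")
  lev <- sort(unique(c(as.character(r1), as.character(r2))))
  tab <- table(factor(as.character(r1), levels = lev),
               factor(as.character(r2), levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1)
    stop("kappa undefined: both raters constant and identical (p_e = 1)")
  (po - pe) / (1 - pe)
}

#' Overall subjective image-quality score
#'
#' Sum of the three component scores (general image quality, image
#' sharpness, lesion conspicuity), each rated on a 1-5 scale where
#' non-integer values are allowed.
#'
#' @param general,sharpness,conspicuity component scores in [1, 5].
#' @return The exact sum.
#' @export
overall_score <- function(general, sharpness, conspicuity) {
  comp <- c(general, sharpness, conspicuity)
  if (length(comp) != 3L) stop("provide exactly three component scores")
  if (any(!is.finite(comp)) || any(comp < 1) || any(comp > 5))
    stop("component scores must lie in [1, 5]")
  general + sharpness + conspicuity
}
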