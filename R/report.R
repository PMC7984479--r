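#' Load the packaged reader-score table
#'
#' Subjective image-quality ratings of two readers (general image quality,
#' image sharpness, lesion conspicuity, each 1-5 with halves allowed, plus
#' their sum as the overall score) for both lesion-size groups over the
#' 10-beta rating grid, shipped with the package.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A validated data frame with columns `group`, `beta`, `reader`,
#'   `general`, `sharpness`, `conspicuity`, `overall`.
#' @export
reader_scores <- function(path = system.file("extdata", "reader_scores.csv",
                                             package = "bplquant")) {
  read_table(path, type = "scores")
}

#' Best overall-score beta per size group
#'
#' Averages the overall score over readers per (group, beta) and returns
#' the beta with the highest mean overall score in each group, together
#' with each reader's own argmax.
#'
#' @param scores a reader-score table (see [reader_scores()]).
#' @return A data frame with columns `group`, `best_beta` (combined),
#'   `best_beta_reader1`, `best_beta_reader2`.
#' @export
best_overall_beta <- function(scores) {
  stopifnot(all(c("group", "beta", "reader", "overall") %in% names(scores)))
  groups <- unique(scores$group)
  res <- lapply(groups, function(g) {
    sub <- scores[scores$group == g, ]
    agg <- stats::aggregate(overall ~ beta, data = sub, FUN = mean)
    per_reader <- vapply(sort(unique(sub$reader)), function(rd) {
      s <- sub[sub$reader == rd, ]
      s$beta[which.max(s$overall)]
    }, 0)
    data.frame(group = g, best_beta = agg$beta[which.max(agg$overall)],
               best_beta_reader1 = per_reader[1],
               best_beta_reader2 = per_reader[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Inter-reader agreement summary
#'
#' Cohen's kappa between the two readers for each rating component and the
#' overall score, over all (group, beta) items.
#'
#' @param scores a reader-score table.
#' @return Named numeric vector of kappas.
#' @export
reader_agreement <- function(scores) {
  r1 <- scores[scores$reader == 1, ]
  r2 <- scores[scores$reader == 2, ]
  key <- function(d) paste(d$group, d$beta)
  r2 <- r2[match(key(r1), key(r2)), ]
  vapply(c("general", "sharpness", "conspicuity", "overall"),
         function(col) cohens_kappa(r1[[col]], r2[[col]]), 0)
}

#' Assemble the study report bundle
#'
#' Aggregates a metrics table and reader scores into the study's endpoint
#' summaries: per-sphere RC/CR/BV curves versus beta (NEMA metrics), SNR
#' and CNR versus beta per size group, SUV-versus-beta correlations before
#' and after partial-volume correction (when PVC columns are present), the
#' reader-agreement kappas, and the best-overall-score beta per group.
#'
#' @param metrics metrics table from [run_sweep()] (NEMA or clinical, the
#'   latter optionally passed through [apply_pvc_to_metrics()]).
#' @param scores reader-score table (default: the packaged fixture).
#' @param out_dir optional directory; when given, summary CSV tables and
#'   PNG figures are written there.
#' @return A list of class `study_report` with elements `curves`,
#'   `snr_cnr`, `correlations`, `kappa`, `best_beta`.
#' @export
build_report <- function(metrics, scores = reader_scores(),
                         out_dir = NULL) {
  if (is.null(metrics) || !nrow(metrics)) stop("empty metrics table")
  if (is.null(scores) || !nrow(scores)) stop("empty scores table")
  is_nema <- any(is.finite(metrics$rc_pct))
  curves <- snr_cnr <- correlations <- NULL
  if (is_nema) {
    curves <- stats::aggregate(
      cbind(rc_pct, cr_pct, bv_pct) ~ diameter_mm + beta, data = metrics,
      FUN = mean)
    curves <- curves[order(curves$diameter_mm, curves$beta), ]
  }
  if (any(is.finite(metrics$snr))) {
    snr_cnr <- stats::aggregate(cbind(snr, cnr) ~ group + beta,
                                data = metrics, FUN = mean)
    snr_cnr <- snr_cnr[order(snr_cnr$group, snr_cnr$beta), ]
    cols <- c("suv_mean", "suv_max", "suv_peak")
    if ("suv_peak_pvc" %in% names(metrics))
      cols <- c(cols, paste0(cols, "_pvc"))
    correlations <- do.call(rbind, lapply(unique(metrics$group), function(g) {
      do.call(rbind, lapply(cols, function(cl) {
        ct <- suv_beta_correlation(metrics, cl, g)
        data.frame(group = g, metric = cl, r = ct$r, p = ct$p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rep <- structure(list(curves = curves, snr_cnr = snr_cnr,
                        correlations = correlations,
                        kappa = reader_agreement(scores),
                        best_beta = best_overall_beta(scores)),
                   class = "study_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  for (i in seq_len(nrow(x$best_beta))) {
    cat(sprintf("  best overall-score beta, %s group: %g\n",
                x$best_beta$group[i], x$best_beta$best_beta[i]))
  }
  cat("  reader agreement (kappa):",
      paste(sprintf("%s %.3f", names(x$kappa), x$kappa), collapse = ", "),
      "\n")
  if (!is.null(x$correlations)) {
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  r(beta, %s | %s) = %+.3f\n",
                  x$correlations$metric[i], x$correlations$group[i],
                  x$correlations$r[i]))
    }
  }
  invisible(x)
}

write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(rep$curves)) {
    utils::write.csv(rep$curves, file.path(out_dir, "nema_curves.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "nema_curves.png"), 900, 600)
    plot_nema_curves(rep$curves)
    grDevices::dev.off()
  }
  if (!is.null(rep$snr_cnr)) {
    utils::write.csv(rep$snr_cnr, file.path(out_dir, "snr_cnr.csv"),
                     row.names = FALSE)
  }
  if (!is.null(rep$correlations)) {
    utils::write.csv(rep$correlations,
                     file.path(out_dir, "suv_beta_correlations.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(rep$best_beta, file.path(out_dir, "best_beta.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(component = names(rep$kappa),
                              kappa = unname(rep$kappa)),
                   file.path(out_dir, "kappa.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Plot RC, CR and BV versus beta per sphere
#'
#' @param curves the `curves` element of a [build_report()] result.
#' @export
plot_nema_curves <- function(curves) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  diam <- sort(unique(curves$diameter_mm))
  cols <- grDevices::hcl.colors(length(diam), "viridis")
  for (metric in c("rc_pct", "cr_pct", "bv_pct")) {
    ylim <- range(curves[[metric]])
    graphics::plot(NA, xlim = range(curves$beta), ylim = ylim,
                   xlab = "beta", ylab = metric,
                   main = toupper(sub("_pct", "", metric)))
    for (i in seq_along(diam)) {
      sub <- curves[curves$diameter_mm == diam[i], ]
      graphics::lines(sub$beta, sub[[metric]], col = cols[i], lwd = 2)
    }
    if (metric == "rc_pct")
      graphics::legend("topright", legend = paste(diam, "mm"), col = cols,
                       lwd = 2, cex = 0.7, bty = "n")
  }
}
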