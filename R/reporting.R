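# Agreement and feature-screening reports: the MAE/HR quality-threshold
# sweep (how r-PPG-vs-reference correlations improve as noisy recordings
# are excluded), the cross-modal correlation map, and per-measure change
# t-tests.

QUALITY_SWEEP_MEASURES <- c("hr_mean_bpm", "rmssd_ms", "pnn50_pct",
                            "sdnn_ms", "ln_hf", "ln_lf")

#' Quality-threshold agreement sweep
#'
#' For each MAE/HR threshold, keeps the recordings whose quality index is
#' at or below it and reports the Pearson correlation (and p-value)
#' between the r-PPG-derived and reference-derived value of each HRV
#' measure, plus the retained n. Thresholds retaining fewer than 3
#' recordings are marked insufficient. Tightening the threshold discards
#' the noisiest extractions, so correlations should improve as the
#' threshold decreases.
#'
#' @param paired data frame with one row per recording: `mae_over_hr` plus,
#'   for each measure in `measures`, columns `<measure>_rppg` and
#'   `<measure>_ref`.
#' @param thresholds numeric vector of MAE/HR thresholds.
#' @param measures measure names (defaults to HR and the five HRV
#'   measures).
#' @return data frame of class `quality_sweep`: one row per threshold with
#'   `r_<measure>`, `p_<measure>`, `n`, `insufficient`.
#' @export
quality_sweep <- function(paired, thresholds,
                          measures = QUALITY_SWEEP_MEASURES) {
  need <- c("mae_over_hr", paste0(rep(measures, each = 2L), c("_rppg", "_ref")))
  miss <- setdiff(need, names(paired))
  if (length(miss))
    pt_validation_error(paste("paired data lacks columns:", paste(miss, collapse = ", ")))
  rows <- lapply(thresholds, function(th) {
    sub <- paired[paired$mae_over_hr <= th, , drop = FALSE]
    row <- data.frame(threshold = th, n = nrow(sub), insufficient = nrow(sub) < 3L)
    for (m in measures) {
      r <- p <- NA_real_
      if (!row$insufficient) {
        a <- sub[[paste0(m, "_rppg")]]
        b <- sub[[paste0(m, "_ref")]]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) >= 3L && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
          ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
          r <- unname(ct$estimate)
          p <- ct$p.value
        }
      }
      row[[paste0("r_", m)]] <- r
      row[[paste0("p_", m)]] <- p
    }
    row
  })
  structure(do.call(rbind, rows), class = c("quality_sweep", "data.frame"))
}

#' Cross-modal correlation map
#'
#' Pearson correlation (and two-sided p) between every HRV change measure
#' and every regional temperature change across subjects, with a
#' significance mask at p < 0.05. Raw p-values are masked by default; a
#' Benjamini-Hochberg-adjusted mask is available via `adjust = "BH"`.
#'
#' @param hrv_deltas data frame or matrix, one row per subject, one column
#'   per HRV change measure.
#' @param thermal_changes data frame or matrix, one row per subject
#'   (aligned with `hrv_deltas`), one column per region change.
#' @param adjust `"none"` (default) or `"BH"` for the significance mask.
#' @param alpha mask level (default 0.05).
#' @return list of class `correlation_map`: matrices `r`, `p`, logical
#'   `significant` (measures x regions), and `n`.
#' @export
correlation_map <- function(hrv_deltas, thermal_changes,
                            adjust = c("none", "BH"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  A <- as.matrix(hrv_deltas)
  B <- as.matrix(thermal_changes)
  if (nrow(A) != nrow(B))
    pt_validation_error("hrv_deltas and thermal_changes must have aligned rows")
  ok <- stats::complete.cases(A) & stats::complete.cases(B)
  A <- A[ok, , drop = FALSE]
  B <- B[ok, , drop = FALSE]
  if (nrow(A) < 3L) pt_validation_error("need at least 3 complete subjects")
  r <- p <- matrix(NA_real_, ncol(A), ncol(B),
                   dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      if (stats::sd(A[, i]) == 0 || stats::sd(B[, j]) == 0) next
      ct <- stats::cor.test(A[, i], B[, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  pm <- if (adjust == "BH") matrix(stats::p.adjust(p, "BH"), nrow(p),
                                   dimnames = dimnames(p)) else p
  structure(list(r = r, p = p, significant = pm < alpha, n = nrow(A),
                 adjust = adjust, alpha = alpha),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d measures x %d regions, n = %d; %d pair(s) significant at %.2f (%s)\n",
              nrow(x$r), ncol(x$r), x$n, sum(x$significant, na.rm = TRUE),
              x$alpha, x$adjust))
  invisible(x)
}

#' Per-measure change t-tests
#'
#' One-sample two-sided t-test of each change column against zero (did the
#' measure shift between the first and last segment across subjects?).
#' Zero-variance columns are undefined and reported missing.
#'
#' @param deltas data frame or matrix, one row per subject, one column per
#'   change measure (HRV deltas and/or regional temperature changes).
#' @return data frame: `measure`, `mean_delta`, `t`, `df`, `p`.
#' @export
change_tests <- function(deltas) {
  D <- as.matrix(deltas)
  if (nrow(D) < 3L) pt_validation_error("need at least 3 subjects")
  rows <- lapply(colnames(D), function(m) {
    v <- D[, m]
    v <- v[is.finite(v)]
    if (length(v) < 3L || stats::sd(v) == 0)
      return(data.frame(measure = m, mean_delta = mean(v), t = NA_real_,
                        df = NA_real_, p = NA_real_))
    tt <- stats::t.test(v, mu = 0)
    data.frame(measure = m, mean_delta = mean(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}
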