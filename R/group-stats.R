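#' Two-tailed Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Mann-Whitney U with midranks for ties. The p-value is exact
#' (distribution of U over all rank assignments) when the combined sample
#' size is at most 20 and there are no ties, and otherwise uses the normal
#' approximation with tie-corrected variance and continuity correction.
#' When every pooled value is identical the tie-corrected variance is zero
#' and the test is vacuous; `p = 1` is returned with `method =
#' "degenerate"`. Swapping the samples maps `U` to `n_x * n_y - U` with an
#' identical p-value.
#'
#' @param x,y Non-empty numeric samples with finite values.
#' @return List with `U` (for `x` relative to `y`), `p` (two-tailed),
#'   `method` (`"exact"`, `"normal_approx"`, or `"degenerate"`).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1.0, method = "degenerate"))
  exact <- (nx + ny) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1.0
  list(U = unname(wt$statistic), p = min(p, 1.0),
       method = if (exact) "exact" else "normal_approx")
}

significance_tier <- function(p, tiers = c(0.05, 0.01)) {
  if (!is.finite(p)) return("untestable")
  if (p < tiers[2]) "**" else if (p < tiers[1]) "*" else "ns"
}

#' Compare normal and abnormal cohorts on per-patient metrics
#'
#' For each (structure, source, metric) cell, drops missing and excluded
#' records, splits the remaining patients by the stratification labels, and
#' runs a two-tailed Wilcoxon rank-sum test. Medians and the median
#' difference (abnormal - normal, so degradation appears as negative
#' Dice/surface-Dice deltas and positive MDA deltas) are reported alongside
#' the p-value and a significance tier (`**` for p < 0.01, `*` for
#' p < 0.05, `ns` otherwise). No multiple-testing correction is applied:
#' each cell is tested at raw p, as is conventional for per-organ
#' per-vendor QA summaries. A group with fewer than 2 usable records makes
#' the cell `untestable` (no p emitted).
#'
#' @param records data.frame with columns `patient`, `structure`, `source`,
#'   the metric columns, and optionally `status` (only `"ok"` rows are
#'   used) and/or `excluded` (TRUE rows are dropped).
#' @param stratification A [stratify()] result covering every patient in
#'   `records`.
#' @param metrics Character vector of metric column names to test.
#' @return data.frame with one row per (structure, source, metric):
#'   `structure`, `source`, `metric`, `n_normal`, `n_abnormal`,
#'   `median_normal`, `median_abnormal`, `median_diff`, `U`, `p`, `tier`,
#'   `method`.
#' @export
compare_cohorts <- function(records, stratification, metrics) {
  stopifnot(inherits(stratification, "cohort_stratification"))
  stopifnot(all(c("patient", "structure", "source") %in% names(records)))
  stopifnot(all(metrics %in% names(records)))
  labs <- stratification$labels
  if (!all(records$patient %in% labs$patient))
    stop("stratification labels must cover every patient with a record",
         call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  if ("status" %in% names(records)) keep <- keep & records$status == "ok"
  if ("excluded" %in% names(records)) keep <- keep & !records$excluded
  rec <- records[keep, , drop = FALSE]
  rec$label <- labs$label[match(rec$patient, labs$patient)]
  cells <- unique(rec[, c("structure", "source")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- rec[rec$structure == cells$structure[ci] &
                 rec$source == cells$source[ci], , drop = FALSE]
    for (metric in metrics) {
      v <- sub[[metric]]
      ok <- is.finite(v)
      xn <- v[ok & sub$label == "normal"]
      xa <- v[ok & sub$label == "abnormal"]
      row <- data.frame(structure = cells$structure[ci],
                        source = cells$source[ci], metric = metric,
                        n_normal = length(xn), n_abnormal = length(xa),
                        median_normal = if (length(xn)) stats::median(xn) else NA_real_,
                        median_abnormal = if (length(xa)) stats::median(xa) else NA_real_,
                        median_diff = NA_real_, U = NA_real_, p = NA_real_,
                        tier = "untestable", method = NA_character_,
                        stringsAsFactors = FALSE)
      if (length(xn) >= 1L && length(xa) >= 1L)
        row$median_diff <- row$median_abnormal - row$median_normal
      if (length(xn) >= 2L && length(xa) >= 2L) {
        tst <- rank_sum_test(xa, xn)
        row$U <- tst$U; row$p <- tst$p
        row$tier <- significance_tier(tst$p)
        row$method <- tst$method
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
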