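#' Per-patient tilt table for a cohort
#'
#' Runs the C1-C4 PCA tilt with the centroid-slope cross-check on every
#' patient.
#'
#' @param cohort A cohort from [simulate_cohort()] or [read_cohort()].
#' @param agreement_tol_deg Agreement tolerance passed to [tilt_result()].
#' @return data.frame: `patient`, `tilt_deg`, `centroid_slope_deg`,
#'   `n_voxels`, `agreement_flag`.
#' @export
tilt_table <- function(cohort, agreement_tol_deg = 2) {
  rows <- lapply(cohort$patients, function(p) {
    need <- c("cord", paste0("C", 1:4))
    missing <- setdiff(need, names(p$spine))
    if (length(missing) > 0L)
      stop(sprintf("patient %s lacks structure '%s' required for tilt analysis",
                   p$id, missing[1]), call. = FALSE)
    tilt_result(p$id, p$spine$cord, p$spine[paste0("C", 1:4)],
                agreement_tol_deg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contour-metric table for a cohort
#'
#' Scores every (patient, organ, vendor) gold/test pair with [score_pair()].
#'
#' @param cohort A cohort object.
#' @param tau_mm Surface-Dice tolerance in mm.
#' @param structures Organ names to score (default: all organs present).
#' @return data.frame of [score_pair()] records.
#' @export
metric_table <- function(cohort, tau_mm = 2.0, structures = cohort$organs) {
  rows <- list()
  for (p in cohort$patients) {
    for (o in intersect(structures, names(p$gold))) {
      gs <- if (mask_count(p$gold[[o]]) > 0L) extract_surface(p$gold[[o]])
      for (v in names(p$auto)) {
        if (is.null(p$auto[[v]][[o]])) next
        rows[[length(rows) + 1L]] <-
          score_pair(p$gold[[o]], p$auto[[v]][[o]], tau_mm,
                     patient = p$id, structure = o, source = v,
                     gold_surface = gs)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dose-difference table for a cohort
#'
#' Computes gold/test mean-dose differences for every (patient, organ,
#' vendor) pair with [dose_difference()].
#'
#' @param cohort A cohort object with dose grids.
#' @param exclusion_gy Gold mean-dose exclusion threshold (default 5 Gy).
#' @param structures Organ names to analyse (default: all organs present).
#' @return data.frame of [dose_difference()] records.
#' @export
dose_table <- function(cohort, exclusion_gy = 5.0, structures = cohort$organs) {
  rows <- list()
  for (p in cohort$patients) {
    if (is.null(p$dose)) next
    for (o in intersect(structures, names(p$gold))) {
      mg <- mean_dose(p$dose, p$gold[[o]])
      for (v in names(p$auto)) {
        if (is.null(p$auto[[v]][[o]])) next
        rows[[length(rows) + 1L]] <-
          dose_difference(p$dose, p$gold[[o]], p$auto[[v]][[o]], exclusion_gy,
                          patient = p$id, structure = o, source = v,
                          mean_gold = mg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Box-plot summary statistics with Tukey 1.5*IQR whiskers.
box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  inliers <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
  data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
             whisker_low = min(inliers), whisker_high = max(inliers),
             n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr))
}

#' Run the full QA pipeline
#'
#' Orchestrates simulate (optional) -> tilt -> stratify -> metrics -> dose
#' -> cohort comparison, writing `tilt.csv`, `cohort.csv`, `metrics.csv`,
#' `dose.csv`, `results.csv`, plus `boxstats.csv` (per-group box-plot
#' summaries, 1.5 IQR whiskers), `tilt_hist.csv` (histogram bins with the
#' percentile cutoffs), and `run_log.json` recording every constant and
#' seed. Outputs are pure functions of (inputs, config, seed): re-running
#' with an identical configuration reproduces the CSVs byte for byte.
#'
#' @param cohort A cohort object, a `cohort_manifest`, or a manifest path.
#'   Alternatively NULL with `simulate` set.
#' @param out_dir Output directory (created if needed).
#' @param simulate Optional [generator_config()]; when given, a phantom
#'   cohort is simulated instead of reading `cohort`.
#' @param tau_mm Surface-Dice tolerance (mm).
#' @param percentiles Lower/upper stratification percentiles.
#' @param exclusion_gy Dose-analysis exclusion threshold (Gy).
#' @param structures Organs to analyse (default: all found).
#' @return Invisibly, a list with all tables: `tilt`, `stratification`,
#'   `metrics`, `dose`, `results`, `boxstats`.
#' @export
run_all <- function(cohort = NULL, out_dir, simulate = NULL, tau_mm = 2.0,
                    percentiles = c(12, 88), exclusion_gy = 5.0,
                    structures = NULL) {
  stopifnot(tau_mm > 0, exclusion_gy >= 0,
            percentiles[1] > 0, percentiles[1] < percentiles[2],
            percentiles[2] < 100)
  if (!is.null(simulate)) {
    cohort <- simulate_cohort(simulate)
  } else if (is.character(cohort) || inherits(cohort, "cohort_manifest")) {
    cohort <- read_cohort(cohort)
  }
  if (is.null(cohort)) stop("either 'cohort' or 'simulate' must be given",
                            call. = FALSE)
  if (is.null(structures)) structures <- cohort$organs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tilt <- tilt_table(cohort)
  strat <- stratify(tilt, percentiles[1], percentiles[2])
  metrics <- metric_table(cohort, tau_mm, structures)
  dose <- dose_table(cohort, exclusion_gy, structures)

  geo <- compare_cohorts(metrics, strat, c("dsc", "sdsc", "mda_mm"))
  dos <- compare_cohorts(dose, strat, c("abs_diff_gy", "signed_diff_gy"))
  results <- rbind(geo, dos)

  # per-group box-plot summaries
  rec <- metrics[metrics$status == "ok", ]
  rec$label <- strat$labels$label[match(rec$patient, strat$labels$patient)]
  drec <- dose[!dose$excluded, ]
  drec$label <- strat$labels$label[match(drec$patient, strat$labels$patient)]
  bs <- list()
  for (df in list(list(d = rec, cols = c("dsc", "sdsc", "mda_mm")),
                  list(d = drec, cols = c("abs_diff_gy", "signed_diff_gy")))) {
    cells <- unique(df$d[, c("structure", "source")])
    for (ci in seq_len(nrow(cells))) for (metric in df$cols)
      for (lab in c("normal", "abnormal")) {
        v <- df$d[[metric]][df$d$structure == cells$structure[ci] &
                              df$d$source == cells$source[ci] &
                              df$d$label == lab]
        v <- v[is.finite(v)]
        if (length(v) == 0L) next
        bs[[length(bs) + 1L]] <-
          cbind(data.frame(structure = cells$structure[ci],
                           source = cells$source[ci], metric = metric,
                           group = lab, stringsAsFactors = FALSE),
                box_stats(v))
      }
  }
  boxstats <- do.call(rbind, bs)

  h <- graphics::hist(tilt$tilt_deg, breaks = "Sturges", plot = FALSE)
  tilt_hist <- data.frame(bin_low = h$breaks[-length(h$breaks)],
                          bin_high = h$breaks[-1], count = h$counts)

  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(tilt, "tilt.csv")
  wcsv(strat$labels, "cohort.csv")
  wcsv(metrics, "metrics.csv")
  wcsv(dose, "dose.csv")
  wcsv(results, "results.csv")
  wcsv(boxstats, "boxstats.csv")
  wcsv(tilt_hist, "tilt_hist.csv")

  log <- list(tau_mm = tau_mm, percentiles = percentiles,
              exclusion_gy = exclusion_gy,
              significance_tiers = c(0.05, 0.01),
              whisker_rule = "1.5*IQR",
              signed_diff_convention = "test_minus_gold",
              structures = structures,
              lower_threshold_deg = strat$lower_threshold_deg,
              upper_threshold_deg = strat$upper_threshold_deg,
              n_patients = nrow(tilt),
              generator = if (!is.null(simulate)) unclass(simulate) else NULL)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tilt = tilt, stratification = strat, metrics = metrics,
                 dose = dose, results = results, boxstats = boxstats,
                 cohort = cohort))
}

#' Histogram of cohort tilt with percentile cutoffs
#'
#' @param tilt A [tilt_table()] data.frame.
#' @param stratification A [stratify()] result.
#' @param binwidth Histogram bin width in degrees.
#' @return A ggplot object.
#' @export
plot_tilt_histogram <- function(tilt, stratification, binwidth = 5) {
  ggplot2::ggplot(tilt, ggplot2::aes(x = .data$tilt_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(stratification$lower_threshold_deg,
                                       stratification$upper_threshold_deg),
                        colour = "red", linetype = 2) +
    ggplot2::geom_vline(xintercept = stats::median(tilt$tilt_deg),
                        colour = "cyan3") +
    ggplot2::labs(x = "Neck tilt (deg, flexion positive)", y = "Patients")
}

#' Median-difference tier plot across structures and sources
#'
#' Shows the abnormal-minus-normal median difference for one metric per
#' (structure, source) cell, coloured by significance tier.
#'
#' @param results A [compare_cohorts()] data.frame.
#' @param metric Metric name to display.
#' @return A ggplot object.
#' @export
plot_metric_deltas <- function(results, metric = "sdsc") {
  d <- results[results$metric == metric & results$tier != "untestable", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$structure,
                                  fill = .data$median_diff)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$tier == "ns", "",
                                                   .data$tier))) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = sprintf("Abnormal - normal median %s", metric),
                  x = NULL, y = NULL, fill = "median diff")
}
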