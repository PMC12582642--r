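#' Cord voxels within the C1-C4 longitudinal extent
#'
#' Restricts the spinal-cord mask to the axial slices spanned by the union
#' of the four cervical vertebra masks and returns the physical centres of
#' the retained cord voxels. "Longitudinal extent" is a slice-range notion:
#' a cord voxel is kept when its z-slice contains at least one foreground
#' voxel of any of C1-C4.
#'
#' @param cord Cord [binary_mask()].
#' @param vertebrae List of four vertebra masks (C1-C4), sharing the cord's
#'   grid.
#' @return n x 3 matrix of physical coordinates (mm).
#' @export
cord_c1c4_voxels <- function(cord, vertebrae) {
  stopifnot(inherits(cord, "binary_mask"), length(vertebrae) == 4L)
  for (v in vertebrae) {
    if (!same_grid(cord, v)) stop_grid_mismatch("cord and vertebra masks")
    if (mask_count(v) == 0L)
      stop(sprintf("vertebra mask '%s' is empty", v$label), call. = FALSE)
  }
  if (mask_count(cord) == 0L) stop("cord mask is empty", call. = FALSE)
  vert_union <- Reduce(`|`, lapply(vertebrae, function(v) v$values == 1))
  vert_slices <- which(apply(vert_union, 3, any))
  cord_keep <- cord$values == 1
  drop_slices <- setdiff(seq_len(dim(cord_keep)[3]), vert_slices)
  if (length(drop_slices) > 0L) cord_keep[, , drop_slices] <- FALSE
  if (!any(cord_keep))
    stop("no z-slice overlap between the cord and the C1-C4 union",
         call. = FALSE)
  idx <- which(cord_keep, arr.ind = TRUE)
  coords <- sweep(sweep(idx - 1, 2, cord$spacing, "*"), 2, cord$origin, "+")
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' PCA neck-tilt angle from cord voxel coordinates
#'
#' Centres the coordinates, takes the eigenvector of the 3x3 covariance
#' with the largest eigenvalue, orients it superiorly (`vz >= 0`), and
#' reports the sagittal angle between its (y, z) projection and the
#' longitudinal axis: `tilt_deg = atan2(-vy, vz)` in degrees, so that in
#' LPS an anterior lean of the superior cord (flexion) is positive and
#' extension is negative. Deterministic under permutation of the input
#' points.
#'
#' @param coords n x 3 matrix of physical coordinates (mm), e.g. from
#'   [cord_c1c4_voxels()].
#' @param min_voxels Minimum number of points for a reliable covariance
#'   (default 20).
#' @return List with `tilt_deg`, `principal_vector` (unit, `vz >= 0`),
#'   `n_voxels`, and `tie_flag` (TRUE when the two largest eigenvalues are
#'   nearly equal and the axis choice fell back to deterministic ordering).
#' @export
pca_tilt_angle <- function(coords, min_voxels = 20) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < min_voxels)
    stop(sprintf("need at least %d cord voxels for PCA, got %d",
                 min_voxels, n), call. = FALSE)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  if (all(abs(cc) < 1e-12))
    stop("degenerate geometry: all cord points identical", call. = FALSE)
  cv <- crossprod(cc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  tie <- (eg$values[1] - eg$values[2]) <= 1e-9 * max(eg$values[1], 1e-300)
  if (v[3] < 0 || (v[3] == 0 && -v[2] < 0)) v <- -v
  list(tilt_deg = atan2(-v[2], v[3]) * 180 / pi,
       principal_vector = v, n_voxels = n, tie_flag = tie)
}

#' Centroid-slope neck-tilt angle from C1-C4
#'
#' Cross-check for the PCA angle: computes each vertebra's foreground
#' centroid in the sagittal plane (y, z in mm), least-squares fits
#' `y = a z + b` over the four centroids, and returns `atan(-a)` in
#' degrees — the same flexion-positive sign convention as
#' [pca_tilt_angle()].
#'
#' @param vertebrae List of four non-empty vertebra masks on one grid.
#' @return Angle in degrees.
#' @export
centroid_slope_angle <- function(vertebrae) {
  stopifnot(length(vertebrae) == 4L)
  g1 <- vertebrae[[1]]
  cents <- t(vapply(vertebrae, function(v) {
    if (!same_grid(g1, v)) stop_grid_mismatch("vertebra masks")
    co <- mask_foreground_coords(v)
    if (nrow(co) == 0L)
      stop(sprintf("vertebra mask '%s' is empty", v$label), call. = FALSE)
    colMeans(co)[c("y", "z")]
  }, numeric(2)))
  z <- cents[, 2]; y <- cents[, 1]
  vz <- stats::var(z)
  if (vz < 1e-12)
    stop("degenerate geometry: vertebra centroids share one z, slope undefined",
         call. = FALSE)
  a <- stats::cov(z, y) / vz
  atan(-a) * 180 / pi
}

#' Per-patient tilt result with cross-check
#'
#' Bundles the PCA tilt over the C1-C4 cord extent with the centroid-slope
#' angle and an agreement flag.
#'
#' @param patient Patient id.
#' @param cord Cord mask.
#' @param vertebrae List of four vertebra masks.
#' @param agreement_tol_deg Maximum |PCA - centroid slope| (deg) for the
#'   agreement flag (default 2).
#' @return One-row data.frame: `patient`, `tilt_deg`, `centroid_slope_deg`,
#'   `n_voxels`, `agreement_flag`.
#' @export
tilt_result <- function(patient, cord, vertebrae, agreement_tol_deg = 2) {
  coords <- cord_c1c4_voxels(cord, vertebrae)
  pca <- pca_tilt_angle(coords)
  cs <- centroid_slope_angle(vertebrae)
  data.frame(patient = patient,
             tilt_deg = pca$tilt_deg,
             centroid_slope_deg = cs,
             n_voxels = pca$n_voxels,
             agreement_flag = abs(pca$tilt_deg - cs) <= agreement_tol_deg,
             stringsAsFactors = FALSE)
}

#' Stratify a cohort into normal/abnormal tilt by percentile cutoffs
#'
#' Thresholds are nearest-rank percentiles: the value at rank
#' `ceiling(p/100 * n)` of the sorted tilts. A patient is labelled
#' `abnormal` iff the tilt is strictly below the lower threshold or
#' strictly above the upper one (both thresholds inclusive for `normal`).
#' With 35 distinct tilts and the default 12th/88th percentiles this labels
#' exactly 8 patients abnormal (4 in each tail).
#'
#' @param tilts data.frame with columns `patient` and `tilt_deg` (or a
#'   named numeric vector).
#' @param lower_pct,upper_pct Percentile cutoffs (defaults 12 and 88).
#' @return An object of class `cohort_stratification`: list with
#'   `lower_threshold_deg`, `upper_threshold_deg`, `lower_pct`,
#'   `upper_pct`, and `labels` (data.frame `patient`, `tilt_deg`, `label`).
#' @export
stratify <- function(tilts, lower_pct = 12, upper_pct = 88) {
  if (is.numeric(tilts))
    tilts <- data.frame(patient = names(tilts) %||% as.character(seq_along(tilts)),
                        tilt_deg = as.numeric(tilts), stringsAsFactors = FALSE)
  stopifnot(all(c("patient", "tilt_deg") %in% names(tilts)))
  n <- nrow(tilts)
  if (n < 3L) stop("need at least 3 patients to stratify", call. = FALSE)
  if (any(!is.finite(tilts$tilt_deg)))
    stop("all tilt values must be finite", call. = FALSE)
  if (!(lower_pct > 0 && lower_pct < upper_pct && upper_pct < 100))
    stop("need 0 < lower_pct < upper_pct < 100", call. = FALSE)
  s <- sort(tilts$tilt_deg)
  lo <- s[ceiling(lower_pct / 100 * n)]
  up <- s[ceiling(upper_pct / 100 * n)]
  label <- ifelse(tilts$tilt_deg < lo | tilts$tilt_deg > up,
                  "abnormal", "normal")
  structure(list(lower_threshold_deg = lo, upper_threshold_deg = up,
                 lower_pct = lower_pct, upper_pct = upper_pct,
                 labels = data.frame(patient = tilts$patient,
                                     tilt_deg = tilts$tilt_deg,
                                     label = label,
                                     stringsAsFactors = FALSE)),
            class = "cohort_stratification")
}

#' @export
print.cohort_stratification <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<cohort_stratification> n=%d, thresholds [%.2f, %.2f] deg (pct %g/%g): %d normal, %d abnormal\n",
              nrow(x$labels), x$lower_threshold_deg, x$upper_threshold_deg,
              x$lower_pct, x$upper_pct,
              if ("normal" %in% names(tab)) tab[["normal"]] else 0L,
              if ("abnormal" %in% names(tab)) tab[["abnormal"]] else 0L))
  invisible(x)
}
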