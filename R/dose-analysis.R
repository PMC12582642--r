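# Trilinear interpolation of a dose grid at physical points (mm).
# Errors when any point lies outside the grid's physical extent.
trilinear_sample <- function(dose, points) {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$values)
  f <- sweep(sweep(points, 2, dose$origin), 2, dose$spacing, "/")
  eps <- 1e-9
  bad <- which(f[, 1] < -eps | f[, 1] > d[1] - 1 + eps |
                 f[, 2] < -eps | f[, 2] > d[2] - 1 + eps |
                 f[, 3] < -eps | f[, 3] > d[3] - 1 + eps)
  if (length(bad) > 0L)
    stop(sprintf("mask voxel at (%.2f, %.2f, %.2f) mm lies outside the dose grid extent",
                 points[bad[1], 1], points[bad[1], 2], points[bad[1], 3]),
         call. = FALSE)
  fx <- pmin(pmax(f[, 1], 0), d[1] - 1)
  fy <- pmin(pmax(f[, 2], 0), d[2] - 1)
  fz <- pmin(pmax(f[, 3], 0), d[3] - 1)
  ix <- pmax(pmin(floor(fx), d[1] - 2), 0)
  iy <- pmax(pmin(floor(fy), d[2] - 2), 0)
  iz <- pmax(pmin(floor(fz), d[3] - 2), 0)
  wx <- fx - ix; wy <- fy - iy; wz <- fz - iz
  v <- dose$values
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  base <- 1 + ix + iy * sy + iz * sz
  (1 - wx) * (1 - wy) * (1 - wz) * v[base] +
    wx * (1 - wy) * (1 - wz) * v[base + sx] +
    (1 - wx) * wy * (1 - wz) * v[base + sy] +
    wx * wy * (1 - wz) * v[base + sx + sy] +
    (1 - wx) * (1 - wy) * wz * v[base + sz] +
    wx * (1 - wy) * wz * v[base + sx + sz] +
    (1 - wx) * wy * wz * v[base + sy + sz] +
    wx * wy * wz * v[base + sx + sy + sz]
}

#' Mean dose over a structure
#'
#' Average of the dose trilinearly interpolated at the physical centres of
#' all foreground mask voxels. The mask and dose grid need not share a
#' grid, but every foreground voxel centre must lie inside the dose grid's
#' physical extent (no silent clamping). Trilinear sampling is exact for
#' dose fields linear in position.
#'
#' @param dose A [dose_grid()].
#' @param m Non-empty [binary_mask()].
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, m) {
  pts <- mask_foreground_coords(m)
  if (nrow(pts) == 0L)
    stop("cannot compute the mean dose of an empty mask", call. = FALSE)
  mean(trilinear_sample(dose, pts))
}

#' Gold-versus-test mean-dose difference with low-dose exclusion
#'
#' Computes both structures' mean doses and their signed difference,
#' defined as `test - gold` (negative values mean the auto contour sits in
#' lower-dose tissue than the gold contour). Records whose gold mean dose
#' falls below `exclusion_gy` are flagged excluded — they carry their
#' values but are omitted from cohort statistics.
#'
#' @param dose A [dose_grid()].
#' @param gold,test Non-empty [binary_mask()] objects (any grids).
#' @param exclusion_gy Gold mean-dose threshold below which the record is
#'   excluded (default 5 Gy).
#' @param patient,structure,source Identifiers copied into the record.
#' @param mean_gold Optional precomputed gold mean dose (Gy), to avoid
#'   resampling the same gold contour for several sources.
#' @return One-row data.frame: `patient`, `structure`, `source`,
#'   `mean_gold_gy`, `mean_test_gy`, `signed_diff_gy` (test - gold),
#'   `abs_diff_gy`, `excluded`, `reason`.
#' @export
dose_difference <- function(dose, gold, test, exclusion_gy = 5.0,
                            patient = NA_character_,
                            structure = gold$label,
                            source = test$source,
                            mean_gold = NULL) {
  mg <- if (is.null(mean_gold)) mean_dose(dose, gold) else mean_gold
  mt <- mean_dose(dose, test)
  excluded <- mg < exclusion_gy
  data.frame(patient = patient, structure = structure, source = source,
             mean_gold_gy = mg, mean_test_gy = mt,
             signed_diff_gy = mt - mg, abs_diff_gy = abs(mt - mg),
             excluded = excluded,
             reason = if (excluded)
               sprintf("gold mean dose %.2f Gy < %.2f Gy", mg, exclusion_gy)
             else "",
             stringsAsFactors = FALSE)
}
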