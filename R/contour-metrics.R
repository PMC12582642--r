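#' Volumetric Dice similarity coefficient
#'
#' Sorensen overlap by voxel counts: `2|A n B| / (|A| + |B|)`. Both masks
#' must share one grid; comparing two empty masks is an undefined-metric
#' error.
#'
#' @param a,b [binary_mask()] objects on one grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!same_grid(a, b)) stop_grid_mismatch()
  na <- mask_count(a); nb <- mask_count(b)
  if (na + nb == 0L)
    stop("undefined metric: both masks are empty", call. = FALSE)
  2 * sum(a$values == 1 & b$values == 1) / (na + nb)
}

#' Extract the boundary-face surface of a mask
#'
#' The surface is the set of voxel faces separating a foreground voxel from
#' a background voxel, with the volume implicitly padded by background (so
#' foreground touching the array edge still contributes faces). Each
#' element is the face centre (mm) and its area (the product of the two
#' spacing components orthogonal to the face normal).
#'
#' @param m Non-empty [binary_mask()].
#' @return An object of class `surface_mesh`: list with `points` (n x 3,
#'   mm), `areas` (mm^2), and `total_area`.
#' @export
extract_surface <- function(m) {
  if (!any(m$values == 1))
    stop("cannot extract the surface of an empty mask", call. = FALSE)
  m <- crop_to_foreground(m)
  d <- dim(m$values)
  sp <- m$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  lin <- which(m$values == 1)
  inmask <- logical(prod(d))
  inmask[lin] <- TRUE
  z <- lin - 1L
  i <- z %% d[1]; jk <- z %/% d[1]; j <- jk %% d[2]; k <- jk %/% d[2]
  ijk <- cbind(i, j, k)
  strides <- c(1L, d[1], d[1] * d[2])
  pts <- vector("list", 6L); areas <- vector("list", 6L); kk <- 0L
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      # a face exists where the neighbour along (axis, sgn) is background
      # or out of bounds (implicit padding)
      nb_idx <- ijk[, axis] + sgn
      inb <- nb_idx >= 0L & nb_idx < d[axis]
      exposed <- !inb
      exposed[inb] <- !inmask[lin[inb] + sgn * strides[axis]]
      if (!any(exposed)) next
      coords <- ijk[exposed, , drop = FALSE] *
        rep(sp, each = sum(exposed)) +
        rep(m$origin, each = sum(exposed))
      coords[, axis] <- coords[, axis] + sgn * sp[axis] / 2
      kk <- kk + 1L
      pts[[kk]] <- coords
      areas[[kk]] <- rep(face_area[axis], nrow(coords))
    }
  }
  points <- do.call(rbind, pts[seq_len(kk)])
  areas <- unlist(areas[seq_len(kk)])
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, areas = areas, total_area = sum(areas)),
            class = "surface_mesh")
}

# Surfaces of a mask pair plus the two directed nearest-distance vectors.
# Pre-extracted surfaces can be passed to avoid recomputation.
surface_distances <- function(a, b, sa = NULL, sb = NULL) {
  if (!same_grid(a, b)) stop_grid_mismatch()
  if (is.null(sa)) sa <- extract_surface(a)
  if (is.null(sb)) sb <- extract_surface(b)
  cell <- 2 * max(a$spacing)
  list(sa = sa, sb = sb,
       d_ab = .nn_point_distances(sa$points, sb$points, cell),
       d_ba = .nn_point_distances(sb$points, sa$points, cell))
}

#' Surface Dice similarity coefficient at tolerance tau
#'
#' Area fraction of the two boundary surfaces lying within `tau_mm` of the
#' other surface (nearest face-centre distance):
#' `(area{e in SA : d(e,SB) <= tau} + area{e in SB : d(e,SA) <= tau}) /
#' (area(SA) + area(SB))`. Symmetric in its operands.
#'
#' @param a,b Non-empty [binary_mask()] objects on one grid.
#' @param tau_mm Tolerance in mm (default 2).
#' @return Surface Dice in \[0, 1\].
#' @export
surface_dice <- function(a, b, tau_mm = 2.0) {
  sd <- surface_distances(a, b)
  (sum(sd$sa$areas[sd$d_ab <= tau_mm]) + sum(sd$sb$areas[sd$d_ba <= tau_mm])) /
    (sd$sa$total_area + sd$sb$total_area)
}

#' Mean distance to agreement
#'
#' Symmetric, area-weighted mean nearest-surface distance between the two
#' boundary surfaces:
#' `(sum_A area_e d(e,SB) + sum_B area_e d(e,SA)) / (area(SA) + area(SB))`
#' in mm. Zero iff the two face-centre sets coincide.
#'
#' @param a,b Non-empty [binary_mask()] objects on one grid.
#' @return MDA in mm.
#' @export
mean_distance_to_agreement <- function(a, b) {
  sd <- surface_distances(a, b)
  (sum(sd$sa$areas * sd$d_ab) + sum(sd$sb$areas * sd$d_ba)) /
    (sd$sa$total_area + sd$sb$total_area)
}

#' Score a gold/test contour pair
#'
#' Bundles volumetric Dice, surface Dice at `tau_mm`, and mean distance to
#' agreement into one record. An empty test (or gold) mask yields a row
#' with `status = "missing_empty_mask"` and NA metrics rather than an
#' error, so the patient can be excluded from that structure's cohort test
#' downstream.
#'
#' @param gold,test [binary_mask()] objects on one grid.
#' @param tau_mm Surface-Dice tolerance in mm.
#' @param patient,structure,source Identifiers copied into the record.
#' @param gold_surface Optional pre-extracted [extract_surface()] of
#'   `gold`, to avoid recomputing it when the same gold contour is scored
#'   against several sources.
#' @return One-row data.frame: `patient`, `structure`, `source`, `dsc`,
#'   `sdsc`, `mda_mm`, `tau_mm`, `status`.
#' @export
score_pair <- function(gold, test, tau_mm = 2.0,
                       patient = NA_character_,
                       structure = gold$label,
                       source = test$source,
                       gold_surface = NULL) {
  rec <- data.frame(patient = patient, structure = structure, source = source,
                    dsc = NA_real_, sdsc = NA_real_, mda_mm = NA_real_,
                    tau_mm = tau_mm, status = "ok", stringsAsFactors = FALSE)
  if (!same_grid(gold, test)) stop_grid_mismatch()
  if (mask_count(gold) == 0L || mask_count(test) == 0L) {
    rec$status <- "missing_empty_mask"
    return(rec)
  }
  sd <- surface_distances(gold, test, sa = gold_surface)
  tot <- sd$sa$total_area + sd$sb$total_area
  rec$dsc <- dice(gold, test)
  rec$sdsc <- (sum(sd$sa$areas[sd$d_ab <= tau_mm]) +
                 sum(sd$sb$areas[sd$d_ba <= tau_mm])) / tot
  rec$mda_mm <- (sum(sd$sa$areas * sd$d_ab) + sum(sd$sb$areas * sd$d_ba)) / tot
  rec
}
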