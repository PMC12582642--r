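#' Axis-aligned 3D scalar volume
#'
#' A `volume_grid` is the package's basic spatial container: a 3D numeric
#' array with voxel spacing and origin in millimetres, in the LPS patient
#' convention (x = right-to-left, y = anterior-to-posterior, z =
#' inferior-to-superior). The physical centre of voxel `(i, j, k)` (1-based R
#' indices) is `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param values 3D numeric array, each dimension >= 1.
#' @param spacing Numeric length-3, strictly positive voxel spacing in mm.
#' @param origin Numeric length-3, physical centre of voxel (1,1,1) in mm.
#' @return An object of class `volume_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary structure mask
#'
#' A `binary_mask` is a [volume_grid()] restricted to values 0/1, carrying a
#' structure label (e.g. `"cord"`, `"C1"`, `"parotid_l"`) and a provenance
#' tag (`"gold"`, a vendor identifier, or `"generator"`).
#'
#' @param values 3D array of 0/1 (logical or numeric), or a `volume_grid`.
#' @param spacing,origin Geometry, ignored when `values` is a `volume_grid`.
#' @param label Structure name.
#' @param source Provenance tag.
#' @return An object of class `c("binary_mask", "volume_grid")`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "structure", source = "unknown") {
  if (inherits(values, "volume_grid")) {
    g <- values
  } else {
    g <- volume_grid(values, spacing, origin)
  }
  v <- g$values
  if (is.logical(v)) {
    storage.mode(v) <- "double"
  }
  if (any(!(v == 0 | v == 1)))
    stop("binary mask values must all be 0 or 1", call. = FALSE)
  structure(list(values = v, spacing = g$spacing, origin = g$origin,
                 label = as.character(label), source = as.character(source)),
            class = c("binary_mask", "volume_grid"))
}

#' Dose grid in Gy
#'
#' @param values 3D array of non-negative finite doses (Gy), or a
#'   `volume_grid`.
#' @param spacing,origin Geometry, ignored when `values` is a `volume_grid`.
#' @return An object of class `c("dose_grid", "volume_grid")` with
#'   `units = "Gy"`.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(values, "volume_grid")) g <- values
  else g <- volume_grid(values, spacing, origin)
  if (any(!is.finite(g$values)) || any(g$values < 0))
    stop("dose values must be finite and non-negative", call. = FALSE)
  structure(list(values = g$values, spacing = g$spacing, origin = g$origin,
                 units = "Gy"),
            class = c("dose_grid", "volume_grid"))
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  if (inherits(x, "binary_mask"))
    cat(sprintf("  label '%s', source '%s', %d foreground voxels\n",
                x$label, x$source, sum(x$values)))
  invisible(x)
}

# Per-axis physical coordinates of voxel centres.
grid_axes <- function(g) {
  d <- dim(g$values)
  list(x = g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3])
}

# Do two grids share geometry (dims, spacing, origin)?
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_grid_mismatch <- function(what = "masks") {
  stop(sprintf("grid mismatch: %s must share dimensions, spacing and origin",
               what), call. = FALSE)
}

# n x 3 matrix of physical centres of foreground voxels.
mask_foreground_coords <- function(m) {
  idx <- which(m$values == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  coords <- sweep(sweep(idx - 1, 2, m$spacing, "*"), 2, m$origin, "+")
  colnames(coords) <- c("x", "y", "z")
  coords
}

mask_count <- function(m) sum(m$values == 1)

# Internal fast-path constructor: trusted 0/1 double array, no validation.
new_binary_mask <- function(values, spacing, origin, label, source) {
  structure(list(values = values, spacing = spacing, origin = origin,
                 label = label, source = source),
            class = c("binary_mask", "volume_grid"))
}

# Crop a mask to the bounding box of its foreground plus one voxel of
# background on each side (clamped to the array). Geometry-preserving:
# origin is shifted accordingly. Used to keep surface extraction cheap.
crop_to_foreground <- function(m) {
  d <- dim(m$values)
  lin <- which(m$values == 1) - 1L
  i <- lin %% d[1]
  jk <- lin %/% d[1]
  j <- jk %% d[2]
  k <- jk %/% d[2]
  rng <- list(c(max(1L, min(i) + 0L), min(d[1], max(i) + 2L)),
              c(max(1L, min(j) + 0L), min(d[2], max(j) + 2L)),
              c(max(1L, min(k) + 0L), min(d[3], max(k) + 2L)))
  if (rng[[1]][1] == 1L && rng[[1]][2] == d[1] &&
      rng[[2]][1] == 1L && rng[[2]][2] == d[2] &&
      rng[[3]][1] == 1L && rng[[3]][2] == d[3]) return(m)
  vals <- m$values[rng[[1]][1]:rng[[1]][2],
                   rng[[2]][1]:rng[[2]][2],
                   rng[[3]][1]:rng[[3]][2], drop = FALSE]
  lo <- c(rng[[1]][1], rng[[2]][1], rng[[3]][1])
  new_binary_mask(vals, m$spacing, m$origin + (lo - 1) * m$spacing,
                  m$label %||% "structure", m$source %||% "unknown")
}
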