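#' Read an axis-aligned NIfTI volume as an LPS grid
#'
#' Reads a NIfTI-1 file and normalizes it into the package's fixed LPS
#' convention (x = right-to-left, y = anterior-to-posterior, z =
#' inferior-to-superior). The file's affine may use any axis permutation and
#' sign flips (e.g. RAS); the voxel array is reordered and flipped so that
#' the returned grid always follows LPS with positive spacings, and the
#' physical coordinate of every voxel is preserved. Oblique (rotated or
#' sheared) affines are rejected explicitly rather than misinterpreted.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(dim(img)), path),
         call. = FALSE)
  m <- unclass(RNifti::xform(img))  # 4x4, voxel index (0-based) -> RAS mm
  rot <- m[1:3, 1:3]
  # axis-aligned means exactly one non-negligible entry per column
  tolr <- 1e-4 * max(abs(rot))
  nz_per_col <- colSums(abs(rot) > tolr)
  if (any(nz_per_col != 1L) || any(colSums(abs(rot) > tolr) != rowSums(abs(rot) > tolr)))
    stop(sprintf("unsupported orientation: affine of %s is oblique (rotation/shear); only axis-aligned volumes are supported",
                 path), call. = FALSE)
  # convert RAS -> LPS by negating the first two physical axes
  lps <- m
  lps[1, ] <- -lps[1, ]
  lps[2, ] <- -lps[2, ]
  vals <- as.array(img)
  storage.mode(vals) <- "double"
  d <- dim(vals)
  perm <- integer(3)     # voxel axis feeding each LPS physical axis
  spacing <- numeric(3)
  origin <- numeric(3)
  flip <- logical(3)
  for (k in 1:3) {
    j <- which(abs(lps[k, 1:3]) > tolr)
    if (length(j) != 1L)
      stop(sprintf("unsupported orientation: affine of %s is degenerate", path),
           call. = FALSE)
    perm[k] <- j
    s <- lps[k, j]
    if (s > 0) {
      spacing[k] <- s
      origin[k] <- lps[k, 4]
      flip[k] <- FALSE
    } else {
      spacing[k] <- -s
      origin[k] <- lps[k, 4] + (d[j] - 1) * s
      flip[k] <- TRUE
    }
  }
  if (anyDuplicated(perm))
    stop(sprintf("unsupported orientation: affine of %s is singular", path),
         call. = FALSE)
  for (k in 1:3) {
    if (flip[k]) {
      j <- perm[k]
      idx <- rep(list(quote(expr = )), 3)
      idx[[j]] <- rev(seq_len(d[j]))
      vals <- do.call(`[`, c(list(vals), idx, list(drop = FALSE)))
    }
  }
  vals <- aperm(vals, perm)
  volume_grid(vals, spacing = spacing, origin = origin)
}

#' Write a grid to NIfTI-1
#'
#' Writes the grid with an axis-aligned affine encoding its LPS spacing and
#' origin (stored in the file's native RAS convention), so that
#' `read_volume(write_volume(g, path))` reproduces values, spacing and
#' origin.
#'
#' @param grid A [volume_grid()] (binary masks and dose grids included).
#' @param path Destination `.nii` or `.nii.gz` path.
#' @param datatype NIfTI on-disk datatype, e.g. `"auto"` (double for numeric
#'   arrays) or `"uint8"` for binary masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = "auto") {
  stopifnot(inherits(grid, "volume_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("destination directory does not exist: %s", dir), call. = FALSE)
  vals <- grid$values
  storage.mode(vals) <- "double"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(4)
  aff[1, 1] <- -grid$spacing[1]
  aff[2, 2] <- -grid$spacing[2]
  aff[3, 3] <- grid$spacing[3]
  aff[1:3, 4] <- c(-grid$origin[1], -grid$origin[2], grid$origin[3])
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
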