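#' Load and validate a cohort manifest
#'
#' The manifest is a JSON document with a top-level `"patients"` array; each
#' entry is `{"id": str, "structures": {structName: {sourceName: path}},
#' "dose": path|null}` and may carry an optional precomputed `"tilt"`.
#' Relative paths are resolved against the manifest's directory. Validation
#' is eager: duplicate patient ids and dangling file paths are errors.
#'
#' @param path Path to `manifest.json`.
#' @param check_paths Verify that every referenced file exists (default TRUE).
#' @return An object of class `cohort_manifest`: a list with element
#'   `patients` (named as in the file, paths made absolute).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$patients) || !is.list(doc$patients))
    stop("manifest must contain a top-level 'patients' array", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  ids <- vapply(doc$patients, function(p) as.character(p$id %||% NA_character_),
                character(1))
  if (any(is.na(ids)))
    stop("every patient entry needs an 'id'", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate patient id(s) in manifest: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  patients <- lapply(doc$patients, function(p) {
    structures <- lapply(p$structures, function(sources) {
      lapply(sources, resolve)
    })
    list(id = as.character(p$id),
         structures = structures,
         dose = resolve(p$dose),
         tilt = if (!is.null(p$tilt)) as.numeric(p$tilt) else NULL)
  })
  names(patients) <- ids
  if (isTRUE(check_paths)) {
    for (p in patients) {
      paths <- c(unlist(p$structures, use.names = FALSE), p$dose)
      missing <- paths[!vapply(paths, file.exists, logical(1))]
      if (length(missing) > 0L)
        stop(sprintf("manifest references missing file(s) for patient %s: %s",
                     p$id, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(patients = patients), class = "cohort_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a manifest patient has the structures an analysis needs
#'
#' The tilt stage needs the cord and all four of C1-C4 from one source.
#'
#' @param manifest A `cohort_manifest`.
#' @param structures Required structure names.
#' @param source Source the structures must come from (default `"gold"`).
#' @return Invisibly TRUE; errors naming the first offending patient and
#'   structure otherwise.
#' @export
require_structures <- function(manifest,
                               structures = c("cord", "C1", "C2", "C3", "C4"),
                               source = "gold") {
  stopifnot(inherits(manifest, "cohort_manifest"))
  for (p in manifest$patients) {
    for (s in structures) {
      if (is.null(p$structures[[s]]) || is.null(p$structures[[s]][[source]]))
        stop(sprintf("patient %s lacks required structure '%s' (source '%s')",
                     p$id, s, source), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a cohort manifest to JSON
#'
#' @param manifest A `cohort_manifest` (paths as they should appear in the
#'   file).
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  doc <- list(patients = unname(lapply(manifest$patients, function(p) {
    list(id = p$id, structures = p$structures, dose = p$dose, tilt = p$tilt)
  })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
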