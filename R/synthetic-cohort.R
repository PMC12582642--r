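#' Configuration for the synthetic phantom cohort
#'
#' Defines the study conditions the generator emulates: a head-and-neck
#' cohort whose sagittal neck tilt spans roughly -20 to 66 degrees with a
#' median near 12 degrees, a tilted cylindrical spinal cord with four
#' vertebral boxes stacked along its axis, two laterally placed
#' parotid-like ellipsoids whose simulated auto-contour error grows once
#' tilt deviates from the cohort median beyond a deadband, one
#' tilt-insensitive brainstem-like control organ, and a Gaussian dose
#' distribution centred near the mid cervical cord so that most gold organs
#' receive well over 5 Gy mean dose.
#'
#' All lengths are mm, angles degrees, doses Gy. Flexion (chin toward
#' chest) is positive tilt; in LPS the cord axis at tilt theta is
#' `(0, -sin(theta), cos(theta))`.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; fixes the entire cohort bit-for-bit.
#' @param n_vendors Number of simulated auto-segmentation sources.
#' @param tilt_mean,tilt_sd Normal tilt distribution parameters (deg).
#' @param tilt_range Truncation bounds for the tilt draw (deg).
#' @param tilt_center Reference median tilt used by the perturbation model
#'   (deg).
#' @param cord_radius,cord_length Cord cylinder geometry (mm).
#' @param vertebra_height Height of each of the four stacked vertebral
#'   boxes along z (mm); width/depth are `vertebra_width`,
#'   `vertebra_depth`.
#' @param vertebra_width,vertebra_depth Box extents in x and y (mm).
#' @param parotid_semiaxes Ellipsoid semi-axes (mm) of the parotid-like
#'   organs.
#' @param parotid_offset Lateral (x) offset of each parotid centre from the
#'   cord's superior end (mm), mirrored left/right.
#' @param parotid_inferior How far below the cord's superior end the
#'   parotid centres sit (mm).
#' @param control_semiaxes Semi-axes (mm) of the brainstem-like control
#'   organ.
#' @param control_superior Superior offset of the control organ centre from
#'   the cord's superior end (mm).
#' @param spacing CT voxel spacing (mm) used for all masks.
#' @param sigma0 Baseline per-axis translation SD of the simulated vendor
#'   error (mm).
#' @param k Growth of that SD per degree of tilt deviation beyond the
#'   deadband (mm/deg).
#' @param deadband Tilt deviation (deg) from `tilt_center` below which the
#'   vendor error stays at `sigma0`.
#' @param dose_max Peak dose (Gy) of the Gaussian dose model.
#' @param dose_sigma Isotropic SD (mm) of the Gaussian dose model.
#' @param dose_jitter Per-axis SD (mm) of the patient-specific jitter of
#'   the dose target centre.
#' @param dose_center_frac Position of the nominal dose target centre along
#'   the cord axis, as a fraction of cord length.
#' @param dose_spacing Dose-grid voxel spacing (mm); clinical dose grids
#'   are coarser than CT.
#' @param organ_margin Margin (mm) added around each gold organ when sizing
#'   its mask grid.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 35,
                             seed = 1,
                             n_vendors = 2,
                             tilt_mean = 12, tilt_sd = 15,
                             tilt_range = c(-25, 70),
                             tilt_center = 12,
                             cord_radius = 5, cord_length = 60,
                             vertebra_height = 15,
                             vertebra_width = 20, vertebra_depth = 20,
                             parotid_semiaxes = c(12, 18, 22),
                             parotid_offset = 35,
                             parotid_inferior = 5,
                             control_semiaxes = c(10, 10, 20),
                             control_superior = 15,
                             spacing = c(1.27, 1.27, 2.0),
                             sigma0 = 1.0, k = 0.15, deadband = 15,
                             dose_max = 70, dose_sigma = 30,
                             dose_jitter = 10, dose_center_frac = 0.4,
                             dose_spacing = c(2.5, 2.5, 2.5),
                             organ_margin = 16) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              n_vendors = as.integer(n_vendors),
              tilt_mean = tilt_mean, tilt_sd = tilt_sd,
              tilt_range = tilt_range, tilt_center = tilt_center,
              cord_radius = cord_radius, cord_length = cord_length,
              vertebra_height = vertebra_height,
              vertebra_width = vertebra_width,
              vertebra_depth = vertebra_depth,
              parotid_semiaxes = parotid_semiaxes,
              parotid_offset = parotid_offset,
              parotid_inferior = parotid_inferior,
              control_semiaxes = control_semiaxes,
              control_superior = control_superior,
              spacing = spacing,
              sigma0 = sigma0, k = k, deadband = deadband,
              dose_max = dose_max, dose_sigma = dose_sigma,
              dose_jitter = dose_jitter,
              dose_center_frac = dose_center_frac,
              dose_spacing = dose_spacing,
              organ_margin = organ_margin)
  lens <- c(cfg$cord_radius, cfg$cord_length, cfg$vertebra_height,
            cfg$vertebra_width, cfg$vertebra_depth, cfg$parotid_semiaxes,
            cfg$parotid_offset, cfg$control_semiaxes, cfg$spacing,
            cfg$sigma0, cfg$dose_max, cfg$dose_sigma, cfg$dose_spacing,
            cfg$organ_margin)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all generator sizes must be strictly positive", call. = FALSE)
  if (cfg$n_patients < 1L || cfg$n_vendors < 1L)
    stop("need at least one patient and one vendor", call. = FALSE)
  if (cfg$tilt_range[1] > cfg$tilt_mean || cfg$tilt_range[2] < cfg$tilt_mean)
    stop("tilt truncation bounds must contain the mean", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' Tilt-dependent vendor-error SD
#'
#' Per-axis SD (mm) of the simulated auto-contour translation error:
#' `sigma0 + k * max(0, |theta - tilt_center| - deadband)`. Flat (at
#' `sigma0`) across the normal tilt range, growing linearly once the
#' deviation from the cohort median exceeds the deadband. The control organ
#' always uses `sigma0`.
#'
#' @param theta_deg Tilt angle(s), degrees.
#' @param config A [generator_config()].
#' @return SD in mm, same length as `theta_deg`.
#' @export
perturbation_sd <- function(theta_deg, config = generator_config()) {
  stopifnot(all(is.finite(theta_deg)))
  config$sigma0 +
    config$k * pmax(0, abs(theta_deg - config$tilt_center) - config$deadband)
}

# --- rasterization helpers -------------------------------------------------

make_grid_frame <- function(xlim, ylim, zlim, spacing) {
  d <- pmax(1L, as.integer(floor((c(xlim[2], ylim[2], zlim[2]) -
                                    c(xlim[1], ylim[1], zlim[1])) / spacing)) + 1L)
  list(dim = d, origin = c(xlim[1], ylim[1], zlim[1]), spacing = spacing)
}

frame_coords <- function(fr) {
  d <- fr$dim
  x <- fr$origin[1] + (seq_len(d[1]) - 1) * fr$spacing[1]
  y <- fr$origin[2] + (seq_len(d[2]) - 1) * fr$spacing[2]
  z <- fr$origin[3] + (seq_len(d[3]) - 1) * fr$spacing[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

raster_cylinder <- function(fr, co, p0, p1, radius) {
  v <- p1 - p0
  L2 <- sum(v^2)
  dx <- co$X - p0[1]; dy <- co$Y - p0[2]; dz <- co$Z - p0[3]
  t <- (dx * v[1] + dy * v[2] + dz * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (dx - t * v[1])^2 + (dy - t * v[2])^2 + (dz - t * v[3])^2
  array(as.double(d2 <= radius^2), fr$dim)
}

# Index range of voxels whose centre could fall inside [lo, hi] per axis.
frame_subrange <- function(fr, lo, hi) {
  lapply(1:3, function(a) {
    i0 <- max(1L, as.integer(floor((lo[a] - fr$origin[a]) / fr$spacing[a])) + 1L)
    i1 <- min(fr$dim[a], as.integer(ceiling((hi[a] - fr$origin[a]) / fr$spacing[a])) + 1L)
    if (i0 > i1) integer(0) else i0:i1
  })
}

raster_box <- function(fr, co, center, half) {
  out <- array(0, fr$dim)
  sub <- frame_subrange(fr, center - half, center + half)
  if (any(lengths(sub) == 0L)) return(out)
  ax <- lapply(1:3, function(a) fr$origin[a] + (sub[[a]] - 1) * fr$spacing[a])
  inside <- outer(outer(abs(ax[[1]] - center[1]) <= half[1],
                        abs(ax[[2]] - center[2]) <= half[2], "&"),
                  abs(ax[[3]] - center[3]) <= half[3], "&")
  out[sub[[1]], sub[[2]], sub[[3]]] <- as.double(inside)
  out
}

raster_ellipsoid <- function(fr, co, center, semi) {
  out <- array(0, fr$dim)
  sub <- frame_subrange(fr, center - semi, center + semi)
  if (any(lengths(sub) == 0L)) return(out)
  ax <- lapply(1:3, function(a) fr$origin[a] + (sub[[a]] - 1) * fr$spacing[a])
  q <- outer(outer(((ax[[1]] - center[1]) / semi[1])^2,
                   ((ax[[2]] - center[2]) / semi[2])^2, "+"),
             ((ax[[3]] - center[3]) / semi[3])^2, "+")
  out[sub[[1]], sub[[2]], sub[[3]]] <- as.double(q <= 1)
  out
}

# Shift a 3D array by one voxel along an axis, filling with `fill`.
shift_array <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (n <= 1L && abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  isrc <- rep(list(quote(expr = )), 3); isrc[[axis]] <- src
  idst <- rep(list(quote(expr = )), 3); idst[[axis]] <- dst
  slice <- do.call(`[`, c(list(a), isrc, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idst, list(slice)))
  out
}

# 6-connected binary dilation/erosion by one voxel (background padding).
morph_one <- function(a, op) {
  acc <- a > 0
  nb <- list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))
  for (s in nb) {
    sh <- shift_array(a, s[1], s[2], fill = if (op == "dilate") 0 else 0) > 0
    acc <- if (op == "dilate") acc | sh else acc & sh
  }
  array(as.double(acc), dim(a))
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# --- cohort generation -----------------------------------------------------

#' Simulate a phantom cohort
#'
#' Generates, for each patient: a cord cylinder tilted by a truncated-normal
#' tilt angle, four vertebral boxes (C1-C4) stacked along the cord axis,
#' gold organ masks placed relative to the cord's superior end, per-vendor
#' test masks (gold mask translated by a random vector whose per-axis SD
#' follows [perturbation_sd()] — flat `sigma0` for the control organ — then
#' dilated or eroded by a random radius of 0 or 1 voxels), and a Gaussian
#' dose grid with a per-patient jittered target centre. Masks for one
#' patient live on purpose-sized grids: one spine grid shared by cord and
#' vertebrae, one grid per organ shared by its gold and vendor masks, and a
#' coarser dose grid; no downstream stage assumes a single common grid.
#'
#' The same `(config, seed)` always reproduces the cohort bit-for-bit.
#'
#' @param config A [generator_config()].
#' @param dir Optional directory; when given, all volumes are written as
#'   NIfTI via [write_volume()] together with `manifest.json` and
#'   `truth.json`, and the returned cohort carries the manifest.
#' @return An object of class `phantom_cohort`: `config`, `organs`,
#'   `control_organ`, `vendors`, and `patients` (each with `id`,
#'   `tilt_true`, `spine` masks, `gold` organ masks, `auto[[vendor]]` organ
#'   masks, `dose`, `perturb`, `dose_center`).
#' @export
simulate_cohort <- function(config = generator_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  organs <- c("parotid_l", "parotid_r", "brainstem")
  vendors <- paste0("vendor", seq_len(cfg$n_vendors))

  # spine grid sized for the worst-case tilt range
  thr <- cfg$tilt_range * pi / 180
  L <- cfg$cord_length
  ymin <- -L * sin(max(thr)) - cfg$vertebra_depth / 2 - 4
  ymax <- -L * sin(min(thr)) + cfg$vertebra_depth / 2 + 4
  xhalf <- max(cfg$cord_radius, cfg$vertebra_width / 2) + 4
  spine_fr <- make_grid_frame(c(-xhalf, xhalf), c(ymin, ymax),
                              c(-cfg$vertebra_height / 2 - 4,
                                L + cfg$vertebra_height / 2 + 4),
                              cfg$spacing)
  spine_co <- frame_coords(spine_fr)

  # dose grid sized so every organ-grid voxel centre is inside it
  organ_semi <- list(parotid_l = cfg$parotid_semiaxes,
                     parotid_r = cfg$parotid_semiaxes,
                     brainstem = cfg$control_semiaxes)
  organ_center <- function(organ, theta) {
    dvec <- c(0, -sin(theta * pi / 180), cos(theta * pi / 180))
    p1 <- L * dvec
    switch(organ,
           parotid_l = p1 + c(cfg$parotid_offset, 0, -cfg$parotid_inferior),
           parotid_r = p1 + c(-cfg$parotid_offset, 0, -cfg$parotid_inferior),
           brainstem = p1 + c(0, 0, cfg$control_superior))
  }
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  for (th in seq(cfg$tilt_range[1], cfg$tilt_range[2], length.out = 41)) {
    for (o in organs) {
      ctr <- organ_center(o, th)
      ext <- organ_semi[[o]] + cfg$organ_margin
      lo <- pmin(lo, ctr - ext); hi <- pmax(hi, ctr + ext)
    }
  }
  dose_fr <- make_grid_frame(c(lo[1] - 5, hi[1] + 5), c(lo[2] - 5, hi[2] + 5),
                             c(min(lo[3] - 5, -5), hi[3] + 5),
                             cfg$dose_spacing)
  dose_co <- frame_coords(dose_fr)

  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    id <- sprintf("P%03d", i)
    theta <- rtruncnorm1(cfg$tilt_mean, cfg$tilt_sd,
                         cfg$tilt_range[1], cfg$tilt_range[2])
    dvec <- c(0, -sin(theta * pi / 180), cos(theta * pi / 180))
    p0 <- c(0, 0, 0); p1 <- L * dvec

    cord <- new_binary_mask(raster_cylinder(spine_fr, spine_co, p0, p1,
                                            cfg$cord_radius),
                            spine_fr$spacing, spine_fr$origin, "cord", "gold")
    spine <- list(cord = cord)
    for (vi in 1:4) {
      ctr <- p0 + ((vi - 0.5) / 4 * L) * dvec
      half <- c(cfg$vertebra_width, cfg$vertebra_depth, cfg$vertebra_height) / 2
      spine[[paste0("C", vi)]] <-
        new_binary_mask(raster_box(spine_fr, NULL, ctr, half),
                        spine_fr$spacing, spine_fr$origin,
                        paste0("C", vi), "gold")
    }

    dose_center <- p0 + (cfg$dose_center_frac * L) * dvec +
      stats::rnorm(3, 0, cfg$dose_jitter)
    dd2 <- (dose_co$X - dose_center[1])^2 + (dose_co$Y - dose_center[2])^2 +
      (dose_co$Z - dose_center[3])^2
    dose <- dose_grid(volume_grid(cfg$dose_max * exp(-dd2 / (2 * cfg$dose_sigma^2)),
                                  dose_fr$spacing, dose_fr$origin))

    gold <- list(); frames <- list()
    for (o in organs) {
      ctr <- organ_center(o, theta)
      ext <- organ_semi[[o]] + cfg$organ_margin
      fr <- make_grid_frame(c(ctr[1] - ext[1], ctr[1] + ext[1]),
                            c(ctr[2] - ext[2], ctr[2] + ext[2]),
                            c(ctr[3] - ext[3], ctr[3] + ext[3]),
                            cfg$spacing)
      frames[[o]] <- fr
      gold[[o]] <- new_binary_mask(raster_ellipsoid(fr, NULL, ctr,
                                                    organ_semi[[o]]),
                                   fr$spacing, fr$origin, o, "gold")
    }

    auto <- list(); perturb <- list()
    for (v in vendors) {
      auto[[v]] <- list(); perturb[[v]] <- list()
      for (o in organs) {
        sd_o <- if (o == "brainstem") cfg$sigma0 else perturbation_sd(theta, cfg)
        shift <- stats::rnorm(3, 0, sd_o)
        radius <- sample(0:1, 1)
        op <- sample(c("dilate", "erode"), 1)
        ctr <- organ_center(o, theta) + shift
        fr <- frames[[o]]
        vals <- raster_ellipsoid(fr, NULL, ctr, organ_semi[[o]])
        if (radius == 1) {
          sub <- frame_subrange(fr, ctr - organ_semi[[o]] - 2 * fr$spacing,
                                ctr + organ_semi[[o]] + 2 * fr$spacing)
          vals[sub[[1]], sub[[2]], sub[[3]]] <-
            morph_one(vals[sub[[1]], sub[[2]], sub[[3]], drop = FALSE], op)
        }
        auto[[v]][[o]] <- new_binary_mask(vals, fr$spacing, fr$origin, o, v)
        perturb[[v]][[o]] <- list(translation = shift, radius = radius,
                                  op = if (radius == 1) op else "none")
      }
    }

    patients[[i]] <- list(id = id, tilt_true = theta, spine = spine,
                          gold = gold, auto = auto, dose = dose,
                          perturb = perturb, dose_center = dose_center)
  }
  names(patients) <- vapply(patients, `[[`, character(1), "id")
  cohort <- structure(list(config = cfg, organs = organs,
                           control_organ = "brainstem", vendors = vendors,
                           patients = patients),
                      class = "phantom_cohort")
  if (!is.null(dir)) cohort$manifest <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, %d vendor(s), organs: %s\n",
              length(x$patients), length(x$vendors),
              paste(x$organs, collapse = ", ")))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes every mask and dose grid as NIfTI under `dir/<patient id>/`,
#' plus `manifest.json` (paths relative to `dir`) and `truth.json` holding
#' the generator ground truth (true tilt, applied perturbations, dose
#' centre) — enough to recompute every expected downstream value.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return The `cohort_manifest`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list(); truth <- list()
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    structures <- list()
    for (s in names(p$spine)) {
      rel <- file.path(p$id, paste0(s, "_gold.nii.gz"))
      write_volume(p$spine[[s]], file.path(dir, rel), datatype = "uint8")
      structures[[s]] <- list(gold = rel)
    }
    for (o in names(p$gold)) {
      rel <- file.path(p$id, paste0(o, "_gold.nii.gz"))
      write_volume(p$gold[[o]], file.path(dir, rel), datatype = "uint8")
      structures[[o]] <- list(gold = rel)
      for (v in names(p$auto)) {
        relv <- file.path(p$id, paste0(o, "_", v, ".nii.gz"))
        write_volume(p$auto[[v]][[o]], file.path(dir, relv), datatype = "uint8")
        structures[[o]][[v]] <- relv
      }
    }
    dose_rel <- file.path(p$id, "dose.nii.gz")
    write_volume(p$dose, file.path(dir, dose_rel))
    entries[[p$id]] <- list(id = p$id, structures = structures,
                            dose = dose_rel, tilt = NULL)
    truth[[p$id]] <- list(tilt_deg = p$tilt_true,
                          dose_center = p$dose_center,
                          perturbations = p$perturb)
  }
  manifest <- structure(list(patients = entries), class = "cohort_manifest")
  write_manifest(manifest, file.path(dir, "manifest.json"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # re-load so paths are absolute and validated
  invisible(load_manifest(file.path(dir, "manifest.json")))
}

#' Load a cohort from a manifest into memory
#'
#' Inverse of [write_cohort()]: reads every referenced volume and assembles
#' the same in-memory layout [simulate_cohort()] produces (without
#' generator ground truth). Spine structures are `cord` and `C1`-`C4` from
#' the gold source; any other structure is treated as an organ, with its
#' non-gold sources as vendors.
#'
#' @param manifest A `cohort_manifest` or path to one.
#' @return A `phantom_cohort`-shaped object of class `cohort`.
#' @export
read_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  spine_names <- c("cord", "C1", "C2", "C3", "C4")
  patients <- list(); all_organs <- character(0); all_vendors <- character(0)
  for (p in manifest$patients) {
    spine <- list(); gold <- list(); auto <- list()
    for (s in names(p$structures)) {
      sources <- p$structures[[s]]
      if (s %in% spine_names) {
        if (!is.null(sources$gold))
          spine[[s]] <- binary_mask(read_volume(sources$gold),
                                    label = s, source = "gold")
      } else {
        all_organs <- union(all_organs, s)
        for (src in names(sources)) {
          m <- binary_mask(read_volume(sources[[src]]), label = s, source = src)
          if (src == "gold") gold[[s]] <- m
          else {
            all_vendors <- union(all_vendors, src)
            if (is.null(auto[[src]])) auto[[src]] <- list()
            auto[[src]][[s]] <- m
          }
        }
      }
    }
    dose <- if (!is.null(p$dose)) dose_grid(read_volume(p$dose)) else NULL
    patients[[p$id]] <- list(id = p$id, tilt_true = p$tilt %||% NA_real_,
                             spine = spine, gold = gold, auto = auto,
                             dose = dose)
  }
  structure(list(organs = all_organs, vendors = all_vendors,
                 control_organ = NA_character_, patients = patients),
            class = c("cohort", "phantom_cohort"))
}
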