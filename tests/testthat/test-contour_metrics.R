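test_that("surface extraction matches face-enumeration oracles", {
  # single voxel, unit spacing: 6 faces, total area 6
  m1 <- cube_mask(c(3, 3, 3), c(2, 2, 2), c(2, 2, 2))
  s1 <- extract_surface(m1)
  expect_equal(nrow(s1$points), 6L)
  expect_equal(s1$total_area, 6)

  # single voxel at CT spacing: 2 axial + 4 sagittal/coronal faces
  m2 <- cube_mask(c(3, 3, 3), c(2, 2, 2), c(2, 2, 2),
                  spacing = c(1.27, 1.27, 2))
  expect_equal(extract_surface(m2)$total_area,
               2 * 1.27 * 1.27 + 4 * 1.27 * 2)

  # 2x1x1 block: 10 faces, area 10
  m3 <- cube_mask(c(4, 3, 3), c(2, 2, 2), c(3, 2, 2))
  expect_equal(nrow(extract_surface(m3)$points), 10L)
  expect_equal(extract_surface(m3)$total_area, 10)

  # mask touching the array boundary still emits the boundary faces
  m4 <- cube_mask(c(2, 2, 2), c(1, 1, 1), c(2, 2, 2))
  expect_equal(extract_surface(m4)$total_area, 6 * 4)

  # random masks agree with the brute-force enumerator
  set.seed(4)
  for (i in 1:5) {
    m <- rand_mask(c(6, 5, 4), spacing = c(1.27, 1.27, 2), p = 0.35)
    s <- extract_surface(m)
    o <- oracle_faces(m)
    expect_equal(s$total_area, o$total_area, tolerance = 1e-12)
    key <- function(p, a) paste(round(p[, 1], 6), round(p[, 2], 6),
                                round(p[, 3], 6), round(a, 9))
    expect_setequal(key(s$points, s$areas), key(o$points, o$areas))
  }
})

test_that("Dice matches voxel counting on analytic and random cases", {
  a <- cube_mask(c(12, 12, 12), c(1, 1, 1), c(10, 10, 10))
  b <- cube_mask(c(12, 12, 12), c(1, 1, 6), c(10, 10, 12))
  # overlap is a 10x10x5 block against two 10x10x10 and 10x10x7 cubes
  inter <- sum(a$values * b$values)
  expect_equal(dice(a, b), 2 * inter / (sum(a$values) + sum(b$values)))

  # identical / disjoint
  expect_equal(dice(a, a), 1)
  d2 <- cube_mask(c(12, 12, 12), c(11, 11, 11), c(12, 12, 12))
  expect_equal(dice(a, d2), 0)

  empty <- binary_mask(array(0, c(12, 12, 12)))
  expect_error(dice(empty, empty), "empty")
  expect_error(dice(a, cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))),
               "mismatch")

  # textbook case: two 10-cubes overlapping in a 10x10x5 block -> 0.5
  g <- c(12, 12, 18)
  c1 <- cube_mask(g, c(1, 1, 1), c(10, 10, 10))
  c2 <- cube_mask(g, c(1, 1, 6), c(10, 10, 15))
  expect_equal(dice(c1, c2), 0.5)
})

test_that("surface metrics match the all-pairs oracle on random mask pairs", {
  set.seed(2)
  n_pairs <- 100
  for (i in seq_len(n_pairs)) {
    sp <- list(c(1, 1, 1), c(1.27, 1.27, 2), c(0.5, 2, 1))[[1 + i %% 3]]
    dims <- sample(4:12, 3, replace = TRUE)
    a <- rand_mask(dims, spacing = sp, p = stats::runif(1, 0.2, 0.6))
    b <- rand_mask(dims, spacing = sp, p = stats::runif(1, 0.2, 0.6))
    sd <- impl_surface_distances(a, b)
    oab <- oracle_nn_dist(sd$sa$points, sd$sb$points)
    oba <- oracle_nn_dist(sd$sb$points, sd$sa$points)
    tau <- sample(c(1, 2, 3.5), 1)
    # membership at tau identical, distances to 1e-9
    expect_identical(sd$d_ab <= tau, oab <= tau)
    expect_identical(sd$d_ba <= tau, oba <= tau)
    expect_lt(max(abs(sd$d_ab - oab)), 1e-9)
    expect_lt(max(abs(sd$d_ba - oba)), 1e-9)

    # aggregated metrics against oracle formulas
    osdsc <- (sum(sd$sa$areas[oab <= tau]) + sum(sd$sb$areas[oba <= tau])) /
      (sd$sa$total_area + sd$sb$total_area)
    omda <- (sum(sd$sa$areas * oab) + sum(sd$sb$areas * oba)) /
      (sd$sa$total_area + sd$sb$total_area)
    expect_equal(surface_dice(a, b, tau), osdsc, tolerance = 1e-12)
    expect_equal(mean_distance_to_agreement(a, b), omda, tolerance = 1e-9)

    # DSC against voxel-count arithmetic
    expect_identical(dice(a, b),
                     2 * sum(a$values == 1 & b$values == 1) /
                       (sum(a$values) + sum(b$values)))
  }
})

test_that("identity, symmetry, tolerance monotonicity, and scaling laws hold", {
  set.seed(6)
  a <- rand_mask(c(9, 8, 10), spacing = c(1.27, 1.27, 2), p = 0.4)
  b <- rand_mask(c(9, 8, 10), spacing = c(1.27, 1.27, 2), p = 0.4)

  expect_equal(dice(a, a), 1)
  expect_equal(surface_dice(a, a, 2), 1)
  expect_equal(mean_distance_to_agreement(a, a), 0)

  expect_equal(dice(a, b), dice(b, a))
  expect_equal(surface_dice(a, b, 2), surface_dice(b, a, 2))
  expect_equal(mean_distance_to_agreement(a, b),
               mean_distance_to_agreement(b, a), tolerance = 1e-12)

  # sDSC non-increasing as tau decreases; -> 1 for huge tau
  taus <- c(0.25, 0.5, 1, 2, 4, 8, 1e6)
  vals <- vapply(taus, function(t) surface_dice(a, b, t), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)

  # two well-separated cubes at tau = 2: nothing within tolerance
  g <- c(20, 5, 5)
  c1 <- cube_mask(g, c(1, 1, 1), c(5, 5, 5))
  c2 <- cube_mask(g, c(16, 1, 1), c(20, 5, 5))
  expect_equal(surface_dice(c1, c2, 2), 0)

  # spacing scaling: s-scaled grids scale MDA by s, keep DSC, match sDSC
  # at s-scaled tau; the sDSC check uses a power-of-two factor so distances
  # exactly at the tolerance stay on the same side after scaling
  for (s in c(2, 2.5)) {
    as <- binary_mask(a$values, a$spacing * s, a$origin * s)
    bs <- binary_mask(b$values, b$spacing * s, b$origin * s)
    expect_equal(dice(as, bs), dice(a, b))
    expect_equal(mean_distance_to_agreement(as, bs),
                 s * mean_distance_to_agreement(a, b), tolerance = 1e-9)
    if (s == 2)
      expect_equal(surface_dice(as, bs, 2 * s), surface_dice(a, b, 2),
                   tolerance = 1e-12)
  }

  # translation equivariance: same whole-voxel shift of both masks, with
  # enough padding that nothing is clipped at the array edge
  pad_embed <- function(m, k = 0) {
    d <- dim(m$values)
    v <- array(0, d + 4)
    v[(1 + k):(d[1] + k), (1 + k):(d[2] + k), (1 + k):(d[3] + k)] <-
      m$values
    binary_mask(v, m$spacing, m$origin)
  }
  a0 <- pad_embed(a, 0); b0 <- pad_embed(b, 0)
  at <- pad_embed(a, 2); bt <- pad_embed(b, 2)
  expect_equal(dice(at, bt), dice(a0, b0))
  expect_equal(surface_dice(at, bt, 2), surface_dice(a0, b0, 2))
  expect_equal(mean_distance_to_agreement(at, bt),
               mean_distance_to_agreement(a0, b0), tolerance = 1e-12)
})

test_that("score_pair bundles metrics and degrades gracefully on empty masks", {
  a <- cube_mask(c(8, 8, 8), c(2, 2, 2), c(6, 6, 6))
  rec <- score_pair(a, a, tau_mm = 2, patient = "P1")
  expect_equal(rec$dsc, 1)
  expect_equal(rec$sdsc, 1)
  expect_equal(rec$mda_mm, 0)
  expect_identical(rec$status, "ok")

  empty <- binary_mask(array(0, c(8, 8, 8)), label = "cube", source = "v1")
  rec2 <- score_pair(a, empty, tau_mm = 2, patient = "P1")
  expect_identical(rec2$status, "missing_empty_mask")
  expect_true(is.na(rec2$dsc) && is.na(rec2$sdsc) && is.na(rec2$mda_mm))

  # phantom calibration: near-median tilt keeps parotid DSC high
  co <- simulate_cohort(generator_config(n_patients = 6, n_vendors = 1,
                                         seed = 13))
  tt <- vapply(co$patients, `[[`, numeric(1), "tilt_true")
  cfg <- co$config
  near <- which.min(abs(tt - cfg$tilt_center))
  expect_lte(abs(tt[near] - cfg$tilt_center), cfg$deadband)
  p <- co$patients[[near]]
  rec3 <- score_pair(p$gold$parotid_l, p$auto$vendor1$parotid_l, 2)
  expect_gt(rec3$dsc, 0.8)
})
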