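test_that("PCA tilt matches analytic line directions and sign convention", {
  # points on the longitudinal axis -> zero tilt
  z <- seq(0, 58, by = 2)
  pts <- cbind(x = 0 * z, y = 0 * z, z = z)
  r0 <- pca_tilt_angle(pts)
  expect_equal(r0$tilt_deg, 0, tolerance = 1e-9)
  expect_gte(r0$principal_vector[3], 0)

  # direction (0, -1, 1)/sqrt(2): anterior lean of the superior cord = +45
  t <- seq(0, 40, by = 1)
  pts45 <- cbind(0 * t, -t / sqrt(2), t / sqrt(2))
  expect_equal(pca_tilt_angle(pts45)$tilt_deg, 45, tolerance = 1e-9)

  # posterior lean (extension) is negative
  ptsm <- cbind(0 * t, t / sqrt(2), t / sqrt(2))
  expect_equal(pca_tilt_angle(ptsm)$tilt_deg, -45, tolerance = 1e-9)

  # permutation invariance
  set.seed(1)
  perm <- sample(nrow(pts45))
  expect_equal(pca_tilt_angle(pts45[perm, ])$tilt_deg,
               pca_tilt_angle(pts45)$tilt_deg)

  expect_error(pca_tilt_angle(pts45[1:5, ]), "at least")
  expect_error(pca_tilt_angle(matrix(1, 30, 3)), "identical")
})

test_that("PCA recovers a sampled cylinder axis at 20 degrees", {
  set.seed(7)
  n <- 5000
  theta <- 20 * pi / 180
  d <- c(0, -sin(theta), cos(theta))
  t <- stats::runif(n, 0, 60)
  phi <- stats::runif(n, 0, 2 * pi)
  rr <- 5 * sqrt(stats::runif(n))
  # orthonormal frame around the axis
  u <- c(1, 0, 0)
  w <- c(0, cos(theta), sin(theta))
  pts <- cbind(t * d[1] + rr * cos(phi) * u[1] + rr * sin(phi) * w[1],
               t * d[2] + rr * cos(phi) * u[2] + rr * sin(phi) * w[2],
               t * d[3] + rr * cos(phi) * u[3] + rr * sin(phi) * w[3])
  expect_equal(pca_tilt_angle(pts)$tilt_deg, 20, tolerance = 0.5)
})

test_that("mirror, rotation, and subsampling invariances hold on a phantom cord", {
  co <- simulate_cohort(generator_config(n_patients = 2, n_vendors = 1,
                                         seed = 21))
  p <- co$patients[[1]]
  pts <- cord_c1c4_voxels(p$spine$cord, p$spine[paste0("C", 1:4)])
  base <- pca_tilt_angle(pts)$tilt_deg

  # negating y flips flexion to extension exactly
  mir <- pts
  mir[, 2] <- -mir[, 2]
  expect_equal(pca_tilt_angle(mir)$tilt_deg, -base, tolerance = 1e-9)

  # rotating about x by phi (toward flexion) adds phi to the tilt
  for (phi in c(-20, 10, 25)) {
    a <- phi * pi / 180
    rot <- cbind(pts[, 1],
                 cos(a) * pts[, 2] - sin(a) * pts[, 3],
                 sin(a) * pts[, 2] + cos(a) * pts[, 3])
    expect_equal(pca_tilt_angle(rot)$tilt_deg, base + phi, tolerance = 0.1)
  }

  # fixed-stride subsampling barely moves the estimate
  half <- pts[seq(1, nrow(pts), by = 2), ]
  expect_lt(abs(pca_tilt_angle(half)$tilt_deg - base), 0.5)
})

test_that("cord voxel selection matches a brute-force slice filter", {
  # hand-built geometry: cord occupies slices 1-50, vertebra union 21-50
  dims <- c(5, 5, 50)
  cord <- cube_mask(dims, c(3, 3, 1), c(3, 3, 50), label = "cord")
  verts <- lapply(0:3, function(i) {
    cube_mask(dims, c(1, 1, 21 + i * 7), c(2, 2, 27 + i * 7),
              label = paste0("C", i + 1))
  })
  pts <- cord_c1c4_voxels(cord, verts)
  # vertebra union occupies slices 21..48 -> 28 cord voxels retained
  expect_equal(nrow(pts), 28)
  expect_true(all(pts[, "z"] >= 20 & pts[, "z"] <= 47))

  # z-disjoint vertebrae -> explicit no-overlap error
  lowverts <- lapply(1:4, function(i)
    cube_mask(c(5, 5, 50), c(1, 1, i), c(2, 2, i), label = paste0("C", i)))
  cord_hi <- cube_mask(c(5, 5, 50), c(3, 3, 30), c(3, 3, 50), label = "cord")
  expect_error(cord_c1c4_voxels(cord_hi, lowverts), "overlap")

  # grid mismatch is rejected
  other <- cube_mask(c(5, 5, 50), c(1, 1, 21), c(2, 2, 27),
                     spacing = c(2, 2, 2))
  expect_error(cord_c1c4_voxels(cord, list(verts[[1]], verts[[2]],
                                           verts[[3]], other)), "mismatch")

  # phantom patient: voxel count equals an independent slice filter
  co <- simulate_cohort(generator_config(n_patients = 1, n_vendors = 1,
                                         seed = 1))
  p <- co$patients[[1]]
  vert_union <- Reduce(`+`, lapply(p$spine[paste0("C", 1:4)],
                                   function(m) m$values))
  keep_slices <- which(apply(vert_union > 0, 3, any))
  expected <- sum(p$spine$cord$values[, , keep_slices])
  expect_equal(nrow(cord_c1c4_voxels(p$spine$cord,
                                     p$spine[paste0("C", 1:4)])), expected)
})

test_that("centroid-slope angle matches exact lines and the PCA angle on phantoms", {
  # centroids exactly on a 45-degree flexion line (slope dy/dz = -1)
  dims <- c(9, 40, 40)
  verts <- lapply(1:4, function(i) {
    z <- 5 + 7 * i
    y <- 45 - z
    v <- array(0, dims)
    v[4:6, y + (-1:1), z + (-1:1)] <- 1
    binary_mask(v, c(1, 1, 1), origin = c(0, 0, 0), label = paste0("C", i))
  })
  expect_equal(centroid_slope_angle(verts), 45, tolerance = 1e-9)

  expect_error(centroid_slope_angle(lapply(1:4, function(i)
    cube_mask(c(5, 5, 5), c(i, 1, 3), c(i, 2, 3), label = paste0("C", i)))),
    "degenerate")
})

test_that("nearest-rank stratification reproduces the printed conventions", {
  # values 1..100 at 12/88: thresholds 12 and 88, 23 abnormal
  st <- stratify(data.frame(patient = sprintf("P%03d", 1:100),
                            tilt_deg = as.numeric(1:100)))
  expect_equal(st$lower_threshold_deg, 12)
  expect_equal(st$upper_threshold_deg, 88)
  expect_equal(sum(st$labels$label == "abnormal"), 23)
  expect_equal(sum(st$labels$tilt_deg < 12), 11)
  expect_equal(sum(st$labels$tilt_deg > 88), 12)

  # all-equal cohort: thresholds collapse, nobody abnormal
  st0 <- stratify(data.frame(patient = as.character(1:35),
                             tilt_deg = rep(4.2, 35)))
  expect_equal(sum(st0$labels$label == "abnormal"), 0)

  # conservation and order invariance
  set.seed(9)
  tl <- data.frame(patient = as.character(1:35),
                   tilt_deg = stats::rnorm(35, 12, 15))
  st1 <- stratify(tl)
  expect_equal(nrow(st1$labels), 35L)
  expect_setequal(st1$labels$label, c("normal", "abnormal"))
  perm <- sample(35)
  st2 <- stratify(tl[perm, ])
  m <- match(st1$labels$patient, st2$labels$patient)
  expect_identical(st1$labels$label, st2$labels$label[m])

  expect_error(stratify(tl[1:2, ]), "at least 3")
})
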