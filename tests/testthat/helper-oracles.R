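# Independent oracles and fixture builders used across the suite.
# These deliberately use the slowest, most literal formulation of each
# quantity so they stay independent of the package's accelerated paths.

# random non-empty binary mask
rand_mask <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      p = 0.3, label = "blob", source = "test") {
  repeat {
    v <- array(as.double(stats::runif(prod(dims)) < p), dims)
    if (sum(v) > 0) break
  }
  binary_mask(v, spacing, origin, label = label, source = source)
}

# solid cube mask
cube_mask <- function(dims, from, to, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), label = "cube", source = "test") {
  v <- array(0, dims)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1
  binary_mask(v, spacing, origin, label = label, source = source)
}

# brute-force boundary-face enumeration: loop over foreground voxels and
# their six neighbours
oracle_faces <- function(m) {
  v <- m$values
  d <- dim(v)
  sp <- m$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  pts <- NULL
  areas <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] != 1) next
    ctr <- m$origin + (c(i, j, k) - 1) * sp
    for (axis in 1:3) for (sgn in c(-1L, 1L)) {
      nb <- c(i, j, k)
      nb[axis] <- nb[axis] + sgn
      bg <- nb[axis] < 1 || nb[axis] > d[axis] ||
        v[nb[1], nb[2], nb[3]] != 1
      if (bg) {
        p <- ctr
        p[axis] <- p[axis] + sgn * sp[axis] / 2
        pts <- rbind(pts, p)
        areas <- c(areas, face_area[axis])
      }
    }
  }
  list(points = pts, areas = areas, total_area = sum(areas))
}

# all-pairs nearest distances (O(n*m))
oracle_nn_dist <- function(from, to) {
  apply(from, 1, function(p) {
    sqrt(min((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2 + (to[, 3] - p[3])^2))
  })
}

# exact two-tailed rank-sum p by full enumeration of group assignments,
# midranks for ties; p = min(1, 2 * min(P(U <= u), P(U >= u)))
oracle_rank_sum_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# quick access to both directed surface-distance vectors of the package
impl_surface_distances <- function(a, b) tiltQA:::surface_distances(a, b)
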