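# Independent brute-force oracles for the superposition metrics. These share
# no code with the package implementations: rotations are parameterised by
# Euler angles, the optimum is located by a coarse grid search and polished
# with a derivative-free simplex, and TM scoring is re-written inline.

euler_rotation <- function(a, b, c) {
  # intrinsic z-y-z Euler angles, radians
  Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

# RMSD oracle: centroid alignment, then exhaustive coarse Euler grid plus a
# Nelder-Mead polish of the best grid cell. Never touches the SVD route.
oracle_rmsd <- function(fixed, mobile, grid_step = 20) {
  F <- sweep(fixed, 2, colMeans(fixed))
  M <- sweep(mobile, 2, colMeans(mobile))
  rms_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((M %*% t(R) - F)^2)))
  }
  gs <- grid_step * pi / 180
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in seq(0, 2 * pi - gs / 2, by = gs)) {
    for (b in seq(0, pi, by = gs)) {
      for (c in seq(0, 2 * pi - gs / 2, by = gs)) {
        v <- rms_of(c(a, b, c))
        if (v < best) { best <- v; best_ang <- c(a, b, c) }
      }
    }
  }
  op <- stats::optim(best_ang, rms_of, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  min(best, op$value)
}

# TM-score oracle: direct maximization of the inline-scored TM over Euler
# rotation + translation, multi-started from a rotation grid.
oracle_tm <- function(fixed, mobile, d0, grid_step = 45) {
  F <- fixed
  M0 <- sweep(mobile, 2, colMeans(mobile))
  cf <- colMeans(F)
  tm_of <- function(par) {
    R <- euler_rotation(par[1], par[2], par[3])
    moved <- sweep(M0 %*% t(R), 2, cf + par[4:6], `+`)
    mean(1 / (1 + rowSums((moved - F)^2) / d0^2))
  }
  gs <- grid_step * pi / 180
  best <- -Inf
  starts <- list()
  for (a in seq(0, 2 * pi - gs / 2, by = gs))
    for (b in seq(0, pi, by = gs))
      for (c in seq(0, 2 * pi - gs / 2, by = gs))
        starts[[length(starts) + 1]] <- c(a, b, c, 0, 0, 0)
  for (st in starts) {
    op <- stats::optim(st, function(p) -tm_of(p), method = "Nelder-Mead",
                       control = list(maxit = 1500, reltol = 1e-12))
    if (-op$value > best) best <- -op$value
  }
  best
}

random_rigid_transform <- function(x) {
  ang <- stats::runif(3, 0, 2 * pi)
  R <- euler_rotation(ang[1], ang[2], ang[3])
  t <- stats::runif(3, -10, 10)
  sweep(x %*% t(R), 2, t, `+`)
}
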