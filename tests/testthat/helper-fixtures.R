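# shared fixtures and small numerical utilities for the suite

rand_scalar <- function(d, seed) {
  set.seed(seed)
  array(rnorm(prod(d)), dim = d)
}

rand_vec <- function(d, seed) {
  set.seed(seed)
  array(rnorm(prod(d) * 3), dim = c(d, 3))
}

rand_tens <- function(d, seed) {
  set.seed(seed)
  array(rnorm(prod(d) * 6), dim = c(d, 6))
}

# inner product on tensor fields: off-diagonal slots counted twice
dot_tens <- function(a, b) {
  n <- prod(dim(a)[1:3])
  av <- as.double(a); bv <- as.double(b)
  sum(av[1:(3 * n)] * bv[1:(3 * n)]) +
    2 * sum(av[(3 * n + 1):(6 * n)] * bv[(3 * n + 1):(6 * n)])
}

rel_residual <- function(lhs, rhs, x, y) {
  abs(lhs - rhs) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

# centered disk phantom of radius r (in physical units) on the pixel grid
disk_phantom <- function(Nx, Nz = 1L, r = 0.3) {
  xc <- -sqrt(2) / 2 + (seq_len(Nx) - 0.5) * sqrt(2) / Nx
  sl <- outer(xc^2, xc^2, `+`) <= r^2
  array(rep(as.double(sl), Nz), dim = c(Nx, Nx, Nz))
}

# leapfrog finite-difference time-domain solver for the 2D wave equation on a
# periodic (s, z) grid with zero initial velocity (fourth-order spatial
# stencil); independent oracle for the spectral propagator
fdtd_wave <- function(u0, ds, dz, cs, tim, cfl = 0.15) {
  roll <- function(m, k, axis) {
    n <- dim(m)[axis]
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  lap1 <- function(m, axis, dd)
    (-roll(m, 2, axis) + 16 * roll(m, 1, axis) - 30 * m +
       16 * roll(m, -1, axis) - roll(m, -2, axis)) / (12 * dd^2)
  lap <- function(m) lap1(m, 1, ds) + lap1(m, 2, dz)
  dt <- cfl * min(ds, dz) / (cs * sqrt(2))
  n_steps <- ceiling(tim / dt)
  dt <- tim / n_steps
  um <- u0
  u <- u0 + (cs * dt)^2 / 2 * lap(u0)
  for (s in seq_len(n_steps - 1)) {
    up <- 2 * u - um + (cs * dt)^2 * lap(u)
    um <- u
    u <- up
  }
  u
}
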