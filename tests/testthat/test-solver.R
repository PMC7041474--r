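test_that("combined operator and adjoint are consistent", {
  geo <- pat_geometry(Nx = 16, Nz = 2, Nphi = 8)
  d <- c(16L, 16L, 2L)
  z <- apply_A(array(0, d), array(0, c(d, 3)), geo)
  expect_equal(sum(abs(z$g)) + sum(abs(z$v)) + sum(abs(z$w)), 0)
  za <- apply_A_adjoint(array(0, c(geo$Ns, 8, 2)), array(0, c(d, 3)),
                        array(0, c(d, 6)), geo)
  expect_equal(sum(abs(za$p)) + sum(abs(za$q)), 0)
  # inner-product adjointness with the tensor-weighted pairing
  p <- rand_scalar(d, 81); q <- rand_vec(d, 82)
  g <- rand_scalar(c(geo$Ns, 8L, 2L), 83); v <- rand_vec(d, 84); w <- rand_tens(d, 85)
  Ax <- apply_A(p, q, geo)
  Aty <- apply_A_adjoint(g, v, w, geo)
  lhs <- sum(Ax$g * g) + sum(Ax$v * v) + dot_tens(Ax$w, w)
  rhs <- sum(p * Aty$p) + sum(q * Aty$q)
  nx <- sqrt(sum(p^2) + sum(q^2)); ny <- sqrt(sum(g^2) + sum(v^2) + sum(w^2))
  expect_lt(abs(lhs - rhs) / (nx * ny), 1e-10)
  # linearity of the adjoint
  g2 <- rand_scalar(c(geo$Ns, 8L, 2L), 86)
  s1 <- apply_A_adjoint(g + 2 * g2, v, w, geo)
  s2 <- apply_A_adjoint(g, v, w, geo)
  s3 <- apply_A_adjoint(g2, 0 * v, 0 * w, geo)
  expect_equal(s1$p, s2$p + 2 * s3$p)
})

test_that("combined operator matches a dense-matrix transpose on a small grid", {
  geo <- pat_geometry(Nx = 6, Nz = 1, Nphi = 4, Ns = 12)
  d <- c(6L, 6L, 1L)
  n <- prod(d)
  sc6 <- rep(rep(c(1, sqrt(2)), each = 3), each = n)
  fwd <- function(x) {
    p <- array(x[1:n], d); q <- array(x[n + 1:(3 * n)], c(d, 3))
    out <- apply_A(p, q, geo)
    c(as.double(out$g), as.double(out$v), as.double(out$w) * sc6)
  }
  adj <- function(y) {
    g <- array(y[1:48], c(12, 4, 1))
    v <- array(y[48 + 1:(3 * n)], c(d, 3))
    w <- array(y[48 + 3 * n + 1:(6 * n)] / sc6, c(d, 6))
    out <- apply_A_adjoint(g, v, w, geo)
    c(as.double(out$p), as.double(out$q))
  }
  Amat <- dense_from_op(fwd, 4L * n)
  Atmat <- dense_from_op(adj, 48L + 9L * n)
  expect_equal(Atmat, t(Amat), tolerance = 1e-12)
})

test_that("combined operator norm stays below the printed bound", {
  geo <- pat_geometry(Nx = 32, Nz = 1, Nphi = 12)
  f0 <- array(0, c(geo$Ns, 12, 1))
  np <- normalize_problem(geo, f0, n_iter = 200, seed = 1)
  A <- patgv:::tgv_operator_map(np$op, 32, 32, 1)
  expect_lt(power_method_norm(A, 300, seed = 1)^2, 12)
})

test_that("dual proximal maps match their definitions", {
  g <- rand_scalar(c(8L, 4L, 1L), 91)
  f <- rand_scalar(c(8L, 4L, 1L), 92)
  sigma <- 0.7; mu <- 3
  expect_equal(prox_discrepancy(sigma * f, f, sigma, mu),
               array(0, dim = dim(f)))
  expect_equal(prox_discrepancy(array(2, c(1, 1, 1)), array(0, c(1, 1, 1)), 1, 1),
               array(1, c(1, 1, 1)))
  # scalar oracle: argmin of |xi - g|^2 / 2 + sigma G*(xi), with
  # G*(xi) = xi^2 / (2 mu) + xi f, evaluated by numerical minimization
  g0 <- 1.3; f0 <- -0.4
  orc <- optimize(function(xi) (xi - g0)^2 / 2 + sigma * (xi^2 / (2 * mu) + xi * f0),
                  c(-10, 10), tol = 1e-12)$minimum
  expect_equal(prox_discrepancy(array(g0, c(1, 1, 1)), array(f0, c(1, 1, 1)),
                                sigma, mu)[1],
               orc, tolerance = 1e-8)
  # sigma -> 0 limit is the identity
  expect_equal(prox_discrepancy(g, f, 1e-12, mu), g, tolerance = 1e-10)
})

test_that("ball projections clip norms pointwise and are idempotent", {
  d <- c(5L, 5L, 2L)
  v <- 3 * rand_vec(d, 93)
  pv <- project_l2ball_vec(v, 1)
  nrm <- sqrt(apply(pv^2, 1:3, sum))
  expect_lt(max(nrm), 1 + 1e-12)
  inside <- project_l2ball_vec(0.1 * v / max(abs(v)), 1)
  expect_equal(inside, 0.1 * v / max(abs(v)))
  expect_equal(project_l2ball_vec(pv, 1), pv)
  v1 <- array(0, c(1, 1, 1, 3)); v1[1, 1, 1, 1] <- 2
  expect_equal(project_l2ball_vec(v1, 1)[1, 1, 1, ], c(1, 0, 0))
  # tensor projection in the Frobenius norm with doubled off-diagonals
  alpha0 <- 2.5
  w <- 4 * rand_tens(d, 94)
  pw <- project_l2ball_tens(w, alpha0)
  fro <- sqrt(pw[, , , 1]^2 + pw[, , , 2]^2 + pw[, , , 3]^2 +
                2 * (pw[, , , 4]^2 + pw[, , , 5]^2 + pw[, , , 6]^2))
  expect_lt(max(fro), alpha0 + 1e-12)
  w1 <- array(0, c(1, 1, 1, 6)); w1[1, 1, 1, 1] <- 2 * alpha0
  expect_equal(project_l2ball_tens(w1, alpha0)[1, 1, 1, ], c(alpha0, 0, 0, 0, 0, 0))
  expect_equal(project_l2ball_tens(0 * w, alpha0), 0 * w)
})

test_that("tv_value follows the forward-difference l1 definition", {
  expect_equal(tv_value(array(2.3, c(5, 5, 3))), 0)
  p <- rand_scalar(c(6L, 6L, 2L), 95)
  expect_equal(tv_value(-2.5 * p), 2.5 * tv_value(p))
  # 2-voxel 1D image [0, 1]: single forward difference of 1
  expect_equal(tv_value(array(c(0, 1), c(2, 1, 1))), 1)
})

test_that("tgv_value vanishes on constants and is dominated by alpha1 * TV", {
  expect_equal(tgv_value(array(1.7, c(6, 6, 2)), inner_iters = 50), 0)
  for (s in 1:3) {
    p <- rand_scalar(c(6L, 6L, 2L), 100 + s)
    expect_lte(tgv_value(p, alpha0 = 2.5, alpha1 = 1, inner_iters = 2000),
               tv_value(p) + 1e-8)
  }
})

test_that("tgv_value of an affine volume matches the independent minimum", {
  # with the trailing-zero gradient closure the discrete TGV of an affine
  # volume is a small boundary term, not exactly zero; both routes agree
  xc <- 1:8
  aff <- array(outer(xc, xc, function(a, b) 0.3 * a + 0.1 * b), c(8, 8, 1))
  v_pd <- tgv_value(aff, 2.5, 1, inner_iters = 10000)
  v_orc <- oracle_tgv_value(aff, 2.5, 1, n_iter = 20000)
  expect_equal(v_pd, v_orc, tolerance = 1e-6)
  expect_lt(v_pd, 0.25 * tv_value(aff))   # far below the TV bound
})

test_that("reconstruction from zero data is identically zero", {
  geo <- pat_geometry(Nx = 12, Nz = 1, Nphi = 6)
  f0 <- array(0, c(geo$Ns, 6, 1))
  fit <- pat_reconstruct(f0, geo, method = "tgv", mu = 1, iters = 50)
  expect_equal(fit$volume, array(0, c(12, 12, 1)))
  fit_tv <- pat_reconstruct(f0, geo, method = "tv", mu = 1, iters = 50)
  expect_equal(fit_tv$volume, array(0, c(12, 12, 1)))
})

test_that("step sizes violating the stability bound are rejected", {
  geo <- pat_geometry(Nx = 8, Nz = 1, Nphi = 4)
  f <- array(0, c(16, 4, 1))
  expect_error(pat_reconstruct(f, geo, mu = 1, iters = 10,
                               sigma = 0.3, tau = 0.3), "sigma")
  expect_error(pat_reconstruct(f, geo, mu = -1, iters = 10), "positive")
  f[1] <- NaN
  expect_error(pat_reconstruct(f, geo, mu = 1, iters = 10), "finite")
})

test_that("iterates remain bounded at the default step sizes on 3D grids", {
  geo <- pat_geometry(Nx = 12, Nz = 4, Nphi = 6)
  set.seed(7)
  f <- array(rnorm(geo$Ns * 6 * 4), c(geo$Ns, 6, 4))
  fit <- pat_reconstruct(f, geo, method = "tgv", mu = 1, iters = 2500,
                         record_every = 500)
  expect_lt(max(abs(fit$volume)), 10)
  expect_true(all(is.finite(fit$diagnostics$objective)))
})

test_that("primal-dual TGV reconstruction matches the convex-program oracle", {
  geo <- pat_geometry(Nx = 8, Nz = 1, Nphi = 6, Ns = 16)
  set.seed(3)
  p_true <- array(0, c(8, 8, 1)); p_true[3:6, 3:6, 1] <- 1; p_true[5, 5, 1] <- 1.5
  f <- radon_forward(p_true, geo) + 0.01 * array(rnorm(16 * 6), c(16, 6, 1))
  mu <- 10
  fit <- pat_reconstruct(f, geo, method = "tgv", mu = mu, iters = 20000)
  orc <- oracle_tgv_recon(f / fit$scale, geo, mu, 1, 2.5, scale = fit$scale,
                          n_iter = 20000)
  expect_lt(max(abs(fit$volume - orc$p)), 1e-3)
  # objective value at the solver's solution matches the oracle optimum
  o_orc <- tgv_objective(orc$p, orc$q, f / fit$scale, geo, mu, 1, 2.5, fit$scale)
  expect_true(is.finite(o_orc))
})

test_that("primal-dual TV reconstruction matches the convex-program oracle", {
  geo <- pat_geometry(Nx = 8, Nz = 1, Nphi = 6, Ns = 16)
  set.seed(3)
  p_true <- array(0, c(8, 8, 1)); p_true[3:6, 3:6, 1] <- 1
  f <- radon_forward(p_true, geo) + 0.01 * array(rnorm(16 * 6), c(16, 6, 1))
  mu <- 10
  fit <- pat_reconstruct(f, geo, method = "tv", mu = mu, iters = 20000)
  orc <- oracle_tv_recon(f / fit$scale, geo, mu, 1, scale = fit$scale,
                         n_iter = 20000)
  expect_lt(max(abs(fit$volume - orc)), 1e-3)
})

test_that("tgv_value agrees with the convex-program oracle on random volumes", {
  set.seed(4)
  p <- array(rnorm(64), c(8, 8, 1))
  v <- tgv_value(p, alpha0 = 2.5, alpha1 = 1, inner_iters = 20000)
  orc <- oracle_tgv_value(p, 2.5, 1, n_iter = 30000)
  expect_lt(abs(v - orc), 1e-4)
})

test_that("a large discrepancy weight reproduces exact data", {
  geo <- pat_geometry(Nx = 32, Nz = 1, Nphi = 16)
  p0 <- disk_phantom(32, r = 0.3)
  f <- radon_forward(p0, geo)
  fit <- pat_reconstruct(f, geo, method = "tgv", mu = 1e4, iters = 1500)
  rel <- sqrt(sum((radon_forward(fit$volume, geo) - f)^2) / sum(f^2))
  expect_lt(rel, 1e-2)
})

test_that("mu trades data fidelity against regularity monotonically", {
  geo <- pat_geometry(Nx = 16, Nz = 1, Nphi = 8)
  set.seed(17)
  p0 <- disk_phantom(16, r = 0.35)
  f <- radon_forward(p0, geo) + 0.05 * array(rnorm(geo$Ns * 8), c(geo$Ns, 8, 1))
  res <- reg <- numeric(0)
  for (mu in c(0.1, 1, 10)) {
    fit <- pat_reconstruct(f, geo, method = "tgv", mu = mu, iters = 4000)
    res <- c(res, sqrt(sum((radon_forward(fit$volume, geo) / fit$scale -
                              f / fit$scale)^2)))
    reg <- c(reg, tgv_value(fit$volume, 2.5, 1, inner_iters = 4000))
  }
  expect_true(all(diff(res) < 0))      # residual decreases with mu
  expect_true(all(diff(reg) > 0))      # regularizer value increases with mu
})

test_that("fit object methods are coherent", {
  geo <- pat_geometry(Nx = 12, Nz = 1, Nphi = 6)
  p0 <- disk_phantom(12, r = 0.3)
  f <- radon_forward(p0, geo)
  fit <- pat_reconstruct(f, geo, method = "tgv", mu = 100, iters = 300,
                         record_every = 100)
  expect_identical(coef(fit), fit$volume)
  expect_equal(fitted(fit), radon_forward(fit$volume, geo))
  expect_equal(residuals(fit), fitted(fit) - f)
  expect_output(print(fit), "TGV")
  expect_output(print(summary(fit)), "residual")
  expect_equal(nrow(fit$diagnostics), 3)
  expect_lte(fit$diagnostics$objective[3], fit$diagnostics$objective[1])
})
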