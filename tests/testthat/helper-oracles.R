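# Independent oracles for the variational solver tests.
#
# The reconstruction objectives are solved a second way: dense operator
# matrices (assembled column-by-column from the package's linear operators,
# which are adjointness-tested separately) and an ADMM iteration with exact
# proximal steps and a cached Cholesky factor. Different algorithm, different
# code path from the package's primal-dual solver. Tensor blocks are scaled
# by sqrt(2) on off-diagonal slots so every norm is plain Euclidean.

dense_from_op <- function(apply, dim_in) {
  cols <- lapply(seq_len(dim_in), function(j) {
    e <- numeric(dim_in); e[j] <- 1; apply(e)
  })
  do.call(cbind, cols)
}

tens_scale <- function(n) rep(rep(c(1, sqrt(2)), each = 3L), each = n)

# group-wise soft threshold: shrink Euclidean norms of consecutive groups
group_shrink <- function(z, group_size, thresh) {
  m <- matrix(z, nrow = group_size)
  nrm <- sqrt(colSums(m^2))
  fac <- pmax(0, 1 - thresh / pmax(nrm, 1e-300))
  as.double(m * rep(fac, each = group_size))
}

# rows of the stacked operator, as index lists per block
admm_generic <- function(Amat, blocks, prox_list, n_iter, rho = 1) {
  AtA <- crossprod(Amat)
  ch <- chol(AtA + diag(1e-12, ncol(Amat)))
  x <- numeric(ncol(Amat))
  y <- numeric(nrow(Amat))
  u <- numeric(nrow(Amat))
  for (it in seq_len(n_iter)) {
    rhs <- crossprod(Amat, y - u)
    x <- backsolve(ch, forwardsolve(t(ch), rhs))
    Ax <- as.double(Amat %*% x)
    zu <- Ax + u
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      y[idx] <- prox_list[[b]](zu[idx], rho)
    }
    u <- u + Ax - y
  }
  x
}

# oracle for min_p,q mu/2 ||Rs p - fs||^2 + a1 ||grad p - q|| + a0 ||E q||
# (Rs, fs already scaled as the solver scales them)
oracle_tgv_recon <- function(fs, geo, mu, alpha1, alpha0, scale = 1,
                             n_iter = 30000, rho = 1) {
  n <- geo$Nx * geo$Nx * geo$Nz
  dP <- c(geo$Nx, geo$Nx, geo$Nz)
  sc6 <- tens_scale(n)
  Rm <- dense_from_op(function(x)
    as.double(radon_forward(array(x, dP), geo)) / scale, n)
  Gm <- dense_from_op(function(x) as.double(grad3(array(x, dP))), n)
  Em <- dense_from_op(function(x)
    as.double(symgrad3(array(x, c(dP, 3)))) * sc6, 3 * n)
  m1 <- nrow(Rm)
  Amat <- rbind(cbind(Rm, matrix(0, m1, 3 * n)),
                cbind(Gm, -diag(3 * n)),
                cbind(matrix(0, 6 * n, n), Em))
  blocks <- list(seq_len(m1),
                 m1 + seq_len(3 * n),
                 m1 + 3 * n + seq_len(6 * n))
  fvec <- as.double(fs)
  prox_list <- list(
    function(z, rho) (mu * fvec + rho * z) / (mu + rho),
    function(z, rho) group_shrink_strided(z, n, 3L, alpha1 / rho),
    function(z, rho) group_shrink_strided(z, n, 6L, alpha0 / rho))
  x <- admm_generic(Amat, blocks, prox_list, n_iter, rho)
  list(p = array(x[seq_len(n)], dP), q = array(x[n + seq_len(3 * n)], c(dP, 3)))
}

# voxel groups are strided (component-major storage): voxel i has components
# at i, i + n, i + 2n, ...
group_shrink_strided <- function(z, n, n_comp, thresh) {
  m <- matrix(z, nrow = n)            # rows voxels, cols components
  nrm <- sqrt(rowSums(m^2))
  fac <- pmax(0, 1 - thresh / pmax(nrm, 1e-300))
  as.double(m * fac)
}

oracle_tv_recon <- function(fs, geo, mu, alpha1, scale = 1,
                            n_iter = 30000, rho = 1) {
  n <- geo$Nx * geo$Nx * geo$Nz
  dP <- c(geo$Nx, geo$Nx, geo$Nz)
  Rm <- dense_from_op(function(x)
    as.double(radon_forward(array(x, dP), geo)) / scale, n)
  Gm <- dense_from_op(function(x) as.double(grad3(array(x, dP))), n)
  m1 <- nrow(Rm)
  Amat <- rbind(Rm, Gm)
  fvec <- as.double(fs)
  blocks <- list(seq_len(m1), m1 + seq_len(3 * n))
  prox_list <- list(
    function(z, rho) (mu * fvec + rho * z) / (mu + rho),
    function(z, rho) group_shrink_strided(z, n, 3L, alpha1 / rho))
  x <- admm_generic(Amat, blocks, prox_list, n_iter, rho)
  array(x, dP)
}

# oracle for TGV(p) = min_q a1 ||grad p - q|| + a0 ||E q||
oracle_tgv_value <- function(p, alpha0, alpha1, n_iter = 30000, rho = 1) {
  dP <- dim(p)
  n <- prod(dP)
  sc6 <- tens_scale(n)
  Em <- dense_from_op(function(x)
    as.double(symgrad3(array(x, c(dP, 3)))) * sc6, 3 * n)
  Amat <- rbind(diag(3 * n), Em)
  gp <- as.double(grad3(p))
  blocks <- list(seq_len(3 * n), 3 * n + seq_len(6 * n))
  prox_list <- list(
    function(z, rho) gp + group_shrink_strided(z - gp, n, 3L, alpha1 / rho),
    function(z, rho) group_shrink_strided(z, n, 6L, alpha0 / rho))
  q <- admm_generic(Amat, blocks, prox_list, n_iter, rho)
  qa <- array(q, c(dP, 3))
  a <- as.double(grad3(p)) - q
  Ew <- as.double(symgrad3(qa))
  alpha1 * sum(sqrt(rowSums(matrix(a, nrow = n)^2))) +
    alpha0 * sum(sqrt(rowSums(matrix(Ew, nrow = n)^2 *
                                rep(c(1, 1, 1, 2, 2, 2), each = n))))
}

# objective of the (scaled) TGV problem at (p, q)
tgv_objective <- function(p, q, fs, geo, mu, alpha1, alpha0, scale = 1) {
  n <- prod(dim(p))
  res <- as.double(radon_forward(p, geo)) / scale - as.double(fs)
  gq <- as.double(grad3(p)) - as.double(q)
  Ew <- as.double(symgrad3(q))
  mu / 2 * sum(res^2) +
    alpha1 * sum(sqrt(rowSums(matrix(gq, nrow = n)^2))) +
    alpha0 * sum(sqrt(rowSums(matrix(Ew, nrow = n)^2 *
                                rep(c(1, 1, 1, 2, 2, 2), each = n))))
}
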