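# TGV- and TV-regularized inversion of the slice-wise Radon transform by the
# Chambolle-Pock primal-dual algorithm. The TGV problem
#   min_{p,q} mu/2 ||R p - f||^2 + alpha1 ||grad p - q||_l1 + alpha0 ||E q||_l1
# is cast as min F + G(A(p,q)) with F = 0, A(p,q) = (R p, grad p - q, E q),
# and G(g,v,w) = mu/2 ||g - f||^2 + alpha1 ||v||_l1 + alpha0 ||w||_l1. The
# dual proximal steps are the discrepancy prox and pointwise projections onto
# l-infinity balls of Euclidean / Frobenius norms.

#' Combined saddle-point operator and its adjoint
#'
#' `apply_A()` evaluates `A(p, q) = (R p, grad p - q, E q)`;
#' `apply_A_adjoint()` evaluates `A*(g, v, w) = (R* g - div v, -div w - v)`.
#' Adjointness holds with the tensor-space inner product that double-counts
#' off-diagonal slots.
#'
#' @param p volume `(Nx, Nx, Nz)`; `q` vector field `(Nx, Nx, Nz, 3)`.
#' @param g sinogram `(Ns, Nphi, Nz)`; `v` vector field; `w` tensor field.
#' @param geo a [pat_geometry()].
#' @return `apply_A()`: list `(g, v, w)`; `apply_A_adjoint()`: list `(p, q)`.
#' @export
apply_A <- function(p, q, geo) {
  check_volume(p, geo)
  list(g = radon_forward(p, geo), v = grad3(p) - q, w = symgrad3(q))
}

#' @rdname apply_A
#' @export
apply_A_adjoint <- function(g, v, w, geo) {
  check_sinogram(g, geo)
  list(p = radon_adjoint(g, geo) - div_vec3(v),
       q = -div_tens3(w) - v)
}

#' Proximal map of the conjugate discrepancy term
#'
#' For the data term `mu/2 ||. - f||^2`, the dual proximal step is
#' `g -> mu / (mu + sigma) * (g - sigma * f)`, applied elementwise.
#'
#' @param g,f sinogram arrays of equal shape.
#' @param sigma dual step size (> 0).
#' @param mu discrepancy weight (> 0).
#' @return Sinogram array.
#' @export
prox_discrepancy <- function(g, f, sigma, mu) {
  stopifnot(sigma > 0, mu > 0)
  mu / (mu + sigma) * (g - sigma * f)
}

#' Pointwise projections onto l-infinity balls
#'
#' `project_l2ball_vec()` projects each per-voxel 3-vector onto the Euclidean
#' ball of radius `alpha`; `project_l2ball_tens()` projects each per-voxel
#' symmetric tensor onto the Frobenius-norm ball (off-diagonal slots counted
#' twice). Both leave points inside the ball unchanged and are idempotent.
#'
#' @param v vector field `(Nx, Ny, Nz, 3)`; `w` tensor field `(Nx, Ny, Nz, 6)`.
#' @param alpha ball radius (> 0).
#' @return Field of the same shape.
#' @export
project_l2ball_vec <- function(v, alpha) {
  stopifnot(alpha > 0)
  d <- dim(v)
  array(.cpp_proj_vec(as.double(v), alpha, prod(d[1:3])), dim = d)
}

#' @rdname project_l2ball_vec
#' @export
project_l2ball_tens <- function(w, alpha) {
  stopifnot(alpha > 0)
  d <- dim(w)
  array(.cpp_proj_tens(as.double(w), alpha, prod(d[1:3])), dim = d)
}

#' Discrete total variation
#'
#' `||grad p||_l1`: the sum over voxels of the Euclidean magnitude of the
#' forward-difference gradient.
#'
#' @param p volume array.
#' @return Scalar TV value.
#' @export
tv_value <- function(p) {
  d <- dim(p)
  .cpp_l1_vec(.cpp_grad(as.double(p), d[1], d[2], d[3]), prod(d))
}

# combined operator in coordinates where all inner products are Euclidean
# (tensor block scaled by sqrt(2) on off-diagonal slots), for norm estimation
tgv_operator_map <- function(R_op, Nx, Ny, Nz) {
  n <- Nx * Ny * Nz
  sc <- rep(c(1, sqrt(2)), each = 3L)
  sc6 <- rep(sc, each = n)
  linear_map(
    apply = function(x) {
      p <- array(x[seq_len(n)], c(Nx, Ny, Nz))
      q <- array(x[n + seq_len(3 * n)], c(Nx, Ny, Nz, 3))
      c(R_op$apply(x[seq_len(n)]),
        as.double(grad3(p) - q),
        as.double(symgrad3(q)) * sc6)
    },
    adjoint = function(y) {
      g <- y[seq_len(R_op$dim_out)]
      v <- array(y[R_op$dim_out + seq_len(3 * n)], c(Nx, Ny, Nz, 3))
      w <- array(y[R_op$dim_out + 3 * n + seq_len(6 * n)] / sc6, c(Nx, Ny, Nz, 6))
      c(R_op$adjoint(g) - as.double(div_vec3(v)),
        -as.double(div_tens3(w)) - as.double(v))
    },
    dim_in = 4L * n, dim_out = R_op$dim_out + 9L * n)
}

#' Discrete second-order total generalized variation
#'
#' Evaluates `TGV(p) = min_q alpha1 ||grad p - q||_l1 + alpha0 ||E q||_l1` by
#' solving the inner minimization over the auxiliary vector field `q` with
#' the same primal-dual machinery as the reconstruction (no data term). The
#' returned value is the primal objective at the final iterate, hence an
#' upper bound on the true minimum that tightens with `inner_iters`; it never
#' exceeds `alpha1 * tv_value(p)` (take `q = 0`).
#'
#' @param p volume array.
#' @param alpha0,alpha1 TGV weights (> 0).
#' @param inner_iters iterations of the inner primal-dual solve.
#' @return Scalar TGV value.
#' @export
tgv_value <- function(p, alpha0 = 2.5, alpha1 = 1, inner_iters = 500L) {
  stopifnot(alpha0 > 0, alpha1 > 0, inner_iters >= 1L)
  d <- dim(p)
  n <- prod(d)
  gp <- grad3(p)
  # operator B q = (q, E q); norm estimated in Euclidean-ized coordinates
  sc6 <- rep(rep(c(1, sqrt(2)), each = 3L), each = n)
  B <- linear_map(
    apply = function(x) {
      q <- array(x, c(d, 3))
      c(x, as.double(symgrad3(q)) * sc6)
    },
    adjoint = function(y) {
      v <- y[seq_len(3 * n)]
      w <- array(y[3 * n + seq_len(6 * n)] / sc6, c(d, 6))
      v - as.double(div_tens3(w))
    },
    dim_in = 3L * n, dim_out = 9L * n)
  nb <- power_method_norm(B, n_iter = 30L, seed = 7L)
  st <- 0.95 / max(nb, 1e-12)
  q <- qb <- array(0, dim = c(d, 3))
  v <- array(0, dim = c(d, 3))
  w <- array(0, dim = c(d, 6))
  for (it in seq_len(inner_iters)) {
    v <- project_l2ball_vec(v + st * (qb - gp), alpha1)
    w <- project_l2ball_tens(w + st * symgrad3(qb), alpha0)
    qn <- q - st * (v - div_tens3(w))
    qb <- 2 * qn - q
    q <- qn
  }
  alpha1 * .cpp_l1_vec(as.double(gp - q), n) +
    alpha0 * .cpp_l1_tens(as.double(symgrad3(q)), n)
}

#' Variational reconstruction of the initial pressure
#'
#' Fits the initial pressure volume to a measured sinogram stack by
#' minimizing `mu/2 ||R p - f||^2 + Reg(p)` with `Reg` either second-order
#' total generalized variation (`method = "tgv"`, weights `alpha1`, `alpha0`)
#' or total variation (`method = "tv"`, weight `alpha1`), using the
#' primal-dual (Chambolle-Pock) algorithm with zero initialization, dual
#' updates (discrepancy prox, ball projections), primal gradient steps and an
#' extragradient step, run for exactly `iters` iterations. The Radon
#' projector and the datum are first rescaled to unit projector norm
#' (estimated by power iteration), as the step-size bound requires.
#' `method = "fbp"` dispatches to the direct [pat_fbp()] baseline instead.
#'
#' Negative values are permitted in the solution (no positivity constraint).
#'
#' @param f sinogram stack `(Ns, Nphi, Nz)`, e.g. from [back_propagate()].
#' @param geometry a [pat_geometry()].
#' @param method regularizer: `"tgv"` (default), `"tv"`, or `"fbp"`.
#' @param mu discrepancy weight (> 0): large `mu` trusts the data (low
#'   noise), small `mu` strengthens the regularization.
#' @param alpha1 first-order weight (default 1, for comparability with TV).
#' @param alpha0 second-order TGV weight (default 2.5).
#' @param iters number of primal-dual iterations (the only stopping rule).
#' @param sigma,tau step sizes; defaults are the symmetric choice just inside
#'   the stability bound (`sigma tau ||A||^2 < 1` with `||A||^2 < 12` for TGV
#'   and `<= 13` for TV at unit projector norm).
#' @param record_every if positive, record residual and objective every this
#'   many iterations in `diagnostics`.
#' @param norm_iters,seed power-iteration budget and seed for the projector
#'   norm estimate.
#' @param ... passed on to [pat_fbp()] when `method = "fbp"`.
#' @return An object of class `pat_recon` with elements `volume` (the
#'   reconstruction), `method`, `mu`, `alpha0`, `alpha1`, `sigma`, `tau`,
#'   `iters`, `scale` (projector normalization factor), `geometry`, and
#'   `diagnostics` (data frame of iteration, residual, objective). Supports
#'   `print()`, `summary()`, `plot()`, `coef()`, `fitted()`, `residuals()`.
#' @examples
#' geo <- pat_geometry(Nx = 16, Nz = 1, Nphi = 8)
#' p0 <- array(0, c(16, 16, 1)); p0[6:10, 6:10, 1] <- 1
#' f <- radon_forward(p0, geo)
#' fit <- pat_reconstruct(f, geo, method = "tgv", mu = 100, iters = 200)
#' fit
#' @export
pat_reconstruct <- function(f, geometry, method = c("tgv", "tv", "fbp"),
                            mu = 1, alpha1 = 1, alpha0 = 2.5,
                            iters = 1000L, sigma = NULL, tau = NULL,
                            record_every = 0L, norm_iters = 100L, seed = 1L,
                            ...) {
  method <- match.arg(method)
  if (method == "fbp") return(pat_fbp(f, geometry, ...))
  stopifnot(inherits(geometry, "pat_geometry"))
  check_sinogram(f, geometry)
  stopifnot_finite(f)
  if (mu <= 0 || alpha1 <= 0 || alpha0 <= 0)
    stop("`mu`, `alpha1`, `alpha0` must be positive", call. = FALSE)
  if (iters < 1L) stop("`iters` must be >= 1", call. = FALSE)
  Lsq <- if (method == "tgv") 12 else 13
  if (is.null(sigma) && is.null(tau)) sigma <- tau <- 1 / sqrt(Lsq) - 1e-6
  if (is.null(sigma)) sigma <- (1 / Lsq - 1e-9) / tau
  if (is.null(tau)) tau <- (1 / Lsq - 1e-9) / sigma
  if (sigma <= 0 || tau <= 0 || sigma * tau * Lsq >= 1)
    stop(sprintf("step sizes must satisfy sigma * tau < 1/%d", Lsq), call. = FALSE)

  np <- normalize_problem(geometry, f, n_iter = norm_iters, seed = seed)
  fs <- np$f
  Rfwd <- function(p) array(np$op$apply(as.double(p)),
                            dim = c(geometry$Ns, geometry$Nphi, geometry$Nz))
  Radj <- function(g) array(np$op$adjoint(as.double(g)),
                            dim = c(geometry$Nx, geometry$Nx, geometry$Nz))

  dP <- c(geometry$Nx, geometry$Nx, geometry$Nz)
  p <- pb <- array(0, dim = dP)
  g <- array(0, dim = dim(f))
  v <- array(0, dim = c(dP, 3))
  tgv <- method == "tgv"
  if (tgv) {
    q <- qb <- array(0, dim = c(dP, 3))
    w <- array(0, dim = c(dP, 6))
  }
  diag_it <- integer(0); diag_res <- numeric(0); diag_obj <- numeric(0)
  n <- prod(dP)

  for (it in seq_len(iters)) {
    g <- prox_discrepancy(g + sigma * Rfwd(pb), fs, sigma, mu)
    if (tgv) {
      v <- project_l2ball_vec(v + sigma * (grad3(pb) - qb), alpha1)
      w <- project_l2ball_tens(w + sigma * symgrad3(qb), alpha0)
    } else {
      v <- project_l2ball_vec(v + sigma * grad3(pb), alpha1)
    }
    pn <- p - tau * (Radj(g) - div_vec3(v))
    pb <- 2 * pn - p
    p <- pn
    if (tgv) {
      qn <- q + tau * (v + div_tens3(w))
      qb <- 2 * qn - q
      q <- qn
    }
    if (record_every > 0L && (it %% record_every == 0L || it == iters)) {
      res <- sqrt(sum((Rfwd(p) - fs)^2))
      reg <- if (tgv) {
        alpha1 * .cpp_l1_vec(as.double(grad3(p) - q), n) +
          alpha0 * .cpp_l1_tens(as.double(symgrad3(q)), n)
      } else {
        alpha1 * tv_value(p)
      }
      obj <- mu / 2 * res^2 + reg
      diag_it <- c(diag_it, it); diag_res <- c(diag_res, res)
      diag_obj <- c(diag_obj, obj)
    }
  }

  structure(list(
    volume = p,
    method = method, mu = mu, alpha0 = if (tgv) alpha0 else NA_real_,
    alpha1 = alpha1, sigma = sigma, tau = tau, iters = as.integer(iters),
    scale = np$scale, norm_estimate = np$norm_estimate,
    geometry = geometry, f = f,
    diagnostics = data.frame(iter = diag_it, residual = diag_res,
                             objective = diag_obj),
    call = match.call()
  ), class = "pat_recon")
}
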