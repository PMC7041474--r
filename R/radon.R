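# Slice-wise discrete 2D Radon transform.
#
# Each square pixel (side dx) deposits its exact projection footprint -- the
# trapezoid obtained by convolving the two box profiles of widths
# dx*|cos(phi)| and dx*|sin(phi)| -- onto the s-bin grid: the weight of bin k
# is the integral of the trapezoid over the bin divided by the bin width, so
# sinogram values approximate line integrals (physical length units) and the
# per-pixel mass sum(weights) * ds equals the pixel area exactly. Forward and
# adjoint share one sparse matrix (the adjoint is its transpose), so the
# pair is exact to machine precision.

# antiderivative of the trapezoid footprint: plateau half-width r1, support
# half-width r2, height H, total area `area`; t is relative to the center
trap_cdf <- function(t, r1, r2, H, area) {
  tt <- pmin(pmax(t, -r2), r2)
  rise <- r2 - r1
  if (rise < 1e-14) return(H * pmin(pmax(tt + r1, 0), 2 * r1))
  ifelse(tt < -r1, H * (tt + r2)^2 / (2 * rise),
         ifelse(tt <= r1, H * rise / 2 + H * (tt + r1),
                area - H * (r2 - tt)^2 / (2 * rise)))
}

.projector_cache <- new.env(parent = emptyenv())

# sparse (Ns*Nphi) x (Nx^2) slice projection matrix
radon_matrix <- function(geo) {
  key <- paste(geo$Nx, geo$Ns, geo$Nphi, sep = "_")
  hit <- get0(key, envir = .projector_cache)
  if (!is.null(hit)) return(hit)
  Nx <- geo$Nx; Ns <- geo$Ns; Nphi <- geo$Nphi
  dx <- geo$dx; ds <- geo$ds
  xc <- -sqrt(2) / 2 + (seq_len(Nx) - 0.5) * dx   # pixel centers
  area <- dx^2
  ii <- vector("list", Nphi); jj <- vector("list", Nphi); xx <- vector("list", Nphi)
  pix <- seq_len(Nx * Nx)
  for (a in seq_len(Nphi)) {
    phi <- geo$angles[a]
    cphi <- cos(phi); sphi <- sin(phi)
    b1 <- dx * max(abs(cphi), abs(sphi)); b2 <- dx * min(abs(cphi), abs(sphi))
    r1 <- (b1 - b2) / 2; r2 <- (b1 + b2) / 2; H <- area / b1
    s0 <- as.vector(outer(xc * cphi, xc * sphi, `+`))
    klo <- floor((s0 - r2 + 1) / ds)               # 0-based bin of left support edge
    K <- ceiling(2 * r2 / ds) + 1L
    ai <- list(); aj <- list(); ax <- list()
    for (m in 0:K) {
      kb <- klo + m
      left <- -1 + kb * ds
      wgt <- (trap_cdf(left + ds - s0, r1, r2, H, area) -
              trap_cdf(left - s0, r1, r2, H, area)) / ds
      keep <- kb >= 0 & kb < Ns & wgt > 0
      if (!any(keep)) next
      ai[[length(ai) + 1L]] <- kb[keep] + 1L + (a - 1L) * Ns
      aj[[length(aj) + 1L]] <- pix[keep]
      ax[[length(ax) + 1L]] <- wgt[keep]
    }
    ii[[a]] <- unlist(ai); jj[[a]] <- unlist(aj); xx[[a]] <- unlist(ax)
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(Ns * Nphi, Nx * Nx))
  keys <- ls(.projector_cache)
  if (length(keys) >= 8L) rm(list = keys[1L], envir = .projector_cache)
  assign(key, M, envir = .projector_cache)
  M
}

#' Slice-wise discrete Radon transform and its adjoint
#'
#' `radon_forward()` maps a pressure volume to its sinogram stack by exact
#' line integration of the piecewise-constant image over the parallel-beam
#' line set `{s w(phi) + r w_perp(phi)}`, independently per z slice;
#' `radon_adjoint()` applies the exact adjoint (back projection with the same
#' footprint weights), so `<R p, g> = <p, R* g>` holds to machine precision.
#'
#' @param p volume, array `(Nx, Nx, Nz)`.
#' @param g sinogram stack, array `(Ns, Nphi, Nz)`.
#' @param geo a [pat_geometry()].
#' @return `radon_forward()`: sinogram array `(Ns, Nphi, Nz)` in line-integral
#'   (length) units; `radon_adjoint()`: volume array.
#' @examples
#' geo <- pat_geometry(Nx = 16, Nz = 1, Nphi = 8)
#' p <- array(0, c(16, 16, 1)); p[8, 8, 1] <- 1
#' f <- radon_forward(p, geo)
#' sum(f[, 1, 1]) * geo$ds / geo$dx^2   # mass conservation: = 1
#' @export
radon_forward <- function(p, geo) {
  check_volume(p, geo)
  stopifnot_finite(p)
  M <- radon_matrix(geo)
  out <- as.matrix(M %*% matrix(p, geo$Nx * geo$Nx, geo$Nz))
  array(out, dim = c(geo$Ns, geo$Nphi, geo$Nz))
}

#' @rdname radon_forward
#' @export
radon_adjoint <- function(g, geo) {
  check_sinogram(g, geo)
  stopifnot_finite(g)
  M <- radon_matrix(geo)
  out <- as.matrix(Matrix::crossprod(M, matrix(g, geo$Ns * geo$Nphi, geo$Nz)))
  array(out, dim = c(geo$Nx, geo$Nx, geo$Nz))
}

#' Radon projector as a matrix-free linear map
#'
#' @param geo a [pat_geometry()].
#' @return A [linear_map()] acting on flattened volumes / sinogram stacks.
#' @export
radon_map <- function(geo) {
  nin <- geo$Nx * geo$Nx * geo$Nz
  nout <- geo$Ns * geo$Nphi * geo$Nz
  linear_map(
    apply = function(x) as.double(radon_forward(array(x, c(geo$Nx, geo$Nx, geo$Nz)), geo)),
    adjoint = function(y) as.double(radon_adjoint(array(y, c(geo$Ns, geo$Nphi, geo$Nz)), geo)),
    dim_in = nin, dim_out = nout)
}

#' Operator norm by power iteration
#'
#' Estimates `||A|| = sqrt(lambda_max(A* A))` of a [linear_map()] by power
#' iteration from a seeded random start. The returned Rayleigh-type estimate
#' `||A*A v_k|| / ||v_k||` is non-decreasing in the iteration count (A*A is
#' positive semi-definite) and converges to the largest eigenvalue.
#'
#' @param op a [linear_map()].
#' @param n_iter number of power iterations (>= 1).
#' @param seed RNG seed for the start vector.
#' @return The estimated operator norm (0 for the zero operator).
#' @export
power_method_norm <- function(op, n_iter = 100L, seed = 1L) {
  stopifnot(inherits(op, "pat_linear_map"), n_iter >= 1L)
  v <- with_seed(seed, rnorm(op$dim_in))
  lam <- 0
  for (it in seq_len(n_iter)) {
    u <- op$adjoint(op$apply(v))
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    lam <- nu / sqrt(sum(v^2))
    v <- u / nu
  }
  sqrt(lam)
}

#' Normalize the inversion problem to a unit-norm projector
#'
#' Estimates `||R||` by power iteration; if it exceeds 1, returns the
#' projector, adjoint and datum scaled by `1/||R||` so the rescaled projector
#' has operator norm (approximately) 1, as required by the step-size bound of
#' the primal-dual solver. If `||R|| <= 1` the inputs are returned unchanged
#' with scale 1.
#'
#' @param geo a [pat_geometry()].
#' @param f sinogram stack consistent with `geo`.
#' @param n_iter power iterations for the norm estimate.
#' @param seed RNG seed for the power iteration.
#' @return A list with `op` (scaled [linear_map()]), `f` (scaled datum),
#'   `scale` (the factor `c`), and `norm_estimate` (the raw `||R||` estimate).
#' @export
normalize_problem <- function(geo, f, n_iter = 100L, seed = 1L) {
  check_sinogram(f, geo)
  op <- radon_map(geo)
  nrm <- power_method_norm(op, n_iter = n_iter, seed = seed)
  cfac <- if (nrm > 1) nrm else 1
  sop <- linear_map(apply = function(x) op$apply(x) / cfac,
                    adjoint = function(y) op$adjoint(y) / cfac,
                    dim_in = op$dim_in, dim_out = op$dim_out)
  list(op = sop, f = f / cfac, scale = cfac, norm_estimate = nrm)
}
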