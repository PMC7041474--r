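#' Synthetic vessel-skeleton phantom component
#'
#' Generates a binary volume whose nonzero set is a union of `n_curves`
#' one-voxel-wide smooth discrete 3D curves (26-connected rasterizations of
#' random cubic-spline paths), emulating a skeletonized vasculature with
#' pressure 1 on the skeleton.
#'
#' @param shape integer triple `(Nx, Ny, Nz)`.
#' @param n_curves number of curves (0 gives an all-zero volume).
#' @param seed RNG seed; fixed seed gives a bit-identical volume.
#' @param n_control number of spline control points per curve.
#' @return 3D array with values in `{0, 1}`.
#' @examples
#' sk <- make_vessel_skeleton(c(32, 32, 8), n_curves = 2, seed = 1)
#' table(sk)
#' @export
make_vessel_skeleton <- function(shape, n_curves, seed = 1L, n_control = 5L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be a positive integer triple", call. = FALSE)
  if (n_curves < 0L) stop("`n_curves` must be >= 0", call. = FALSE)
  vol <- array(0, dim = shape)
  if (n_curves == 0L) return(vol)
  with_seed(seed, {
    nsamp <- max(200L, 30L * max(shape))
    for (cu in seq_len(n_curves)) {
      # control points kept off the faces so curves stay inside the box
      ctrl <- sapply(shape, function(n)
        runif(n_control, 1 + 0.08 * (n - 1), 1 + 0.92 * (n - 1)))
      path <- sapply(1:3, function(a)
        spline(seq_len(n_control), ctrl[, a], n = nsamp, method = "natural")$y)
      ij <- round(path)
      for (a in 1:3) ij[, a] <- pmin(pmax(ij[, a], 1L), shape[a])
      vol[ij] <- 1
    }
  })
  vol
}

#' Add an ellipsoidal pressure inclusion
#'
#' Adds `value` times the indicator of an axis-aligned ellipsoid to a volume.
#' The composition is additive: skeleton voxels inside the ellipsoid end up at
#' `1 + value`. Support reaching outside the volume is clipped.
#'
#' @param vol 3D array.
#' @param center voxel-coordinate triple (1-based, may be fractional).
#' @param semiaxes positive triple of semi-axis lengths in voxels.
#' @param value pressure added inside the ellipsoid.
#' @return The modified volume.
#' @export
add_ellipsoid <- function(vol, center, semiaxes, value) {
  stopifnot(length(dim(vol)) == 3L, length(center) == 3L, length(semiaxes) == 3L)
  if (any(semiaxes <= 0)) stop("`semiaxes` must be positive", call. = FALSE)
  if (!is.finite(value)) stop("`value` must be finite", call. = FALSE)
  d <- dim(vol)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(center[a] - semiaxes[a]))
    hi <- min(d[a], ceiling(center[a] + semiaxes[a]))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0L)) return(vol)
  u <- (rng[[1]] - center[1]) / semiaxes[1]
  v <- (rng[[2]] - center[2]) / semiaxes[2]
  w <- (rng[[3]] - center[3]) / semiaxes[3]
  mask <- outer(outer(u^2, v^2, `+`), w^2, `+`) <= 1
  sub <- vol[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] + value * mask
  vol[rng[[1]], rng[[2]], rng[[3]]] <- sub
  vol
}

#' Add a linear pressure ramp
#'
#' Adds, inside a box region, a value varying affinely from `vmin` on the
#' first slice of the region along `axis` to `vmax` on the last slice. A
#' single-slice region receives the constant `vmin`.
#'
#' @param vol 3D array.
#' @param region 3x2 integer matrix of inclusive index ranges (rows x, y, z).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param vmin,vmax ramp endpoint values, `vmin <= vmax`.
#' @return The modified volume.
#' @export
add_ramp <- function(vol, region, axis = c("x", "y", "z"), vmin, vmax) {
  axis <- match.arg(axis)
  region <- matrix(as.integer(region), nrow = 3)
  d <- dim(vol)
  if (any(region[, 1] > region[, 2])) {
    warning("empty ramp region: no-op")
    return(vol)
  }
  if (any(region[, 1] < 1L) || any(region[, 2] > d))
    stop("ramp region outside volume", call. = FALSE)
  if (vmin > vmax) stop("`vmin` must be <= `vmax`", call. = FALSE)
  ax <- match(axis, c("x", "y", "z"))
  idx <- lapply(1:3, function(a) seq.int(region[a, 1], region[a, 2]))
  nax <- length(idx[[ax]])
  vals <- if (nax == 1L) vmin else seq(vmin, vmax, length.out = nax)
  for (m in seq_len(nax)) {
    sl <- idx
    sl[[ax]] <- idx[[ax]][m]
    vol[sl[[1]], sl[[2]], sl[[3]]] <- vol[sl[[1]], sl[[2]], sl[[3]]] + vals[m]
  }
  vol
}

#' Phantom specification
#'
#' Parameters for [pat_phantom()]: a vessel-skeleton + two ellipsoids + ramp
#' structure of size `inner_shape`, embedded centered in a zero-padded
#' `outer_shape` volume. Ellipsoid and ramp placements are specified as
#' fractions of the inner shape so the phantom scales to any grid; defaults
#' emulate thin bright curvilinear structures over elevated smooth
#' backgrounds (vasculature, tumor-like inclusions, tissue ramp).
#'
#' @param inner_shape voxel triple of the structured region.
#' @param outer_shape voxel triple of the full (zero-padded) volume.
#' @param n_curves number of skeleton curves.
#' @param ellipsoids list of `list(center=, semiaxes=, value=)` with center
#'   and semiaxes as fractions of `inner_shape`.
#' @param ramp `list(region=, axis=, vmin=, vmax=)`, region as a 3x2 matrix of
#'   fractions of `inner_shape`.
#' @param seed RNG seed for the skeleton.
#' @return An object of class `pat_phantom_spec`.
#' @export
phantom_spec <- function(inner_shape = c(128L, 128L, 40L),
                         outer_shape = c(281L, 281L, 40L),
                         n_curves = 6L,
                         ellipsoids = list(
                           list(center = c(0.32, 0.35, 0.5),
                                semiaxes = c(0.20, 0.16, 0.45), value = 0.3),
                           list(center = c(0.68, 0.66, 0.5),
                                semiaxes = c(0.17, 0.21, 0.45), value = 0.6)),
                         ramp = list(
                           region = rbind(c(0.15, 0.85), c(0.62, 0.92), c(0.1, 0.9)),
                           axis = "x", vmin = 0, vmax = 0.8),
                         seed = 1L) {
  inner_shape <- as.integer(inner_shape); outer_shape <- as.integer(outer_shape)
  if (any(inner_shape > outer_shape))
    stop("inner shape must fit inside outer shape", call. = FALSE)
  structure(list(inner_shape = inner_shape, outer_shape = outer_shape,
                 n_curves = as.integer(n_curves), ellipsoids = ellipsoids,
                 ramp = ramp, seed = as.integer(seed)),
            class = "pat_phantom_spec")
}

#' Compose the default synthetic pressure phantom
#'
#' Builds the numerical test phantom: a vessel skeleton with pressure 1, two
#' ellipsoids with sub-unit pressure and a linear ramp, composed additively on
#' the inner grid and embedded centered in a larger zero volume (mirroring a
#' 128x128x40 structure inside a 281x281x40 reconstruction domain at default
#' sizes). Deterministic under a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return 3D array of shape `spec$outer_shape` with non-negative values.
#' @examples
#' sp <- phantom_spec(inner_shape = c(32, 32, 4), outer_shape = c(48, 48, 4))
#' p0 <- pat_phantom(sp)
#' range(p0)
#' @export
pat_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "pat_phantom_spec"))
  ish <- spec$inner_shape
  inner <- make_vessel_skeleton(ish, spec$n_curves, seed = spec$seed)
  for (e in spec$ellipsoids)
    inner <- add_ellipsoid(inner, center = e$center * ish,
                           semiaxes = pmax(e$semiaxes * ish, 0.5),
                           value = e$value)
  rg <- spec$ramp$region
  region <- rbind(pmax(1L, round(rg[1, ] * ish[1])),
                  pmax(1L, round(rg[2, ] * ish[2])),
                  pmax(1L, round(rg[3, ] * ish[3])))
  inner <- add_ramp(inner, region, axis = spec$ramp$axis,
                    vmin = spec$ramp$vmin, vmax = spec$ramp$vmax)
  embed_centered(inner, spec$outer_shape)
}

embed_centered <- function(inner, outer_shape) {
  d <- dim(inner)
  off <- (outer_shape - d) %/% 2L
  out <- array(0, dim = outer_shape)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- inner
  out
}

#' Hair-loop and microsphere phantom
#'
#' Emulates a physical phantom of thin closed hair loops and small absorbing
#' microspheres: thin (1-2 voxel) closed loops with random orientation plus
#' small filled spheres, value 1 on zero background.
#'
#' @param shape voxel triple.
#' @param n_loops,n_spheres counts (>= 0).
#' @param seed RNG seed.
#' @return 3D array with values in `{0, 1}`.
#' @export
make_hairloop_phantom <- function(shape, n_loops = 3L, n_spheres = 5L, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be a positive integer triple", call. = FALSE)
  if (n_loops < 0L || n_spheres < 0L) stop("counts must be >= 0", call. = FALSE)
  vol <- array(0, dim = shape)
  with_seed(seed, {
    half <- shape / 2
    for (l in seq_len(n_loops)) {
      r <- runif(1, 0.15, 0.35) * min(shape[1:2])
      cen <- sapply(shape, function(n) runif(1, 0.3 * n, 0.7 * n))
      # random orientation via two Euler angles
      th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
      u <- c(cos(ph), sin(ph), 0)
      v <- c(-sin(ph) * cos(th), cos(ph) * cos(th), sin(th))
      tt <- seq(0, 2 * pi, length.out = max(100L, ceiling(20 * r)))
      pts <- cbind(cen[1] + r * (cos(tt) * u[1] + sin(tt) * v[1]),
                   cen[2] + r * (cos(tt) * u[2] + sin(tt) * v[2]),
                   cen[3] + r * (cos(tt) * u[3] + sin(tt) * v[3]))
      ij <- round(pts)
      for (a in 1:3) ij[, a] <- pmin(pmax(ij[, a], 1L), shape[a])
      vol[ij] <- 1
    }
    for (s in seq_len(n_spheres)) {
      cen <- sapply(shape, function(n) runif(1, 0.2 * n, 0.8 * n))
      r <- runif(1, 1, max(2, 0.03 * min(shape)))
      tmp <- array(0, dim = shape)
      tmp <- add_ellipsoid(tmp, cen, rep(r, 3), 1)
      vol[tmp > 0] <- 1
    }
  })
  vol
}
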