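# Acoustic propagation in the sinogram domain. The projection data obeys the
# 2D wave equation in (s, z) per angle (the Radon transform intertwines the
# 3D and 2D Laplacians), with zero initial velocity. Evolution by time T is
# therefore the Fourier multiplier cos(cs |k| T), evaluated spectrally on a
# zero-padded grid so the periodic solution coincides with the free-space one
# as long as the wave stays inside the padded cell (support grows by at most
# cs*T in time T).

# cos(cs|k|T) multiplier applied slice-wise in (s, z) for each angle.
# pad_margin: physical zero-padding added on every side of both axes.
propagate_cos <- function(arr, ds, dz, cs, tim, pad_margin = cs * tim) {
  d <- dim(arr)
  ns <- d[1]; na <- d[2]; nz <- d[3]
  ms <- ceiling(pad_margin / ds)
  Ms <- fft_length(ns + 2 * ms)
  if (nz > 1L) {
    mz <- ceiling(pad_margin / dz)
    Mz <- fft_length(nz + 2 * mz)
  } else { mz <- 0L; Mz <- 1L }
  os <- (Ms - ns) %/% 2L; oz <- (Mz - nz) %/% 2L
  fs <- c(0:(Ms %/% 2), -((Ms - Ms %/% 2 - 1):1))[seq_len(Ms)] / (Ms * ds)
  kz <- if (Mz > 1L) {
    fz <- c(0:(Mz %/% 2), -((Mz - Mz %/% 2 - 1):1))[seq_len(Mz)] / (Mz * dz)
    2 * pi * fz
  } else 0
  kmag <- sqrt(outer((2 * pi * fs)^2, kz^2, `+`))
  mult <- cos(cs * kmag * tim)
  out <- array(0, dim = d)
  buf <- matrix(0, Ms, Mz)
  for (a in seq_len(na)) {
    buf[] <- 0
    buf[os + seq_len(ns), oz + seq_len(nz)] <- arr[, a, ]
    sp <- stats::fft(buf) * mult
    res <- Re(stats::fft(sp, inverse = TRUE)) / (Ms * Mz)
    out[, a, ] <- res[os + seq_len(ns), oz + seq_len(nz)]
  }
  out
}

#' Forward acoustic evolution of projection data
#'
#' Evolves a sinogram stack under the 2D wave equation in `(s, z)` per angle
#' (initial value `sino0`, zero initial velocity) to time `geo$T`: spectrally,
#' the Fourier transform over `(s, z)` is multiplied by `cos(cs |k| T)`. The
#' map is linear, norm-nonincreasing, and the identity at `T = 0`.
#'
#' @param sino0 sinogram array `(Ns, Nphi, Nz)` (or any grid with spacings
#'   `geo$ds`, `geo$dz`).
#' @param geo a [pat_geometry()] providing `cs`, `T` and the spacings.
#' @param pad_margin physical zero padding per side (default `cs * T`, enough
#'   that no energy wraps around the periodic computational cell).
#' @return Array of the same shape: the time-`T` snapshot of the field.
#' @export
forward_propagate <- function(sino0, geo, pad_margin = geo$cs * geo$T) {
  stopifnot(length(dim(sino0)) == 3L)
  stopifnot_finite(sino0)
  if (geo$T == 0) return(sino0 + 0)
  propagate_cos(sino0, geo$ds, geo$dz, geo$cs, geo$T, pad_margin)
}

#' Phase-contrast scaling of a pressure sinogram
#'
#' Converts line-integrated pressure at the snapshot time into phase shifts:
#' a pointwise multiplication by the calibration constant `k_pc` (radians per
#' pressure-length; physically `2 pi / lambda_PB * dn/dp`).
#'
#' @param sinoT time-`T` sinogram stack.
#' @param k_pc calibration constant (finite).
#' @return A `pat_snapshots` array: phase shifts with attribute `k_pc`.
#' @export
to_phase_contrast <- function(sinoT, k_pc = 1) {
  if (!is.finite(k_pc)) stop("`k_pc` must be finite", call. = FALSE)
  out <- unclass(sinoT) * k_pc
  attr(out, "k_pc") <- k_pc
  attr(out, "crop") <- attr(sinoT, "crop")
  class(out) <- "pat_snapshots"
  out
}

#' Frequency-domain back propagation of snapshot data
#'
#' Recovers the initial projection data `R[p0]` from phase-contrast snapshots
#' of the field at time `T`: divides by `k_pc` to obtain `R[pT]`, then applies
#' the inverse Fourier transform of the spectrum of `2 R[pT]` multiplied by
#' `cos(cs |k| T)`. Since `2 cos^2 = 1 + cos(2 cs |k| T)`, the result is
#' `R[p0]` plus an echo term at time `2T`; inside the region of interest the
#' echo is negligible once `2 cs T` exceeds the support separation. At `T = 0`
#' the result is exactly `2 R[pT]`.
#'
#' @param snap a `pat_snapshots` array (possibly on an extended field-of-view
#'   grid carrying a `crop` attribute locating the sinogram window).
#' @param geo a [pat_geometry()].
#' @param k_pc calibration constant; default taken from `snap` (must be
#'   nonzero).
#' @param pad_margin extra spectral zero padding (default `cs * T`).
#' @return Sinogram array `(Ns, Nphi, Nz)` approximating `R[p0]`.
#' @export
back_propagate <- function(snap, geo, k_pc = attr(snap, "k_pc") %||% 1,
                           pad_margin = geo$cs * geo$T) {
  if (!is.finite(k_pc) || k_pc == 0)
    stop("`k_pc` must be finite and nonzero", call. = FALSE)
  crop <- attr(snap, "crop")
  x <- unclass(snap)
  attributes(x) <- list(dim = dim(x))
  x <- 2 * x / k_pc
  out <- if (geo$T == 0) x else
    propagate_cos(x, geo$ds, geo$dz, geo$cs, geo$T, pad_margin)
  if (!is.null(crop)) out <- out[crop$s, , crop$z, drop = FALSE]
  out
}

#' Simulate a phase-contrast measurement
#'
#' Composition of the measurement model: Radon projection of the initial
#' pressure, acoustic evolution to the snapshot time on a field of view
#' extended so that it covers the whole wave pattern, phase-contrast scaling,
#' and optional additive white Gaussian camera noise.
#'
#' @param p0 initial pressure volume `(Nx, Nx, Nz)`.
#' @param geo a [pat_geometry()].
#' @param k_pc phase-contrast calibration constant.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed RNG seed for the noise.
#' @param fov_margin physical margin added around the sinogram window so the
#'   camera grid contains the full wave pattern (default `cs * T` plus a small
#'   guard band).
#' @return A `pat_snapshots` array on the extended grid, with attributes
#'   `k_pc` and `crop` (the sinogram window indices).
#' @export
simulate_measurement <- function(p0, geo, k_pc = 1, noise_sd = 0, seed = 1L,
                                 fov_margin = geo$cs * geo$T + 0.15) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  sino <- radon_forward(p0, geo)
  if (geo$T > 0) {
    ms <- ceiling(fov_margin / geo$ds)
    mz <- if (geo$Nz > 1L) ceiling(fov_margin / geo$dz) else 0L
    ext <- array(0, dim = c(geo$Ns + 2L * ms, geo$Nphi, geo$Nz + 2L * mz))
    crop <- list(s = ms + seq_len(geo$Ns), z = mz + seq_len(geo$Nz))
    ext[crop$s, , crop$z] <- sino
    # the extended cell already contains the full pattern; a small extra pad
    # keeps the FFT length friendly and guards the boundary
    snapT <- propagate_cos(ext, geo$ds, geo$dz, geo$cs, geo$T,
                           pad_margin = 2 * geo$ds)
  } else {
    snapT <- sino
    crop <- NULL
  }
  out <- snapT * k_pc
  if (noise_sd > 0)
    out <- out + with_seed(seed, array(rnorm(length(out), 0, noise_sd), dim = dim(out)))
  attr(out, "k_pc") <- k_pc
  attr(out, "crop") <- crop
  class(out) <- "pat_snapshots"
  out
}
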