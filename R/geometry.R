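#' Acquisition and reconstruction geometry
#'
#' Describes the discretization shared by all stages: the reconstruction
#' volume lives on `[-sqrt(2)/2, sqrt(2)/2]^2 x [0, h]` sampled on an
#' `Nx x Nx x Nz` voxel grid, and the sinogram / snapshot domain on
#' `[-1, 1] x [0, pi) x [0, h]` sampled on an `Ns x Nphi x Nz` grid. The
#' projection integration half-length is normalized to `L = 1`, so a line
#' offset `s` spans `[-1, 1]` and covers the full square cross-section
#' including its corners.
#'
#' @param Nx lateral voxel count (volume is `Nx x Nx x Nz`).
#' @param Nz number of z slices.
#' @param Nphi number of projection angles, uniform on `[0, pi)`.
#' @param Ns number of line-offset bins; default `2 * Nx`, matching the
#'   diagonal sampling rate of the pixel grid.
#' @param h physical height of the volume; default gives cubic voxels
#'   (`sqrt(2) * Nz / Nx`).
#' @param cs speed of sound (length per unit time; lengths in the normalized
#'   units of the reconstruction domain).
#' @param T snapshot time: the acoustic field is imaged at this time after
#'   excitation.
#'
#' @return An object of class `pat_geometry`: a list with the fields above
#'   plus derived spacings `ds = 2/Ns`, `dz = h/Nz`, pixel side
#'   `dx = sqrt(2)/Nx`, and the angle grid `angles = (0:(Nphi-1)) * pi/Nphi`.
#' @examples
#' geo <- pat_geometry(Nx = 32, Nz = 4, Nphi = 12)
#' geo$angles
#' @export
pat_geometry <- function(Nx, Nz = 1L, Nphi, Ns = 2L * Nx,
                         h = sqrt(2) * Nz / Nx, cs = 1, T = 0) {
  Nx <- as.integer(Nx); Nz <- as.integer(Nz)
  Ns <- as.integer(Ns); Nphi <- as.integer(Nphi)
  if (Nx < 1L || Nz < 1L || Ns < 1L || Nphi < 1L)
    stop("grid sizes Nx, Nz, Ns, Nphi must be positive integers", call. = FALSE)
  if (h <= 0 || cs <= 0 || T < 0)
    stop("h and cs must be positive, T non-negative", call. = FALSE)
  structure(list(
    Nx = Nx, Nz = Nz, Ns = Ns, Nphi = Nphi,
    h = h, L = 1, cs = cs, T = T,
    dx = sqrt(2) / Nx, ds = 2 / Ns, dz = h / Nz,
    angles = (seq_len(Nphi) - 1L) * pi / Nphi
  ), class = "pat_geometry")
}

#' @export
print.pat_geometry <- function(x, ...) {
  cat(sprintf("PAT geometry: %d x %d x %d volume, %d x %d x %d sinogram\n",
              x$Nx, x$Nx, x$Nz, x$Ns, x$Nphi, x$Nz))
  cat(sprintf("  h = %.4g, cs = %.4g, T = %.4g  (dx = %.4g, ds = %.4g, dz = %.4g)\n",
              x$h, x$cs, x$T, x$dx, x$ds, x$dz))
  invisible(x)
}

check_volume <- function(p, geo) {
  if (!identical(dim(p), c(geo$Nx, geo$Nx, geo$Nz)))
    stop(sprintf("volume shape %s does not match geometry (%d, %d, %d)",
                 paste(dim(p), collapse = "x"), geo$Nx, geo$Nx, geo$Nz),
         call. = FALSE)
  invisible(p)
}

check_sinogram <- function(f, geo, Nphi = geo$Nphi) {
  if (!identical(dim(f), c(geo$Ns, as.integer(Nphi), geo$Nz)))
    stop(sprintf("sinogram shape %s does not match geometry (%d, %d, %d)",
                 paste(dim(f), collapse = "x"), geo$Ns, Nphi, geo$Nz),
         call. = FALSE)
  invisible(f)
}

#' Matrix-free linear map
#'
#' Bundles a forward and an adjoint action on flat numeric vectors. Used by
#' [power_method_norm()] and [normalize_problem()]; the Radon projector and
#' the combined TGV saddle-point operator are exposed in this form.
#'
#' @param apply function mapping a numeric vector of length `dim_in` to one of
#'   length `dim_out`.
#' @param adjoint function implementing the adjoint (transpose) action.
#' @param dim_in,dim_out input/output dimensions.
#' @return An object of class `pat_linear_map`.
#' @export
linear_map <- function(apply, adjoint, dim_in, dim_out) {
  stopifnot(is.function(apply), is.function(adjoint))
  structure(list(apply = apply, adjoint = adjoint,
                 dim_in = as.integer(dim_in), dim_out = as.integer(dim_out)),
            class = "pat_linear_map")
}

#' @export
print.pat_linear_map <- function(x, ...) {
  cat(sprintf("linear map: R^%d -> R^%d (matrix-free)\n", x$dim_in, x$dim_out))
  invisible(x)
}
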