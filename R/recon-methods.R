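#' @export
print.pat_recon <- function(x, ...) {
  cat(sprintf("PAT reconstruction (%s)\n", toupper(x$method)))
  g <- x$geometry
  cat(sprintf("  volume: %d x %d x %d, data: %d offsets x %d angles x %d slices\n",
              g$Nx, g$Nx, g$Nz, g$Ns, g$Nphi, g$Nz))
  if (x$method %in% c("tgv", "tv")) {
    if (x$method == "tgv")
      cat(sprintf("  mu = %.4g, alpha1 = %.4g, alpha0 = %.4g, %d iterations\n",
                  x$mu, x$alpha1, x$alpha0, x$iters))
    else
      cat(sprintf("  mu = %.4g, alpha1 = %.4g, %d iterations\n",
                  x$mu, x$alpha1, x$iters))
    cat(sprintf("  projector norm %.4g (scaled by %.4g)\n",
                x$norm_estimate, x$scale))
  }
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$volume), max(x$volume)))
  invisible(x)
}

#' @export
summary.pat_recon <- function(object, ...) {
  stats <- volume_stats(object$volume, n_bins = 32L)
  res <- residuals(object)
  out <- list(method = object$method, geometry = object$geometry,
              mu = object$mu, alpha1 = object$alpha1, alpha0 = object$alpha0,
              iters = object$iters,
              mean = stats$mean, sd = stats$sd,
              range = range(object$volume),
              data_residual = sqrt(sum(res^2)),
              rel_data_residual = sqrt(sum(res^2)) / max(sqrt(sum(object$f^2)), .Machine$double.eps),
              diagnostics = object$diagnostics)
  class(out) <- "summary.pat_recon"
  out
}

#' @export
print.summary.pat_recon <- function(x, ...) {
  cat(sprintf("PAT reconstruction summary (%s)\n", toupper(x$method)))
  cat(sprintf("  voxel mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              x$mean, x$sd, x$range[1], x$range[2]))
  cat(sprintf("  data residual ||Rp - f|| = %.4g (relative %.4g)\n",
              x$data_residual, x$rel_data_residual))
  if (nrow(x$diagnostics) > 0) {
    cat("  objective trace (last rows):\n")
    print(utils::tail(x$diagnostics, 3L), row.names = FALSE)
  }
  invisible(x)
}

#' Extract the reconstructed volume
#' @param object a `pat_recon` fit.
#' @param ... unused.
#' @return The reconstructed pressure volume (3D array).
#' @export
coef.pat_recon <- function(object, ...) object$volume

#' Forward-projected reconstruction
#' @param object a `pat_recon` fit.
#' @param ... unused.
#' @return The sinogram stack `R p` of the reconstruction (unscaled units).
#' @export
fitted.pat_recon <- function(object, ...) {
  radon_forward(object$volume, object$geometry)
}

#' Sinogram-domain residuals
#' @param object a `pat_recon` fit.
#' @param ... unused.
#' @return `R p - f` as a sinogram stack.
#' @export
residuals.pat_recon <- function(object, ...) {
  fitted(object) - object$f
}

#' Display a reconstruction
#'
#' Shows either the maximum amplitude projection along an axis or a single z
#' slice of the reconstructed volume as a grayscale image.
#'
#' @param x a `pat_recon` fit.
#' @param what `"map"` (maximum amplitude projection) or `"slice"`.
#' @param axis projection axis for `what = "map"`.
#' @param slice z index for `what = "slice"`.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the displayed 2D matrix.
#' @export
plot.pat_recon <- function(x, what = c("map", "slice"), axis = "z",
                           slice = 1L, ...) {
  what <- match.arg(what)
  img <- if (what == "map") map_projection(x$volume, axis = axis)
         else x$volume[, , slice]
  graphics::image(img, col = grDevices::gray.colors(256), asp = 1,
                  axes = FALSE, ...)
  invisible(img)
}
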