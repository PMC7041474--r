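# File interchange: multi-page 32-bit float TIFF for arrays plus a YAML
# sidecar (<file>.yml) carrying grid attributes, so stacks survive round
# trips with their geometry.

#' Read and write volumes and sinogram stacks as multi-page TIFF
#'
#' Volumes `(Nx, Nx, Nz)` are stored as z pages; sinogram / snapshot stacks
#' `(Ns, Nphi, Nz)` as angle pages of `s x z` images. Data is written as
#' 32-bit float TIFF; grid attributes (and any extra metadata) go to a YAML
#' sidecar `<path>.yml` and are restored as attributes on reading.
#'
#' Values are affinely mapped to `[0, 1]` for storage (the TIFF writer's
#' float range); the offset and scale are recorded in the sidecar and undone
#' on reading, so negative-valued reconstructions survive the round trip to
#' 32-bit precision.
#'
#' @param vol volume array; `sino` sinogram/snapshot array.
#' @param path output file path (`.tif`).
#' @param attrs named list of metadata stored in the sidecar.
#' @return Readers return the array with sidecar metadata in
#'   `attr(x, "meta")`; writers return `path` invisibly.
#' @export
write_volume_tiff <- function(vol, path, attrs = list()) {
  stopifnot(length(dim(vol)) == 3L)
  nv <- normalize_store(vol)
  pages <- lapply(seq_len(dim(vol)[3]), function(z) nv$x[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(kind = "volume", dim = as.integer(dim(vol)),
                 value_offset = nv$offset, value_scale = nv$scale), attrs)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

normalize_store <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) list(x = (x - lo) / (hi - lo), offset = lo, scale = hi - lo)
  else list(x = array(0, dim = dim(x)), offset = lo, scale = 1)
}

denormalize_store <- function(x, meta) {
  if (!is.null(meta$value_scale)) x * meta$value_scale + meta$value_offset
  else x
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- pages[[z]]
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    vol <- denormalize_store(vol, meta)
    attr(vol, "meta") <- meta
  }
  vol
}

#' @rdname write_volume_tiff
#' @export
write_sinogram_tiff <- function(sino, path, attrs = list()) {
  stopifnot(length(dim(sino)) == 3L)
  d <- dim(sino)
  nv <- normalize_store(unclass(sino))
  pages <- lapply(seq_len(d[2]), function(a) {
    m <- nv$x[, a, , drop = FALSE]
    dim(m) <- d[c(1, 3)]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(kind = "sinogram", dim = as.integer(d),
                 value_offset = nv$offset, value_scale = nv$scale), attrs)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_sinogram_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  sino <- array(0, dim = c(d1[1], length(pages), d1[2]))
  for (a in seq_along(pages)) sino[, a, ] <- pages[[a]]
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    sino <- denormalize_store(sino, meta)
    attr(sino, "meta") <- meta
  }
  sino
}
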