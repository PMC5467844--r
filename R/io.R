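#' Write / read an image as 32-bit float TIFF
#'
#' Pixel pitch and value semantics travel in a small YAML sidecar written
#' next to the TIFF.
#'
#' @param img An `image2d`.
#' @param path File path (`.tif`).
#' @return `read_image_tiff` returns an `image2d`.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  tiff::writeTIFF(t(img$values[, rev(seq_len(ncol(img$values)))]),
                  path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(pitch = img$pitch, semantics = img$semantics),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pitch,semantics Metadata overrides when no sidecar is present.
#' @export
read_image_tiff <- function(path, pitch = NULL, semantics = "attenuation") {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    pitch <- meta$pitch
    semantics <- meta$semantics
  }
  if (is.null(pitch)) stop("pixel pitch unknown: pass `pitch` or keep the sidecar")
  v <- t(m)[, rev(seq_len(nrow(m)))]
  image2d(v, pitch, semantics)
}

#' Save / load a sinogram with its geometry
#'
#' Plain RDS serialization for intermediate pipeline artifacts.
#'
#' @param sino A `sinogram`.
#' @param path File path (`.rds`).
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino, path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "sinogram"))
  s
}

#' Serialize a region stack
#'
#' Writes the nested masks as a multi-page TIFF plus a JSON sidecar carrying
#' the region count, fill values and `mu`.
#'
#' @param stack A `region_stack`.
#' @param path File path (`.tif`).
#' @export
write_region_stack <- function(stack, path) {
  stopifnot(inherits(stack, "region_stack"))
  pages <- lapply(stack$masks, function(m) t(m[, rev(seq_len(ncol(m)))]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(n_regions = stack$n_regions, fills = stack$fills,
                            mu = stack$mu),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
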