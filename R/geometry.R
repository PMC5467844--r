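#' Fan-beam acquisition geometry
#'
#' Describes a 2-D fan-beam CT system with a flat, equispaced detector and a
#' circular 360-degree source trajectory, together with the reconstruction
#' grid. Defaults reproduce the simulation geometry used throughout the
#' package: 929.19 mm source-to-isocenter distance, 525.24 mm
#' detector-to-isocenter distance, 1024 channels of 0.388 mm pitch, 1080
#' views, and a 512 x 512 image at 0.2 mm pixels (102.4 mm field of view).
#'
#' @param sid Source-to-isocenter distance in mm.
#' @param did Detector-to-isocenter distance in mm.
#' @param n_channels Number of detector channels.
#' @param channel_pitch Detector channel spacing in mm (at the detector).
#' @param n_views Number of projection views over 360 degrees.
#' @param n_pixels Reconstruction grid side length in pixels.
#' @param pixel_pitch Reconstruction pixel size in mm.
#' @param oversample Focal-spot/detector subsampling factor (rays per channel
#'   averaged). `1` traces a single central ray per channel; larger values
#'   emulate finite source and detector extent.
#' @return An object of class `fan_geometry`.
#' @export
fan_geometry <- function(sid = 929.19, did = 525.24,
                         n_channels = 1024L, channel_pitch = 0.388,
                         n_views = 1080L,
                         n_pixels = 512L, pixel_pitch = 0.2,
                         oversample = 1L) {
  stopifnot(sid > 0, did > 0, n_channels >= 2, channel_pitch > 0,
            n_views >= 1, n_pixels >= 2, pixel_pitch > 0, oversample >= 1)
  structure(list(
    sid = sid, did = did, sdd = sid + did,
    n_channels = as.integer(n_channels), channel_pitch = channel_pitch,
    n_views = as.integer(n_views),
    n_pixels = as.integer(n_pixels), pixel_pitch = pixel_pitch,
    oversample = as.integer(oversample)
  ), class = "fan_geometry")
}

#' Reduced-size geometry for quick experiments
#'
#' Same source/detector distances, detector (1024 channels at 0.388 mm) and
#' field of view as [fan_geometry()], with coarser angular and image
#' sampling (default 360 views and a 256 x 256 grid at 0.4 mm pixels). Used
#' by the package's own simulation study so a full phantom run stays within
#' minutes on one core.
#'
#' @param n_views,n_channels,n_pixels Sampling overrides.
#' @return A `fan_geometry` object.
#' @export
desk_geometry <- function(n_views = 360L, n_channels = 1024L,
                          n_pixels = 256L) {
  fan_geometry(n_channels = n_channels, channel_pitch = 0.388 * 1024 / n_channels,
               n_views = n_views, n_pixels = n_pixels,
               pixel_pitch = 102.4 / n_pixels)
}

view_angles <- function(geom) {
  seq(0, 2 * pi, length.out = geom$n_views + 1L)[seq_len(geom$n_views)]
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf(
    "<fan_geometry> SID %.2f mm, SDD %.2f mm, %d ch x %.3f mm, %d views, %d px @ %.3g mm\n",
    x$sid, x$sdd, x$n_channels, x$channel_pitch, x$n_views, x$n_pixels,
    x$pixel_pitch))
  invisible(x)
}

#' 2-D image container
#'
#' A square pixel grid with physical pitch and value semantics. The first
#' matrix index runs along +x (right), the second along +y (up), with the
#' grid centre at the isocenter.
#'
#' @param values Numeric matrix (square).
#' @param pitch Pixel size in mm.
#' @param semantics Either `"attenuation"` (linear attenuation, 1/mm) or
#'   `"hu"` (Hounsfield units).
#' @return An object of class `image2d`.
#' @export
image2d <- function(values, pitch, semantics = c("attenuation", "hu")) {
  semantics <- match.arg(semantics)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("image2d values must be square")
  if (!all(is.finite(values))) stop("image2d values must be finite")
  structure(list(values = values, pitch = pitch, semantics = semantics),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px @ %.3g mm [%s], range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pitch, x$semantics,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.image2d <- function(x, window = NULL, ...) {
  v <- x$values
  if (!is.null(window)) v <- pmin(pmax(v, window[1]), window[2])
  graphics::image(t(v), col = grDevices::grey.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

#' Sinogram container
#'
#' Post-log line integrals (dimensionless) on a views x channels grid, tied
#' to a [fan_geometry()].
#'
#' @param values Numeric matrix, `n_views` rows by `n_channels` columns.
#' @param geom A `fan_geometry`.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geom) {
  stopifnot(inherits(geom, "fan_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geom$n_views || ncol(values) != geom$n_channels)
    stop("sinogram shape does not match geometry (views x channels)")
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, geom = geom), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d channels, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

grid_coords <- function(n, pitch) {
  (seq_len(n) - 1 - (n - 1) / 2) * pitch
}

#' Convert an attenuation image to Hounsfield units
#'
#' HU = 1000 (mu - mu_water) / mu_water, with the water attenuation taken at
#' a stated reference energy (conventionally the mean energy of the
#' acquisition spectrum).
#'
#' @param image An `image2d` with attenuation semantics.
#' @param mu_water Water linear attenuation (1/mm) at the reference energy.
#' @return An `image2d` in HU.
#' @export
to_hu <- function(image, mu_water) {
  stopifnot(inherits(image, "image2d"), mu_water > 0)
  if (image$semantics == "hu") return(image)
  image2d(1000 * (image$values - mu_water) / mu_water, image$pitch, "hu")
}
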