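#' Fan-beam forward projection
#'
#' Computes line integrals of an attenuation image along every source-channel
#' ray (a discrete fan-beam Radon transform). Ray tracing is Joseph-style:
#' bilinear interpolation sampled at half-pixel steps, which makes the
#' operator linear in the image. With `geom$oversample > 1`, that many
#' equally spaced sub-rays per channel are averaged to emulate finite
#' detector extent.
#'
#' @param image An `image2d` with attenuation semantics.
#' @param geom A `fan_geometry`.
#' @param step_frac Ray sampling step as a fraction of the pixel pitch.
#' @return A `sinogram` (views x channels, dimensionless line integrals).
#' @export
forward_project <- function(image, geom, step_frac = 0.5) {
  stopifnot(inherits(image, "image2d"), inherits(geom, "fan_geometry"))
  if (image$semantics != "attenuation")
    stop("forward projection expects an attenuation image, not ", image$semantics)
  ang <- view_angles(geom)
  os <- geom$oversample
  if (os == 1L) {
    v <- cpp_fan_forward(image$values, image$pitch, geom$sid, geom$sdd,
                         geom$n_channels, geom$channel_pitch, ang, step_frac)
  } else {
    offs <- ((seq_len(os) - 0.5) / os - 0.5) * geom$channel_pitch
    v <- 0
    for (o in offs)
      v <- v + cpp_fan_forward_offset(image$values, image$pitch, geom$sid,
                                      geom$sdd, geom$n_channels,
                                      geom$channel_pitch, ang, step_frac, o)
    v <- v / os
  }
  sinogram(v, geom)
}

# Averaged-subray variant used when oversample > 1: same projector with the
# whole channel comb shifted by `offset` mm.
cpp_fan_forward_offset <- function(img, pitch, sid, sdd, n_ch, ch_pitch,
                                   angles, step_frac, offset) {
  # shift by a fractional channel via a denser virtual comb
  shift <- offset / ch_pitch
  v <- cpp_fan_forward(img, pitch, sid, sdd, n_ch + 2L, ch_pitch, angles,
                       step_frac)
  idx <- seq_len(n_ch) + 1L
  f <- shift - floor(shift)
  i0 <- idx + as.integer(floor(shift))
  (1 - f) * v[, i0, drop = FALSE] + f * v[, i0 + 1L, drop = FALSE]
}

#' Unfiltered backprojection (adjoint of the forward projector)
#'
#' The exact matrix transpose of [forward_project()] at `oversample = 1`:
#' spreads each sinogram sample back along its ray with the same bilinear
#' weights. Useful for adjoint-consistency checks and algebraic methods; not
#' a reconstruction.
#'
#' @param sino A `sinogram`.
#' @param n,pitch Target image grid (defaults from the geometry).
#' @param step_frac Ray sampling step as in [forward_project()].
#' @return An `image2d`.
#' @export
unfiltered_backproject <- function(sino, n = sino$geom$n_pixels,
                                   pitch = sino$geom$pixel_pitch,
                                   step_frac = 0.5) {
  g <- sino$geom
  v <- cpp_fan_adjoint(sino$values, as.integer(n), pitch, g$sid, g$sdd,
                       g$n_channels, g$channel_pitch, view_angles(g),
                       step_frac)
  image2d(v, pitch)
}

#' Polychromatic (and optionally noisy) sinogram of a material map
#'
#' Simulates Beer-Lambert transmission of a polychromatic beam: per ray,
#' `I = sum_E S(E) exp(-sum_m mu_m(E) l_m)` where `l_m` is the
#' material-specific intersection length obtained by forward-projecting each
#' material's (density-scaled) indicator image. With `photons_per_cell` set,
#' the detected intensity is Poisson-sampled with the open-beam mean scaled
#' to that photon count, and clamped to at least one photon before the log.
#' Air paths are neglected.
#'
#' @param map A `material_map`.
#' @param spectrum A `spectrum`.
#' @param geom A `fan_geometry`.
#' @param photons_per_cell Open-beam photons per detector cell, or `NULL`
#'   for a noiseless acquisition.
#' @param seed Optional RNG seed used for the Poisson draw.
#' @return A post-log `sinogram`.
#' @export
polychromatic_sinogram <- function(map, spectrum, geom,
                                   photons_per_cell = NULL, seed = NULL) {
  stopifnot(inherits(map, "material_map"), inherits(spectrum, "spectrum"),
            inherits(geom, "fan_geometry"))
  mats <- setdiff(unique(map$legend$material), "air")
  paths <- lapply(mats, function(m) {
    rows <- map$legend[map$legend$material == m, ]
    ind <- matrix(0, map$n, map$n)
    for (i in seq_len(nrow(rows)))
      ind[map$labels == rows$label[i]] <- rows$scale[i]
    forward_project(image2d(ind, map$pitch), geom)$values
  })
  transmitted <- matrix(0, geom$n_views, geom$n_channels)
  for (b in seq_along(spectrum$energy_kev)) {
    a <- matrix(0, geom$n_views, geom$n_channels)
    for (im in seq_along(mats))
      a <- a + attenuation(mats[im], spectrum$energy_kev[b]) * paths[[im]]
    transmitted <- transmitted + spectrum$fluence[b] * exp(-a)
  }
  if (is.null(photons_per_cell)) {
    p <- -log(transmitted)
  } else {
    stopifnot(photons_per_cell > 0)
    if (!is.null(seed)) set.seed(seed)
    counts <- matrix(
      stats::rpois(length(transmitted), photons_per_cell * transmitted),
      nrow(transmitted), ncol(transmitted))
    p <- -log(pmax(counts, 1) / photons_per_cell)
  }
  sinogram(p, geom)
}

ramp_kernel_freq <- function(nfft, du, apodization = c("hann", "ramp"),
                             cutoff = NULL) {
  apodization <- match.arg(apodization)
  m <- c(0:(nfft / 2), -(nfft / 2 - 1):-1)
  h <- numeric(nfft)
  h[1] <- 1 / (4 * du^2)
  odd <- which(m %% 2 != 0)
  h[odd] <- -1 / (pi * m[odd] * du)^2
  H <- Re(stats::fft(h))
  f <- abs(m) / (nfft * du)            # cycles/mm
  fn <- 1 / (2 * du)                   # detector Nyquist
  fc <- if (is.null(cutoff)) fn else min(cutoff, fn)
  if (apodization == "hann") {
    H <- H * ifelse(f <= fc, 0.5 * (1 + cos(pi * f / fc)), 0)
  } else {
    H <- H * (f <= fc)
  }
  H
}

#' Fan-beam filtered backprojection
#'
#' Reconstructs an attenuation image from a full-scan fan-beam sinogram:
#' cosine weighting of each channel, ramp filtering along the channel axis
#' (Ram-Lak kernel, Hann-apodized by default), and distance-weighted
#' backprojection onto the configured grid. All operations use the virtual
#' detector through the isocenter.
#'
#' @param sino A `sinogram`.
#' @param filter `"hann"` (default) or `"ramp"` (no apodization).
#' @param n,pitch Reconstruction grid (defaults from the geometry).
#' @param cutoff Filter cutoff in cycles/mm. Defaults to the reconstruction
#'   grid's Nyquist frequency (capped at the detector Nyquist): frequencies
#'   the pixel grid cannot represent would only add aliased noise.
#' @return An `image2d` of attenuation (1/mm).
#' @export
fbp_reconstruct <- function(sino, filter = c("hann", "ramp"),
                            n = sino$geom$n_pixels,
                            pitch = sino$geom$pixel_pitch,
                            cutoff = 1 / (2 * pitch)) {
  stopifnot(inherits(sino, "sinogram"))
  filter <- match.arg(filter)
  g <- sino$geom
  if (g$n_views < 2) stop("at least 2 views are required for reconstruction")
  du <- g$channel_pitch * g$sid / g$sdd        # channel pitch at the isocenter
  nch <- g$n_channels
  up <- (seq_len(nch) - 1 - (nch - 1) / 2) * du
  w <- g$sid / sqrt(g$sid^2 + up^2)
  pw <- sweep(sino$values, 2, w, `*`)
  nfft <- 2^ceiling(log2(2 * nch))
  H <- ramp_kernel_freq(nfft, du, filter, cutoff)
  pad <- matrix(0, nfft, nrow(pw))
  pad[seq_len(nch), ] <- t(pw)
  q <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / nfft
  q <- t(q[seq_len(nch), , drop = FALSE]) * du * 0.5  # half: 360deg double coverage
  v <- cpp_fan_backproject(q, g$sid, as.integer(n), pitch, du, view_angles(g))
  image2d(v, pitch)
}

#' Metal trace of a binary metal mask
#'
#' Forward-projects the mask and thresholds at a small fraction of the
#' maximum trace value, yielding the set of sinogram samples whose rays
#' intersect metal. Boundary channels (the nearest non-trace channel on each
#' side of every trace run, per view) are recorded for the boundary-gradient
#' term of the coefficient fit.
#'
#' @param mask_image An `image2d` whose values are 0/1 (metal indicator), or
#'   a logical matrix plus `pitch`.
#' @param geom A `fan_geometry`.
#' @param pitch Pixel pitch, required when `mask_image` is a plain matrix.
#' @param eps_frac Threshold as a fraction of the maximum trace value.
#' @return A `metal_trace`: logical `mask` (views x channels), logical
#'   `boundary`, and the geometry.
#' @export
metal_trace <- function(mask_image, geom, pitch = NULL, eps_frac = 1e-6) {
  if (is.matrix(mask_image) && !inherits(mask_image, "image2d")) {
    stopifnot(!is.null(pitch))
    mask_image <- image2d(matrix(as.numeric(mask_image), nrow(mask_image)),
                          pitch)
  }
  vals <- mask_image$values
  if (!all(vals %in% c(0, 1))) stop("metal mask must be binary")
  tr <- matrix(FALSE, geom$n_views, geom$n_channels)
  if (any(vals > 0)) {
    s <- forward_project(mask_image, geom)$values
    tr <- s > eps_frac * max(s)
  }
  structure(list(mask = tr, boundary = trace_boundary(tr), geom = geom),
            class = "metal_trace")
}

# Nearest outside channels on each side of every trace run, per view.
trace_boundary <- function(tr) {
  nc <- ncol(tr)
  left <- !tr & cbind(tr[, -1, drop = FALSE], FALSE)   # trace starts right of me
  right <- !tr & cbind(FALSE, tr[, -nc, drop = FALSE]) # trace ends left of me
  left | right
}

#' @export
print.metal_trace <- function(x, ...) {
  cat(sprintf("<metal_trace> %d / %d samples in trace (%.1f%%)\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}
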