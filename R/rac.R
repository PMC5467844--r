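#' Recursive active-contour (RAC) segmentation
#'
#' Repeatedly applies [chan_vese()]: each round's foreground becomes the next
#' prior region, the background values are replaced by the minimum of the
#' foreground (a low quantile is used as a noise-robust minimum), and the
#' recursion continues on the flattened image until the contour degenerates,
#' the working image is constant to within `range_tol` of the initial range,
#' or the level cap is reached. The number of regions is therefore chosen
#' adaptively by the data and by `mu`: a smaller `mu` resolves lower-contrast
#' tiers into additional regions.
#'
#' Every round evaluates the Chan-Vese energy on the same absolute
#' intensity scale (by default attenuation expressed in 1/cm, the unit `mu
#' = 0.1` is calibrated for), so each successive, lower-contrast tier
#' competes against the same length penalty — this is what makes the
#' recursion stop by itself and what makes `mu` the sensitivity knob.
#'
#' @param image An `image2d` or numeric matrix.
#' @param mu Regularization weight passed to [chan_vese()].
#' @param exclude Optional logical matrix of pixels (e.g. metal) excluded
#'   from the energy, the masks, and the fill statistics.
#' @param max_levels Hard cap on the number of recursion levels.
#' @param range_tol Terminate when the working image's (robust) value range
#'   falls below this fraction of the initial range.
#' @param fill_quantile Quantile of the foreground values used as the
#'   "minimum of the foreground" background fill; the default 0.1 is robust
#'   to noise and to the partial-volume ramp at region edges and equals the
#'   minimum for piecewise-constant data.
#' @param scale Intensity divisor handed to [chan_vese()]; the default 0.1
#'   converts 1/mm attenuation images to 1/cm inside the energy.
#' @param cv_max_iter,cv_tol Passed to [chan_vese()].
#' @return A `region_stack`: nested logical masks `masks[[1]] >= ... >=
#'   masks[[N]]`, region count `n_regions`, per-level fill values, `mu`.
#' @export
rac_segment <- function(image, mu = 0.1, exclude = NULL, max_levels = 10,
                        range_tol = 0.01, fill_quantile = 0.1, scale = 0.1,
                        cv_max_iter = 150, cv_tol = 1e-6) {
  J <- if (inherits(image, "image2d")) image$values else as.matrix(image)
  if (!all(is.finite(J))) stop("image must be finite")
  w <- if (is.null(exclude)) matrix(TRUE, nrow(J), ncol(J)) else !exclude
  scale0 <- diff(range(J[w]))
  masks <- list()
  fills <- numeric(0)
  if (scale0 > 0) {
    for (lev in seq_len(max_levels)) {
      q <- stats::quantile(J[w], c(0.005, 0.995), names = FALSE)
      if (diff(q) < range_tol * scale0) break
      cv <- chan_vese(J, mu = mu, max_iter = cv_max_iter, tol = cv_tol,
                      scale = scale, exclude = !w)
      if (cv$degenerate) break
      mask <- cv$mask
      if (lev > 1) mask <- mask & masks[[lev - 1]]
      prev <- if (lev > 1) masks[[lev - 1]] else w
      if (sum(mask) == 0 || sum(prev & !mask) == 0) break  # no progress
      masks[[lev]] <- mask
      fills[lev] <- stats::quantile(J[mask], fill_quantile, names = FALSE)
      J[!mask] <- fills[lev]
    }
  }
  structure(list(masks = masks, n_regions = length(masks), fills = fills,
                 mu = mu),
            class = "region_stack")
}

#' @export
print.region_stack <- function(x, ...) {
  cat(sprintf("<region_stack> N = %d nested regions (mu = %g)\n",
              x$n_regions, x$mu))
  if (x$n_regions > 0)
    cat("  px per level:", vapply(x$masks, sum, 0L), "\n")
  invisible(x)
}

#' Exclusive subregions of a region stack
#'
#' The nested RAC foregrounds partition the object into disjoint intensity
#' tiers: tier `j` is `masks[[j]]` minus `masks[[j+1]]` (the innermost tier
#' is `masks[[N]]` itself). These tiers are the prior images whose forward
#' projections form the sinogram basis.
#'
#' @param stack A `region_stack`.
#' @return A list of `n_regions` disjoint logical matrices.
#' @export
region_partition <- function(stack) {
  stopifnot(inherits(stack, "region_stack"))
  N <- stack$n_regions
  if (N == 0) return(list())
  lapply(seq_len(N), function(j) {
    if (j < N) stack$masks[[j]] & !stack$masks[[j + 1]] else stack$masks[[N]]
  })
}

#' Representative image value of each exclusive subregion
#'
#' By default the median, which estimates the subregion's plateau value
#' robustly: the mean is dragged down by the partial-volume ring at region
#' edges, while for a homogeneous region the two coincide.
#'
#' @param stack A `region_stack`.
#' @param image The image the stack was derived from (`image2d` or matrix).
#' @param exclude Optional logical matrix of pixels excluded from the
#'   statistic.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Numeric vector of length `n_regions`.
#' @export
region_means <- function(stack, image, exclude = NULL,
                         stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  v <- if (inherits(image, "image2d")) image$values else as.matrix(image)
  parts <- region_partition(stack)
  vapply(parts, function(m) {
    if (!is.null(exclude)) m <- m & !exclude
    if (sum(m) == 0) 0 else f(v[m])
  }, 0)
}

#' Segment metal from an uncorrected reconstruction
#'
#' Clips the image to `[0, cap]` to bound the influence of photon-starvation
#' streaks, runs [chan_vese()] on the clipped image with the contour
#' initialized at the metal intensity range, and keeps the connected
#' components whose mean attenuation exceeds `metal_floor` — which handles
#' several disjoint implants and returns an empty mask on metal-free images.
#' Each kept component is trimmed at half its median value, since the
#' reconstruction point-spread smears the very high metal edge into
#' neighbouring pixels.
#'
#' @param image An `image2d` of attenuation (1/mm), typically the
#'   uncorrected FBP reconstruction.
#' @param cap Clip level in 1/mm; should sit above the metal reconstruction
#'   values (gold reconstructs around 1-3 /mm under photon clamping).
#' @param metal_floor Minimum mean attenuation (1/mm) of a metal component,
#'   several times cortical bone.
#' @param mu Chan-Vese regularization weight.
#' @param min_px Discard components smaller than this many pixels.
#' @return Logical matrix, `TRUE` on metal.
#' @export
segment_metal <- function(image, cap = 3.0, metal_floor = 0.3, mu = 0.5,
                          min_px = 3) {
  v <- if (inherits(image, "image2d")) image$values else as.matrix(image)
  vc <- pmin(pmax(v, 0), cap)
  empty <- matrix(FALSE, nrow(v), ncol(v))
  if (max(vc) - min(vc) <= 0) return(empty)
  # start the contour around half the cap so the descent refines a
  # metal / non-metal split instead of the dominant object / air split
  cv <- chan_vese(vc, mu = mu, init = 10 * (vc - cap / 2) / cap)
  if (cv$degenerate) return(empty)
  mask <- cv$mask
  if (sum(mask) == 0 || mean(v[mask]) < metal_floor) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  keep <- empty
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (sum(comp) < min_px || mean(v[comp]) < metal_floor) next
    # half-maximum refinement: the reconstruction PSF smears the metal edge,
    # so trim component pixels below half the component's median value
    keep <- keep | (comp & v >= 0.5 * stats::median(v[comp]))
  }
  keep
}
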