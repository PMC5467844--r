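#' Linear interpolation across the metal trace
#'
#' For each view independently, every maximal run of trace channels is
#' replaced by the 1-D linear interpolant between the adjacent non-trace
#' channel values; runs touching the detector border clamp to the nearest
#' measured value. All non-trace samples are returned bit-for-bit unchanged.
#'
#' @param sino A `sinogram`.
#' @param trace A `metal_trace` on the same grid.
#' @return A `sinogram` with the trace region filled in.
#' @export
interpolate_trace <- function(sino, trace) {
  stopifnot(inherits(sino, "sinogram"), inherits(trace, "metal_trace"))
  v <- sino$values
  tr <- trace$mask
  if (!all(dim(v) == dim(tr))) stop("sinogram / trace shape mismatch")
  for (r in which(rowSums(tr) > 0)) {
    t <- tr[r, ]
    nt <- which(!t)
    if (length(nt) == 0) {
      warning("view ", r, ": trace covers the whole row; values left unchanged")
    } else if (length(nt) == 1) {
      v[r, t] <- v[r, nt]
    } else {
      v[r, t] <- stats::approx(nt, v[r, nt], xout = which(t), rule = 2)$y
    }
  }
  sinogram(v, sino$geom)
}

new_mar_result <- function(method, sino, image, fit = NULL,
                           residual_norms = numeric(0), iterations = 0L,
                           tau = NA_real_, flags = character(0), ...) {
  structure(list(method = method, sinogram = sino, image = image, fit = fit,
                 residual_norms = residual_norms,
                 iterations = as.integer(iterations), tau = tau,
                 flags = flags, ...),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("<mar_result> method=%s, %d outer iteration(s)%s\n", x$method,
              x$iterations,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (length(x$residual_norms))
    cat("  ||delta|| per iteration:",
        paste(signif(x$residual_norms, 4), collapse = " "), "\n")
  invisible(x)
}

reinsert_metal <- function(image, uncorrected, metal) {
  if (is.null(uncorrected) || is.null(metal) || !any(metal)) return(image)
  v <- image$values
  v[metal] <- uncorrected$values[metal]
  image2d(v, image$pitch, image$semantics)
}

#' MAR by linear sinogram interpolation (LIN)
#'
#' The classical baseline and the initializer of the multi-prior method:
#' interpolate across the metal trace, reconstruct by FBP, and (when the
#' uncorrected reconstruction and the metal mask are supplied) re-insert the
#' metal pixels into the displayed image.
#'
#' @param p0 Original post-log `sinogram`.
#' @param trace A `metal_trace`.
#' @param uncorrected Optional uncorrected reconstruction (`image2d`) used
#'   for metal re-insertion.
#' @param metal Optional logical metal mask on the image grid.
#' @param filter FBP apodization, see [fbp_reconstruct()].
#' @return A `mar_result`.
#' @export
lin_mar <- function(p0, trace, uncorrected = NULL, metal = NULL,
                    filter = "hann") {
  corrected <- interpolate_trace(p0, trace)
  img <- fbp_reconstruct(corrected, filter = filter)
  new_mar_result("lin", corrected, reinsert_metal(img, uncorrected, metal))
}

#' Sinogram basis from segmented subregions
#'
#' Forward-projects each exclusive subregion of a RAC [region_stack()] (unit
#' intensity inside the region, zero elsewhere); the projections `beta_j`
#' form the basis that models the measured sinogram as `sum_j d_j beta_j`.
#' Pixels under the segmented metal are attributed to the outermost
#' subregion: the basis must model the tissue the implant displaced, since
#' rays through those pixels are exactly the ones being re-estimated and a
#' hole there cannot be repaired by boundary interpolation.
#'
#' @param stack A `region_stack` with at least one region.
#' @param geom A `fan_geometry`.
#' @param pitch Image pixel pitch in mm.
#' @param metal Optional logical metal mask added to the outermost region.
#' @return A `prior_basis`: list of basis sinogram matrices plus the stack.
#' @export
build_prior_basis <- function(stack, geom, pitch, metal = NULL) {
  stopifnot(inherits(stack, "region_stack"))
  if (stack$n_regions == 0)
    stop("region stack is empty (N = 0); fall back to lin_mar()")
  parts <- region_partition(stack)
  if (!is.null(metal)) parts[[1]] <- parts[[1]] | (metal & !stack$masks[[1]])
  basis <- lapply(parts, function(m) {
    forward_project(image2d(m * 1, pitch), geom)$values
  })
  structure(list(basis = basis, stack = stack), class = "prior_basis")
}

# Outward one-sided channel-direction finite differences of a sinogram at
# the trace-boundary samples; differences that would touch a trace channel
# are zeroed so corrupt data never enters the fit.
boundary_gradient <- function(v, trace) {
  tr <- trace$mask
  nc <- ncol(v)
  idx <- which(trace$boundary, arr.ind = TRUE)
  g <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]
    c <- idx[i, 2]
    if (c < nc && tr[r, c + 1]) {        # left boundary: trace to the right
      if (c > 1 && !tr[r, c - 1]) g[i] <- v[r, c] - v[r, c - 1]
    } else if (c > 1 && tr[r, c - 1]) {  # right boundary: trace to the left
      if (c < nc && !tr[r, c + 1]) g[i] <- v[r, c + 1] - v[r, c]
    }
  }
  g
}

#' Fit subregion coefficients to the measured sinogram
#'
#' Solves `min_{d >= 0} ||p0 - sum_j d_j beta_j||_{T_M^c} +
#' alpha ||grad p0 - sum_j d_j grad beta_j||_{dT_M}` by Nelder-Mead simplex
#' search on `u = log d` (which enforces nonnegativity), where the norms are
#' Euclidean, the first term runs over all samples outside the metal trace
#' and the second over channel-direction finite differences at the trace
#' boundary. The default initial guess is the nonnegative least-squares
#' solution; the multi-prior pipeline passes the mean image value of each
#' subregion instead.
#'
#' @param p0 Measured `sinogram`.
#' @param basis A `prior_basis`.
#' @param trace A `metal_trace`.
#' @param alpha Boundary-smoothness weight (default 0.1).
#' @param init Optional initial coefficients (length N).
#' @param maxit Simplex iteration cap (default `200 * N`, restarted once
#'   from the best vertex).
#' @param reltol Simplex relative convergence tolerance.
#' @return A `coefficient_fit`: fitted `d`, objective value, evaluation
#'   counts, `init`, and a `converged` flag.
#' @export
fit_coefficients <- function(p0, basis, trace, alpha = 0.1, init = NULL,
                             maxit = NULL, reltol = 1e-10) {
  stopifnot(inherits(p0, "sinogram"), inherits(basis, "prior_basis"),
            alpha > 0)
  N <- length(basis$basis)
  off <- !trace$mask
  B <- vapply(basis$basis, function(b) b[off], numeric(sum(off)))
  y <- p0$values[off]
  g0 <- boundary_gradient(p0$values, trace)
  Gb <- vapply(basis$basis, function(b) boundary_gradient(b, trace),
               numeric(length(g0)))
  if (length(g0) == 0) {
    Gb <- matrix(0, 1, N)
    g0 <- 0
  }
  obj <- function(d) {
    sqrt(sum((y - B %*% d)^2)) + alpha * sqrt(sum((g0 - Gb %*% d)^2))
  }
  if (is.null(init)) {
    ls <- tryCatch(qr.solve(crossprod(B), crossprod(B, y)),
                   error = function(e) rep(mean(y) / max(rowSums(B), 1), N))
    init <- pmax(as.numeric(ls), 1e-4)
  }
  init <- pmax(init, 1e-6)
  if (is.null(maxit)) maxit <- 200L * N
  fn <- function(u) obj(exp(u))
  run <- function(par) {
    if (N == 1) # simplex degenerates in 1-D; use bounded Brent instead
      stats::optim(par, fn, method = "Brent", lower = log(1e-8),
                   upper = log(1e3), control = list(maxit = maxit))
    else
      stats::optim(par, fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
  }
  o1 <- run(log(init))
  o2 <- run(o1$par)
  best <- if (o2$value <= o1$value) o2 else o1
  structure(list(d = exp(best$par), objective = best$value,
                 evaluations = o1$counts[1] + o2$counts[1],
                 init = init,
                 converged = best$convergence == 0),
            class = "coefficient_fit")
}

#' @export
print.coefficient_fit <- function(x, ...) {
  cat(sprintf("<coefficient_fit> d = (%s), objective %.6g%s\n",
              paste(signif(x$d, 4), collapse = ", "), x$objective,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

combine_basis <- function(basis, d) {
  Reduce(`+`, Map(function(b, w) b * w, basis$basis, as.list(d)))
}

#' Residual-error compensation inside the metal trace
#'
#' Computes the residual `delta = p0 - p_hat`, fills its metal trace by
#' linear interpolation, and returns `p_hat + delta_hat`. Because
#' `delta_hat` equals `delta` outside the trace, the result coincides with
#' the original sinogram on the trace complement exactly (enforced
#' bit-for-bit).
#'
#' @param p0 Measured `sinogram`.
#' @param p_hat Linearly combined prior sinogram (`sinogram` or matrix).
#' @param trace A `metal_trace`.
#' @return A `sinogram`.
#' @export
residual_compensation <- function(p0, p_hat, trace) {
  ph <- if (inherits(p_hat, "sinogram")) p_hat$values else p_hat
  if (!all(dim(ph) == dim(p0$values))) stop("sinogram shape mismatch")
  delta <- p0$values - ph
  dhat <- interpolate_trace(sinogram(delta, p0$geom), trace)$values
  out <- ph + dhat
  out[!trace$mask] <- p0$values[!trace$mask]
  sinogram(out, p0$geom)
}

#' Multi-prior MAR with residual-error compensation
#'
#' The three-step iterative correction. Step 1 reconstructs the uncorrected
#' image, segments the metal, and builds the initial corrected image by
#' [lin_mar()]. Step 2 partitions the current corrected image into N
#' subregions by [rac_segment()], forward-projects them into a sinogram
#' basis, and fits nonnegative coefficients with [fit_coefficients()]
#' (initialized at the subregion means). Step 3 replaces the metal trace by
#' the combined prior sinogram plus a trace-interpolated copy of the
#' residual `delta = p0 - p_hat` ([residual_compensation()]) and
#' reconstructs. Steps 2-3 repeat until the residual norm over the trace
#' complement drops below `tau = tau_frac` times its first-iteration value,
#' stops improving (no 1% decrease over the best value for three
#' consecutive iterations — with noisy data the norm settles at the noise
#' floor and oscillates), or `max_outer` is reached. The state of the best
#' iteration (smallest residual norm) is returned, with the segmented metal
#' pixels re-inserted from the uncorrected reconstruction.
#'
#' @param p0 Measured post-log `sinogram`.
#' @param trace A `metal_trace` (from the segmented metal); if `NULL` it is
#'   derived from `metal`.
#' @param mu RAC regularization weight.
#' @param alpha Boundary-smoothness weight of the coefficient fit.
#' @param tau_frac Stopping tolerance as a fraction of the first residual
#'   norm (default 0.10).
#' @param max_outer Outer-iteration cap.
#' @param metal Optional logical metal mask; segmented from the uncorrected
#'   reconstruction when missing.
#' @param filter FBP apodization.
#' @param rac_args Extra arguments passed to [rac_segment()].
#' @param verbose Print per-iteration diagnostics.
#' @return A `mar_result` with the corrected sinogram, final image (metal
#'   re-inserted), last fit and region stack, residual-norm history,
#'   iteration count and `tau`.
#' @export
proposed_mar <- function(p0, trace = NULL, mu = 0.1, alpha = 0.1,
                         tau_frac = 0.10, max_outer = 50, metal = NULL,
                         filter = "hann", rac_args = list(),
                         verbose = FALSE) {
  stopifnot(inherits(p0, "sinogram"), tau_frac > 0)
  geom <- p0$geom
  uncorrected <- fbp_reconstruct(p0, filter = filter)
  if (is.null(metal)) metal <- segment_metal(uncorrected)
  if (is.null(trace)) trace <- metal_trace(metal, geom, pitch = uncorrected$pitch)
  if (!any(trace$mask))
    return(new_mar_result("proposed", p0, uncorrected,
                          flags = "no_metal", tau = NA_real_))
  lin <- lin_mar(p0, trace, filter = filter)
  f_img <- lin$image
  resid <- numeric(0)
  tau <- NA_real_
  flags <- character(0)
  stack <- NULL
  fit <- NULL
  corrected <- lin$sinogram
  d_history <- list()
  best <- NULL
  stale <- 0L
  k <- 0L
  while (k < max_outer) {
    k <- k + 1L
    stack <- do.call(rac_segment,
                     c(list(f_img, mu = mu, exclude = metal), rac_args))
    if (stack$n_regions == 0) {
      flags <- c(flags, "lin_fallback")
      res <- lin_mar(p0, trace, uncorrected, metal, filter = filter)
      res$flags <- flags
      res$method <- "proposed"
      return(res)
    }
    basis <- build_prior_basis(stack, geom, f_img$pitch, metal = metal)
    fit <- fit_coefficients(p0, basis, trace, alpha = alpha,
                            init = region_means(stack, f_img, exclude = metal))
    d_history[[k]] <- fit$d
    p_hat <- combine_basis(basis, fit$d)
    rn <- sqrt(sum((p0$values - p_hat)[!trace$mask]^2))
    resid[k] <- rn
    if (k == 1L) tau <- tau_frac * rn
    corrected <- residual_compensation(p0, p_hat, trace)
    f_img <- fbp_reconstruct(corrected, filter = filter)
    if (verbose)
      message(sprintf("iter %d: N = %d, ||delta|| = %.5g (tau = %.5g), d = %s",
                      k, stack$n_regions, rn, tau,
                      paste(signif(fit$d, 3), collapse = " ")))
    if (is.null(best) || rn < 0.99 * best$rn) {
      best <- list(rn = rn, corrected = corrected, f_img = f_img,
                   stack = stack, fit = fit, k = k)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (rn <= tau) {
      flags <- c(flags, "converged")
      break
    }
    if (stale >= 3L) {
      flags <- c(flags, "stagnated")
      break
    }
  }
  new_mar_result("proposed", best$corrected,
                 reinsert_metal(best$f_img, uncorrected, metal),
                 fit = best$fit, residual_norms = resid, iterations = k,
                 tau = tau, flags = flags, stack = best$stack,
                 d_history = d_history, image_no_metal = best$f_img,
                 uncorrected = uncorrected, metal = metal,
                 best_iteration = best$k)
}

#' Normalized MAR (NMAR)
#'
#' Divides the measured sinogram by the forward projection of a prior image
#' (plus a small guard), interpolates the normalized sinogram across the
#' metal trace, and multiplies the prior projection back. Non-trace samples
#' are restored to the measured values exactly. Trace runs over which the
#' prior projection is essentially zero fall back to plain interpolation of
#' the unnormalized data (with a warning), which is the failure mode of
#' surface metals.
#'
#' @param p0 Measured `sinogram`.
#' @param trace A `metal_trace`.
#' @param prior Prior image (`image2d`, attenuation) whose forward
#'   projection normalizes the sinogram. See [prior_threshold()] and
#'   [prior_from_stack()].
#' @param eps_frac Guard, as a fraction of the maximum prior projection.
#' @param uncorrected,metal Optional, for metal re-insertion.
#' @param filter FBP apodization.
#' @param method Label stored in the result.
#' @return A `mar_result`.
#' @export
nmar <- function(p0, trace, prior, eps_frac = 1e-6, uncorrected = NULL,
                 metal = NULL, filter = "hann", method = "nmar") {
  stopifnot(inherits(p0, "sinogram"), inherits(prior, "image2d"))
  pp <- forward_project(prior, p0$geom)$values
  eps <- eps_frac * max(max(pp), 1e-12)
  pn <- p0$values / (pp + eps)
  pni <- interpolate_trace(sinogram(pn, p0$geom), trace)$values
  out <- pni * (pp + eps)
  # degenerate runs: prior projection ~ 0 across a whole run
  tr <- trace$mask
  bad <- FALSE
  lin_fill <- NULL
  for (r in which(rowSums(tr) > 0)) {
    runs <- rle(tr[r, ])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (j in which(runs$values)) {
      sel <- starts[j]:ends[j]
      if (max(pp[r, sel]) < 10 * eps) {
        if (is.null(lin_fill))
          lin_fill <- interpolate_trace(p0, trace)$values
        out[r, sel] <- lin_fill[r, sel]
        bad <- TRUE
      }
    }
  }
  if (bad)
    warning("prior projection vanished across some trace runs; ",
            "used unnormalized interpolation there")
  out[!tr] <- p0$values[!tr]
  corrected <- sinogram(out, p0$geom)
  img <- fbp_reconstruct(corrected, filter = filter)
  new_mar_result(method, corrected, reinsert_metal(img, uncorrected, metal),
                 prior = prior)
}

#' Threshold prior image
#'
#' Classifies a pre-corrected reconstruction into air / soft-tissue /
#' transitional / bone classes by fixed attenuation thresholds and assigns
#' each class its mean attenuation. Defaults place the class boundaries at
#' 0, 0.028 and 0.040 1/mm (0, 0.28 and 0.4 1/cm). Metal pixels are
#' assigned to the first tissue class.
#'
#' @param image Pre-corrected `image2d` (attenuation).
#' @param thresholds Ascending class boundaries in 1/mm.
#' @param metal Optional logical metal mask.
#' @return List: `prior` (`image2d`), class means `d`, class count `N`.
#' @export
prior_threshold <- function(image, thresholds = c(0, 0.028, 0.040),
                            metal = NULL) {
  stopifnot(inherits(image, "image2d"))
  v <- image$values
  use <- if (is.null(metal)) matrix(TRUE, nrow(v), ncol(v)) else !metal
  cls <- findInterval(v, thresholds)  # 0 = air (<= 0), 1..K tissue classes
  K <- length(thresholds)
  means <- numeric(K)
  pv <- matrix(0, nrow(v), ncol(v))
  for (k in seq_len(K)) {
    m <- cls == k & use
    means[k] <- if (sum(m) > 0) mean(v[m]) else 0
    pv[cls == k] <- means[k]
  }
  if (!is.null(metal)) pv[metal] <- means[1]
  list(prior = image2d(pv, image$pitch), d = means[means > 0],
       N = sum(means > 0))
}

#' Segmentation prior image from a region stack
#'
#' Builds a piecewise-constant prior: each exclusive RAC subregion gets its
#' mean value in the source image; pixels outside the object are zero and
#' metal pixels take the outermost (soft tissue) region's mean.
#'
#' @param stack A `region_stack`.
#' @param image The image the stack was derived from.
#' @param metal Optional logical metal mask.
#' @return List: `prior` (`image2d`), coefficients `d` (region means),
#'   region count `N`.
#' @export
prior_from_stack <- function(stack, image, metal = NULL) {
  stopifnot(inherits(image, "image2d"))
  d <- region_means(stack, image, exclude = metal)
  parts <- region_partition(stack)
  pv <- matrix(0, nrow(image$values), ncol(image$values))
  for (j in seq_along(parts)) pv[parts[[j]]] <- d[j]
  if (!is.null(metal) && length(d) > 0) pv[metal] <- d[1]
  list(prior = image2d(pv, image$pitch), d = d, N = stack$n_regions)
}
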