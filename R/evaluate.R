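#' Metal-free reference reconstruction
#'
#' Drops the metal primitives from a phantom specification, simulates
#' noiseless polychromatic projections of the remaining tissues and bones,
#' and reconstructs. The reference therefore carries the same beam-hardening
#' signature as the measured data but no metal and no noise; it is the
#' ground truth for MSE evaluation. Deterministic.
#'
#' @param spec A `phantom_spec`.
#' @param spectrum A `spectrum`.
#' @param geom A `fan_geometry`.
#' @param filter FBP apodization.
#' @return An `image2d` (attenuation, 1/mm).
#' @export
reference_image <- function(spec, spectrum, geom, filter = "hann") {
  map <- rasterize(drop_metal(spec))
  fbp_reconstruct(polychromatic_sinogram(map, spectrum, geom),
                  filter = filter)
}

#' Mean squared error outside the metal region
#'
#' @param img,ref `image2d` objects on identical grids and with identical
#'   value semantics.
#' @param metal Logical matrix; `TRUE` pixels are excluded.
#' @return Mean of squared differences over non-metal pixels (HU^2 when the
#'   inputs are HU).
#' @export
mse_nonmetal <- function(img, ref, metal = NULL) {
  stopifnot(inherits(img, "image2d"), inherits(ref, "image2d"))
  if (!all(dim(img$values) == dim(ref$values)) || img$pitch != ref$pitch)
    stop("image grids do not match")
  if (img$semantics != ref$semantics)
    stop("image value semantics do not match")
  if (is.null(metal)) metal <- matrix(FALSE, nrow(img$values), ncol(img$values))
  mean((img$values - ref$values)[!metal]^2)
}

roi_mask <- function(img, roi) {
  n <- nrow(img$values)
  xy <- grid_coords(n, img$pitch)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  dx <- X - roi$center[1]
  dy <- Y - roi$center[2]
  if (roi$shape == "circle") {
    dx^2 + dy^2 <= roi$size[1]^2
  } else if (roi$shape == "rectangle") {
    abs(dx) <= roi$size[1] / 2 & abs(dy) <= roi$size[2] / 2
  } else stop("roi shape must be 'circle' or 'rectangle'")
}

#' Standard deviation over a region of interest
#'
#' Population standard deviation of the image values inside a rectangular or
#' circular ROI specified in mm.
#'
#' @param img An `image2d`.
#' @param roi List with `shape` (`"circle"` or `"rectangle"`), `center`
#'   (x, y in mm) and `size` (radius, or `c(w, h)`).
#' @return The population standard deviation (divisor `n`).
#' @export
roi_std <- function(img, roi) {
  stopifnot(inherits(img, "image2d"))
  m <- roi_mask(img, roi)
  if (sum(m) == 0) stop("ROI contains no pixels")
  x <- img$values[m]
  sqrt(mean((x - mean(x))^2))
}

#' Default study configuration
#'
#' @param phantoms Phantom names from [phantom_library()].
#' @param methods Methods to run, a subset of `uncorrected`, `lin`,
#'   `nmar_th`, `nmar_seg_s`, `nmar_seg_e`, `proposed`.
#' @param n_views,n_channels,n_pixels Sampling (defaults = [desk_geometry()]).
#' @param kvp Tube voltage.
#' @param photons Open-beam photons per detector cell (`NULL` = noiseless).
#' @param seed Base RNG seed.
#' @param mu,alpha,tau_frac,max_outer Algorithm parameters.
#' @return A named list usable as `run_study()` config.
#' @export
study_config <- function(phantoms = c("shepp_logan_metal", "jaw_like",
                                      "abdomen_like"),
                         methods = c("uncorrected", "lin", "nmar_th",
                                     "nmar_seg_s", "nmar_seg_e", "proposed"),
                         n_views = 360L, n_channels = 1024L, n_pixels = 256L,
                         kvp = 120, photons = 1e6, seed = 1L,
                         mu = 0.1, alpha = 0.1, tau_frac = 0.10,
                         max_outer = 8L) {
  list(phantoms = phantoms, methods = methods, n_views = n_views,
       n_channels = n_channels, n_pixels = n_pixels, kvp = kvp,
       photons = photons, seed = seed, mu = mu, alpha = alpha,
       tau_frac = tau_frac, max_outer = max_outer)
}

run_phantom <- function(name, cfg, spectrum, geom, verbose = FALSE) {
  spec <- phantom_library(name, n = geom$n_pixels, pitch = geom$pixel_pitch)
  map <- rasterize(spec)
  seed <- cfg$seed + match(name, cfg$phantoms, nomatch = 1L) - 1L
  p0 <- polychromatic_sinogram(map, spectrum, geom,
                               photons_per_cell = cfg$photons, seed = seed)
  uncorr <- fbp_reconstruct(p0)
  metal <- segment_metal(uncorr)
  trace <- metal_trace(metal, geom, pitch = uncorr$pitch)
  ref <- reference_image(spec, spectrum, geom)
  mu_w <- mu_water_at(spectrum)
  hu <- function(img) to_hu(img, mu_w)
  mse <- function(img) mse_nonmetal(hu(img), hu(ref), metal)

  out <- list(phantom = name, seed = seed, metal_px = sum(metal),
              trace_frac = mean(trace$mask), results = list())
  lin <- prop <- NULL
  need_lin <- any(c("lin", "nmar_th", "nmar_seg_s") %in% cfg$methods)
  need_prop <- any(c("proposed", "nmar_seg_e") %in% cfg$methods)
  if (need_lin || need_prop)
    lin <- lin_mar(p0, trace, uncorr, metal)
  if (need_prop)
    prop <- proposed_mar(p0, trace, mu = cfg$mu, alpha = cfg$alpha,
                         tau_frac = cfg$tau_frac, max_outer = cfg$max_outer,
                         metal = metal, verbose = verbose)
  for (m in cfg$methods) {
    rec <- switch(m,
      uncorrected = list(image = uncorr, N = NA, d = NULL, iterations = 0),
      lin = list(image = lin$image, N = NA, d = NULL, iterations = 0),
      proposed = list(image = prop$image,
                      N = if (is.null(prop$stack)) 0 else prop$stack$n_regions,
                      d = if (is.null(prop$fit)) NULL else prop$fit$d,
                      iterations = prop$iterations),
      nmar_th = {
        pr <- prior_threshold(lin$image, metal = metal)
        r <- nmar(p0, trace, pr$prior, uncorrected = uncorr, metal = metal,
                  method = "nmar_th")
        list(image = r$image, N = pr$N, d = pr$d, iterations = 0)
      },
      nmar_seg_s = {
        st <- rac_segment(lin$image, mu = cfg$mu, exclude = metal)
        pr <- prior_from_stack(st, lin$image, metal = metal)
        r <- nmar(p0, trace, pr$prior, uncorrected = uncorr, metal = metal,
                  method = "nmar_seg_s")
        list(image = r$image, N = pr$N, d = pr$d, iterations = 0)
      },
      nmar_seg_e = {
        src <- if (!is.null(prop$image_no_metal)) prop$image_no_metal
               else lin$image
        st <- rac_segment(src, mu = cfg$mu, exclude = metal)
        pr <- prior_from_stack(st, src, metal = metal)
        r <- nmar(p0, trace, pr$prior, uncorrected = uncorr, metal = metal,
                  method = "nmar_seg_e")
        list(image = r$image, N = pr$N, d = pr$d, iterations = 0)
      },
      stop("unknown method '", m, "'"))
    rec$mse <- mse(rec$image)
    out$results[[m]] <- rec
  }
  out$proposed_detail <- if (!is.null(prop))
    list(residual_norms = prop$residual_norms, tau = prop$tau,
         flags = prop$flags, d_history = prop$d_history)
  out
}

#' Run the full simulation study
#'
#' Executes the end-to-end pipeline (phantom -> polychromatic noisy sinogram
#' -> metal segmentation -> every requested MAR method -> MSE in HU against
#' the metal-free polychromatic reference) for each configured phantom.
#' Fully reproducible given the seed. If a stage fails for one phantom the
#' report carries the failure record and the remaining phantoms still run.
#'
#' @param config A config list (see [study_config()]) or the path of a YAML
#'   file holding one.
#' @param out_dir Optional directory; when given, the MSE table is written
#'   as CSV and the full report as JSON.
#' @param verbose Print per-iteration diagnostics of the multi-prior method.
#' @return An `experiment_report`: `mse` data frame (phantom x method),
#'   per-phantom detail, config snapshot.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(study_config(), config)
  spectrum <- load_spectrum(cfg$kvp)
  geom <- fan_geometry(n_channels = cfg$n_channels,
                       channel_pitch = 0.388 * 1024 / cfg$n_channels,
                       n_views = cfg$n_views, n_pixels = cfg$n_pixels,
                       pixel_pitch = 102.4 / cfg$n_pixels)
  detail <- list()
  rows <- list()
  failures <- list()
  for (ph in cfg$phantoms) {
    res <- tryCatch(run_phantom(ph, cfg, spectrum, geom, verbose = verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ph]] <- conditionMessage(res)
      next
    }
    detail[[ph]] <- res
    for (m in names(res$results))
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = ph, method = m, mse_hu2 = res$results[[m]]$mse,
        N = res$results[[m]]$N, iterations = res$results[[m]]$iterations)
  }
  mse <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phantom = character(0), method = character(0),
               mse_hu2 = numeric(0), N = numeric(0), iterations = numeric(0))
  report <- structure(list(mse = mse, detail = detail, failures = failures,
                           config = cfg, units = "HU^2"),
                      class = "experiment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(mse, file.path(out_dir, "mse.csv"), row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(report) {
  list(units = report$units, config = report$config,
       mse = report$mse, failures = report$failures,
       detail = lapply(report$detail, function(ph) {
         list(phantom = ph$phantom, seed = ph$seed, metal_px = ph$metal_px,
              trace_frac = ph$trace_frac,
              methods = lapply(ph$results, function(r) {
                r[c("mse", "N", "d", "iterations")]
              }),
              proposed = ph$proposed_detail)
       }))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> MSE (", x$units, ", metal excluded):\n", sep = "")
  if (nrow(x$mse)) {
    wide <- stats::reshape(x$mse[, c("phantom", "method", "mse_hu2")],
                           idvar = "phantom", timevar = "method",
                           direction = "wide")
    names(wide) <- sub("^mse_hu2\\.", "", names(wide))
    print(wide, row.names = FALSE, digits = 4)
  }
  if (length(x$failures))
    cat("failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
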