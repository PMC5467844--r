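toy_trace <- function(mask, geom) {
  structure(list(mask = mask, boundary = ctmar:::trace_boundary(mask),
                 geom = geom), class = "metal_trace")
}

test_that("trace interpolation is exact on linear data and leaves measurements alone", {
  g <- fan_geometry(n_channels = 16L, n_views = 4L)
  set.seed(9)
  v <- matrix(rnorm(64), 4, 16)
  tr0 <- toy_trace(matrix(FALSE, 4, 16), g)
  expect_identical(interpolate_trace(sinogram(v, g), tr0)$values, v)

  # linear row with an interior gap is recovered to machine precision
  lin <- matrix(rep(seq(0, 3, length.out = 16), each = 4), 4, 16)
  mask <- matrix(FALSE, 4, 16)
  mask[, 6:9] <- TRUE
  tr <- toy_trace(mask, g)
  out <- interpolate_trace(sinogram(lin, g), tr)$values
  expect_equal(out, lin, tolerance = 1e-12)

  # off-trace samples are bit-for-bit untouched
  out2 <- interpolate_trace(sinogram(v, g), tr)$values
  expect_identical(out2[!mask], v[!mask])

  # border run clamps to the nearest measured value
  mask_b <- matrix(FALSE, 4, 16)
  mask_b[, 1:3] <- TRUE
  out3 <- interpolate_trace(sinogram(v, g), toy_trace(mask_b, g))$values
  expect_true(all(out3[, 1:3] == out3[, 4]))
})

test_that("residual compensation restores measurements exactly off-trace", {
  g <- fan_geometry(n_channels = 5L, n_views = 1L)
  p0 <- sinogram(matrix(c(4, 5, 9, 7, 6), 1), g)
  ph <- sinogram(matrix(c(4, 5, 6, 7, 6), 1), g)
  mask <- matrix(c(FALSE, FALSE, TRUE, FALSE, FALSE), 1)
  tr <- toy_trace(mask, g)

  # hand-computed: delta = (0,0,.,0,0); interpolated across the gap -> 0
  out <- residual_compensation(p0, ph, tr)
  expect_identical(out$values, ph$values)

  # p_hat = p0: output is p0 everywhere
  expect_identical(residual_compensation(p0, p0, tr)$values, p0$values)

  # arbitrary inputs: off-trace equals p0 bit-for-bit
  set.seed(2)
  g2 <- fan_geometry(n_channels = 32L, n_views = 6L)
  v0 <- matrix(rnorm(192), 6)
  vh <- matrix(rnorm(192), 6)
  m2 <- matrix(FALSE, 6, 32)
  m2[, 10:14] <- TRUE
  m2[3, 20:22] <- TRUE
  tr2 <- toy_trace(m2, g2)
  out2 <- residual_compensation(sinogram(v0, g2), sinogram(vh, g2), tr2)
  expect_identical(out2$values[!m2], v0[!m2])
})

test_that("prior basis projects exclusive subregions and refuses empty stacks", {
  g <- small_geom()
  empty <- structure(list(masks = list(), n_regions = 0L,
                          fills = numeric(0), mu = 0.1),
                     class = "region_stack")
  expect_error(build_prior_basis(empty, g, 1.6), "N = 0")

  # single full-disk prior: beta_1 is the chord-length sinogram of the disk
  disk <- rasterize(phantom_spec(list(primitive("circle", c(0, 0), 20,
                                               material = "water")),
                                 n = 64, pitch = 1.6))$labels > 0
  st1 <- structure(list(masks = list(disk), n_regions = 1L, fills = 0,
                        mu = 0.1), class = "region_stack")
  b1 <- build_prior_basis(st1, g, 1.6)
  chord <- forward_project(image2d(disk * 1, 1.6), g)$values
  expect_equal(b1$basis[[1]], chord)
  expect_equal(max(b1$basis[[1]]), 2 * 20, tolerance = 0.02)
  expect_true(all(b1$basis[[1]] >= 0))

  # nested mask projections are pointwise ordered
  inner <- rasterize(phantom_spec(list(primitive("circle", c(2, 1), 9,
                                                material = "water")),
                                  n = 64, pitch = 1.6))$labels > 0
  bo <- forward_project(image2d(disk * 1, 1.6), g)$values
  bi <- forward_project(image2d(inner * 1, 1.6), g)$values
  expect_true(all(bo - bi >= -1e-9))
})

test_that("coefficient fitting recovers exact representations", {
  g <- small_geom()
  disk <- rasterize(phantom_spec(list(primitive("circle", c(0, 0), 20,
                                               material = "water")),
                                 n = 64, pitch = 1.6))$labels > 0
  st1 <- structure(list(masks = list(disk), n_regions = 1L, fills = 0,
                        mu = 0.1), class = "region_stack")
  basis <- build_prior_basis(st1, g, 1.6)
  p0 <- sinogram(0.37 * basis$basis[[1]], g)
  mask <- matrix(FALSE, g$n_views, g$n_channels)
  mask[, 120:136] <- TRUE
  tr <- toy_trace(mask, g)
  fit <- fit_coefficients(p0, basis, tr)
  expect_equal(fit$d, 0.37, tolerance = 1e-6)
  expect_true(all(fit$d >= 0))
})

test_that("NMAR is exact when the prior explains the data", {
  g <- small_geom()
  spec <- phantom_spec(list(primitive("circle", c(0, 0), 24,
                                      material = "muscle")),
                       n = 64, pitch = 1.6)
  prior <- mu_image(rasterize(spec), 60)
  p0 <- forward_project(prior, g)
  mask <- matrix(FALSE, g$n_views, g$n_channels)
  mask[, 124:132] <- TRUE
  tr <- toy_trace(mask, g)
  out <- nmar(p0, tr, prior)
  expect_identical(out$sinogram$values[!mask], p0$values[!mask])
  expect_lt(max(abs(out$sinogram$values - p0$values)) / max(p0$values), 1e-4)
})

test_that("a trace covering a whole view clamps with a warning", {
  g <- fan_geometry(n_channels = 8L, n_views = 2L)
  v <- matrix(rnorm(16), 2, 8)
  mask <- matrix(FALSE, 2, 8)
  mask[1, ] <- TRUE
  tr <- toy_trace(mask, g)
  expect_warning(out <- interpolate_trace(sinogram(v, g), tr), "whole row")
  expect_identical(out$values, v)
})

test_that("the outer loop returns its best state with nonnegative weights", {
  n <- 128
  geom <- fan_geometry(n_channels = 512, channel_pitch = 0.776,
                       n_views = 180, n_pixels = n, pixel_pitch = 102.4 / n)
  map <- rasterize(ideal_phantom_spec(n))
  p0 <- polychromatic_sinogram(map, monochromatic(60), geom)
  un <- fbp_reconstruct(p0)
  metal <- segment_metal(un)
  trace <- metal_trace(metal, geom, pitch = un$pitch)
  res <- proposed_mar(p0, trace, metal = metal, max_outer = 6)
  expect_true(all(res$fit$d >= 0))
  # the returned state is never worse than the first iteration and is
  # within 1% of the smallest residual seen
  expect_lte(res$residual_norms[res$best_iteration], res$residual_norms[1])
  expect_lte(res$residual_norms[res$best_iteration],
             1.01 * min(res$residual_norms))
  expect_true(any(c("converged", "stagnated") %in% res$flags) ||
                res$iterations == 6L)
})

test_that("metal-free inputs pass through LIN and the multi-prior method", {
  g <- small_geom()
  spec <- phantom_spec(list(primitive("circle", c(0, 0), 24,
                                      material = "muscle")),
                       n = 64, pitch = 1.6)
  p0 <- forward_project(mu_image(rasterize(spec), 60), g)
  tr0 <- toy_trace(matrix(FALSE, g$n_views, g$n_channels), g)
  lin <- lin_mar(p0, tr0)
  expect_identical(lin$sinogram$values, p0$values)
  expect_equal(lin$image$values, fbp_reconstruct(p0)$values)

  prop <- proposed_mar(p0, tr0)
  expect_identical(prop$iterations, 0L)
  expect_true("no_metal" %in% prop$flags)
  expect_equal(prop$image$values, fbp_reconstruct(p0)$values)
})
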