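test_that("forward projection reproduces analytic disk chords and is linear", {
  g <- small_geom()
  zero <- forward_project(image2d(matrix(0, 64, 64), 1.6), g)
  expect_true(all(zero$values == 0))

  # centred disk: central ray line integral = 2 r mu
  gd <- fan_geometry(n_channels = 256, channel_pitch = 0.776, n_views = 8,
                     n_pixels = 64, pixel_pitch = 0.2)
  spec <- phantom_spec(list(primitive("circle", c(0, 0), 2,
                                      material = "water")),
                       n = 64, pitch = 0.2)
  img <- image2d((rasterize(spec)$labels > 0) * 0.02, 0.2)
  s <- forward_project(img, gd)
  expect_equal(apply(s$values, 1, max), rep(2 * 2 * 0.02, 8),
               tolerance = 0.01)

  # linearity to near machine precision
  set.seed(3)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  ra <- forward_project(image2d(a, 1.6), g)$values
  rb <- forward_project(image2d(b, 1.6), g)$values
  rab <- forward_project(image2d(2.5 * a - 0.5 * b, 1.6), g)$values
  expect_lt(max(abs(rab - (2.5 * ra - 0.5 * rb))) / max(abs(rab)), 1e-10)

  expect_error(forward_project(to_hu(image2d(a, 1.6), 0.02), g),
               "attenuation")
})

test_that("backprojection is the exact adjoint of the projector", {
  g <- small_geom()
  set.seed(4)
  f <- matrix(runif(64 * 64), 64)
  s <- matrix(runif(g$n_views * g$n_channels), g$n_views)
  lhs <- sum(forward_project(image2d(f, 1.6), g)$values * s)
  rhs <- sum(f * unfiltered_backproject(sinogram(s, g))$values)
  expect_equal(lhs, rhs, tolerance = 1e-2 * abs(lhs))
})

test_that("polychromatic synthesis reduces to Beer-Lambert and hardens beams", {
  g <- small_geom()
  spec <- phantom_spec(list(
    primitive("circle", c(-10, 0), 12, material = "water"),
    primitive("circle", c(12, 4), 8, material = "bone_cortical")),
    n = 64, pitch = 1.6)
  map <- rasterize(spec)

  # monochromatic spectrum: identical to projecting the mono attenuation map
  p_mono <- polychromatic_sinogram(map, monochromatic(60), g)
  p_ref <- forward_project(mu_image(map, 60), g)
  expect_lt(max(abs(p_mono$values - p_ref$values)), 1e-10)

  # open beam with noise: post-log mean 0 within 3 sigma / sqrt(n)
  air <- rasterize(phantom_spec(list(), n = 64, pitch = 1.6))
  open <- polychromatic_sinogram(air, fx_spectrum(), g,
                                 photons_per_cell = 1e6, seed = 5)
  n <- length(open$values)
  expect_lt(abs(mean(open$values)), 3 / sqrt(1e6) / sqrt(n) * 5)

  # beam hardening: doubling the water path less than doubles the post-log
  w1 <- rasterize(phantom_spec(list(primitive("circle", c(0, 0), 10,
                                              material = "water")),
                               n = 64, pitch = 1.6))
  w2 <- rasterize(phantom_spec(list(primitive("circle", c(0, 0), 20,
                                              material = "water")),
                               n = 64, pitch = 1.6))
  v1 <- max(polychromatic_sinogram(w1, fx_spectrum(), g)$values)
  v2 <- max(polychromatic_sinogram(w2, fx_spectrum(), g)$values)
  expect_lt(v2, 2 * v1)
})

test_that("noise realizations are seed-reproducible and always finite", {
  g <- small_geom()
  spec <- phantom_spec(list(
    primitive("circle", c(0, 0), 20, material = "water"),
    primitive("rectangle", c(0, 0), c(4, 4), material = "gold")),
    n = 64, pitch = 1.6)
  map <- rasterize(spec)
  a <- polychromatic_sinogram(map, fx_spectrum(), g,
                              photons_per_cell = 1e6, seed = 11)
  b <- polychromatic_sinogram(map, fx_spectrum(), g,
                              photons_per_cell = 1e6, seed = 11)
  c <- polychromatic_sinogram(map, fx_spectrum(), g,
                              photons_per_cell = 1e6, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_true(all(is.finite(a$values))) # photon clamp bounds rays through gold
  expect_lte(max(a$values), log(1e6) + 1e-9)
})

test_that("FBP reconstructs uniform and structured phantoms quantitatively", {
  g <- desk_geometry()
  zero <- fbp_reconstruct(sinogram(matrix(0, g$n_views, g$n_channels), g))
  expect_true(all(zero$values == 0))

  spec <- phantom_spec(list(primitive("circle", c(0, 0), 30,
                                      material = "water")),
                       n = 256, pitch = 0.4)
  img <- mu_image(rasterize(spec), 60)
  rec <- fbp_reconstruct(forward_project(img, g))
  xy <- (seq_len(256) - 1 - 127.5) * 0.4
  r2 <- outer(xy^2, rep(1, 256)) + outer(rep(1, 256), xy^2)
  inner <- r2 <= (30 - 2 * 0.4)^2
  mu <- max(img$values)
  expect_lt(max(abs(rec$values[inner] - mu)) / mu, 0.02)

  sl <- drop_metal(phantom_library("shepp_logan_metal", n = 256))
  truth <- mu_image(rasterize(sl), 60)
  rec2 <- fbp_reconstruct(forward_project(truth, g))
  skull <- (outer(xy^2, rep(1, 256)) / (0.65 * 50)^2 +
            outer(rep(1, 256), xy^2) / (0.88 * 50)^2) <= 1
  rel_rmse <- sqrt(mean((rec2$values[skull] - truth$values[skull])^2)) /
    diff(range(truth$values))
  expect_lt(rel_rmse, 0.05)

  g1 <- fan_geometry(n_views = 1)
  expect_error(fbp_reconstruct(sinogram(matrix(0, 1, g1$n_channels), g1)),
               "views")
})

test_that("metal traces cover exactly the rays that intersect metal", {
  g <- small_geom()
  empty <- metal_trace(matrix(FALSE, 64, 64), g, pitch = 1.6)
  expect_false(any(empty$mask))

  # single pixel at the isocenter: every view sees it at the central channel
  m <- matrix(FALSE, 64, 64)
  m[32, 32] <- TRUE # centre pixel (grid centre falls between 32 and 33)
  tr <- metal_trace(m, g, pitch = 1.6)
  centre <- (g$n_channels + 1) / 2
  for (v in seq_len(g$n_views)) {
    hit <- which(tr$mask[v, ])
    expect_true(length(hit) > 0 && min(abs(hit - centre)) <= 2)
  }

  # monotone in the mask
  m2 <- m
  m2[40, 20] <- TRUE
  tr2 <- metal_trace(m2, g, pitch = 1.6)
  expect_true(all(tr2$mask[tr$mask]))

  # boundary channels touch the trace but are never inside it
  expect_false(any(tr2$boundary & tr2$mask))
  nb <- ncol(tr2$mask)
  adj <- (tr2$boundary & cbind(tr2$mask[, -1], FALSE)) |
    (tr2$boundary & cbind(FALSE, tr2$mask[, -nb]))
  expect_true(all(adj[tr2$boundary]))
})
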