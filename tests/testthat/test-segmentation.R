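test_that("Chan-Vese separates piecewise-constant objects with monotone energy", {
  # constant image: degenerate, one region
  cv0 <- chan_vese(matrix(1, 32, 32))
  expect_true(cv0$degenerate)
  expect_true(all(cv0$mask))

  expect_error(chan_vese(matrix(c(1, NA, 1, 1), 2, 2)), "finite")

  # two disks on background: foreground = disk union
  spec <- phantom_library("two_disk_test", n = 128)
  img <- mu_image(rasterize(spec), 60)
  truth <- rasterize(spec)$labels > 0
  cv <- chan_vese(img, mu = 0.1)
  expect_energy_monotone(cv)
  expect_gte(dice(cv$mask, truth), 0.99)
  expect_gt(cv$c1, cv$c2)

  # idempotence at the fixpoint: restart from converged phi
  cv2 <- chan_vese(img, mu = 0.1, init = cv$phi)
  expect_energy_monotone(cv2)
  expect_lt(mean(cv2$mask != cv$mask), 0.001)
})

test_that("recursive segmentation finds nested tiers matching a threshold oracle", {
  # two-object image: N = 2, first mask both objects, second the brighter
  spec <- phantom_library("two_disk_test", n = 128)
  img <- mu_image(rasterize(spec), 60)
  st <- rac_segment(img)
  lab <- rasterize(spec)$labels
  expect_identical(st$n_regions, 2L)
  expect_gte(dice(st$masks[[1]], lab > 0), 0.99)
  expect_gte(dice(st$masks[[2]], lab == 2), 0.99)

  # constant image: nothing to segment
  expect_identical(rac_segment(matrix(2, 32, 32))$n_regions, 0L)

  # three nested intensity levels
  spec3 <- phantom_library("nested_levels_test", n = 128)
  img3 <- mu_image(rasterize(spec3), 60)
  st3 <- rac_segment(img3)
  lab3 <- rasterize(spec3)$labels
  expect_identical(st3$n_regions, 3L)
  for (j in 1:3) expect_gte(dice(st3$masks[[j]], lab3 >= j), 0.98)

  # nesting invariant and level cap
  for (st_i in list(st, st3)) {
    if (st_i$n_regions > 1)
      for (j in 2:st_i$n_regions)
        expect_true(all(st_i$masks[[j - 1]][st_i$masks[[j]]]))
    expect_lte(st_i$n_regions, 10)
  }

  # exclusive partition + region means recover the tier values
  mus <- attenuation("muscle", 60) * c(1, 1.8, 2.8)
  expect_equal(region_means(st3, img3), mus, tolerance = 0.02)
})

test_that("regularization weight controls segmentation sensitivity", {
  # background ramps up toward one object's intensity: small mu resolves
  # more tiers than large mu
  n <- 96
  ramp <- matrix(rep(seq(0, 0.02, length.out = n), each = n), n, n)
  obj <- matrix(0, n, n)
  obj[20:40, 30:60] <- 0.035
  obj[60:80, 30:60] <- 0.06
  img <- ramp + obj
  n_small <- rac_segment(img, mu = 0.01)$n_regions
  n_large <- rac_segment(img, mu = 1)$n_regions
  expect_gte(n_small, n_large)
  expect_gte(n_small, 2)
})

test_that("metal segmentation isolates implants and ignores metal-free images", {
  geom <- desk_geometry()
  spec <- phantom_library("shepp_logan_metal", n = geom$n_pixels,
                          pitch = geom$pixel_pitch)
  map <- rasterize(spec)
  p0 <- polychromatic_sinogram(map, fx_spectrum(), geom) # noiseless
  un <- fbp_reconstruct(p0)
  m <- segment_metal(un)
  truth <- metal_mask(map)
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)

  # metal-free image: empty mask
  ref <- reference_image(spec, fx_spectrum(), geom)
  expect_false(any(segment_metal(ref)))

  # three separated implants: three connected components
  jaw <- rasterize(phantom_library("jaw_like", n = geom$n_pixels,
                                   pitch = geom$pixel_pitch))
  pj <- polychromatic_sinogram(jaw, fx_spectrum(), geom)
  mj <- segment_metal(fbp_reconstruct(pj))
  expect_identical(max(EBImage::bwlabel(mj * 1)), 3L)
})
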