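test_that("phantom library provides the documented specimens", {
  expect_error(phantom_library("nope"), "available")

  sl <- phantom_library("shepp_logan_metal", n = 128)
  gold <- Filter(function(p) p$material == "gold", sl$primitives)
  expect_length(gold, 2)
  expect_true(all(vapply(gold, function(p) p$shape, "") == "rectangle"))

  jaw <- phantom_library("jaw_like", n = 128)
  gold_j <- Filter(function(p) p$material == "gold", jaw$primitives)
  expect_length(gold_j, 3)
  expect_true(all(vapply(gold_j, function(p) p$shape, "") == "circle"))

  td <- phantom_library("two_disk_test", n = 64)
  expect_length(td$primitives, 2)
  sc <- vapply(td$primitives, function(p) p$scale, 0)
  expect_true(sc[1] != sc[2]) # distinct intensities

  expect_error(
    phantom_spec(list(primitive("circle", c(60, 0), 10, material = "water")),
                 n = 128, pitch = 0.8),
    "field of view")
})

test_that("rasterization follows painter's order and matches analytic areas", {
  empty <- rasterize(phantom_spec(list(), n = 32, pitch = 1))
  expect_true(all(empty$labels == 0L))

  r <- 20
  spec <- phantom_spec(list(primitive("circle", c(0, 0), r,
                                      material = "water")),
                       n = 256, pitch = 0.4)
  map <- rasterize(spec)
  expect_equal(sum(map$labels == 1L), pi * r^2 / 0.4^2, tolerance = 0.02)

  # overlap carries the later label
  spec2 <- phantom_spec(list(
    primitive("circle", c(0, 0), 10, material = "water"),
    primitive("rectangle", c(5, 0), c(10, 10), material = "muscle")),
    n = 64, pitch = 0.8)
  m2 <- rasterize(spec2)
  iy <- round((64 - 1) / 2) + 1
  ix_rect <- round(5 / 0.8 + (64 - 1) / 2) + 1   # overlap region
  ix_circ <- round(-5 / 0.8 + (64 - 1) / 2) + 1  # circle only
  expect_identical(m2$labels[ix_rect, iy], 2L)
  expect_identical(m2$labels[ix_circ, iy], 1L)

  # determinism: identical spec -> bit-identical map
  expect_identical(rasterize(spec2)$labels, m2$labels)
})

test_that("library phantom metal stays inside the object, off the border", {
  for (name in c("shepp_logan_metal", "jaw_like", "abdomen_like")) {
    map <- rasterize(phantom_library(name, n = 128))
    metal <- metal_mask(map)
    expect_true(sum(metal) > 0)
    expect_true(all(map$labels[metal] > 0))
    n <- nrow(metal)
    expect_false(any(metal[c(1, n), ]) || any(metal[, c(1, n)]))
    # strict subset of the object support
    expect_lt(sum(metal), sum(map$labels > 0))
  }
})

test_that("spectra are normalized and physically sensible", {
  mono <- monochromatic(70)
  expect_equal(mono$energy_kev, 70)
  expect_equal(mono$fluence, 1)

  s <- load_spectrum(120)
  expect_equal(sum(s$fluence), 1, tolerance = 1e-12)
  expect_lte(max(s$energy_kev), 120)
  expect_gt(mean_energy(s), 50)
  expect_lt(mean_energy(s), 75)

  expect_error(load_spectrum(-1))
  tmp <- tempfile(fileext = ".csv")
  writeLines("energy_kev,fluence\n60,-1", tmp)
  expect_error(load_spectrum(120, path = tmp), "positive")
})

test_that("attenuation lookup interpolates and refuses extrapolation", {
  expect_gt(attenuation("gold", 70), 10 * attenuation("bone_cortical", 70))
  expect_gt(attenuation("bone_cortical", 70), 2 * attenuation("muscle", 70))
  expect_gt(attenuation("water", 40), attenuation("water", 80))
  # exact at a tabulated grid point: water 60 keV, 0.2059 cm^2/g * 1 g/cm^3
  expect_equal(attenuation("water", 60), 0.02059, tolerance = 1e-12)
  expect_error(attenuation("water", 5), "range")
  expect_error(attenuation("kryptonite", 60), "unknown material")
  # monotone non-increasing for water/muscle over 30-120 keV
  for (m in c("water", "muscle"))
    expect_true(all(diff(attenuation(m, seq(30, 120, 5))) <= 0))
})

test_that("phantom specs survive a YAML round trip", {
  spec <- phantom_library("two_disk_test", n = 64)
  tmp <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, tmp)
  back <- read_phantom_spec(tmp)
  expect_identical(rasterize(back)$labels, rasterize(spec)$labels)
})
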