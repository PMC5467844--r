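# Shared fixtures, built lazily and cached for the session.
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small geometry: full 102.4 mm FOV at coarse sampling, fast enough for unit
# tests (a forward projection takes well under a second).
small_geom <- function(n_views = 72L, n_channels = 256L, n_pixels = 64L) {
  fan_geometry(n_channels = n_channels,
               channel_pitch = 0.388 * 1024 / n_channels,
               n_views = n_views, n_pixels = n_pixels,
               pixel_pitch = 102.4 / n_pixels)
}

fx_spectrum <- function() fx("spectrum", function() load_spectrum(120))

# Piecewise-constant phantom with a metal disk, used by the ideal-case
# (monochromatic, noiseless) equivalence and recovery tests.
ideal_phantom_spec <- function(n = 128L) {
  phantom_spec(list(
    primitive("circle", center = c(0, 0), size = 32, material = "muscle"),
    primitive("circle", center = c(6, -4), size = 14, material = "muscle",
              scale = 1.9),
    primitive("circle", center = c(-12, 8), size = 2.4, material = "gold")
  ), n = n, pitch = 102.4 / n)
}

# Desk-scale uncorrected Shepp-Logan pipeline state shared by several tests.
fx_sl_desk <- function() fx("sl_desk", function() {
  geom <- desk_geometry()
  spec <- phantom_library("shepp_logan_metal", n = geom$n_pixels,
                          pitch = geom$pixel_pitch)
  map <- rasterize(spec)
  p0 <- polychromatic_sinogram(map, fx_spectrum(), geom,
                               photons_per_cell = 1e6, seed = 101)
  uncorrected <- fbp_reconstruct(p0)
  metal <- segment_metal(uncorrected)
  trace <- metal_trace(metal, geom, pitch = uncorrected$pitch)
  list(geom = geom, spec = spec, map = map, p0 = p0,
       uncorrected = uncorrected, metal = metal, trace = trace)
})

# The full desk-scale comparison study (expensive; computed once at the
# package's default configuration and reused by the ranking and adaptivity
# tests).
fx_study <- function() fx("study", function() {
  run_study(study_config())
})

expect_energy_monotone <- function(cv) {
  if (length(cv$energy) > 1)
    expect_true(all(diff(cv$energy) <= 1e-8 * max(abs(cv$energy)) + 1e-8))
  invisible(cv)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
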