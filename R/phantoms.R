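#' Geometric primitive for a phantom
#'
#' @param shape One of `"ellipse"`, `"rectangle"`, `"circle"`.
#' @param center Length-2 centre (x, y) in mm, isocenter origin.
#' @param size For an ellipse the semi-axes `c(a, b)` in mm, for a rectangle
#'   the full side lengths `c(w, h)`, for a circle the radius.
#' @param rotation Rotation in degrees, counter-clockwise.
#' @param material Material name from [materials()].
#' @param scale Density scale factor: the primitive's attenuation is
#'   `scale * attenuation(material, E)` at every energy. This is the usual
#'   density-scaled-material device for building tissue variants.
#' @return A list describing the primitive.
#' @export
primitive <- function(shape = c("ellipse", "rectangle", "circle"),
                      center, size, rotation = 0, material, scale = 1) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2, scale > 0)
  size <- switch(shape,
    circle = {
      stopifnot(length(size) == 1, size > 0)
      c(size, size)
    },
    {
      stopifnot(length(size) == 2, all(size > 0))
      size
    })
  list(shape = shape, center = as.numeric(center), size = as.numeric(size),
       rotation = rotation, material = material, scale = scale)
}

#' Phantom specification
#'
#' An ordered list of primitives (painter's order: later primitives overwrite
#' earlier ones) plus the raster grid. Background is air.
#'
#' @param primitives List of [primitive()]s.
#' @param n Grid side length in pixels.
#' @param pitch Pixel size in mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, n = 512L, pitch = 0.2) {
  half <- n * pitch / 2
  for (p in primitives) {
    ext <- if (p$shape == "rectangle") sqrt(sum((p$size / 2)^2)) else max(p$size)
    if (any(abs(p$center) + ext > half))
      stop("primitive extends outside the field of view")
    if (!p$material %in% materials())
      stop("material '", p$material, "' not in the attenuation table")
  }
  structure(list(primitives = primitives, n = as.integer(n), pitch = pitch),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d primitives on %d x %d px @ %.3g mm\n",
              length(x$primitives), x$n, x$n, x$pitch))
  invisible(x)
}

# Standard Shepp-Logan ellipse geometry (unit disc coordinates):
# x0, y0, a, b, rotation (deg).
shepp_logan_ellipses <- function() {
  rbind(
    c(0, 0, 0.69, 0.92, 0),
    c(0, -0.0184, 0.65, 0.88, 0),
    c(0.22, 0, 0.11, 0.31, -18),
    c(-0.22, 0, 0.16, 0.41, 18),
    c(0, 0.35, 0.21, 0.25, 0),
    c(0, 0.1, 0.046, 0.046, 0),
    c(0, -0.1, 0.046, 0.046, 0),
    c(-0.08, -0.605, 0.046, 0.023, 0),
    c(0, -0.605, 0.023, 0.023, 0),
    c(0.06, -0.605, 0.023, 0.046, 0))
}

# Head-like phantom: Shepp-Logan geometry with a cortical-bone shell,
# muscle-equivalent interior and a brighter soft-tissue tier (density-scaled
# muscle), plus two 4 x 4 mm rectangular gold inserts placed symmetrically
# inside the tissue. Tier attenuations at 60 keV are roughly 0.21, 0.32 and
# 0.60 1/cm for base tissue, bright tier and bone.
shepp_logan_metal_spec <- function(n, pitch) {
  s <- 50 # mm per Shepp-Logan unit; keeps the skull inside the 102.4 mm FOV
  e <- shepp_logan_ellipses()
  tier <- c("bone", "base", "dark", "mid", "mid", "mid", "mid", "mid", "mid", "mid")
  sc <- c(bone = 1, base = 1, dark = 0.95, mid = 1.8)
  mat <- c(bone = "bone_cortical", base = "muscle", dark = "muscle", mid = "muscle")
  prims <- lapply(seq_len(nrow(e)), function(i) {
    primitive("ellipse", center = e[i, 1:2] * s, size = e[i, 3:4] * s,
              rotation = e[i, 5], material = mat[[tier[i]]],
              scale = sc[[tier[i]]])
  })
  # larger of the two tilted inner ellipses joins the bright tier so that the
  # tier has enough area to form its own segmentation level
  prims[[4]] <- primitive("ellipse", center = e[4, 1:2] * s, size = e[4, 3:4] * s,
                          rotation = e[4, 5], material = "muscle", scale = 1.8)
  gold <- list(
    primitive("rectangle", center = c(-15, -10), size = c(4, 4),
              material = "gold"),
    primitive("rectangle", center = c(15, -10), size = c(4, 4),
              material = "gold"))
  phantom_spec(c(prims, gold), n, pitch)
}

# Jaw-like phantom: soft-tissue oval, a denser inner tissue region, an arc of
# bone "teeth" plus condyles, and three gold implants.
jaw_like_spec <- function(n, pitch) {
  prims <- list(
    primitive("ellipse", center = c(0, -2), size = c(38, 30),
              material = "muscle", scale = 1.25),
    primitive("ellipse", center = c(0, -8), size = c(26, 18),
              material = "muscle", scale = 1.75))
  ang <- seq(-30, 210, length.out = 6) * pi / 180
  teeth <- lapply(ang, function(a) {
    primitive("circle", center = c(27 * cos(a), -4 + 20 * sin(a)), size = 4,
              material = "bone_cortical")
  })
  condyles <- list(
    primitive("ellipse", center = c(-30, 12), size = c(6, 3), rotation = 30,
              material = "bone_cortical"),
    primitive("ellipse", center = c(30, 12), size = c(6, 3), rotation = -30,
              material = "bone_cortical"))
  gold <- lapply(list(c(27, -4 + 20 * sin(ang[1])),
                      c(27 * cos(ang[3]), -4 + 20 * sin(ang[3])),
                      c(-27, -4)), function(ct) {
    primitive("circle", center = ct, size = 2, material = "gold")
  })
  phantom_spec(c(prims, teeth, condyles, gold), n, pitch)
}

# Abdomen-like phantom: four tissue tiers (soft tissue, dense organ,
# trabecular bone, cortical bone) and two gold implants. Dense structures
# are deliberately compact (large area relative to perimeter) so each tier
# is a genuine segmentation level rather than a sliver.
abdomen_like_spec <- function(n, pitch) {
  prims <- list(
    primitive("ellipse", center = c(0, 0), size = c(45, 32),
              material = "muscle", scale = 1.15),                 # body
    primitive("ellipse", center = c(10, 8), size = c(25, 18), rotation = -10,
              material = "muscle", scale = 1.9),                  # organ
    primitive("ellipse", center = c(-25, -4), size = c(14, 18),
              material = "bone_cortical", scale = 0.925),         # kidney-like
    primitive("ellipse", center = c(27, -6), size = c(14, 18),
              material = "bone_cortical", scale = 0.925),
    primitive("circle", center = c(0, -14), size = 16,
              material = "bone_cortical", scale = 1.2))           # vertebra
  gold <- list(
    primitive("circle", center = c(-8, 6), size = 2, material = "gold"),
    primitive("circle", center = c(10, -14), size = 2, material = "gold"))
  phantom_spec(c(prims, gold), n, pitch)
}

two_disk_spec <- function(n, pitch) {
  phantom_spec(list(
    primitive("circle", center = c(-12, 0), size = 9, material = "muscle"),
    primitive("circle", center = c(14, 2), size = 7, material = "muscle",
              scale = 2.5)), n, pitch)
}

nested_levels_spec <- function(n, pitch) {
  phantom_spec(list(
    primitive("circle", center = c(0, 0), size = 20, material = "muscle"),
    primitive("circle", center = c(2, 1), size = 13, material = "muscle",
              scale = 1.8),
    primitive("circle", center = c(3, 0), size = 7, material = "muscle",
              scale = 2.8)), n, pitch)
}

#' Built-in phantom library
#'
#' Returns a fully parameterized [phantom_spec()]. `shepp_logan_metal` is a
#' head-like Shepp-Logan variant with two rectangular gold inserts,
#' `jaw_like` a jaw phantom with bone objects and three gold implants, and
#' `abdomen_like` a heterogeneous four-tier phantom with two implants.
#' `two_disk_test` and `nested_levels_test` are small fixtures used by the
#' segmentation machinery.
#'
#' @param name Phantom identifier.
#' @param n Grid side length (default 512).
#' @param pitch Pixel size in mm; default keeps the 102.4 mm field of view.
#' @return A `phantom_spec`.
#' @examples
#' spec <- phantom_library("shepp_logan_metal", n = 128)
#' @export
phantom_library <- function(name, n = 512L, pitch = 102.4 / n) {
  builders <- list(shepp_logan_metal = shepp_logan_metal_spec,
                   jaw_like = jaw_like_spec,
                   abdomen_like = abdomen_like_spec,
                   two_disk_test = two_disk_spec,
                   nested_levels_test = nested_levels_spec)
  if (!name %in% names(builders))
    stop("unknown phantom '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  builders[[name]](n, pitch)
}

#' Rasterize a phantom specification to a material map
#'
#' Each pixel is labelled by the last primitive covering its centre
#' (painter's order); uncovered pixels are air (label 0).
#'
#' @param spec A `phantom_spec`.
#' @return A `material_map`: integer label image plus a legend mapping labels
#'   to (material, scale).
#' @export
rasterize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  xy <- grid_coords(n, spec$pitch)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  labels <- matrix(0L, n, n)
  for (k in seq_along(spec$primitives)) {
    p <- spec$primitives[[k]]
    th <- -p$rotation * pi / 180
    xr <- (X - p$center[1]) * cos(th) - (Y - p$center[2]) * sin(th)
    yr <- (X - p$center[1]) * sin(th) + (Y - p$center[2]) * cos(th)
    inside <- switch(p$shape,
      rectangle = abs(xr) <= p$size[1] / 2 & abs(yr) <= p$size[2] / 2,
      (xr / p$size[1])^2 + (yr / p$size[2])^2 <= 1)
    labels[inside] <- k
  }
  legend <- data.frame(
    label = seq_along(spec$primitives),
    material = vapply(spec$primitives, `[[`, "", "material"),
    scale = vapply(spec$primitives, `[[`, 0, "scale"))
  structure(list(labels = labels, legend = legend,
                 n = n, pitch = spec$pitch),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  cat(sprintf("<material_map> %d x %d px @ %.3g mm, %d labels\n",
              x$n, x$n, x$pitch, nrow(x$legend)))
  invisible(x)
}

#' Monochromatic attenuation image of a material map
#'
#' @param map A `material_map`.
#' @param energy_kev Photon energy in keV.
#' @return An `image2d` of linear attenuation (1/mm).
#' @export
mu_image <- function(map, energy_kev) {
  stopifnot(inherits(map, "material_map"))
  mu <- c(0, vapply(seq_len(nrow(map$legend)), function(i) {
    attenuation(map$legend$material[i], energy_kev) * map$legend$scale[i]
  }, 0))
  vals <- matrix(mu[map$labels + 1L], map$n, map$n)
  image2d(vals, map$pitch)
}

#' Ground-truth metal mask of a material map
#'
#' @param map A `material_map`.
#' @param metal Material name treated as metal.
#' @return Logical matrix, `TRUE` on metal pixels.
#' @export
metal_mask <- function(map, metal = "gold") {
  lab <- map$legend$label[map$legend$material == metal]
  matrix(map$labels %in% lab, map$n, map$n)
}

#' Remove metal primitives from a specification
#'
#' Used to build the metal-free reference object: dropping a gold primitive
#' exposes whatever tissue the painter's order placed beneath it.
#'
#' @param spec A `phantom_spec`.
#' @param metal Material treated as metal.
#' @return A `phantom_spec` without the metal primitives.
#' @export
drop_metal <- function(spec, metal = "gold") {
  keep <- vapply(spec$primitives, function(p) p$material != metal, TRUE)
  phantom_spec(spec$primitives[keep], spec$n, spec$pitch)
}

#' Write / read a phantom specification as YAML
#'
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @return `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(list(n = spec$n, pitch = spec$pitch,
                        primitives = spec$primitives), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  prims <- lapply(y$primitives, function(p) {
    size <- unlist(p$size)
    if (p$shape == "circle") size <- size[1]
    primitive(p$shape, unlist(p$center), size, p$rotation,
              p$material, p$scale)
  })
  phantom_spec(prims, y$n, y$pitch)
}

#' Load an externally supplied phantom image
#'
#' Reads a whitespace-separated plain-text matrix (one image row per line)
#' as an attenuation image, e.g. a phantom exported from another toolchain.
#'
#' @param path File path.
#' @param pitch Pixel size in mm.
#' @return An `image2d`.
#' @export
read_phantom_tsv <- function(path, pitch = 0.2) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  image2d(m, pitch)
}
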