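#' @useDynLib ctmar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

the_tables <- new.env(parent = emptyenv())

load_raw_tables <- function() {
  if (is.null(the_tables$atten)) {
    path <- system.file("extdata", "attenuation_tables.csv", package = "ctmar")
    the_tables$atten <- utils::read.csv(path, comment.char = "#")
    dpath <- system.file("extdata", "material_densities.csv", package = "ctmar")
    dens <- utils::read.csv(dpath, comment.char = "#")
    the_tables$density <- stats::setNames(dens$density_g_cm3, dens$material)
  }
  invisible(the_tables)
}

#' Tabulated materials
#'
#' Names of the materials shipped in the package's attenuation table
#' (an approximate ICRU-44-style tabulation of mass attenuation
#' coefficients; gold includes its K edge at 80.7 keV).
#'
#' @return Character vector of material names.
#' @export
materials <- function() {
  load_raw_tables()
  unique(the_tables$atten$material)
}

#' Linear attenuation coefficient of a material
#'
#' Looks up the shipped mass attenuation table, log-log interpolates between
#' tabulated energies, and multiplies by the material's nominal density.
#' Queries outside the tabulated energy range are an error (no
#' extrapolation).
#'
#' @param material Material name (see [materials()]).
#' @param energy_kev Photon energy (keV); may be a vector.
#' @return Linear attenuation in 1/mm.
#' @examples
#' attenuation("water", 60)
#' attenuation("bone_cortical", c(40, 80))
#' @export
attenuation <- function(material, energy_kev) {
  load_raw_tables()
  tab <- the_tables$atten[the_tables$atten$material == material, ]
  if (nrow(tab) == 0)
    stop("unknown material '", material, "'; available: ",
         paste(materials(), collapse = ", "))
  if (any(energy_kev < min(tab$energy_kev) | energy_kev > max(tab$energy_kev)))
    stop("energy outside tabulated range [", min(tab$energy_kev), ", ",
         max(tab$energy_kev), "] keV for ", material)
  lmu <- stats::approx(log(tab$energy_kev), log(tab$mass_atten_cm2_g),
                       xout = log(energy_kev), ties = "ordered")$y
  # cm^2/g * g/cm^3 -> 1/cm -> 1/mm
  exp(lmu) * the_tables$density[[material]] / 10
}

new_spectrum <- function(energy_kev, fluence) {
  if (length(energy_kev) == 0 || any(fluence < 0) || sum(fluence) <= 0)
    stop("spectrum must have at least one bin with positive fluence")
  o <- order(energy_kev)
  structure(list(energy_kev = energy_kev[o],
                 fluence = fluence[o] / sum(fluence)),
            class = "spectrum")
}

#' X-ray spectrum
#'
#' Returns a normalized tube spectrum. The built-in model is a tungsten-anode
#' bremsstrahlung approximation: Kramers' law hardened by an
#' aluminium-equivalent total filtration (default 8 mm, which accounts for
#' inherent filtration plus the anode self-filtration that the bare Kramers
#' model lacks and brings the 120 kVp mean energy to ~60 keV, typical of
#' measured clinical spectra), sampled at 1 keV bins from 10 keV to the tube
#' voltage. A two-column text file (`energy_kev`, `fluence`) can be supplied
#' instead.
#'
#' @param kvp Tube voltage in kV; bins above `kvp` are excluded. Must lie in
#'   (0, 150].
#' @param path Optional path to a CSV/whitespace table with columns
#'   `energy_kev` and `fluence`; overrides the built-in model.
#' @param filtration_mm_al Aluminium-equivalent filtration in mm for the
#'   built-in model.
#' @return A `spectrum` object (ascending energies, fluence summing to 1).
#' @seealso [monochromatic()]
#' @export
load_spectrum <- function(kvp = 120, path = NULL, filtration_mm_al = 8) {
  stopifnot(kvp > 0, kvp <= 150)
  if (!is.null(path)) {
    tab <- utils::read.csv(path, comment.char = "#")
    keep <- tab$energy_kev <= kvp
    return(new_spectrum(tab$energy_kev[keep], tab$fluence[keep]))
  }
  e <- seq(10, floor(kvp), by = 1)
  kramers <- pmax(kvp / e - 1, 0)
  filt <- exp(-attenuation("aluminium", e) * filtration_mm_al)
  new_spectrum(e, kramers * filt)
}

#' Monochromatic (delta) spectrum
#'
#' @param energy_kev Single photon energy in keV.
#' @return A `spectrum` with one bin of weight 1.
#' @export
monochromatic <- function(energy_kev) {
  stopifnot(length(energy_kev) == 1, energy_kev > 0)
  new_spectrum(energy_kev, 1)
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean photon energy, used as the reference energy for
#' Hounsfield conversion.
#'
#' @param spectrum A `spectrum` object.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  sum(spectrum$energy_kev * spectrum$fluence)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bins, %.4g-%.4g keV, mean %.1f keV\n",
              length(x$energy_kev), min(x$energy_kev), max(x$energy_kev),
              mean_energy(x)))
  invisible(x)
}

#' Water attenuation at the spectrum's mean energy
#'
#' Convenience used for HU conversion of polychromatic reconstructions.
#'
#' @param spectrum A `spectrum` object.
#' @return Linear attenuation of water in 1/mm.
#' @export
mu_water_at <- function(spectrum) {
  attenuation("water", mean_energy(spectrum))
}
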