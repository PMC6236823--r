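#' Discrete X-ray energy spectrum
#'
#' An energy spectrum is a set of strictly increasing energy bin centers
#' (keV) with non-negative relative fluence weights. All polychromatic
#' computations in the package work on the normalized form, whose weights
#' sum to one.
#'
#' @param energies_keV strictly increasing numeric vector of bin centers.
#' @param weights non-negative relative fluence per bin; at least one must
#'   be positive.
#' @return An object of class `energy_spectrum` with fields `energies_keV`
#'   and `weights`.
#' @examples
#' s <- energy_spectrum(c(40, 80), c(2, 2))
#' normalize_spectrum(s)$weights
#' mean_energy(s)
#' @export
energy_spectrum <- function(energies_keV, weights) {
  energies_keV <- as.numeric(energies_keV)
  weights <- as.numeric(weights)
  if (length(energies_keV) != length(weights) || length(weights) == 0)
    stop("energies_keV and weights must be non-empty and equally long")
  if (any(!is.finite(energies_keV)) || any(!is.finite(weights)))
    stop("invalid spectrum: non-finite entries")
  if (length(energies_keV) > 1 && any(diff(energies_keV) <= 0))
    stop("invalid spectrum: energies must be strictly increasing")
  if (any(weights < 0) || !any(weights > 0))
    stop("invalid spectrum: weights must be non-negative with at least one positive")
  structure(list(energies_keV = energies_keV, weights = weights),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d bins, %.1f-%.1f keV, mean %.2f keV\n",
              length(x$energies_keV), min(x$energies_keV),
              max(x$energies_keV), mean_energy(x)))
  invisible(x)
}

#' Normalize a spectrum to unit total fluence
#'
#' @param spectrum an [energy_spectrum()].
#' @return The spectrum with weights rescaled to sum to 1.
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  energy_spectrum(spectrum$energies_keV,
                  spectrum$weights / sum(spectrum$weights))
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean of the bin energies, used as the global reference
#' energy of the dome artifact correction.
#'
#' @inheritParams normalize_spectrum
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  s <- normalize_spectrum(spectrum)
  sum(s$weights * s$energies_keV)
}

#' Harden a spectrum by a filter material
#'
#' Multiplies each bin weight by the Beer-Lambert transmission through
#' `thickness_mm` of `material` (e.g. the aluminum bowtie path of one
#' detector column). The result is not renormalized.
#'
#' @inheritParams normalize_spectrum
#' @param material a [material_table()].
#' @param thickness_mm filter path length in mm.
#' @export
apply_filtration <- function(spectrum, material, thickness_mm) {
  stopifnot(inherits(spectrum, "energy_spectrum"), thickness_mm >= 0)
  mu <- mu_at(material, spectrum$energies_keV)
  energy_spectrum(spectrum$energies_keV,
                  spectrum$weights * exp(-mu * thickness_mm))
}

#' Rebin a spectrum onto fewer energy bins
#'
#' Aggregates consecutive bins into `n_bins` groups; each group keeps the
#' summed weight at its fluence-weighted mean energy. Used to run the
#' polychromatic projector at a desk-scale number of energies.
#'
#' @inheritParams normalize_spectrum
#' @param n_bins target number of bins.
#' @export
resample_spectrum <- function(spectrum, n_bins) {
  stopifnot(inherits(spectrum, "energy_spectrum"), n_bins >= 1)
  n <- length(spectrum$energies_keV)
  if (n_bins >= n) return(spectrum)
  grp <- cut(seq_len(n), breaks = n_bins, labels = FALSE)
  w <- tapply(spectrum$weights, grp, sum)
  e <- tapply(spectrum$weights * spectrum$energies_keV, grp, sum) / w
  keep <- w > 0
  energy_spectrum(as.numeric(e[keep]), as.numeric(w[keep]))
}

#' Read a spectrum from a two-column text file
#'
#' Format: comment lines starting with `#`, then two whitespace-separated
#' columns (energy keV, relative fluence).
#'
#' @param path file path.
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("spectrum file must have two columns (keV, fluence): ", path)
  energy_spectrum(tab[[1]], tab[[2]])
}

#' Write a spectrum to a two-column text file
#' @inheritParams normalize_spectrum
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: energy_keV relative_fluence", con)
  utils::write.table(data.frame(spectrum$energies_keV, spectrum$weights),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Packaged generic 90 kVp spectrum
#'
#' A generic filtered 90 kVp tungsten-anode spectrum shipped with the
#' package, optionally rebinned.
#'
#' @param n_bins optional number of bins to rebin to (default: full table).
#' @export
default_spectrum <- function(n_bins = NULL) {
  s <- read_spectrum(system.file("extdata", "spectrum_90kvp.txt",
                                 package = "cbctcorr", mustWork = TRUE))
  if (!is.null(n_bins)) s <- resample_spectrum(s, n_bins)
  normalize_spectrum(s)
}
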