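#' Material attenuation table
#'
#' Linear attenuation of a material versus photon energy, derived from a
#' mass-attenuation table (cm^2/g) and a mass density. Attenuation between
#' tabulated energies is interpolated log-log, the standard behavior for
#' photon cross sections.
#'
#' @param name material identifier.
#' @param energies_keV strictly increasing energy grid.
#' @param mass_atten_cm2_g mass attenuation coefficients (cm^2/g); give
#'   either this or `mu_linear_per_mm`.
#' @param density_g_cm3 mass density (g/cm^3).
#' @param mu_linear_per_mm linear attenuation per mm at each energy.
#' @return An object of class `material_table`.
#' @export
material_table <- function(name, energies_keV, mass_atten_cm2_g = NULL,
                           density_g_cm3 = 1, mu_linear_per_mm = NULL) {
  energies_keV <- as.numeric(energies_keV)
  if (length(energies_keV) < 1 || any(diff(energies_keV) <= 0))
    stop("material energy grid must be strictly increasing")
  if (is.null(mu_linear_per_mm)) {
    if (is.null(mass_atten_cm2_g)) stop("give mass_atten_cm2_g or mu_linear_per_mm")
    mu_linear_per_mm <- as.numeric(mass_atten_cm2_g) * density_g_cm3 / 10
  }
  mu_linear_per_mm <- as.numeric(mu_linear_per_mm)
  if (length(mu_linear_per_mm) != length(energies_keV))
    stop("attenuation and energy grids differ in length")
  if (any(!is.finite(mu_linear_per_mm)) || any(mu_linear_per_mm <= 0))
    stop("linear attenuation must be finite and positive at every energy")
  structure(list(name = name, energies_keV = energies_keV,
                 mu_linear_per_mm = mu_linear_per_mm,
                 density_g_cm3 = density_g_cm3),
            class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %s, rho %.4g g/cm3, %d energies (%g-%g keV)\n",
              x$name, x$density_g_cm3, length(x$energies_keV),
              min(x$energies_keV), max(x$energies_keV)))
  invisible(x)
}

#' Linear attenuation at arbitrary energies
#'
#' Log-log interpolation of the tabulated linear attenuation. Energies
#' outside the tabulated range raise an out-of-range error rather than
#' extrapolating.
#'
#' @param material a [material_table()].
#' @param energies_keV energies at which to evaluate (keV).
#' @return Linear attenuation per mm at each requested energy.
#' @export
mu_at <- function(material, energies_keV) {
  stopifnot(inherits(material, "material_table"))
  e <- material$energies_keV
  if (any(energies_keV < min(e) - 1e-9) || any(energies_keV > max(e) + 1e-9))
    stop(sprintf("energy outside the %s table range [%g, %g] keV",
                 material$name, min(e), max(e)))
  if (length(e) == 1) return(rep(material$mu_linear_per_mm, length(energies_keV)))
  ek <- pmin(pmax(energies_keV, min(e)), max(e))
  exp(stats::approx(log(e), log(material$mu_linear_per_mm), log(ek))$y)
}

#' Spectrum-weighted mean attenuation
#'
#' The equivalent attenuation of a material under a polychromatic spectrum:
#' the fluence-weighted mean of the linear attenuation over the spectrum
#' bins. This is the attenuation scale on which corrected images are
#' expressed.
#'
#' @inheritParams mu_at
#' @param spectrum an [energy_spectrum()]; the material table must cover
#'   its energy support.
#' @return Mean attenuation per mm.
#' @export
effective_mu <- function(material, spectrum) {
  s <- normalize_spectrum(spectrum)
  sum(s$weights * mu_at(material, s$energies_keV))
}

#' Per-energy attenuation ratio
#'
#' Ratio between the attenuation of a material in each spectrum energy bin
#' and its spectrum-weighted mean attenuation. By construction the
#' fluence-weighted mean of the ratios is exactly one. For a degenerate
#' material with zero mean attenuation the ratio is defined as one
#' everywhere (such a material contributes nothing to line integrals).
#'
#' @inheritParams effective_mu
#' @return Numeric vector of ratios, one per spectrum bin.
#' @export
sigma_hat <- function(material, spectrum) {
  s <- normalize_spectrum(spectrum)
  mu <- mu_at(material, s$energies_keV)
  mbar <- sum(s$weights * mu)
  if (mbar <= 0) return(rep(1, length(mu)))
  mu / mbar
}

#' Read a material table from a text file
#'
#' Format: comment header with `# density_g_cm3: <value>` then two columns
#' (energy keV, mass attenuation cm^2/g).
#'
#' @param path file path.
#' @param name optional material name (default: parsed from the header or
#'   the file name).
#' @export
read_material <- function(path, name = NULL) {
  hdr <- readLines(path, n = 10)
  dline <- grep("density_g_cm3", hdr, value = TRUE)
  if (length(dline) == 0) stop("material file lacks a '# density_g_cm3:' header: ", path)
  density <- as.numeric(sub(".*density_g_cm3:\\s*", "", dline[1]))
  if (is.null(name)) {
    nline <- grep("^#\\s*material:", hdr, value = TRUE)
    name <- if (length(nline)) sub("^#\\s*material:\\s*", "", nline[1]) else
      sub("\\.txt$", "", basename(path))
  }
  tab <- utils::read.table(path, comment.char = "#")
  material_table(name, tab[[1]], mass_atten_cm2_g = tab[[2]],
                 density_g_cm3 = density)
}

#' Packaged material tables
#'
#' Load one of the material attenuation tables shipped with the package
#' (NIST-style mass attenuation at 20-150 keV).
#'
#' @param name one of [list_materials()].
#' @export
cbct_material <- function(name) {
  path <- system.file("extdata", "materials", paste0(name, ".txt"),
                      package = "cbctcorr")
  if (!nzchar(path))
    stop("unknown packaged material '", name, "'; see list_materials()")
  read_material(path, name = name)
}

#' @rdname cbct_material
#' @export
list_materials <- function() {
  sub("\\.txt$", "",
      dir(system.file("extdata", "materials", package = "cbctcorr")))
}
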