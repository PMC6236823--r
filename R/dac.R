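#' Dome/capping artifact correction
#'
#' Post-reconstruction correction of the radial bias caused by the bowtie
#' filter's spatially varying beam energy. Each voxel's attenuation is
#' decomposed with the linear basis-material mapping evaluated at *local*
#' basis node values -- the mean attenuation each basis material would
#' show under the spectrum the voxel was actually sensed with -- and
#' re-composed with the node values of the global reference spectrum.
#'
#' The local nodes are obtained from a one-parameter family of
#' bowtie-hardened spectra: the (mean energy, mean basis attenuation)
#' pairs are tabulated along filter thickness and interpolated at the
#' voxel's mean sensed energy (from [backproject_energy()]). A voxel
#' sensed exactly at the reference energy is returned unchanged.
#'
#' @param volume reconstructed [volume_image()] (mm^-1) after
#'   beam-hardening correction.
#' @param emap mean sensed energy map ([volume_image()], keV) on the same
#'   grid.
#' @param materials ordered basis [material_table()]s (air, soft, bone).
#' @param spectrum the acquisition [energy_spectrum()] (unfiltered).
#' @param filter_material bowtie material (default packaged aluminum).
#' @param max_filter_mm upper end of the hardening family (should cover
#'   the thickest bowtie path).
#' @return Corrected [volume_image()].
#' @export
dac_correct <- function(volume, emap, materials, spectrum,
                        filter_material = cbct_material("aluminum"),
                        max_filter_mm = 15) {
  stopifnot(inherits(volume, "volume_image"), inherits(emap, "volume_image"))
  if (!identical(volume$grid$n, emap$grid$n))
    stop("energy map must be on the same grid as the volume")
  fam <- hardened_basis_family(spectrum, materials, filter_material,
                               max_filter_mm)
  e <- as.numeric(emap$values)
  if (any(e < min(fam$energy) - 2) || any(e > max(fam$energy) + 2))
    stop("local energies outside the hardening family range")
  e <- pmin(pmax(e, min(fam$energy)), max(fam$energy))
  M <- length(materials)
  nodes <- lapply(seq_len(M), function(i)
    stats::approx(fam$energy, fam$mu[, i], e)$y)
  e_ref <- mean_energy(spectrum)
  ref <- vapply(seq_len(M), function(i)
    stats::approx(fam$energy, fam$mu[, i], min(max(e_ref, min(fam$energy)),
                                               max(fam$energy)))$y,
    numeric(1))
  f <- as.numeric(volume$values)
  n1 <- nodes[[1]]; n2 <- nodes[[2]]; n3 <- nodes[[3]]
  f <- pmin(pmax(f, n1), n3)
  out <- numeric(length(f))
  lowr <- f < n2
  w <- (f[lowr] - n1[lowr]) / (n2[lowr] - n1[lowr])
  out[lowr] <- (1 - w) * ref[1] + w * ref[2]
  w <- (f[!lowr] - n2[!lowr]) / (n3[!lowr] - n2[!lowr])
  out[!lowr] <- (1 - w) * ref[2] + w * ref[3]
  volume_image(array(out, volume$grid$n), volume$grid, unit = volume$unit)
}

# (mean energy, spectrum-weighted basis attenuation) along filter thickness
hardened_basis_family <- function(spectrum, materials, filter_material,
                                  max_filter_mm, n_steps = 25) {
  t_grid <- seq(0, max_filter_mm, length.out = n_steps)
  energy <- numeric(n_steps)
  mu <- matrix(0, n_steps, length(materials))
  for (k in seq_len(n_steps)) {
    sp <- apply_filtration(spectrum, filter_material, t_grid[k])
    energy[k] <- mean_energy(sp)
    mu[k, ] <- vapply(materials, effective_mu, numeric(1), spectrum = sp)
  }
  if (any(diff(energy) <= 0))
    stop("hardening family mean energy is not monotone")
  list(t_mm = t_grid, energy = energy, mu = mu)
}
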