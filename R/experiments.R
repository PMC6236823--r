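#' Desk-scale sensitometry study fixture
#'
#' The standard scaled-down acquisition used throughout the package's
#' validation experiments: a 150 mm digital sensitometry phantom on a
#' 120^3 grid of 1.35 mm voxels, a 164 x 48 pixel detector at 1.8 mm
#' pitch (SAD 500 mm, SDD 900 mm), 60 views over 200 degrees, a 10-bin
#' 90 kVp spectrum, a parabolic 10 mm aluminum bowtie, a 3% flood
#' saturation error, and Poisson noise at 5e4 photons/pixel. These sizes
#' preserve the artifact structure of a clinical half-fan scan at desk
#' scale.
#'
#' @param grid_n in-plane grid size.
#' @param grid_nz axial grid size; sized so the reconstruction volume
#'   stays within the detector's axial coverage, as on a scanner.
#' @param voxel_mm voxel size.
#' @param n_views number of views over `span_deg`.
#' @param span_deg angular span.
#' @param n_bins spectrum bins.
#' @param photons_per_pixel Poisson fluence of the base degradation.
#' @param seed RNG seed of the base degradation.
#' @return list with `grid`, `geom`, `phantom`, `spectrum`, `materials`
#'   (air, water, Teflon basis -- the densest material present; basis
#'   materials should span the object's composition), `bowtie`, and
#'   `base` (a [degradation_model()] with every field but the scatter
#'   level set).
#' @export
catphan_fixture <- function(grid_n = 120, grid_nz = 36, voxel_mm = 1.35,
                            n_views = 60, span_deg = 200, n_bins = 10,
                            photons_per_pixel = 5e4, seed = 0) {
  grid <- voxel_grid(grid_n, grid_n, grid_nz, voxel_mm = voxel_mm)
  geom <- cone_beam_geometry(
    source_axis_dist_mm = 500, source_detector_dist_mm = 900,
    det_rows = 48, det_cols = 164, det_pitch_mm = 1.8,
    angles_deg = seq(0, span_deg, length.out = n_views + 1)[1:n_views])
  spectrum <- default_spectrum(n_bins)
  phantom <- make_catphan_sensitometry(grid)
  bowtie <- bowtie_profile(geom, max_mm = 10)
  base <- degradation_model(
    scatter_to_primary = 0, scatter_kernel_fwhm_mm = 80,
    bowtie_profile = bowtie,
    flood_saturation_error = default_flood_error(geom, 0.03),
    photons_per_pixel = photons_per_pixel, seed = seed)
  list(grid = grid, geom = geom, phantom = phantom, spectrum = spectrum,
       materials = list(cbct_material("air"), cbct_material("water"),
                        cbct_material("teflon")),
       bowtie = bowtie, base = base)
}

#' Desk-scale head study fixture
#'
#' Companion fixture for brain-like experiments (shading null tests,
#' metal artifact reduction): a digital head phantom on a 64^3 grid of
#' 2.2 mm voxels with a 80 x 124 detector and 48 views over 200 degrees.
#'
#' @param with_metal add titanium frame pins.
#' @inheritParams catphan_fixture
#' @export
head_fixture <- function(with_metal = FALSE, grid_n = 64, grid_nz = 48,
                         voxel_mm = 2.2, n_views = 48, span_deg = 200,
                         n_bins = 10, photons_per_pixel = 0, seed = 0) {
  grid <- voxel_grid(grid_n, grid_n, grid_nz, voxel_mm = voxel_mm)
  geom <- cone_beam_geometry(
    source_axis_dist_mm = 500, source_detector_dist_mm = 900,
    det_rows = 80, det_cols = 124, det_pitch_mm = 2.4,
    angles_deg = seq(0, span_deg, length.out = n_views + 1)[1:n_views])
  spectrum <- default_spectrum(n_bins)
  phantom <- make_head_phantom(grid, with_metal = with_metal,
                               semi_axes_mm = c(50, 60, 45), skull_mm = 6)
  base <- degradation_model(photons_per_pixel = photons_per_pixel,
                            seed = seed)
  list(grid = grid, geom = geom, phantom = phantom, spectrum = spectrum,
       materials = list(cbct_material("air"), cbct_material("brain"),
                        cbct_material("cortical_bone")),
       base = base)
}

#' Linearity and CT-number accuracy experiment
#'
#' Reproduces the sensitometry linearity experiment end to end: the
#' scatter level is calibrated so the uncorrected FDK CT-number slope
#' matches `target_slope`, then the full correction pipeline (shading +
#' beam-hardening + dome) is run and both reconstructions are scored
#' against the spectrum-weighted true CT numbers.
#'
#' @param seed RNG seed for the simulated acquisition.
#' @param target_slope uncorrected operating point (default 0.80).
#' @param fixture a [catphan_fixture()] (built fresh when `NULL`).
#' @return list with `fixture`, `degradation`, `measured`,
#'   `uncorrected`/`corrected` ([catphan_report()] lists), and
#'   `pipeline` (the [cbct_correct()] output).
#' @export
linearity_study <- function(seed = 0, target_slope = 0.80, fixture = NULL) {
  fx <- fixture %||% catphan_fixture(seed = seed)
  fx$base$seed <- as.integer(seed)
  deg <- calibrate_degradation(target_slope, fx$phantom, fx$geom, fx$grid,
                               fx$spectrum, base = fx$base)
  measured <- apply_degradation(attr(deg, "primary"), deg)
  rec0 <- fdk_reconstruct(as_line_integrals(measured), fx$grid)
  uncorrected <- catphan_report(rec0, fx$phantom, fx$spectrum)
  pipe <- cbct_correct(measured, fx$spectrum, fx$materials, fx$geom, fx$grid,
                       bowtie = fx$bowtie)
  corrected <- catphan_report(pipe$volume, fx$phantom, fx$spectrum)
  list(fixture = fx, degradation = deg, measured = measured,
       uncorrected = uncorrected, corrected = corrected, pipeline = pipe)
}

#' Contrast-to-noise experiment
#'
#' Reproduces the acrylic-insert CNR experiment: the photon fluence is
#' calibrated so the uncorrected FDK reconstruction reads a target CNR
#' (default 1.8) for the acrylic rod, then the correction pipeline is run
#' with the TV-regularized reconstruction and the CNR re-measured with
#' the same ROIs (signal: 3/4 of the rod radius; background: same area
#' in the water region).
#'
#' @param seed RNG seed.
#' @param target_cnr uncorrected operating point (default 1.8).
#' @param degradation a calibrated [degradation_model()] (e.g. from
#'   [linearity_study()]) supplying the scatter level; the base model of
#'   a fresh fixture is used when `NULL`.
#' @param fixture a [catphan_fixture()] (built fresh when `NULL`).
#' @return list with `cnr_uncorrected`, `cnr_corrected`, `degradation`,
#'   and `volume` (the corrected reconstruction).
#' @export
cnr_study <- function(seed = 0, target_cnr = 1.8, degradation = NULL,
                      fixture = NULL) {
  fx <- fixture %||% catphan_fixture(seed = seed)
  base <- degradation %||% fx$base
  base$seed <- as.integer(seed)
  deg <- calibrate_photons(target_cnr, fx$phantom, fx$geom, fx$grid,
                           fx$spectrum, base = base)
  measured <- apply_degradation(attr(deg, "primary"), deg)
  rois <- catphan_rois(fx$phantom, "acrylic")
  rec0 <- fdk_reconstruct(as_line_integrals(measured), fx$grid)
  cnr0 <- cnr(rec0, rois$signal, rois$background)
  pipe <- cbct_correct(measured, fx$spectrum, fx$materials, fx$geom, fx$grid,
                       bowtie = fx$bowtie, recon = "tv")
  cnr1 <- cnr(pipe$volume, rois$signal, rois$background)
  list(cnr_uncorrected = cnr0, cnr_corrected = cnr1, degradation = deg,
       volume = pipe$volume)
}

#' Beam-hardening convergence experiment
#'
#' Runs the shading correction then tracks the per-iteration relative
#' change of the beam-hardening-corrected projections on the
#' sensitometry fixture.
#'
#' @param study a [linearity_study()] result to reuse (built fresh when
#'   `NULL`).
#' @param n_iter iterations to track.
#' @param seed seed used if a fresh study is needed.
#' @return list with `rel_change` and `n_to_1pct` (first iteration whose
#'   update is below 1%).
#' @export
bhc_convergence_study <- function(study = NULL, n_iter = 4, seed = 0) {
  st <- study %||% linearity_study(seed = seed)
  fx <- st$fixture
  lf <- st$pipeline$lfac_projections
  bh <- bhc_iterate(projection_stack(lf$values, "line_integral", fx$geom),
                    fx$spectrum, fx$materials, fx$geom, fx$grid,
                    n_iter = n_iter)
  below <- which(bh$rel_change < 0.01)
  list(rel_change = bh$rel_change,
       n_to_1pct = if (length(below)) min(below) else NA_integer_)
}
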