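#' Projection degradation model
#'
#' The physical degradations the simulator applies to ideal polychromatic
#' primary intensities: additive low-frequency scatter (Gaussian-blurred
#' scaled primary), bowtie filtration (spectral, per detector column), a
#' multiplicative flood-field saturation error that survives flood
#' normalization, and Poisson counting noise.
#'
#' @param scatter_to_primary scatter-to-primary ratio scaling the blurred
#'   primary added to each view (0 disables scatter).
#' @param scatter_kernel_fwhm_mm FWHM of the Gaussian scatter blur at the
#'   detector.
#' @param bowtie_profile per-column bowtie filter path (mm of
#'   `filter_material`), or `NULL` for none.
#' @param filter_material bowtie material (default packaged aluminum).
#' @param flood_saturation_error multiplicative error map
#'   (`det_rows x det_cols`) or scalar; models saturated gain/flood
#'   calibration images.
#' @param photons_per_pixel mean unattenuated photon count per pixel for
#'   Poisson noise; 0 disables noise.
#' @param seed RNG seed; every random draw of a simulation goes through a
#'   single RNG seeded with it.
#' @export
degradation_model <- function(scatter_to_primary = 0,
                              scatter_kernel_fwhm_mm = 80,
                              bowtie_profile = NULL,
                              filter_material = cbct_material("aluminum"),
                              flood_saturation_error = 1,
                              photons_per_pixel = 0, seed = 0) {
  stopifnot(scatter_to_primary >= 0, photons_per_pixel >= 0,
            all(flood_saturation_error > 0))
  structure(list(scatter_to_primary = scatter_to_primary,
                 scatter_kernel_fwhm_mm = scatter_kernel_fwhm_mm,
                 bowtie_profile = bowtie_profile,
                 filter_material = filter_material,
                 flood_saturation_error = flood_saturation_error,
                 photons_per_pixel = photons_per_pixel,
                 seed = as.integer(seed)),
            class = "degradation_model")
}

#' Parabolic bowtie filter profile
#'
#' Filter path length per detector column: thin at the center, thick at
#' the fan periphery.
#'
#' @param geom a [cone_beam_geometry()].
#' @param max_mm path length at the outermost column.
#' @param power profile exponent (2 = parabolic).
#' @export
bowtie_profile <- function(geom, max_mm = 10, power = 2) {
  u <- det_u_coords(geom)
  max_mm * (abs(u) / max(abs(u)))^power
}

#' Smooth flood-field saturation error map
#'
#' A low-frequency multiplicative error field (Gaussian bump at the
#' detector center) emulating saturated flood calibration images.
#'
#' @inheritParams bowtie_profile
#' @param amplitude peak relative error.
#' @export
default_flood_error <- function(geom, amplitude = 0.03) {
  u <- det_u_coords(geom); v <- det_v_coords(geom)
  su <- diff(range(u)) / 3; sv <- max(diff(range(v)) / 3, geom$det_pitch_mm)
  1 + amplitude * outer(exp(-v^2 / (2 * sv^2)), exp(-u^2 / (2 * su^2)))
}

# row-normalized Gaussian blur matrices: blur = Br %*% X %*% t(Bc)
gauss_blur_ops <- function(n, pitch, fwhm) {
  sigma <- fwhm / 2.35482
  pos <- (seq_len(n) - 1) * pitch
  B <- exp(-outer(pos, pos, `-`)^2 / (2 * sigma^2))
  B / rowSums(B)
}

#' Ideal polychromatic primary intensities of a phantom
#'
#' Flood-normalized primary intensities (no scatter, no flood error, no
#' noise) including bowtie spectral hardening: each detector column uses
#' its post-bowtie normalized spectrum. Exposed separately so degradation
#' parameters can be re-applied cheaply (e.g. during calibration).
#'
#' @param phantom a [labeled_phantom()].
#' @param geom a [cone_beam_geometry()].
#' @param spectrum an [energy_spectrum()].
#' @param bowtie_profile per-column filter path (mm) or `NULL`.
#' @param filter_material bowtie material.
#' @param step_mm projector sampling step.
#' @return A [projection_stack()] in the intensity domain.
#' @export
simulate_primary <- function(phantom, geom, spectrum, bowtie_profile = NULL,
                             filter_material = cbct_material("aluminum"),
                             step_mm = NULL) {
  s <- normalize_spectrum(spectrum)
  lp <- project_label_paths(phantom, geom, step_mm)
  nr <- geom$det_rows; nc <- geom$det_cols; nv <- length(geom$angles_deg)
  mu <- lapply(lp$materials, mu_at, energies_keV = s$energies_keV)
  # per-column post-bowtie spectrum weights, normalized per column
  if (is.null(bowtie_profile)) {
    wcol <- matrix(s$weights, length(s$weights), nc)
  } else {
    if (length(bowtie_profile) != nc)
      stop("bowtie_profile must have one entry per detector column")
    tr <- exp(-outer(mu_at(filter_material, s$energies_keV), bowtie_profile))
    wcol <- s$weights * tr
  }
  wcol <- sweep(wcol, 2, colSums(wcol), `/`)
  acc <- array(0, c(nr, nc, nv))
  for (e in seq_along(s$energies_keV)) {
    expo <- array(0, c(nr, nc, nv))
    for (i in seq_along(lp$paths)) expo <- expo + mu[[i]][e] * lp$paths[[i]]
    acc <- acc + rep(rep(wcol[e, ], each = nr), nv) * exp(-expo)
  }
  projection_stack(acc, "intensity", geom)
}

#' Apply a degradation model to primary intensities
#'
#' Adds blurred scatter, multiplies by the flood saturation error, and
#' draws Poisson noise, reproducing what flood-normalized measured
#' projections of the modeled system look like. Deterministic for a fixed
#' model seed.
#'
#' @param primary intensity-domain [projection_stack()] from
#'   [simulate_primary()].
#' @param degradation a [degradation_model()].
#' @export
apply_degradation <- function(primary, degradation) {
  stopifnot(inherits(primary, "projection_stack"),
            primary$domain == "intensity",
            inherits(degradation, "degradation_model"))
  geom <- primary$geometry
  vals <- primary$values
  d <- degradation
  if (d$scatter_to_primary > 0) {
    Br <- gauss_blur_ops(geom$det_rows, geom$det_pitch_mm, d$scatter_kernel_fwhm_mm)
    Bc <- gauss_blur_ops(geom$det_cols, geom$det_pitch_mm, d$scatter_kernel_fwhm_mm)
    for (a in seq_len(dim(vals)[3])) {
      sc <- d$scatter_to_primary * (Br %*% vals[, , a] %*% t(Bc))
      vals[, , a] <- vals[, , a] + sc
    }
  }
  if (!isTRUE(all(d$flood_saturation_error == 1)))
    vals <- vals * rep(as.numeric(d$flood_saturation_error),
                       dim(vals)[3])
  if (d$photons_per_pixel > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(d$seed)
    counts <- stats::rpois(length(vals), lambda = d$photons_per_pixel * vals)
    vals <- array(pmax(counts, 0.5) / d$photons_per_pixel, dim(vals))
  }
  projection_stack(vals, "intensity", geom)
}

#' Simulate a degraded cone-beam acquisition
#'
#' Full simulation chain: bowtie-hardened polychromatic primary via the
#' ray-driven projector, additive low-frequency scatter, flood saturation
#' error, Poisson noise, normalized by an ideal object-free flood (so the
#' saturation error persists after normalization).
#'
#' @inheritParams simulate_primary
#' @param degradation a [degradation_model()]; its `bowtie_profile` and
#'   `filter_material` are used for the primary as well.
#' @return An intensity-domain [projection_stack()].
#' @export
simulate_acquisition <- function(phantom, geom, spectrum, degradation,
                                 step_mm = NULL) {
  primary <- simulate_primary(phantom, geom, spectrum,
                              bowtie_profile = degradation$bowtie_profile,
                              filter_material = degradation$filter_material,
                              step_mm = step_mm)
  apply_degradation(primary, degradation)
}

#' Calibrate the scatter level to a target uncorrected linearity slope
#'
#' One-dimensional search over the scatter-to-primary ratio such that the
#' uncorrected FDK CT-number linearity slope of the sensitometry phantom
#' matches `target_slope` (higher scatter lowers the slope). The primary
#' is simulated once and the degradation re-applied per candidate.
#'
#' @param target_slope desired uncorrected slope, in (0, 1).
#' @param phantom sensitometry [labeled_phantom()] with an `inserts` table.
#' @param geom,grid,spectrum acquisition fixture.
#' @param base a [degradation_model()] providing all non-scatter fields.
#' @param tol slope tolerance (default 0.03).
#' @param spr_range search bracket for the scatter-to-primary ratio.
#' @param max_iter bisection iterations.
#' @return The calibrated [degradation_model()]; attributes
#'   `achieved_slope` and `primary` (for reuse).
#' @export
calibrate_degradation <- function(target_slope, phantom, geom, grid, spectrum,
                                  base = degradation_model(), tol = 0.03,
                                  spr_range = c(0, 2), max_iter = 12) {
  stopifnot(target_slope > 0, target_slope < 1)
  primary <- simulate_primary(phantom, geom, spectrum,
                              bowtie_profile = base$bowtie_profile,
                              filter_material = base$filter_material)
  slope_of <- function(spr) {
    d <- base; d$scatter_to_primary <- spr
    meas <- apply_degradation(primary, d)
    rec <- fdk_reconstruct(as_line_integrals(meas), grid)
    uncorrected_slope(rec, phantom, spectrum)
  }
  lo <- spr_range[1]; hi <- spr_range[2]
  s_lo <- slope_of(lo)
  if (s_lo < target_slope - tol)
    stop(sprintf("target slope %.2f unreachable: slope at SPR=%g is already %.2f",
                 target_slope, lo, s_lo))
  if (abs(s_lo - target_slope) <= tol) {
    hit <- lo; s_hit <- s_lo
  } else {
    s_hi <- slope_of(hi)
    if (s_hi > target_slope)
      stop(sprintf("target slope %.2f unreachable within SPR range [%g, %g]",
                   target_slope, spr_range[1], spr_range[2]))
    hit <- lo; s_hit <- s_lo
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      s_mid <- slope_of(mid)
      if (abs(s_mid - target_slope) < abs(s_hit - target_slope)) {
        hit <- mid; s_hit <- s_mid
      }
      if (abs(s_mid - target_slope) <= tol / 6) break
      if (s_mid > target_slope) lo <- mid else hi <- mid
    }
    if (abs(s_hit - target_slope) > tol)
      stop(sprintf("calibration did not reach slope %.2f within +/-%.2f (best %.3f)",
                   target_slope, tol, s_hit))
  }
  out <- base; out$scatter_to_primary <- hit
  attr(out, "achieved_slope") <- s_hit
  attr(out, "primary") <- primary
  out
}

# slope of uncorrected insert HU vs true HU (helper shared with metrics)
uncorrected_slope <- function(recon, phantom, spectrum) {
  rep_tab <- insert_means(recon, phantom, spectrum)
  linearity_slope(rep_tab$measured_hu, rep_tab$true_hu)$slope
}

#' Calibrate the photon count to a target uncorrected CNR
#'
#' Searches the Poisson fluence (log-scale bisection) so the uncorrected
#' FDK reconstruction reaches a target contrast-to-noise ratio for a
#' given insert. CNR grows with fluence.
#'
#' @inheritParams calibrate_degradation
#' @param target_cnr desired uncorrected CNR.
#' @param insert insert name for the signal ROI (default `"acrylic"`).
#' @param photon_range search bracket (mean photons per pixel).
#' @export
calibrate_photons <- function(target_cnr, phantom, geom, grid, spectrum,
                              base, insert = "acrylic", tol = 0.1,
                              photon_range = c(50, 5e6), max_iter = 14) {
  primary <- attr(base, "primary")
  if (is.null(primary))
    primary <- simulate_primary(phantom, geom, spectrum,
                                bowtie_profile = base$bowtie_profile,
                                filter_material = base$filter_material)
  rois <- catphan_rois(phantom, insert)
  cnr_of <- function(ph) {
    d <- base; d$photons_per_pixel <- ph
    meas <- apply_degradation(primary, d)
    rec <- fdk_reconstruct(as_line_integrals(meas), grid)
    cnr(rec, rois$signal, rois$background)
  }
  lo <- log(photon_range[1]); hi <- log(photon_range[2])
  c_lo <- cnr_of(exp(lo)); c_hi <- cnr_of(exp(hi))
  if (c_lo > target_cnr || c_hi < target_cnr)
    stop(sprintf("target CNR %.2f unreachable in [%g, %g] photons (got %.2f..%.2f)",
                 target_cnr, photon_range[1], photon_range[2], c_lo, c_hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    c_mid <- cnr_of(exp(mid))
    if (abs(c_mid - target_cnr) <= tol) break
    if (c_mid < target_cnr) lo <- mid else hi <- mid
  }
  out <- base; out$photons_per_pixel <- exp(mid)
  attr(out, "achieved_cnr") <- c_mid
  attr(out, "primary") <- primary
  out
}
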