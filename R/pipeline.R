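#' Full CBCT artifact-correction pipeline
#'
#' Chains the projection-domain shading correction, the iterative
#' beam-hardening correction, reconstruction (FDK or the TV-regularized
#' iterative reconstructor), and the post-reconstruction dome artifact
#' correction. Every stage can be toggled; with all stages disabled the
#' result is the plain FDK reconstruction of `-log I`.
#'
#' @param measured a [projection_stack()] (intensity or line-integral).
#' @param spectrum an [energy_spectrum()].
#' @param materials ordered basis [material_table()]s (air, soft tissue,
#'   bone) used by segmentation, beam-hardening and dome correction.
#' @param geom,grid acquisition geometry and reconstruction grid.
#' @param lfac,bhc,dac stage toggles.
#' @param bowtie per-column bowtie filter path (mm) for the dome
#'   correction energy map; `NULL` yields a uniform map (dome stage
#'   becomes the identity).
#' @param n_bhc beam-hardening iterations (default 3).
#' @param recon final reconstruction: `"fdk"` (default) or `"tv"`.
#' @param tv_weight_lfac TV weight of the shading residual smoothing.
#' @param tv_recon_weight,tv_recon_iter parameters of the TV
#'   reconstruction (when `recon = "tv"`).
#' @param cone_mask optional precomputed [cone_artifact_mask()].
#' @param step_mm projector step.
#' @param verbose print per-stage timing and summaries.
#' @return list with `volume` (corrected [volume_image()]),
#'   `projections` (final corrected stack), `lfac_projections`,
#'   `emap` (mean-energy map or `NULL`), `bhc_rel_change`, and `timings`.
#' @export
cbct_correct <- function(measured, spectrum, materials, geom, grid,
                         lfac = TRUE, bhc = TRUE, dac = TRUE,
                         bowtie = NULL, n_bhc = 3,
                         recon = c("fdk", "tv"), tv_weight_lfac = 0.05,
                         tv_recon_weight = 2e-4, tv_recon_iter = 10,
                         cone_mask = NULL, step_mm = NULL, verbose = FALSE) {
  recon <- match.arg(recon)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))

  p <- as_line_integrals(measured)
  lfac_p <- p
  if ((lfac || bhc) && is.null(cone_mask)) {
    t0 <- tic()
    cone_mask <- cone_artifact_mask(geom, grid, step_mm = step_mm)
    t_all$cone_mask <- tic() - t0
  }
  if (lfac) {
    t0 <- tic()
    lfac_p <- run_lfac(p, spectrum, materials, geom, grid, bowtie = bowtie,
                       tv_weight = tv_weight_lfac, cone_mask = cone_mask,
                       step_mm = step_mm)
    p <- projection_stack(lfac_p$values, "line_integral", geom)
    t_all$lfac <- tic() - t0
    say("shading correction: %.1f s, thresholds %s", t_all$lfac,
        paste(signif(attr(lfac_p, "seg")$thresholds, 3), collapse = "/"))
  }

  rel <- numeric(0)
  vol <- NULL
  if (bhc) {
    t0 <- tic()
    bh <- bhc_iterate(p, spectrum, materials, geom, grid, n_iter = n_bhc,
                      cone_mask = cone_mask, step_mm = step_mm)
    p <- bh$projections
    vol <- bh$volume
    rel <- bh$rel_change
    t_all$bhc <- tic() - t0
    say("beam-hardening: %.1f s, rel change %s", t_all$bhc,
        paste(signif(rel, 3), collapse = " "))
  }

  t0 <- tic()
  if (recon == "tv") {
    vol <- tv_reconstruct(p, grid, n_iter = tv_recon_iter,
                          tv_weight = tv_recon_weight, step_mm = step_mm)
  } else if (is.null(vol)) {
    vol <- fdk_reconstruct(p, grid)
  }
  t_all$recon <- tic() - t0

  emap <- NULL
  if (dac) {
    t0 <- tic()
    emap <- backproject_energy(spectrum, bowtie, geom, grid)
    vol <- dac_correct(vol, emap, materials, spectrum)
    t_all$dac <- tic() - t0
    say("dome correction: %.1f s, energy range %.2f-%.2f keV", t_all$dac,
        min(emap$values), max(emap$values))
  }

  list(volume = vol, projections = p, lfac_projections = lfac_p,
       emap = emap, bhc_rel_change = rel, timings = t_all)
}
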