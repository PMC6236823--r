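---
title: "Attenuation-map correction for cone-beam CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation-map correction for cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cone-beam CT volumes are quantitatively unreliable: scatter and
flood-calibration errors add a low-frequency shading field, the
polychromatic beam hardens as it crosses the object (cupping, streaks),
and a bowtie filter makes the beam spectrum vary across the fan so that
the center of the image is reconstructed at a lower effective energy than
the periphery (the dome/capping artifact). `cbctcorr` implements a chain
of corrections that addresses each mechanism where it lives — shading and
beam hardening in the projection domain, the dome in the image domain —
plus a sinogram-in-painting metal artifact workflow, and a synthetic
acquisition simulator so that every stage can be validated without
scanner data.

This vignette explains the models, the tunable parameters, and the
design decisions that were genuinely open.

## The physical model

Projections are flood-normalized intensities
$I(u,v) = \sum_E \hat S_{u}(E)\, e^{-\int \mu(E, x)\,dl}$, where
$\hat S_u(E)$ is the normalized spectrum of the detector column $u$
(source spectrum hardened by that column's bowtie path). The simulator
(`simulate_acquisition()`) degrades these primaries with

* additive scatter: a Gaussian-blurred, scaled copy of the primary
  (`scatter_to_primary`, blur FWHM 80 mm at the detector) — a
  low-frequency additive model standing in for full Monte-Carlo
  transport;
* a multiplicative flood-field saturation error (a smooth ~3% bump
  centered on the detector) that survives flood normalization;
* Poisson counting noise at `photons_per_pixel` mean unattenuated
  fluence, behind a single seeded RNG.

All spectral bookkeeping runs on discrete energy bins
(`energy_spectrum`), with material attenuation tabulated 20–150 keV and
interpolated log-log (`material_table`). The packaged 90 kVp spectrum is
a heavily filtered Kramers bremsstrahlung model (8.5 mm Al equivalent,
mean energy ≈ 52 keV); the packaged material tables are NIST-style
transcriptions, with the plastics composed from elemental H/C/O/F values
that reproduce the water and PMMA anchor tables to better than 0.1%.

## Reconstruction

`fdk_reconstruct()` is a standard short-scan FDK: cosine pre-weighting
on the virtual detector, band-limited ramp filtering per row, Parker
redundancy weights for the 200° span, voxel-driven backprojection with
bilinear detector interpolation. The ray-driven projector
(`forward_project_mono`, trilinear sampling at half-voxel steps) and the
polychromatic projector (`forward_project_poly`, a loop over basis
materials and energy bins) are the same operators every correction uses.
On noiseless cylinder data the FDK central-ROI value is accurate to
≈0.1%, and the projector reproduces analytic chords to better than 1%.
A TV-regularized SIRT (`tv_reconstruct()`) is provided as a generic
iterative reconstructor for noise-limited studies.

Voxels outside the scanned field-of-view cylinder are undefined in a
short-scan reconstruction; the package masks them to air before any
re-projection of a reconstructed volume (`fov_mask()`). The fixtures
likewise size the reconstruction grid to the detector's axial coverage,
as a scanner does — a grid extending beyond coverage consists mostly of
cone-artifact region, and re-projecting in-painted values there corrupts
the projection-domain corrections.

## Shading correction

`run_lfac()` rebuilds an idealized, degradation-free copy of the
projections and subtracts the smooth part of the difference:

1. FDK reconstruction; cone-artifact region (`cone_artifact_mask()`,
   voxels whose unity-volume round trip deviates by more than 30%)
   in-painted by TV interpolation so its error does not propagate.
2. Three-class histogram segmentation (air / soft tissue / dense) by
   exact two-threshold Otsu. The histogram split is accepted only when
   the class means are plausible for the basis materials assigned to
   them; for objects without a genuine dense class (an all-plastic
   phantom) the soft/dense threshold falls back to the basis midpoint.
   Partial-volume "skin" at air-bone surfaces is returned to air, small
   spurious components are dropped, and the class indicators are
   anti-aliased with a one-voxel boxcar: a hard-thresholded surface is
   only accurate to half a voxel, and at desk-scale voxel sizes the
   resulting silhouette error would otherwise dominate the residual.
3. Polychromatic re-projection of the class maps at their
   spectrum-weighted attenuations (`ideal_projections()`), per-column
   bowtie spectra included when the bowtie is known — the residual then
   isolates the additive degradations while the dome signature stays in
   the projections for the downstream stages.
4. The measured-minus-ideal difference is formed **in the intensity
   domain**, where additive scatter is exactly additive (a line-integral
   difference would leave a `log(1 + S/I)` modulation at every structure
   that no smooth subtraction can remove). Pixels on the ideal
   projections' silhouette edges — where the residual is dominated by
   the prior's half-voxel surface error — are interpolated across before
   smoothing. The residual is then ROF-smoothed per view on a 4×
   down-sampled grid (it is low-frequency by construction; structures
   narrower than ≈20 detector pixels are removed), capped at 98% of the
   measured intensity, and subtracted. The output is returned as line
   integrals.

On undegraded head data the whole operation changes the projections by
less than 1% rms; under calibrated scatter it removes most of the
shading while leaving structure intact.

## Beam-hardening correction

`bhc_iterate()` linearizes the corrected projections against a basis
material model. Each voxel's attenuation is decomposed onto ordered
basis materials by the two-neighbor linear mapping (`map_to_basis()`;
the decomposition is an exact partition of unity inside the basis range,
values above the top material are capped and recovered over the outer
iterations). The update adds the mismatch between the monochromatic and
polychromatic re-projections of the decomposition,
$P_{n+1} = -\log I_C + P_{mono}^{(n)} - P_{poly}^{(n)}$, re-reconstructing
each iteration; three iterations bring the relative projection update
below 1% on the sensitometry fixture, and with a monochromatic spectrum
the whole operation is the identity.

Two design choices matter:

* **Basis materials must span the object.** For brain anatomy the basis
  is air / brain / cortical bone. For the all-plastic sensitometry
  phantom, decomposing Teflon as a water-bone blend imports bone's
  photoelectric-heavy energy dependence that no plastic has and
  overcorrects it by hundreds of HU; the sensitometry studies therefore
  use air / water / Teflon. Even so, the hydrocarbon plastics (PMP,
  LDPE, polystyrene) have a flatter energy dependence than any
  water-Teflon blend of equal attenuation, and the model overcorrects
  them by ≈40 HU under this spectrum — a structural limitation of
  value-ordered basis interpolation that shrinks as the beam hardens.
* The divergence guard watches the relative projection-update norm; the
  mono/poly mismatch itself grows toward its asymptote during healthy
  convergence and is not a usable divergence signal.

## Dome correction

`dac_correct()` remaps each voxel from the energy it was actually sensed
at to a global reference. The mean sensed energy map comes from an
unfiltered FDK-weighted backprojection of the per-column post-bowtie
mean energies, normalized by backprojected unity
(`backproject_energy()`); object self-filtration is deliberately
excluded. The basis node attenuations at a voxel's local energy are read
from a one-parameter family of bowtie-hardened spectra — (mean energy,
spectrum-weighted basis attenuation) pairs tabulated along filter
thickness — which keeps the correction on the same spectrum-weighted
attenuation scale as the beam-hardening stage and makes it an exact
identity at the reference energy. On the bowtie fixture the correction
removes 55–60% of the center-vs-periphery dome left after beam
hardening; the residual (including the faint dark-ring behavior at the
object boundary) is an expected limitation of a purely radial,
backprojection-averaged energy model.

## Metal artifact workflow

`run_mar()` handles frame-pin metal: detect metal by thresholding (3×
the bone attenuation by default, small components removed, one-voxel
dilation for the partial-volume shell); in-paint the pins' projection
shadow across rows, columns *and neighboring views* (which see behind
the metal) with a near-harmonic interpolation — an edge-preserving fill
locks onto one side of sinogram gradients and reconstructs as streaks;
run the full correction chain on the in-painted projections; build a
synthetic image (corrected volume with soft tissue flattened to its
mean, metal values restored); re-project it polychromatically; and add
the denoised residual of the shading-corrected original projections
against that synthetic re-projection, so anatomy detail returns while
the synthetic supplies a consistent, streak-free metal signal inside the
shadow. The restored projections are finished through the
beam-hardening and dome stages and the detected metal values reinserted.
Without metal the workflow is a numeric pass-through of the plain
pipeline. The detail denoiser is a Bregman-refined ROF (weight 0.2,
three passes): anatomy above the TV scale threshold keeps its full
amplitude while noise and inconsistent metal residue stay removed — a
single plain ROF pass either shaves the anatomy or passes the noise.

## Study fixtures and problem sizes

The validation experiments run at desk scale: the sensitometry fixture
uses a 150 mm phantom on a 120×120×36 grid of 1.35 mm voxels, a 164×48
detector at 1.8 mm pitch (source-axis 500 mm, source-detector 900 mm),
60 views over 200°, and a 10-bin spectrum; the head fixture is 64×64×48
at 2.2 mm with 48 views. The phantom body spans the full grid axially,
as the physical multi-module phantom extends beyond the imaged field of
view. These sizes keep a full pipeline run around a minute while
preserving the artifact structure; they are 4–6× coarser than a clinical
half-cone system, which is why partial-volume handling (anti-aliased
priors, the PV-skin rule) carries more weight here than it would at
clinical resolution.

The experiments calibrate the simulator to the stated uncorrected
operating points rather than asserting absolute degradation levels: the
scatter level is searched so the uncorrected FDK linearity slope is
0.80 (`calibrate_degradation()`), and the photon fluence so the
uncorrected acrylic CNR is 1.8 (`calibrate_photons()`). The 10 mm
parabolic aluminum bowtie, the 3% flood error and the frame-pin geometry
are fixtures: plausible for a compact half-cone head scanner, not
reconstructions of any particular system.

## What the simulations do and do not show

The simulator shares its projector, spectrum and material tables with
the corrections, so these studies validate the algorithm chain under its
own physics (an "inverse crime" in the reconstruction sense): they
demonstrate that each stage removes the artifact mechanism it targets,
with honest desk-scale discretization effects. They do not test
robustness to detector lag, glare, spectral miscalibration, or scatter
that deviates from the low-frequency additive model — on real data the
ideal projections would disagree with the measurements in ways the
simulator cannot produce. The residual ≈30 HU mean absolute CT-number
error of the corrected sensitometry reconstruction is dominated by the
hydrocarbon-plastic basis mismatch described above, not by the shading
or dome corrections.

## Numerical choices

* Ray sampling step: half a voxel. Backprojection: bilinear on the
  detector. Parker weighting uses the half-fan implied by the span.
* ROF solved by Chambolle's projected dual iteration (`tv_denoise2d`),
  validated against the analytic disk-shrinkage solution.
* TV in-painting is a nonlinear Gauss-Seidel with edge-stopping weights
  `1/sqrt(diff^2 + eps^2)`; `eps` small for image-domain cone
  in-painting (edge-preserving), large for sinogram fill
  (near-harmonic).
* Intensities are floored before logs; the shading subtraction is
  capped at 98% of the measured intensity.
* Negative reconstructed values are clamped to the lowest basis
  attenuation before decomposition; reconstructed values above the top
  basis material are capped by the mapping itself.
* All randomness flows through one seeded RNG per simulation; pipelines
  are bit-deterministic given data and configuration.
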