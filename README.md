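# cbctcorr

Quantitative artifact correction for cone-beam CT (CBCT) attenuation
maps, with a synthetic acquisition simulator for validation.

CBCT volumes from compact image-guidance systems suffer from shading
(scatter and flood-calibration errors), beam hardening, the bowtie
dome/capping artifact, and — with fixation frames — metal streaks.
Together these make CT numbers non-linear and soft tissue hard to see.
`cbctcorr` implements a correction chain for users who need usable CT
numbers and soft-tissue contrast from such systems, and for researchers
who want a fully inspectable, simulation-backed reference
implementation:

* **Shading correction** (`run_lfac`): segment an FDK reconstruction
  into air/soft/dense classes, re-project the classes polychromatically
  as an idealized prior, TV-smooth the measured-minus-ideal intensity
  residual, and subtract it.
* **Beam-hardening correction** (`bhc_iterate`): decompose each voxel
  onto basis materials with the linear two-neighbor mapping
  `T_i(f)` (an exact partition of unity), and iteratively update the
  projections by the monochromatic-minus-polychromatic re-projection
  mismatch, `P_{n+1} = -log I_C + P_mono - P_poly`.
* **Dome correction** (`dac_correct`): estimate each voxel's mean sensed
  energy by energy-dependent backprojection of the bowtie-hardened
  spectrum, then remap the voxel to a global reference energy through
  the same basis mapping.
* **Metal artifact reduction** (`run_mar`): in-paint the metal shadow in
  the sinogram, run the correction chain, restore detail and a
  consistent metal signal from a synthetic-image re-projection.
* **Simulator** (`simulate_acquisition`, `make_catphan_sensitometry`,
  `make_head_phantom`): polychromatic, bowtie-filtered primaries with
  additive low-frequency scatter, flood saturation error and Poisson
  noise, plus digital sensitometry and head phantoms.
* **Metrics** (`catphan_report`, `cnr`, `linearity_slope`,
  `mean_abs_ct_error`): CT-number linearity and accuracy, and
  contrast-to-noise ratio.

The reconstructors are a short-scan FDK (Parker weighting, compiled
ray-driven/voxel-driven projector pair) and a TV-regularized SIRT.
A thin command-line front end is installed at
`system.file("cli", "cbctcorr", package = "cbctcorr")`.

## Worked example

Simulate a degraded sensitometry scan calibrated to an uncorrected
linearity slope of 0.80, correct it, and score both reconstructions:

```r
library(cbctcorr)

st <- linearity_study(seed = 0)   # calibrate, simulate, correct (~1.5 min)

st$uncorrected$slope
#> [1] 0.8039359
st$corrected$slope
#> [1] 0.9820207
st$uncorrected$mae_hu
#> [1] 112.7357
st$corrected$mae_hu
#> [1] 31.02926
round(st$corrected$inserts$measured_hu)
#> [1] -986 -239 -159  -59   94  333 1080
```

The uncorrected reconstruction compresses the CT-number scale (slope
0.80: dense inserts read far too low because of scatter and beam
hardening) and is off by 113 HU on average. After shading,
beam-hardening and dome correction the regression of measured on true
insert CT numbers has slope 0.98 and the mean absolute error drops to
≈31 HU; the per-insert values above run from the air insert (true
−999 HU) to Teflon (true +1104 HU). The contrast-to-noise companion
study starts from a noise level calibrated to an acrylic-insert CNR of
1.8 and reaches ≈17 with the TV-regularized reconstruction:

```r
cn <- cnr_study(seed = 0, degradation = st$degradation,
                fixture = st$fixture)
c(cn$cnr_uncorrected, cn$cnr_corrected)
#> [1]  1.730932 16.603250
```

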