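# Small fixtures and a lazy cache for the expensive shared computations.
# Everything is generated in code; nothing is read from disk.

# two-bin water-like material and flat spectrum used by the closed-form
# polychromatic oracles
twobin_material <- function(mu = c(0.040, 0.020), name = "w2") {
  material_table(name, c(40, 80), mu_linear_per_mm = mu)
}
twobin_spectrum <- function(w = c(1, 1)) energy_spectrum(c(40, 80), w)

# small cone-beam geometry: full 200-degree short scan, centered detector
small_geom <- function(n_views = 24, det_rows = 28, det_cols = 64,
                       pitch = 2.2, offset = c(0, 0)) {
  cone_beam_geometry(500, 900, det_rows, det_cols, pitch,
                     det_offset_mm = offset,
                     angles_deg = seq(0, 200, length.out = n_views + 1)[1:n_views])
}
small_grid <- function(n = 40, nz = 24, voxel = 2.5) {
  voxel_grid(n, n, nz, voxel_mm = voxel)
}

# uniform cylinder volume (axis = rotation axis)
cylinder_volume <- function(grid, radius, mu0) {
  g <- cbctcorr:::grid_fields(grid)
  volume_image(array(mu0 * (g$x^2 + g$y^2 <= radius^2), grid$n), grid)
}

# lazy memoized computations shared across test files
.fix_cache <- new.env(parent = emptyenv())
fix_cached <- function(name, expr) {
  if (!exists(name, envir = .fix_cache))
    assign(name, force(expr), envir = .fix_cache)
  get(name, envir = .fix_cache)
}

cached_study <- function() fix_cached("study", linearity_study(seed = 0))

cached_head_null <- function() fix_cached("head_null", {
  fx <- head_fixture(photons_per_pixel = 0)
  meas <- simulate_acquisition(fx$phantom, fx$geom, fx$spectrum, fx$base)
  li <- as_line_integrals(meas)
  cm <- cone_artifact_mask(fx$geom, fx$grid)
  lf <- run_lfac(li, fx$spectrum, fx$materials, fx$geom, fx$grid,
                 cone_mask = cm)
  list(fx = fx, li = li, lf = lf, cone_mask = cm,
       rms = sqrt(mean((lf$values - li$values)^2)) /
         sqrt(mean(li$values^2)))
})

cached_mar <- function() fix_cached("mar", {
  fxm <- head_fixture(with_metal = TRUE, photons_per_pixel = 0)
  fxf <- head_fixture(with_metal = FALSE, photons_per_pixel = 0)
  m1 <- simulate_acquisition(fxm$phantom, fxm$geom, fxm$spectrum, fxm$base)
  m2 <- simulate_acquisition(fxf$phantom, fxf$geom, fxf$spectrum, fxf$base)
  r1 <- fdk_reconstruct(as_line_integrals(m1), fxm$grid)
  vol_mar <- run_mar(m1, fxm$spectrum, fxm$materials, fxm$geom, fxm$grid)
  ref <- cbct_correct(m2, fxf$spectrum, fxf$materials, fxf$geom,
                      fxf$grid)$volume
  list(fxm = fxm, fxf = fxf, meas = m1, uncorr = r1, mar = vol_mar,
       ref = ref)
})
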