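test_that("sensitometry phantom has the stated layout", {
  grid <- voxel_grid(110, 110, 20, voxel_mm = 1.5)
  ph <- make_catphan_sensitometry(grid)
  labs <- sort(unique(as.integer(ph$labels)))
  # air background + body shell + interior + 7 inserts + spheres
  expect_equal(labs, 0:10)
  expect_equal(nrow(ph$inserts), 7)
  # insert voxel counts match the analytic cylinder volume within a shell
  vox_per_insert <- table(ph$labels[ph$labels %in% 3:9])
  area_vox <- pi * ph$inserts$radius_mm[2]^2 / grid$voxel_mm^2
  expect_equal(as.numeric(vox_per_insert[["4"]]) / grid$n[3], area_vox,
               tolerance = 2 * pi * ph$inserts$radius_mm[2] /
                 grid$voxel_mm / area_vox)
  # true attenuation ordering of the inserts
  sp <- default_spectrum(10)
  mu <- vapply(as.character(ph$inserts$label), function(l)
    effective_mu(ph$material_of_label[[l]], sp), numeric(1))
  expect_true(all(diff(mu) > 0))
  expect_error(make_catphan_sensitometry(voxel_grid(40, 40, 10, voxel_mm = 2)),
               "too small")
})

test_that("head phantom metal flag and ventricle contrast behave as designed", {
  grid <- voxel_grid(64, 64, 48, voxel_mm = 2.2)
  ph0 <- make_head_phantom(grid, with_metal = FALSE)
  expect_false(any(ph0$labels == 5L))
  phm <- make_head_phantom(grid, with_metal = TRUE)
  expect_true(any(phm$labels == 5L))
  # pins lie outside the brain
  expect_equal(sum(phm$labels == 5L & ph0$labels %in% c(2L, 3L, 4L)) /
                 sum(phm$labels == 5L), 0, tolerance = 0.05)
  # CSF-like ventricle contrast is at most 1.5% of brain attenuation
  sp <- default_spectrum(10)
  mu_b <- effective_mu(cbct_material("brain"), sp)
  mu_v <- effective_mu(ph0$material_of_label[["3"]], sp)
  expect_lt(abs(mu_v - mu_b) / mu_b, 0.015)
})

test_that("degradation chain is the identity when all fields are neutral", {
  grid <- voxel_grid(48, 48, 16, voxel_mm = 2.5)
  geom <- small_geom(n_views = 12, det_rows = 16, det_cols = 72, pitch = 2.6)
  sp <- energy_spectrum(60, 1)  # monoenergetic
  ph <- make_catphan_sensitometry(grid, body_diameter_mm = 100)
  meas <- simulate_acquisition(ph, geom, sp, degradation_model())
  li <- as_line_integrals(meas)
  # flood-normalized projections measure attenuation in excess of air
  mu_map <- phantom_to_mu_volume(ph, energy_keV = 60)
  air <- array(ph$labels %in% c(0L, 3L), grid$n)
  mu_map$values[air] <- 0
  ref <- forward_project_mono(mu_map, geom)
  expect_equal(li$values, ref$values, tolerance = 1e-6)
})

test_that("scatter adds intensity and the simulation is seed-deterministic", {
  grid <- voxel_grid(48, 48, 16, voxel_mm = 2.5)
  geom <- small_geom(n_views = 8, det_rows = 16, det_cols = 72, pitch = 2.6)
  sp <- default_spectrum(6)
  ph <- make_catphan_sensitometry(grid, body_diameter_mm = 100)
  prim <- simulate_primary(ph, geom, sp)
  d <- degradation_model(scatter_to_primary = 0.3)
  sc <- apply_degradation(prim, d)
  expect_true(all(sc$values > prim$values))
  dn <- degradation_model(photons_per_pixel = 1e4, seed = 11)
  a <- apply_degradation(prim, dn)
  b <- apply_degradation(prim, dn)
  expect_identical(a$values, b$values)
  d2 <- dn; d2$seed <- 12L
  expect_false(identical(apply_degradation(prim, d2)$values, a$values))
})

test_that("Poisson stage has the right mean-variance relation", {
  geom <- small_geom(n_views = 1, det_rows = 40, det_cols = 50, pitch = 2)
  # constant intensity field: every pixel is an independent draw
  prim <- projection_stack(array(0.5, c(40, 50, 1)), "intensity", geom)
  d <- degradation_model(photons_per_pixel = 2e4, seed = 3)
  out <- apply_degradation(prim, d)
  counts <- out$values * 2e4
  expect_equal(var(as.numeric(counts)), mean(counts), tolerance = 0.1)
})

test_that("scatter calibration is monotone and reaches its target", {
  # scaled-down sensitometry acquisition to keep the search cheap
  fxs <- catphan_fixture(grid_n = 80, grid_nz = 20, voxel_mm = 2,
                         n_views = 30, photons_per_pixel = 0)
  geom <- cone_beam_geometry(500, 900, 32, 110, 2.7,
                             angles_deg = fxs$geom$angles_deg)
  base <- degradation_model(bowtie_profile = bowtie_profile(geom, 10))
  prim <- simulate_primary(fxs$phantom, geom, fxs$spectrum,
                           bowtie_profile = base$bowtie_profile)
  slopes <- vapply(c(0, 0.1, 0.3), function(spr) {
    dd <- base; dd$scatter_to_primary <- spr
    rec <- fdk_reconstruct(as_line_integrals(apply_degradation(prim, dd)),
                           fxs$grid)
    cbctcorr:::uncorrected_slope(rec, fxs$phantom, fxs$spectrum)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))  # more scatter, lower slope
  deg <- calibrate_degradation(0.80, fxs$phantom, geom, fxs$grid,
                               fxs$spectrum, base = base)
  expect_lt(abs(attr(deg, "achieved_slope") - 0.80), 0.03)
  # closure: re-simulating with the returned model reproduces the slope
  rec <- fdk_reconstruct(as_line_integrals(
    simulate_acquisition(fxs$phantom, geom, fxs$spectrum, deg)), fxs$grid)
  expect_lt(abs(cbctcorr:::uncorrected_slope(rec, fxs$phantom, fxs$spectrum) -
                  attr(deg, "achieved_slope")), 1e-6)
})
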