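test_that("geometry and container validation catch inconsistencies", {
  expect_error(cone_beam_geometry(900, 500, 10, 10, 1, angles_deg = 0:10),
               "source_detector_dist")
  g <- small_geom()
  expect_error(projection_stack(array(0, c(2, 2, 2)), "intensity", g),
               "dimensions")
  grid <- small_grid()
  expect_error(volume_image(array(0, c(2, 2, 2)), grid), "dimensions")
  expect_error(volume_image(array(NA_real_, grid$n), grid), "finite")
})

test_that("ray-driven projector reproduces analytic chords", {
  grid <- voxel_grid(64, 64, 40, voxel_mm = 2)
  geom <- small_geom(det_rows = 32, det_cols = 96, pitch = 2)
  mu0 <- 0.02
  # sphere: central ray crosses the full diameter
  g <- cbctcorr:::grid_fields(grid)
  sph <- volume_image(array(mu0 * (g$x^2 + g$y^2 + g$z^2 <= 40^2), grid$n),
                      grid)
  p <- forward_project_mono(sph, geom, step_mm = 1)
  ctr <- p$values[16, 48, 1] / 2 + p$values[17, 49, 1] / 2  # near-central rays
  ctr <- mean(p$values[16:17, 48:49, 1])
  expect_equal(ctr, 2 * 40 * mu0, tolerance = 0.005)

  # cylinder: off-center ray at impact parameter d has chord 2*sqrt(R^2-d^2)
  R <- 40; d <- 20
  cyl <- cylinder_volume(grid, R, mu0)
  pc <- forward_project_mono(cyl, geom, step_mm = 1)
  u_det <- d * geom$sad / sqrt(geom$sad^2 - d^2) * geom$sdd / geom$sad
  ui <- u_det / geom$det_pitch_mm + (geom$det_cols - 1) / 2 + 1
  lo <- floor(ui); fr <- ui - lo
  row <- (geom$det_rows + 1) / 2
  val <- (1 - fr) * mean(pc$values[floor(row):ceiling(row), lo, 1]) +
    fr * mean(pc$values[floor(row):ceiling(row), lo + 1, 1])
  expect_equal(val, 2 * mu0 * sqrt(R^2 - d^2), tolerance = 0.01)

  # zero volume projects to zero
  z <- forward_project_mono(volume_image(array(0, grid$n), grid), geom)
  expect_true(all(z$values == 0))
})

test_that("polychromatic projection matches the Beer-Lambert oracle", {
  grid <- voxel_grid(50, 50, 20, voxel_mm = 2)
  # 100 mm slab along x centered at isocenter, rendered as one basis map
  g <- cbctcorr:::grid_fields(grid)
  m <- twobin_material()
  sp <- twobin_spectrum()
  mu_bar <- effective_mu(m, sp)                       # 0.030
  slab <- array(mu_bar * (abs(g$x) <= 50), grid$n)
  geom <- small_geom(det_rows = 16, det_cols = 48, pitch = 3)
  pp <- forward_project_poly(list(volume_image(slab, grid)), sp, list(m),
                             geom, step_mm = 0.5)
  # central ray of the first view travels along x through the 100 mm slab:
  # g = 3.0, sigma_hat = (4/3, 2/3); independent hand evaluation of
  # -log(0.5 exp(-4) + 0.5 exp(-2)) = 2.56633
  ctr <- mean(pp$values[8:9, 24:25, 1])
  expect_equal(ctr, -log(0.5 * exp(-4) + 0.5 * exp(-2)), tolerance = 0.01)
  expect_equal(ctr, 2.566219, tolerance = 0.01)

  # monoenergetic spectrum collapses to the sum of material projections
  sp1 <- energy_spectrum(60, 1)
  m1 <- material_table("m1", c(40, 80), mu_linear_per_mm = c(0.03, 0.03))
  maps <- list(volume_image(slab, grid), volume_image(slab / 2, grid))
  pp1 <- forward_project_poly(maps, sp1, list(m1, m1), geom)
  gsum <- Reduce(`+`, attr(pp1, "g"))
  expect_equal(pp1$values, gsum, tolerance = 1e-12)

  # zero maps give zero projections
  pz <- forward_project_poly(list(volume_image(array(0, grid$n), grid)),
                             sp, list(m), geom)
  expect_true(all(abs(pz$values) < 1e-12))
  expect_error(forward_project_poly(maps, sp, list(m), geom), "one map per")
})

test_that("polychromatic projection never exceeds the mono sum (Jensen)", {
  grid <- small_grid()
  set.seed(7)
  g <- cbctcorr:::grid_fields(grid)
  geom <- small_geom()
  sp <- default_spectrum(6)
  mats <- list(cbct_material("water"), cbct_material("cortical_bone"))
  maps <- list(
    volume_image(0.02 * (g$x^2 + g$y^2 <= 35^2), grid),
    volume_image(0.06 * ((g$x - 10)^2 + g$y^2 <= 12^2), grid))
  pp <- forward_project_poly(maps, sp, mats, geom)
  gsum <- Reduce(`+`, attr(pp, "g"))
  expect_true(all(pp$values <= gsum + 1e-10))
})

test_that("FDK recovers a uniform cylinder quantitatively", {
  grid <- voxel_grid(64, 64, 24, voxel_mm = 2)
  geom <- small_geom(n_views = 48, det_rows = 24, det_cols = 96, pitch = 2)
  mu0 <- 0.02
  cyl <- cylinder_volume(grid, 40, mu0)
  p <- forward_project_mono(cyl, geom)
  rec <- fdk_reconstruct(p, grid)
  ctr <- roi_stats(rec, roi_spec(c(0, 0), 15, c(-8, 8)))$mean
  expect_equal(ctr, mu0, tolerance = 0.03)
  off <- roi_stats(rec, roi_spec(c(22, 0), 8, c(-8, 8)))$mean
  expect_equal(off, mu0, tolerance = 0.03)
  # all-zero projections reconstruct to (numerically) zero
  z <- fdk_reconstruct(projection_stack(array(0, dim(p$values)),
                                        "line_integral", geom), grid)
  expect_true(all(abs(z$values) < 1e-12))
})

test_that("short-scan reconstruction requires 180 degrees plus fan", {
  geom <- cone_beam_geometry(500, 900, 16, 64, 2.2,
                             angles_deg = seq(0, 150, length.out = 20))
  p <- projection_stack(array(0, c(16, 64, 20)), "line_integral", geom)
  expect_error(fdk_reconstruct(p, small_grid()), "180")
})

test_that("insert means reconstruct in the true attenuation order", {
  grid <- voxel_grid(96, 96, 16, voxel_mm = 1.7)
  geom <- small_geom(n_views = 48, det_rows = 20, det_cols = 148, pitch = 2)
  sp <- default_spectrum(8)
  ph <- make_catphan_sensitometry(grid)
  vol <- phantom_to_mu_volume(ph, sp)
  rec <- fdk_reconstruct(forward_project_mono(vol, geom), grid)
  tab <- cbctcorr:::insert_means(rec, ph, sp)
  expect_equal(order(tab$measured_hu), order(tab$true_hu))
})

test_that("ray-driven projector and voxel-driven backprojector are near-adjoint", {
  set.seed(1)
  grid <- small_grid()
  geom <- small_geom()
  g <- cbctcorr:::grid_fields(grid)
  for (k in 1:3) {
    cx <- runif(3, -20, 20)
    x <- exp(-((g$x - cx[1])^2 + (g$y - cx[2])^2 + (g$z - cx[3] / 2)^2) /
               (2 * 12^2))
    y <- forward_project_mono(volume_image(
      exp(-((g$x + cx[2])^2 + (g$y - cx[3])^2 + g$z^2) / (2 * 15^2)), grid),
      geom)
    px <- forward_project_mono(volume_image(x, grid), geom)
    bty <- cbctcorr:::backproject_adjoint(y, grid)
    lhs <- sum(px$values * y$values)
    rhs <- sum(x * bty$values)
    expect_lt(abs(lhs - rhs) / abs(lhs), 0.02)
  }
})

test_that("energy backprojection maps bowtie hardening into the volume", {
  grid <- voxel_grid(40, 40, 12, voxel_mm = 3)
  geom <- small_geom(n_views = 24, det_rows = 16, det_cols = 64, pitch = 3)
  sp <- default_spectrum(10)
  # no bowtie: uniform map at the spectrum mean energy
  em0 <- backproject_energy(sp, NULL, geom, grid)
  fov <- fov_mask(geom, grid)
  expect_equal(max(abs(em0$values[fov] - mean_energy(sp))), 0,
               tolerance = 1e-6)
  # bowtie thicker at the periphery: peripheral voxels sense harder beam
  bt <- bowtie_profile(geom, max_mm = 10)
  em <- backproject_energy(sp, bt, geom, grid)
  ctr <- roi_stats(em, roi_spec(c(0, 0), 10, c(-5, 5)))$mean
  per <- roi_stats(em, roi_spec(c(45, 0), 8, c(-5, 5)))$mean
  expect_gt(per, ctr)
})

test_that("cone-artifact mask flags the truncated axial end of a half-cone scan", {
  grid <- voxel_grid(40, 40, 30, voxel_mm = 2.2)
  # full cone, generous coverage: central axial half inside the FOV is clean
  geom_full <- small_geom(n_views = 24, det_rows = 60, det_cols = 72,
                          pitch = 2.4)
  m_full <- cone_artifact_mask(geom_full, grid)
  g <- cbctcorr:::grid_fields(grid)
  interior <- g$x^2 + g$y^2 <= 40^2   # well inside the scan FOV
  central <- m_full[, , 9:22] & interior[, , 9:22]
  expect_equal(sum(central), 0)
  # offset detector (half-cone): mask grows toward the truncated end
  geom_half <- small_geom(n_views = 24, det_rows = 60, det_cols = 72,
                          pitch = 2.4, offset = c(30, 0))
  m_half <- cone_artifact_mask(geom_half, grid)
  frac_low <- mean(m_half[, , 1:6][interior[, , 1:6]])    # truncated end
  frac_mid <- mean(m_half[, , 13:18][interior[, , 13:18]])
  expect_gt(frac_low, frac_mid)
  # default threshold is the 30% deviation rule
  expect_equal(formals(cone_artifact_mask)$threshold, 0.3)
})
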