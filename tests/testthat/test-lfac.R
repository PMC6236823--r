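test_that("segmentation recovers well-separated plateaus and flags empty scans", {
  grid <- voxel_grid(30, 30, 10, voxel_mm = 2)
  g <- cbctcorr:::grid_fields(grid)
  v <- array(0, grid$n)
  v[g$x^2 + g$y^2 <= 25^2] <- 0.02
  v[g$x^2 + g$y^2 <= 10^2] <- 0.04
  seg <- segment_by_histogram(volume_image(v, grid))
  expect_equal(seg$labels == 1L, v == 0.02)
  expect_equal(seg$labels == 2L, v == 0.04)
  expect_equal(seg$labels == 0L, v == 0)
  expect_error(segment_by_histogram(
    volume_image(array(rnorm(9000, 0, 1e-4), grid$n), grid)), "unimodal")
})

test_that("segmentation of a reconstructed head recovers bone accurately", {
  hn <- cached_head_null()
  seg <- attr(hn$lf, "seg")
  truth_bone <- hn$fx$phantom$labels == 1L
  sb <- seg$labels == 2L
  dice <- 2 * sum(sb & truth_bone) / (sum(sb) + sum(truth_bone))
  expect_gte(dice, 0.9)
})

test_that("ideal re-projection collapses correctly in degenerate cases", {
  grid <- voxel_grid(30, 30, 10, voxel_mm = 2)
  geom <- small_geom(n_views = 8, det_rows = 12, det_cols = 48, pitch = 3)
  sp <- default_spectrum(6)
  mats <- list(cbct_material("air"), cbct_material("water"),
               cbct_material("cortical_bone"))
  # air-only segmentation projects to (numerically) zero
  seg0 <- structure(list(labels = array(0L, grid$n),
                         thresholds = c(0.01, 0.04), grid = grid),
                    class = "segmentation_map")
  p0 <- ideal_projections(seg0, sp, mats, geom)
  expect_lt(max(abs(p0$values)), 0.01)
  # single material, monoenergetic spectrum: equals the mono projection
  g <- cbctcorr:::grid_fields(grid)
  lab <- array(0L, grid$n); lab[g$x^2 + g$y^2 <= 20^2] <- 1L
  seg1 <- structure(list(labels = lab, thresholds = c(0.01, 0.04),
                         grid = grid), class = "segmentation_map")
  sp1 <- energy_spectrum(60, 1)
  p1 <- ideal_projections(seg1, sp1, mats, geom, antialias = FALSE)
  ref <- forward_project_mono(volume_image(
    array((lab == 1L) * mu_at(mats[[2]], 60), grid$n), grid), geom)
  expect_equal(p1$values, ref$values, tolerance = 1e-10)
  # unmapped label errors
  expect_error(ideal_projections(seg1, sp, mats[1:1], geom), "no material")
})

test_that("ideal projections of the true labels close the loop with the simulator", {
  # three-material head (air / brain / bone only) so the class prior is an
  # exact description of the object
  fx <- head_fixture(photons_per_pixel = 0)
  labs <- fx$phantom$labels
  labs[labs %in% c(3L, 4L)] <- 2L
  ph <- labeled_phantom(labs, fx$phantom$material_of_label[c("0", "1", "2")],
                        fx$grid)
  li <- as_line_integrals(simulate_acquisition(ph, fx$geom, fx$spectrum,
                                               fx$base))
  tl <- labs
  tl[labs == 2L] <- 1L
  tl[labs == 1L] <- 2L
  seg_true <- structure(list(labels = tl, thresholds = c(NA, NA),
                             grid = fx$grid), class = "segmentation_map")
  id_true <- ideal_projections(seg_true, fx$spectrum, fx$materials, fx$geom,
                               antialias = FALSE)
  expect_lt(sqrt(mean((li$values - id_true$values)^2)), 1e-3)
})

test_that("residual subtraction is exact, passes smooth fields, keeps structure", {
  geom <- small_geom(n_views = 4, det_rows = 48, det_cols = 128, pitch = 2.5)
  base <- array(rep(0.5 + 0.3 * sin(seq(0, pi, length.out = 128)),
                    each = 48), c(48, 128, 4))
  ideal <- projection_stack(-log(base), "line_integral", geom)
  # measured == ideal: output == measured
  out0 <- lfac_correct(ideal, ideal)
  expect_equal(out0$values, ideal$values, tolerance = 1e-9)
  # smooth additive intensity bias is removed almost entirely (interior;
  # the coarse smoothing is less accurate in the outermost rows/columns)
  u <- outer(rep(1, 48), seq_len(128)); v <- outer(seq_len(48), rep(1, 128))
  bias <- 0.15 * exp(-((u - 64)^2 + (v - 24)^2) / (2 * 45^2))
  bias3 <- array(rep(bias, 4), dim(base))
  meas <- projection_stack(base + bias3, "intensity", geom)
  out1 <- lfac_correct(meas, ideal)
  interior <- function(a) a[9:40, 17:112, ]
  expect_lt(mean(abs(interior(exp(-out1$values)) - interior(base)) /
                   interior(base)), 0.02)
  # a sharp small structure absent from the ideal survives the correction
  spot <- array(0, dim(base)); spot[20:25, 60:66, ] <- -0.1
  meas2 <- projection_stack(base + bias3 + spot, "intensity", geom)
  out2 <- lfac_correct(meas2, ideal)
  rec_spot <- exp(-out2$values[22, 62, 1]) - exp(-out2$values[22, 90, 1])
  expect_equal(rec_spot, spot[22, 62, 1], tolerance = 0.25)
  expect_error(lfac_correct(ideal, projection_stack(base[, 1:32, ],
                                                    "intensity",
                            small_geom(n_views = 4, det_rows = 48,
                                       det_cols = 32, pitch = 2.5))),
               "shape")
})

test_that("cone-region in-painting leaves unmasked voxels bit-exact", {
  grid <- small_grid(32, 16)
  set.seed(2)
  vol <- volume_image(array(runif(32 * 32 * 16), grid$n), grid)
  mask <- array(FALSE, grid$n); mask[10:15, 10:15, 4:8] <- TRUE
  out <- inpaint_cone_region(vol, mask)
  expect_identical(out$values[!mask], vol$values[!mask])
  expect_error(inpaint_cone_region(vol, array(TRUE, grid$n)), "entire")
})

test_that("shading correction is a null operation on undegraded head data", {
  hn <- cached_head_null()
  expect_lt(hn$rms, 0.01)
  expect_equal(hn$lf$domain, "line_integral")
})

test_that("shading correction reduces reconstruction error under scatter", {
  st <- cached_study()
  fx <- st$fixture
  truth <- phantom_to_mu_volume(fx$phantom, fx$spectrum)
  cm <- cone_artifact_mask(fx$geom, fx$grid)
  fov <- fov_mask(fx$geom, fx$grid)
  msk <- fov & array(rep(outer(cbctcorr:::voxel_centers(fx$grid, 1)^2,
                               cbctcorr:::voxel_centers(fx$grid, 2)^2, `+`) <= 70^2,
                         fx$grid$n[3]), fx$grid$n)
  for (sd_ in 0:2) {
    d <- st$degradation; d$seed <- sd_
    li <- as_line_integrals(apply_degradation(attr(st$degradation, "primary"), d))
    r0 <- fdk_reconstruct(li, fx$grid)
    lf <- run_lfac(li, fx$spectrum, fx$materials, fx$geom, fx$grid,
                   bowtie = fx$bowtie, cone_mask = cm)
    r1 <- fdk_reconstruct(lf, fx$grid)
    e0 <- sqrt(mean((r0$values - truth$values)[msk]^2))
    e1 <- sqrt(mean((r1$values - truth$values)[msk]^2))
    expect_lt(e1, e0)
  }
})

test_that("repeating the shading correction changes little (contraction)", {
  hn <- cached_head_null()
  fx <- hn$fx
  lf1 <- hn$lf
  lf2 <- run_lfac(projection_stack(lf1$values, "line_integral", fx$geom),
                  fx$spectrum, fx$materials, fx$geom, fx$grid,
                  cone_mask = hn$cone_mask)
  d1 <- sqrt(mean((lf1$values - hn$li$values)^2))
  d2 <- sqrt(mean((lf2$values - lf1$values)^2))
  expect_lt(d2, d1)
})
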