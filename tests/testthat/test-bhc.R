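test_that("basis mapping follows the two-neighbor interpolation with caps", {
  grid <- voxel_grid(4, 4, 4, voxel_mm = 1)
  basis <- c(0.000001, 0.02, 0.04)  # near-air, soft, dense
  mk <- function(f) volume_image(array(f, grid$n), grid)
  # node value: all weight on that material
  dec <- map_to_basis(mk(0.02), basis)
  expect_equal(dec[[2]]$values[1], 0.02)
  expect_equal(dec[[1]]$values[1] + dec[[3]]$values[1], 0, tolerance = 1e-7)
  # midpoint between soft and dense: T_soft = 0.01, T_dense = 0.02
  dec2 <- map_to_basis(mk(0.03), basis)
  expect_equal(dec2[[2]]$values[1], 0.01)
  expect_equal(dec2[[3]]$values[1], 0.02)
  # values above the top material are capped at it
  dec3 <- map_to_basis(mk(0.05), basis)
  expect_equal(dec3[[3]]$values[1], 0.04)
  expect_equal(dec3[[1]]$values[1] + dec3[[2]]$values[1], 0)
  expect_error(map_to_basis(mk(0.02), c(0.04, 0.02)), "increasing")
})

test_that("basis mapping is an exact partition of unity inside the range", {
  grid <- voxel_grid(20, 20, 5, voxel_mm = 1)
  basis <- c(2e-5, 0.0206, 0.0409)
  set.seed(5)
  f <- array(runif(2000, basis[1], basis[3]), grid$n)
  dec <- map_to_basis(volume_image(f, grid), basis)
  total <- dec[[1]]$values + dec[[2]]$values + dec[[3]]$values
  expect_equal(max(abs(total - f)), 0, tolerance = 1e-12)
  expect_true(all(dec[[1]]$values >= 0 & dec[[2]]$values >= 0 &
                    dec[[3]]$values >= 0))
  # below/above range: clamped sums
  f2 <- array(c(-0.01, 0.08), c(2, 1, 1))
  grid2 <- voxel_grid(2, 1, 1, voxel_mm = 1)
  dec2 <- map_to_basis(volume_image(f2, grid2), basis)
  tot2 <- dec2[[1]]$values + dec2[[2]]$values + dec2[[3]]$values
  expect_equal(as.numeric(tot2), c(basis[1], basis[3]), tolerance = 1e-12)
})

test_that("beam-hardening correction is the identity for monochromatic data", {
  grid <- voxel_grid(48, 48, 16, voxel_mm = 2.5)
  geom <- small_geom(n_views = 24, det_rows = 16, det_cols = 72, pitch = 2.6)
  cyl <- cylinder_volume(grid, 40, 0.02)
  p <- forward_project_mono(cyl, geom)
  sp1 <- energy_spectrum(60, 1)
  mats <- list(material_table("a", 60, mu_linear_per_mm = 2e-5),
               material_table("w", 60, mu_linear_per_mm = 0.0206),
               material_table("d", 60, mu_linear_per_mm = 0.0409))
  bh <- bhc_iterate(p, sp1, mats, geom, grid, n_iter = 2)
  expect_equal(bh$projections$values, p$values, tolerance = 1e-9)
})

test_that("beam-hardening correction removes most of the cupping", {
  # polychromatic water cylinder: compare the center-vs-edge cupping
  # amplitude before and after three iterations
  grid <- voxel_grid(72, 72, 16, voxel_mm = 2)
  geom <- small_geom(n_views = 36, det_rows = 16, det_cols = 110, pitch = 2.2)
  sp <- default_spectrum(10)
  water <- cbct_material("water")
  g <- cbctcorr:::grid_fields(grid)
  lab <- array(0L, grid$n); lab[g$x^2 + g$y^2 <= 55^2] <- 1L
  ph <- labeled_phantom(lab, list("0" = cbct_material("air"), "1" = water),
                        grid)
  li <- as_line_integrals(simulate_acquisition(ph, geom, sp,
                                               degradation_model()))
  mats <- list(cbct_material("air"), water, cbct_material("teflon"))
  cup <- function(vol) roi_stats(vol, roi_spec(c(40, 0), 8, c(-8, 8)))$mean -
    roi_stats(vol, roi_spec(c(0, 0), 12, c(-8, 8)))$mean
  r0 <- fdk_reconstruct(li, grid)
  bh <- bhc_iterate(li, sp, mats, geom, grid, n_iter = 3)
  expect_lt(abs(cup(bh$volume)), 0.2 * abs(cup(r0)))
})

test_that("projection updates converge within three iterations on consistent data", {
  # model-exact object (basis materials only): successive updates shrink
  # below 0.1% within three iterations
  grid <- voxel_grid(48, 48, 16, voxel_mm = 2.5)
  geom <- small_geom(n_views = 24, det_rows = 16, det_cols = 72, pitch = 2.6)
  sp <- default_spectrum(8)
  water <- cbct_material("water")
  g <- cbctcorr:::grid_fields(grid)
  lab <- array(0L, grid$n); lab[g$x^2 + g$y^2 <= 40^2] <- 1L
  ph <- labeled_phantom(lab, list("0" = cbct_material("air"), "1" = water),
                        grid)
  li <- as_line_integrals(simulate_acquisition(ph, geom, sp,
                                               degradation_model()))
  mats <- list(cbct_material("air"), water, cbct_material("teflon"))
  bh <- bhc_iterate(li, sp, mats, geom, grid, n_iter = 4)
  expect_lt(bh$rel_change[4], 0.001)
  expect_true(all(diff(bh$rel_change) < 0))
})
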