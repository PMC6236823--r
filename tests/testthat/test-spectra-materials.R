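test_that("spectrum normalization rescales weights and rejects bad input", {
  s <- normalize_spectrum(energy_spectrum(c(40, 80), c(2, 2)))
  expect_equal(s$weights, c(0.5, 0.5))
  expect_equal(normalize_spectrum(energy_spectrum(60, 7))$weights, 1)
  s2 <- normalize_spectrum(energy_spectrum(c(40, 80), c(1, 3)))
  expect_equal(s2$weights, c(0.25, 0.75))
  expect_equal(s2$energies_keV, c(40, 80))
  expect_error(energy_spectrum(c(40, 80), c(0, 0)), "invalid spectrum")
  expect_error(energy_spectrum(c(40, 80), c(-1, 2)), "invalid spectrum")
  expect_error(energy_spectrum(c(80, 40), c(1, 1)), "increasing")
})

test_that("mean energy is the fluence-weighted bin mean", {
  expect_equal(mean_energy(twobin_spectrum(c(1, 1))), 60)
  expect_equal(mean_energy(energy_spectrum(60, 5)), 60)
  expect_equal(mean_energy(twobin_spectrum(c(0.25, 0.75))), 70)
})

test_that("effective_mu is the spectrum-weighted mean attenuation", {
  m <- twobin_material()
  expect_equal(effective_mu(m, energy_spectrum(40, 1)), 0.040)
  # constant attenuation gives the constant under any spectrum
  mc <- material_table("const", c(30, 90), mu_linear_per_mm = c(0.03, 0.03))
  expect_equal(effective_mu(mc, twobin_spectrum(c(2, 5))), 0.03,
               tolerance = 1e-12)
  expect_equal(effective_mu(m, twobin_spectrum()), 0.030)
  # linear in mu
  m2 <- material_table("w2b", c(40, 80), mu_linear_per_mm = c(0.010, 0.030))
  msum <- material_table("sum", c(40, 80),
                         mu_linear_per_mm = 2 * c(0.040, 0.020) +
                           3 * c(0.010, 0.030))
  s <- twobin_spectrum(c(1, 2))
  expect_equal(effective_mu(msum, s),
               2 * effective_mu(m, s) + 3 * effective_mu(m2, s),
               tolerance = 1e-12)
  expect_error(effective_mu(m, energy_spectrum(c(20, 100), c(1, 1))),
               "outside")
})

test_that("sigma_hat is the per-bin ratio to the mean attenuation", {
  m <- twobin_material()
  expect_equal(sigma_hat(m, energy_spectrum(40, 1)), 1)
  expect_equal(sigma_hat(m, twobin_spectrum()), c(4, 2) / 3)
})

test_that("fluence-weighted mean of sigma_hat is one for packaged materials", {
  sp <- default_spectrum(10)
  s <- normalize_spectrum(sp)
  for (nm in list_materials()) {
    sh <- sigma_hat(cbct_material(nm), sp)
    expect_equal(sum(s$weights * sh), 1, tolerance = 1e-12)
  }
  # and for randomized synthetic material/spectrum pairs
  set.seed(42)
  for (k in 1:20) {
    e <- sort(runif(5, 20, 150))
    m <- material_table("r", e, mu_linear_per_mm = runif(5, 0.01, 0.08))
    w <- runif(5)
    sr <- energy_spectrum(e, w)
    expect_equal(sum(normalize_spectrum(sr)$weights * sigma_hat(m, sr)), 1,
                 tolerance = 1e-12)
  }
})

test_that("packaged tables load with sane physics", {
  mats <- list_materials()
  expect_true(all(c("air", "water", "brain", "cortical_bone", "teflon",
                    "titanium", "aluminum") %in% mats))
  w <- cbct_material("water")
  expect_equal(w$density_g_cm3, 1)
  # log-log interpolation is monotone decreasing over this range
  mu <- mu_at(w, seq(25, 145, by = 10))
  expect_true(all(diff(mu) < 0))
  # attenuation ordering of the sensitometry materials at 60 keV
  mu60 <- vapply(c("air", "pmp", "ldpe", "polystyrene", "water", "acrylic",
                   "delrin", "teflon", "cortical_bone"),
                 function(nm) mu_at(cbct_material(nm), 60), numeric(1))
  expect_true(all(diff(mu60) > 0))
})

test_that("filtration hardens and resampling conserves fluence", {
  sp <- default_spectrum()
  al <- cbct_material("aluminum")
  hard <- apply_filtration(sp, al, 5)
  expect_gt(mean_energy(hard), mean_energy(sp))
  rs <- resample_spectrum(sp, 10)
  expect_length(rs$energies_keV, 10)
  expect_equal(sum(rs$weights), sum(sp$weights))
  expect_equal(mean_energy(rs), mean_energy(sp), tolerance = 0.01)
})

test_that("spectrum and material text round-trips preserve values", {
  sp <- energy_spectrum(c(30, 50, 70), c(0.2, 1, 0.4))
  f <- tempfile(fileext = ".txt")
  write_spectrum(sp, f)
  sp2 <- read_spectrum(f)
  expect_equal(sp2$energies_keV, sp$energies_keV)
  expect_equal(sp2$weights, sp$weights)
  expect_error(read_material(f), "density")
})
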