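test_that("shape factor is peak intensity over diameter", {
  grid <- seq(200, 900, by = 1)
  s <- gauss_spectrum(center = 700, sigma = 40, height = 100, grid = grid,
                      role = "scattering")
  p <- scattering_profile(s, mean_diameter = 7)
  expect_equal(as.numeric(shape_factor(p)), 100 / 7)
  p2 <- scattering_profile(s, mean_diameter = 14)
  expect_equal(as.numeric(shape_factor(p2)),
               as.numeric(shape_factor(p)) / 2)
  z <- spectrum1d(grid, rep(0, length(grid)), role = "scattering")
  expect_equal(as.numeric(shape_factor(
    scattering_profile(z, mean_diameter = 7))), 0)
})

test_that("deformability from scattering composes integral over diameter", {
  grid <- seq(200, 900, by = 1)
  flat <- spectrum1d(grid, rep(1, length(grid)), role = "scattering")
  p <- scattering_profile(flat, mean_diameter = 2)
  expect_equal(deformability_from_scattering(p, 400, 600), 100)

  set.seed(51)
  for (i in 1:10) {
    y <- runif(length(grid))
    s <- spectrum1d(grid, y, role = "scattering")
    pr <- scattering_profile(s, mean_diameter = runif(1, 5, 9))
    expect_equal(deformability_from_scattering(pr, 300, 800),
                 integrate_intensity(s, 300, 800) / pr$mean_diameter,
                 tolerance = 1e-12)
  }
})

test_that("di_zeta matches hand-evaluated model values", {
  expect_equal(di_zeta(0), 2.0)                     # 1.5 * e^0 + 0.5
  expect_equal(di_zeta(-1, deformability_model("logarithmic")), 0.5)
  expect_equal(di_zeta(-30), 7.2225336054, tolerance = 1e-9)
  expect_error(di_zeta(0, deformability_model("logarithmic")), "zeta < 0")
})

test_that("DI(zeta) is monotone under both default models", {
  zs <- seq(-60, 0, by = 1)
  di_exp <- di_zeta(zs)
  expect_true(all(diff(di_exp) < 0))  # DI rises as zeta decreases
  zs_log <- seq(-60, -1, by = 1)
  di_log <- di_zeta(zs_log, deformability_model("logarithmic"))
  expect_true(all(diff(di_log) < 0))  # DI rises as -zeta increases
})

test_that("dlvo_energy matches a step-by-step oracle and limit behavior", {
  p <- dlvo_params(permittivity = 7.08e-10, radius = 3.5e-6,
                   zeta = -0.015, inverse_debye = 1.04e9,
                   separation = 5e-9, hamaker = 5e-21)
  e <- dlvo_energy(p)
  # independent step-by-step evaluation of the two terms
  rep_o <- pi * 7.08e-10 * 3.5e-6 * (-0.015)^2 * exp(-1.04e9 * 5e-9)
  vdw_o <- -(5e-21 * 3.5e-6) / (12 * 5e-9)
  expect_lt(abs(e$e_rep - rep_o) / abs(rep_o), 1e-10)
  expect_lt(abs(e$e_vdw - vdw_o) / abs(vdw_o), 1e-10)
  expect_equal(e$e_total, e$e_rep + e$e_vdw)

  z0 <- dlvo_energy(dlvo_params(zeta = 0))
  expect_equal(z0$e_rep, 0)
  expect_lt(z0$e_total, 0)
  expect_equal(z0$regime, "attraction_dominates")

  a0 <- dlvo_energy(dlvo_params(hamaker = 0))
  expect_equal(a0$e_total, a0$e_rep)
  expect_gte(a0$e_total, 0)
  expect_equal(a0$regime, "repulsion_dominates")

  # E_total -> -inf as separation -> 0+ with A_H > 0
  seps <- 10^seq(-8, -11, by = -1)
  totals <- vapply(seps, function(d) {
    dlvo_energy(dlvo_params(separation = d))$e_total
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
  expect_lt(totals[length(totals)], -1e-18)

  # the zero-energy point is classified repulsion_dominates
  e00 <- dlvo_energy(dlvo_params(zeta = 0, hamaker = 0))
  expect_equal(e00$e_total, 0)
  expect_equal(e00$regime, "repulsion_dominates")
})

test_that("regime flips exactly at the repulsion/attraction boundary", {
  base <- dlvo_params(hamaker = 0)
  e_rep <- dlvo_energy(base)$e_rep
  # Hamaker constant making |E_vdw| equal E_rep
  a_star <- 12 * base$separation * e_rep / base$radius
  below <- dlvo_energy(dlvo_params(hamaker = a_star * 0.99))
  above <- dlvo_energy(dlvo_params(hamaker = a_star * 1.01))
  expect_equal(below$regime, "repulsion_dominates")
  expect_equal(above$regime, "attraction_dominates")
})

test_that("diameter_from_scattering inverts the scattering generator", {
  expect_equal(diameter_from_scattering(800, 0.009), 7.2)
  expect_error(diameter_from_scattering(800, 0), "> 0")

  grid <- seq(200, 900, by = 0.5)
  for (d in c(6.0, 7.2, 7.9)) {
    s <- generate_scattering_profile(d, k = 0.009, grid = grid)
    p <- scattering_profile(s, k = 0.009)
    expect_lt(abs(p$mean_diameter - d), 0.009 * 0.5 + 1e-12)
  }
})

test_that("internal composition index integrates emission spectra", {
  grid <- seq(200, 900, by = 1)
  z <- spectrum1d(grid, rep(0, length(grid)), role = "emission")
  expect_equal(internal_composition_index(z), 0)

  s <- gauss_spectrum(center = 455, sigma = 15, grid = grid)
  expect_equal(internal_composition_index(s),
               integrate_intensity(s), tolerance = 1e-12)

  sc <- spectrum1d(grid, rep(1, length(grid)), role = "scattering")
  expect_error(internal_composition_index(sc), "emission")

  young <- generate_patient_spectrum(patient_profile(
    lifecycle_phase = "young"))
  old <- generate_patient_spectrum(patient_profile(
    lifecycle_phase = "old"))
  expect_gt(internal_composition_index(young),
            internal_composition_index(old))
})
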