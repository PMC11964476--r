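test_that("generate_eem places separable Gaussian maxima and respects yields", {
  f <- fluorophore_spec("x", ex_center = 352, ex_width = 10,
                        em_center = 457, em_width = 8,
                        quantum_yield = 0.5, epsilon = 1000,
                        concentration = 1e-5)
  ex <- seq(300, 400, by = 5)
  em <- seq(400, 500, by = 5)
  e <- generate_eem(list(f), source = excitation_source("flat"),
                    ex_grid = ex, em_grid = em, noise_sd = 0)
  ij <- which(e$intensity == max(e$intensity), arr.ind = TRUE)[1, ]
  expect_equal(ex[ij[1]], ex[which.min(abs(ex - 352))])
  expect_equal(em[ij[2]], em[which.min(abs(em - 457))])

  dark <- lapply(blood_fluorophores(), function(g) {
    g$quantum_yield <- 0
    g
  })
  e0 <- generate_eem(dark, noise_sd = 0)
  expect_true(all(e0$intensity == 0))
})

test_that("NADH dominates the noise-free default blood EEM", {
  e <- clean_blood_eem()
  ij <- which(e$intensity == max(e$intensity), arr.ind = TRUE)[1, ]
  nadh <- blood_fluorophores()$NADH
  expect_lt(abs(e$ex[ij[1]] - nadh$ex_center), 3 * nadh$ex_width)
  expect_lt(abs(e$em[ij[2]] - nadh$em_center), 3 * nadh$em_width)
})

test_that("generate_eem validates inputs and is seed-deterministic", {
  expect_error(generate_eem(list()), "at least one")
  expect_error(generate_eem(blood_fluorophores(),
                            ex_grid = c(300, 290, 310)),
               "strictly increasing")
  expect_error(generate_eem(blood_fluorophores(), noise_sd = -1), ">= 0")

  e1 <- generate_eem(blood_fluorophores(), noise_sd = 0.01, seed = 42)
  e2 <- generate_eem(blood_fluorophores(), noise_sd = 0.01, seed = 42)
  expect_identical(e1$intensity, e2$intensity)
  e3 <- generate_eem(blood_fluorophores(), noise_sd = 0)
  e4 <- generate_eem(blood_fluorophores(), noise_sd = 0)
  expect_identical(e3$intensity, e4$intensity)
})

test_that("spatial concentration field scales the EEM by its mean", {
  f <- blood_fluorophores()$NADH
  fld <- concentration_field(1:2, 1:2, 1:2, rep(2, 8))
  e_uni <- generate_eem(list(f), noise_sd = 0)
  e_fld <- generate_eem(list(f), field = fld, noise_sd = 0)
  expect_equal(e_fld$intensity, 2 * e_uni$intensity)
  expect_error(concentration_field(1, 1, 1, -1), "non-negative")
})

test_that("absorption spectrum peaks at 550 nm, monotone in oxygen and glycation", {
  a <- generate_absorption_spectrum(0.9, 5)
  expect_equal(a$wavelength[which.max(a$intensity)], 550)

  peak_height <- function(oxy, gly) {
    max(generate_absorption_spectrum(oxy, gly)$intensity)
  }
  expect_gt(peak_height(0.9, 5), peak_height(0.1, 5))
  expect_lt(peak_height(0.5, 10), peak_height(0.5, 5))
  # strict monotonicity over a sweep
  oxy_heights <- vapply(seq(0, 1, by = 0.1), peak_height, numeric(1),
                        gly = 5)
  expect_true(all(diff(oxy_heights) > 0))
  gly_heights <- vapply(seq(0, 12, by = 2), function(g) peak_height(0.5, g),
                        numeric(1))
  expect_true(all(diff(gly_heights) < 0))
})

test_that("zero-oxygen, zero-glycation absorption equals the deoxy baseline", {
  grid <- seq(400, 700, by = 0.5)
  a <- generate_absorption_spectrum(0, 0, grid = grid,
                                    deoxy_height = 0.4, background = 0.02)
  expected <- 0.02 + 0.4 * exp(-(grid - 550)^2 / (2 * 35^2))
  expect_equal(a$intensity, expected, tolerance = 1e-15)
  expect_error(generate_absorption_spectrum(1.2, 5), "oxygen_fraction")
  expect_error(generate_absorption_spectrum(0.5, -1), "glycation")
})

test_that("patient spectra encode oxygenation, plasma and lifecycle", {
  base <- list(hemoglobin_gdl = 14, plasma_fraction = 0.5, noise_sd = 0)
  s_hi <- generate_patient_spectrum(patient_profile(
    hemoglobin_gdl = 14, oxygen_fraction = 0.95, plasma_fraction = 0.5))
  s_lo <- generate_patient_spectrum(patient_profile(
    hemoglobin_gdl = 14, oxygen_fraction = 0.60, plasma_fraction = 0.5))
  expect_gt(integrate_intensity(s_lo, 600, 700),
            integrate_intensity(s_hi, 600, 700))

  s_np <- generate_patient_spectrum(patient_profile(plasma_fraction = 0))
  idx <- s_np$wavelength >= 800 & s_np$wavelength <= 900
  expect_lt(max(abs(s_np$intensity[idx])), 1e-8)

  s_young <- generate_patient_spectrum(patient_profile(
    lifecycle_phase = "young"))
  s_old <- generate_patient_spectrum(patient_profile(
    lifecycle_phase = "old"))
  expect_gt(integrate_intensity(s_young), integrate_intensity(s_old))
})

test_that("oxy band integral is strictly increasing in hemoglobin", {
  hbs <- seq(8, 18, length.out = 10)
  ints <- vapply(hbs, function(h) {
    s <- generate_patient_spectrum(patient_profile(hemoglobin_gdl = h))
    integrate_intensity(s, 400, 600)
  }, numeric(1))
  expect_true(all(diff(ints) > 0))
})

test_that("UV patient spectra carry negative deoxy excursions, unclipped noise", {
  uv <- excitation_source("UV")
  s <- generate_patient_spectrum(patient_profile(oxygen_fraction = 0.3),
                                 source = uv)
  idx <- s$wavelength >= 620 & s$wavelength <= 680
  expect_lt(min(s$intensity[idx]), 0)
  s_n <- generate_patient_spectrum(patient_profile(
    oxygen_fraction = 0.3, noise_sd = 0.05, seed = 5), source = uv)
  expect_lt(min(s_n$intensity), 0)
  # non-UV emission noise is clipped at zero
  s_h <- generate_patient_spectrum(patient_profile(
    noise_sd = 0.05, seed = 5), source = excitation_source("halogen"))
  expect_gte(min(s_h$intensity), 0)
})

test_that("generate_cbc draws MCH from the age bin and stays self-consistent", {
  for (seed in 1:20) {
    r20 <- generate_cbc(20, "F", "none", seed = seed)
    expect_gte(r20$mch_pg, 27)
    expect_lte(r20$mch_pg, 34)
    r7 <- generate_cbc(7, "M", "none", seed = seed)
    expect_gte(r7$mch_pg, 24)
    expect_lte(r7$mch_pg, 30)
    expect_lt(generate_cbc(20, "F", "iron_deficiency", seed = seed)$mch_pg,
              27)
    expect_gt(generate_cbc(20, "F", "b12_deficiency", seed = seed)$mch_pg,
              34)
    # Hb (g/dL) = RBC (10^6/uL) * MCH (pg) / 10, relative error < 1e-6
    expect_lt(abs(r20$hb_gdl - r20$rbc_1e6_per_ul * r20$mch_pg / 10) /
                r20$hb_gdl, 1e-6)
  }
  expect_identical(generate_cbc(20, "M", seed = 3),
                   generate_cbc(20, "M", seed = 3))
  expect_error(generate_cbc(0.3), "0.5")
})

test_that("scattering profiles peak at diameter/k and validate the grid", {
  grid <- seq(200, 900, by = 0.5)
  s <- generate_scattering_profile(7.2, k = 0.009, grid = grid)
  expect_equal(s$wavelength[which.max(s$intensity)], 800)
  expect_identical(
    generate_scattering_profile(7.2, noise_sd = 1, seed = 9)$intensity,
    generate_scattering_profile(7.2, noise_sd = 1, seed = 9)$intensity)
  # 9 um / 0.009 um/nm = 1000 nm, beyond the 900 nm grid edge
  expect_error(generate_scattering_profile(9, k = 0.009, grid = grid),
               "outside the grid")
})

test_that("noise-free EEM round-trips through the peak mapper within one step", {
  e <- clean_blood_eem()
  pm <- eem_peak_map(e, blood_fluorophores())
  lib <- blood_fluorophores()
  step_ex <- median(diff(e$ex))
  step_em <- median(diff(e$em))
  for (nm in names(lib)) {
    row <- pm[pm$fluorophore == nm, ]
    expect_true(row$assigned)
    expect_lte(abs(row$ex - lib[[nm]]$ex_center), step_ex)
    expect_lte(abs(row$em - lib[[nm]]$em_center), step_em)
  }
})
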