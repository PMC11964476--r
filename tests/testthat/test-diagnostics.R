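test_that("band_summary integrates the three diagnostic windows", {
  grid <- seq(200, 900, by = 0.5)
  flat <- spectrum1d(grid, rep(1, length(grid)))
  b <- band_summary(flat)
  expect_equal(b$band_hb_oxy, 200)
  expect_equal(b$band_deoxy, 100)
  expect_equal(b$band_plasma, 100)
  expect_equal(b$band_unassigned, 100)

  z <- band_summary(spectrum1d(grid, rep(0, length(grid))))
  expect_equal(c(z$band_hb_oxy, z$band_deoxy, z$band_plasma), c(0, 0, 0))

  short <- spectrum1d(seq(400, 700, 1), rep(1, 301))
  expect_error(band_summary(short), "400-900")
})

test_that("band integrals are additive across the 400-900 nm span", {
  set.seed(61)
  grid <- seq(200, 900, by = 0.5)
  for (i in 1:5) {
    s <- spectrum1d(grid, runif(length(grid)))
    b <- band_summary(s)
    total <- integrate_intensity(s, 400, 900)
    expect_lt(abs(b$band_hb_oxy + b$band_deoxy + b$band_unassigned +
                    b$band_plasma - total), 1e-10)
  }
})

test_that("lower oxygenation raises the deoxy band at equal hemoglobin", {
  lo <- band_summary(generate_patient_spectrum(patient_profile(
    hemoglobin_gdl = 14, oxygen_fraction = 0.6)))
  hi <- band_summary(generate_patient_spectrum(patient_profile(
    hemoglobin_gdl = 14, oxygen_fraction = 0.95)))
  expect_gt(lo$band_deoxy, hi$band_deoxy)
})

test_that("compare_patients assigns winners, vocabulary, ties, antisymmetry", {
  pair <- table5_band_pair()
  rep <- compare_patients(pair[[1]], pair[[2]])
  w <- setNames(rep$winner, rep$band)
  expect_equal(w[["hb_oxy"]], "patient_1")
  expect_equal(w[["deoxy"]], "patient_2")
  expect_equal(w[["plasma"]], "patient_1")
  expect_equal(rep$interpretation_1[rep$band == "hb_oxy"],
               "higher Hb/HbO2")
  expect_equal(rep$interpretation_2[rep$band == "hb_oxy"],
               "lower Hb/HbO2 (possible anemia)")
  expect_equal(rep$interpretation_2[rep$band == "deoxy"],
               "higher deoxy-Hb (possible hypoxia)")
  expect_equal(rep$interpretation_2[rep$band == "plasma"],
               "lower plasma content (higher hematocrit)")

  same <- compare_patients(pair[[1]], pair[[1]])
  expect_true(all(same$winner == "tie"))

  swapped <- compare_patients(pair[[2]], pair[[1]])
  flip <- c(patient_1 = "patient_2", patient_2 = "patient_1", tie = "tie")
  expect_equal(unname(flip[rep$winner]), swapped$winner)

  b_other <- pair[[2]]
  b_other$source <- "halogen"
  expect_error(compare_patients(pair[[1]], b_other), "different excitation")
})

test_that("ties are stable under sub-threshold perturbation", {
  pair <- table5_band_pair()
  b1 <- pair[[1]]
  b2 <- b1
  for (f in c("band_hb_oxy", "band_deoxy", "band_plasma")) {
    b2[[f]] <- b1[[f]] * (1 + 0.005)  # below the 1% default threshold
  }
  rep <- compare_patients(b1, b2)
  expect_true(all(rep$winner == "tie"))
})

test_that("rbc_count and implied_mch are exact inverses on printed values", {
  # patient 1: 164 g/L at 30.83 pg -> 5.32e12 cells/L
  rbc <- rbc_count(164, 164 / 5.32)
  expect_equal(rbc_per_ul_millions(rbc), 5.32, tolerance = 1e-12)
  expect_equal(rbc_count(0, 30), 0)
  expect_equal(rbc_count(164, 60), rbc_count(164, 30) / 2)
  expect_error(rbc_count(164, 0), "> 0")

  cbcs <- demo_cbc_records()
  expect_equal(implied_mch(cbcs$patient_1), 164 / 5.32, tolerance = 1e-12)
  expect_equal(implied_mch(cbcs$patient_2), 126 / 4.36, tolerance = 1e-12)

  set.seed(71)
  for (i in 1:20) {
    hb <- runif(1, 8, 20)
    rbc6 <- runif(1, 3, 7)
    c <- cbc_record(hb_gdl = hb, rbc_1e6_per_ul = rbc6, hct_pct = 42,
                    age_years = 30)
    back <- rbc_per_ul_millions(rbc_count(hb * 10, implied_mch(c)))
    expect_lt(abs(back - rbc6) / rbc6, 1e-12)
  }
})

test_that("mch_reference_range maps ages to bins with adult fallback", {
  expect_equal(unname(mch_reference_range(20)), c(27, 34))
  expect_equal(unname(mch_reference_range(10)), c(26, 32))
  expect_equal(unname(mch_reference_range(0.5)), c(24, 30))
  expect_equal(unname(mch_reference_range(14)), c(26, 34))
  expect_equal(unname(mch_reference_range(72)), c(27, 34))
  expect_error(mch_reference_range(0.3), "0.5")
})

test_that("cbc_concordance flags agreement against CBC orderings", {
  cbcs <- demo_cbc_records()
  # halogen-style report: patient 1 wins 400-600, loses 800-900
  b1 <- structure(list(band_hb_oxy = 30, band_deoxy = 3, band_plasma = 8,
                       band_unassigned = 0, source = "halogen"),
                  class = "band_summary")
  b2 <- structure(list(band_hb_oxy = 20, band_deoxy = 9, band_plasma = 14,
                       band_unassigned = 0, source = "halogen"),
                  class = "band_summary")
  rep <- compare_patients(b1, b2)
  conc <- cbc_concordance(cbcs$patient_1, cbcs$patient_2, rep)
  flags <- setNames(conc$bands$concordance, conc$bands$band)
  expect_equal(flags[["hb_oxy"]], "agree")   # higher Hb wins the band
  expect_equal(flags[["plasma"]], "agree")   # lower Hct wins plasma
  expect_equal(flags[["deoxy"]], "functional-only")
  expect_true(all(conc$mch$in_range))

  # identical CBCs -> indeterminate outside the functional-only band
  conc2 <- cbc_concordance(cbcs$patient_1, cbcs$patient_1, rep)
  f2 <- setNames(conc2$bands$concordance, conc2$bands$band)
  expect_equal(f2[["hb_oxy"]], "indeterminate")
  expect_equal(f2[["plasma"]], "indeterminate")
  expect_equal(f2[["deoxy"]], "functional-only")

  # the bundled Table-V-style fixture disagrees on plasma, by design
  pair <- table5_band_pair()
  conc3 <- cbc_concordance(cbcs$patient_1, cbcs$patient_2,
                           compare_patients(pair[[1]], pair[[2]]))
  f3 <- setNames(conc3$bands$concordance, conc3$bands$band)
  expect_equal(f3[["hb_oxy"]], "agree")
  expect_equal(f3[["plasma"]], "disagree")
})
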