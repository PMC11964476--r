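#' Three-band diagnostic summary of a patient spectrum
#'
#' Trapezoidal integrals over the three diagnostic regions:
#' hemoglobin/oxyhemoglobin (400-600 nm), deoxyhemoglobin (600-700 nm)
#' and plasma/water (800-900 nm).  The 700-800 nm interval belongs to
#' no named band and is reported separately as `band_unassigned`.  For
#' UV-source spectra, whose background-subtracted traces can dip
#' negative, integrals are taken over absolute intensities so "more
#' absorption" (a deeper excursion of either sign) always scores
#' higher.
#'
#' @param s A [spectrum1d()] whose grid covers 400-900 nm.
#' @return An object of class `band_summary` with fields
#'   `band_hb_oxy`, `band_deoxy`, `band_plasma`, `band_unassigned`,
#'   `source`.
#' @export
band_summary <- function(s) {
  stopifnot(inherits(s, "spectrum1d"))
  if (min(s$wavelength) > 400 || max(s$wavelength) < 900) {
    stop("spectrum must cover 400-900 nm for band summaries")
  }
  si <- s
  if (identical(s$source, "UV")) si$intensity <- abs(si$intensity)
  structure(
    list(band_hb_oxy = integrate_intensity(si, 400, 600),
         band_deoxy = integrate_intensity(si, 600, 700),
         band_plasma = integrate_intensity(si, 800, 900),
         band_unassigned = integrate_intensity(si, 700, 800),
         source = s$source),
    class = "band_summary"
  )
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf(
    "<band_summary> source=%s\n  Hb/HbO2 400-600: %.4g\n  deoxy-Hb 600-700: %.4g\n  plasma 800-900: %.4g (unassigned 700-800: %.4g)\n",
    x$source, x$band_hb_oxy, x$band_deoxy, x$band_plasma,
    x$band_unassigned))
  invisible(x)
}

# closed interpretation vocabulary, per band, for winner and loser
band_vocabulary <- list(
  hb_oxy = list(winner = "higher Hb/HbO2",
                loser = "lower Hb/HbO2 (possible anemia)"),
  deoxy = list(winner = "higher deoxy-Hb (possible hypoxia)",
               loser = "lower deoxy-Hb (better oxygenation)"),
  plasma = list(winner = "higher plasma content (lower hematocrit)",
                loser = "lower plasma content (higher hematocrit)")
)

#' Compare two patients' band summaries
#'
#' For each diagnostic band the larger integral wins, with a tie
#' declared when the relative difference (against the larger magnitude)
#' falls below `tie_threshold`.  Interpretations come from a closed
#' vocabulary: the 400-600 nm winner has "higher Hb/HbO2" and the loser
#' "possible anemia"; the 600-700 nm winner has "possible hypoxia" and
#' the loser "better oxygenation"; the 800-900 nm winner has "higher
#' plasma content (lower hematocrit)" and the loser "higher
#' hematocrit".
#'
#' @param b1,b2 [band_summary()] objects from the same source kind.
#' @param tie_threshold Relative difference below which a band ties
#'   (default 0.01).
#' @return An object of class `comparison_report`: a data.frame of
#'   bands with winners and per-patient interpretations, plus the
#'   threshold and source in attributes.
#' @export
compare_patients <- function(b1, b2, tie_threshold = 0.01) {
  stopifnot(inherits(b1, "band_summary"), inherits(b2, "band_summary"))
  if (!identical(b1$source, b2$source)) {
    stop("band summaries come from different excitation sources")
  }
  bands <- c(hb_oxy = "band_hb_oxy", deoxy = "band_deoxy",
             plasma = "band_plasma")
  rows <- lapply(names(bands), function(nm) {
    v1 <- b1[[bands[[nm]]]]
    v2 <- b2[[bands[[nm]]]]
    denom <- max(abs(v1), abs(v2))
    rel <- if (denom == 0) 0 else abs(v1 - v2) / denom
    winner <- if (rel < tie_threshold) "tie"
              else if (v1 > v2) "patient_1" else "patient_2"
    voc <- band_vocabulary[[nm]]
    interp <- switch(winner,
      tie = c("comparable", "comparable"),
      patient_1 = c(voc$winner, voc$loser),
      patient_2 = c(voc$loser, voc$winner))
    data.frame(band = nm, value_1 = v1, value_2 = v2, winner = winner,
               interpretation_1 = interp[1], interpretation_2 = interp[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "tie_threshold") <- tie_threshold
  attr(out, "source") <- b1$source
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' RBC count from total hemoglobin and MCH
#'
#' `RBC = total hemoglobin concentration / MCH`: with hemoglobin in g/L
#' and MCH in pg (1 pg = 1e-12 g) the count comes out in cells per
#' liter.
#'
#' @param total_hb_gL Total hemoglobin, g/L, >= 0.
#' @param mch_pg Mean corpuscular hemoglobin, pg, > 0.
#' @return RBC count, cells/L.
#' @seealso [rbc_per_ul_millions()] for the clinical 10^6/uL scale.
#' @export
rbc_count <- function(total_hb_gL, mch_pg) {
  if (any(mch_pg <= 0)) stop("mch_pg must be > 0")
  if (any(total_hb_gL < 0)) stop("total_hb_gL must be >= 0")
  total_hb_gL / (mch_pg * 1e-12)
}

#' Convert an RBC count from cells/L to 10^6 cells/uL
#'
#' @param rbc_per_l RBC count, cells/L.
#' @return Count in 10^6 cells/uL (the conventional CBC scale).
#' @export
rbc_per_ul_millions <- function(rbc_per_l) rbc_per_l / 1e12

#' MCH implied by a CBC record
#'
#' Exact algebraic inverse of [rbc_count()]: hemoglobin mass per cell,
#' `MCH (pg) = Hb (g/dL) * 10 / RBC (10^6/uL)`.
#'
#' @param c A [cbc_record()] with positive `hb_gdl` and
#'   `rbc_1e6_per_ul`.
#' @return MCH in pg.
#' @export
implied_mch <- function(c) {
  stopifnot(inherits(c, "cbc_record"))
  if (is.null(c$hb_gdl) || is.null(c$rbc_1e6_per_ul) ||
      !is.finite(c$hb_gdl) || !is.finite(c$rbc_1e6_per_ul) ||
      c$hb_gdl <= 0 || c$rbc_1e6_per_ul <= 0) {
    stop("hb_gdl and rbc_1e6_per_ul must be present and positive")
  }
  c$hb_gdl * 10 / c$rbc_1e6_per_ul
}

#' Age-specific MCH reference range
#'
#' Reference ranges by age bin (pg): 6 months-8 years 24-30, 9-11
#' years 26-32, 12-17 years 26-34, 18-44 years 27-34.  Bins are closed
#' on the left and open on the right; ages of 45 and over reuse the
#' adult 18-44 range (none older is tabulated).
#'
#' @param age_years Age, >= 0.5.
#' @return Numeric `c(low, high)` in pg.
#' @export
mch_reference_range <- function(age_years) {
  if (age_years < 0.5) stop("age_years must be >= 0.5")
  bins <- mch_bins()
  i <- which(age_years >= bins$lo_age & age_years < bins$hi_age)[1]
  c(low = bins$mch_lo[i], high = bins$mch_hi[i])
}

#' Cross-validate a spectral comparison against CBC data
#'
#' Checks each spectral band winner against the ordering the CBC
#' predicts: the 400-600 nm (Hb/HbO2) band should favor the patient
#' with higher hemoglobin, and the 800-900 nm (plasma) band the patient
#' with the *lower* hematocrit (more plasma).  The 600-700 nm
#' deoxyhemoglobin band has no CBC counterpart — it reflects oxygen
#' dissociation, not cell counts — and is always flagged
#' `functional-only`.  Equal CBC values (within `tie_threshold`
#' relative) give `indeterminate`.  The annotated report also carries
#' each patient's implied MCH and whether it falls inside the
#' age-specific reference range.
#'
#' @param c1,c2 [cbc_record()] objects for patients 1 and 2.
#' @param report A [compare_patients()] result for the same two
#'   subjects.
#' @param tie_threshold Relative difference treated as a CBC tie.
#' @return A list of class `concordance_report` with `bands` (the
#'   report plus `cbc_expected` and `concordance` columns) and `mch`
#'   (implied MCH and range status per patient).
#' @export
cbc_concordance <- function(c1, c2, report, tie_threshold = 0.01) {
  stopifnot(inherits(c1, "cbc_record"), inherits(c2, "cbc_record"),
            inherits(report, "comparison_report"))
  cbc_order <- function(v1, v2, higher_wins = TRUE) {
    denom <- max(abs(v1), abs(v2))
    if (denom == 0 || abs(v1 - v2) / denom < tie_threshold) return("tie")
    w1 <- if (higher_wins) v1 > v2 else v1 < v2
    if (w1) "patient_1" else "patient_2"
  }
  expected <- c(
    hb_oxy = cbc_order(c1$hb_gdl, c2$hb_gdl, higher_wins = TRUE),
    deoxy = NA_character_,  # no CBC counterpart; oxygen dissociation
    plasma = cbc_order(c1$hct_pct, c2$hct_pct, higher_wins = FALSE)
  )
  bands <- as.data.frame(report)
  bands$cbc_expected <- unname(expected[bands$band])
  bands$concordance <- vapply(seq_len(nrow(bands)), function(i) {
    exp_i <- bands$cbc_expected[i]
    if (bands$band[i] == "deoxy") return("functional-only")
    if (exp_i == "tie") return("indeterminate")
    if (bands$winner[i] == "tie") return("indeterminate")
    if (bands$winner[i] == exp_i) "agree" else "disagree"
  }, character(1))

  mch <- do.call(rbind, lapply(list(patient_1 = c1, patient_2 = c2),
    function(cr) {
      m <- implied_mch(cr)
      rng <- mch_reference_range(cr$age_years)
      data.frame(implied_mch_pg = m, range_low = rng[["low"]],
                 range_high = rng[["high"]],
                 in_range = m >= rng[["low"]] & m <= rng[["high"]])
    }))
  structure(list(bands = bands, mch = mch,
                 tie_threshold = tie_threshold),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$bands[, c("band", "winner", "cbc_expected", "concordance")])
  cat("implied MCH:\n")
  print(x$mch)
  invisible(x)
}
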