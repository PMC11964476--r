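#' One-dimensional spectrum
#'
#' The basic container for a spectrometer trace: a strictly increasing
#' wavelength grid (nm) paired with intensities (arbitrary units).  The
#' `role` flag distinguishes emission, absorbance and scattering traces;
#' emission spectra are non-negative by convention except under UV
#' excitation, where background subtraction can produce negative
#' excursions, so negativity is policed by downstream policy rather than
#' here.  `source` records the excitation lamp the trace was acquired
#' (or simulated) under.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 8.
#' @param intensity Numeric vector of intensities (a.u.), same length as
#'   `wavelength`.  May be negative for UV-difference spectra.
#' @param role One of `"emission"`, `"absorbance"`, `"scattering"`.
#' @param source One of `"deuterium"`, `"halogen"`, `"deuterium+halogen"`,
#'   `"UV"`, or `"none"` when no lamp is meaningful.
#' @param meta Named list of free-form provenance (seed, generator
#'   parameters, preprocessing chain).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(wavelength, intensity,
                       role = c("emission", "absorbance", "scattering"),
                       source = c("none", "deuterium", "halogen",
                                  "deuterium+halogen", "UV"),
                       meta = list()) {
  role <- match.arg(role)
  source <- match.arg(source)
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity)) {
    stop("wavelength and intensity must have equal length")
  }
  if (length(wavelength) < 8L) {
    stop("a spectrum needs at least 8 points")
  }
  if (anyNA(wavelength) || anyNA(intensity)) {
    stop("NA values are not allowed in a spectrum")
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(
    list(wavelength = wavelength, intensity = intensity,
         role = role, source = source, meta = meta),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s, source=%s, %d points, %.1f-%.1f nm\n",
              x$role, x$source, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.spectrum1d <- function(x, ...) {
  data.frame(wavelength = x$wavelength, intensity = x$intensity)
}

#' Excitation-emission matrix
#'
#' Fluorescence intensity over a 2-D grid of excitation (rows) and
#' emission (columns) wavelengths.
#'
#' @param ex Excitation wavelengths in nm, strictly increasing.
#' @param em Emission wavelengths in nm, strictly increasing.
#' @param intensity Numeric matrix, `length(ex)` rows by `length(em)`
#'   columns.
#' @param meta Named list of provenance.
#' @return An object of class `eem`.
#' @export
eem <- function(ex, em, intensity, meta = list()) {
  ex <- as.numeric(ex)
  em <- as.numeric(em)
  intensity <- as.matrix(intensity)
  if (any(diff(ex) <= 0) || any(diff(em) <= 0)) {
    stop("excitation and emission grids must be strictly increasing")
  }
  if (!identical(dim(intensity), c(length(ex), length(em)))) {
    stop("intensity must be a length(ex) x length(em) matrix")
  }
  structure(list(ex = ex, em = em, intensity = intensity, meta = meta),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d x %d (ex %.0f-%.0f nm, em %.0f-%.0f nm), max %.4g\n",
              length(x$ex), length(x$em), min(x$ex), max(x$ex),
              min(x$em), max(x$em), max(x$intensity)))
  invisible(x)
}

#' Complete blood count record
#'
#' Clinical hematology values for one subject, in the conventional
#' clinical units: hemoglobin in g/dL, red-cell count in 10^6 cells/uL,
#' hematocrit in %, WBC differential in %.  MCH (pg) is optional and
#' derivable from Hb and RBC via [implied_mch()].
#'
#' @param hb_gdl Hemoglobin, g/dL (> 0).
#' @param rbc_1e6_per_ul RBC count, 10^6 cells/uL (> 0).
#' @param hct_pct Hematocrit, percent (> 0).
#' @param age_years Age in years (>= 0.5).
#' @param sex `"M"` or `"F"`.
#' @param mch_pg Optional MCH in pg.
#' @param neutrophils_pct,lymphocytes_pct,eosinophils_pct,basophils_pct
#'   Optional WBC differential percentages, each in \[0, 100\].
#' @param meta Named list of provenance.
#' @return An object of class `cbc_record`.
#' @export
cbc_record <- function(hb_gdl, rbc_1e6_per_ul, hct_pct, age_years,
                       sex = c("M", "F"), mch_pg = NULL,
                       neutrophils_pct = NA_real_, lymphocytes_pct = NA_real_,
                       eosinophils_pct = NA_real_, basophils_pct = NA_real_,
                       meta = list()) {
  sex <- match.arg(sex)
  for (v in c(hb_gdl, rbc_1e6_per_ul, hct_pct)) {
    if (!is.finite(v) || v <= 0) stop("hb, rbc and hct must be positive")
  }
  if (age_years < 0.5) stop("age_years must be >= 0.5")
  diff_pct <- c(neutrophils_pct, lymphocytes_pct,
                eosinophils_pct, basophils_pct)
  bad <- !is.na(diff_pct) & (diff_pct < 0 | diff_pct > 100)
  if (any(bad)) stop("differential percentages must lie in [0, 100]")
  structure(
    list(hb_gdl = hb_gdl, rbc_1e6_per_ul = rbc_1e6_per_ul,
         hct_pct = hct_pct, mch_pg = mch_pg, age_years = age_years,
         sex = sex, neutrophils_pct = neutrophils_pct,
         lymphocytes_pct = lymphocytes_pct,
         eosinophils_pct = eosinophils_pct, basophils_pct = basophils_pct,
         meta = meta),
    class = "cbc_record"
  )
}

#' @export
print.cbc_record <- function(x, ...) {
  cat(sprintf(
    "<cbc_record> Hb %.1f g/dL, RBC %.2f x10^6/uL, Hct %.1f%%, age %.1f, %s\n",
    x$hb_gdl, x$rbc_1e6_per_ul, x$hct_pct, x$age_years, x$sex))
  invisible(x)
}

# Evaluate a random expression under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed so adding a pipeline stage never perturbs the
# draws of earlier stages.  Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483629L
}
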