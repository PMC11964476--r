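#' Fluorophore specification
#'
#' Parameters of one Gaussian fluorophore: excitation/emission band
#' centers and widths, quantum yield, molar absorptivity at the
#' excitation center, and concentration.  The synthetic EEM is a sum of
#' separable excitation x emission Gaussians, one per fluorophore,
#' weighted by `quantum_yield * epsilon * concentration` and by the lamp
#' power at the excitation wavelength.
#'
#' @param name Fluorophore label, e.g. `"NADH"`.
#' @param ex_center,em_center Band centers in nm; `ex_center < em_center`
#'   (Stokes-positive).
#' @param ex_width,em_width Gaussian sigmas in nm, > 0.
#' @param quantum_yield Fraction of absorbed photons re-emitted, in
#'   \[0, 1\].
#' @param epsilon Molar absorptivity at `ex_center`, L mol^-1 cm^-1,
#'   >= 0.
#' @param concentration mol/L (or relative a.u.), >= 0.
#' @return An object of class `fluorophore_spec`.
#' @export
fluorophore_spec <- function(name, ex_center, ex_width, em_center, em_width,
                             quantum_yield, epsilon, concentration) {
  if (ex_center >= em_center) {
    stop("Stokes-positive fluorophore required: ex_center < em_center")
  }
  if (ex_width <= 0 || em_width <= 0) stop("widths must be positive")
  if (quantum_yield < 0 || quantum_yield > 1) {
    stop("quantum_yield must lie in [0, 1]")
  }
  if (epsilon < 0 || concentration < 0) {
    stop("epsilon and concentration must be non-negative")
  }
  structure(
    list(name = name, ex_center = ex_center, ex_width = ex_width,
         em_center = em_center, em_width = em_width,
         quantum_yield = quantum_yield, epsilon = epsilon,
         concentration = concentration),
    class = "fluorophore_spec"
  )
}

#' Default blood autofluorescence library
#'
#' Three endogenous fluorophores structuring the blood EEM, with band
#' centers at the midpoints of the commonly reported ranges (tryptophan
#' ex 280-300 / em 340-350 nm, NADH ex 340-360 / em 450-460 nm, flavins
#' ex 450-470 / em 520-530 nm) and sigmas at half the range widths.
#' Amplitudes (yield x absorptivity x concentration) are chosen so NADH,
#' the metabolic-state reporter, carries the strongest signal.
#'
#' @return A named list of [fluorophore_spec()] objects.
#' @export
blood_fluorophores <- function() {
  list(
    tryptophan = fluorophore_spec("tryptophan", ex_center = 290,
                                  ex_width = 10, em_center = 345,
                                  em_width = 5, quantum_yield = 0.13,
                                  epsilon = 5500, concentration = 2e-6),
    NADH = fluorophore_spec("NADH", ex_center = 350, ex_width = 10,
                            em_center = 455, em_width = 5,
                            quantum_yield = 0.40, epsilon = 6220,
                            concentration = 5e-6),
    flavins = fluorophore_spec("flavins", ex_center = 460, ex_width = 10,
                               em_center = 525, em_width = 5,
                               quantum_yield = 0.25, epsilon = 12500,
                               concentration = 1e-6)
  )
}

#' Excitation source
#'
#' A lamp kind with a smooth relative power profile I0(lambda) over
#' 200-900 nm.  Profiles are idealized: deuterium is UV-weighted,
#' halogen is visible/NIR-weighted, the combined source is their sum,
#' and UV is a band-limited lamp below ~400 nm.  All profiles are
#' non-negative with maximum 1.
#'
#' @param kind One of `"deuterium"`, `"halogen"`, `"deuterium+halogen"`,
#'   `"UV"`, `"flat"`.
#' @return An object of class `excitation_source` with a `power(lambda)`
#'   function.
#' @export
excitation_source <- function(kind = c("deuterium+halogen", "deuterium",
                                       "halogen", "UV", "flat")) {
  kind <- match.arg(kind)
  power <- switch(
    kind,
    deuterium = function(l) exp(-(l - 230)^2 / (2 * 120^2)),
    halogen = function(l) exp(-(l - 750)^2 / (2 * 220^2)),
    `deuterium+halogen` = function(l) {
      exp(-(l - 230)^2 / (2 * 120^2)) + exp(-(l - 750)^2 / (2 * 220^2))
    },
    UV = function(l) exp(-(l - 300)^2 / (2 * 60^2)),
    flat = function(l) rep(1, length(l))
  )
  structure(list(kind = kind, power = power), class = "excitation_source")
}

# Source kind as stored on spectra (the spectrum1d source field has no
# "flat"; a flat profile is bookkept as "none").
source_label <- function(src) {
  if (src$kind == "flat") "none" else src$kind
}

gauss <- function(x, center, sigma) exp(-(x - center)^2 / (2 * sigma^2))

#' Spatial concentration field
#'
#' A finite grid of erythrocyte concentration over (x, y, z), used by
#' the spatial EEM variant: the fluorescence amplitude of each
#' fluorophore is scaled by the mean concentration over the field
#' relative to a unit reference.
#'
#' @param x,y,z Coordinate vectors (arbitrary spatial units).
#' @param concentration Numeric array of dim
#'   `c(length(x), length(y), length(z))`, all values >= 0 and finite.
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(x, y, z, concentration) {
  concentration <- array(concentration,
                         dim = c(length(x), length(y), length(z)))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("concentration must be finite and non-negative everywhere")
  }
  structure(list(x = x, y = y, z = z, concentration = concentration),
            class = "concentration_field")
}

#' Generate a synthetic excitation-emission matrix
#'
#' Intensity at (lambda_ex, lambda_em) is the sum over fluorophores of
#' `quantum_yield * I0(lambda_ex) * epsilon * C * G_ex * G_em`, with
#' `G_ex`, `G_em` unit-height Gaussians at the fluorophore's excitation
#' and emission centers, plus optional additive Gaussian noise.  With a
#' spatial `field`, each fluorophore's concentration is multiplied by
#' the field's mean concentration (the volume integral normalized by
#' the grid size), emulating a bulk measurement over an inhomogeneous
#' sample.
#'
#' @param fluorophores List of [fluorophore_spec()] objects (at least
#'   one).
#' @param source An [excitation_source()].
#' @param ex_grid,em_grid Strictly increasing wavelength grids (nm).
#' @param field Optional [concentration_field()]; `NULL` means uniform.
#' @param noise_sd Additive Gaussian noise sd (a.u.), >= 0.
#' @param seed Integer seed; with `noise_sd = 0` the output is
#'   bit-identical across calls.
#' @return An [eem()].
#' @export
generate_eem <- function(fluorophores, source = excitation_source(),
                         ex_grid = seq(250, 500, by = 5),
                         em_grid = seq(300, 600, by = 5),
                         field = NULL, noise_sd = 0, seed = NULL) {
  if (length(fluorophores) == 0) stop("at least one fluorophore required")
  if (inherits(fluorophores, "fluorophore_spec")) {
    fluorophores <- list(fluorophores)
  }
  if (any(diff(ex_grid) <= 0) || any(diff(em_grid) <= 0)) {
    stop("grids must be strictly increasing")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  field_scale <- if (is.null(field)) 1 else mean(field$concentration)

  I0 <- source$power(ex_grid)
  M <- matrix(0, nrow = length(ex_grid), ncol = length(em_grid))
  for (f in fluorophores) {
    amp <- f$quantum_yield * f$epsilon * f$concentration * field_scale
    gex <- I0 * gauss(ex_grid, f$ex_center, f$ex_width)
    gem <- gauss(em_grid, f$em_center, f$em_width)
    M <- M + amp * outer(gex, gem)
  }
  if (noise_sd > 0) {
    M <- M + with_seed(seed, matrix(stats::rnorm(length(M), 0, noise_sd),
                                    nrow = nrow(M)))
  }
  eem(ex_grid, em_grid, M,
      meta = list(source = source$kind, noise_sd = noise_sd, seed = seed,
                  fluorophores = vapply(fluorophores, `[[`, "", "name")))
}

#' Simulate a hemoglobin absorption spectrum
#'
#' A single dominant absorption band centered at 550 nm on a small flat
#' background.  Band height rises strictly with the oxygen fraction and
#' falls strictly (exponentially) with the glycation level; glycation
#' also broadens the band, making it less distinct.  Deterministic: no
#' noise is added.
#'
#' The spectrum decomposes as `background + deoxy band + oxygen-scaled
#' oxy band`, so at `oxygen_fraction = 0` and `glycation_pct = 0` the
#' output is exactly the configured deoxygenated baseline.
#'
#' @param oxygen_fraction Fraction of oxygenated hemoglobin, in
#'   \[0, 1\].
#' @param glycation_pct Percent HbA1c, >= 0.
#' @param grid Wavelength grid (nm); must cover 400-700 nm.
#' @param band_center Band center (nm); default 550.
#' @param band_sigma Base band sigma (nm).
#' @param deoxy_height Band height at zero oxygen and zero glycation
#'   (a.u.).
#' @param oxy_height Additional height at full oxygenation (a.u.).
#' @param glycation_scale e-folding glycation level (% HbA1c) for the
#'   height decay.
#' @param background Flat background absorbance (a.u.).
#' @return A [spectrum1d()] with role `"absorbance"`.
#' @export
generate_absorption_spectrum <- function(oxygen_fraction, glycation_pct,
                                         grid = seq(400, 700, by = 0.5),
                                         band_center = 550,
                                         band_sigma = 35,
                                         deoxy_height = 0.4,
                                         oxy_height = 0.8,
                                         glycation_scale = 12,
                                         background = 0.02) {
  if (oxygen_fraction < 0 || oxygen_fraction > 1) {
    stop("oxygen_fraction must lie in [0, 1]")
  }
  if (glycation_pct < 0) stop("glycation_pct must be >= 0")
  if (min(grid) > 400 || max(grid) < 700) {
    stop("grid must cover 400-700 nm")
  }
  height <- (deoxy_height + oxy_height * oxygen_fraction) *
    exp(-glycation_pct / glycation_scale)
  sigma <- band_sigma * (1 + glycation_pct / 25)
  a <- background + height * gauss(grid, band_center, sigma)
  spectrum1d(grid, a, role = "absorbance",
             meta = list(oxygen_fraction = oxygen_fraction,
                         glycation_pct = glycation_pct,
                         band_center = band_center, peak_height = height))
}

#' Patient emulation profile
#'
#' Physiological knobs for the full-range patient spectrum generator.
#'
#' @param hemoglobin_gdl Total hemoglobin, g/dL (> 0).
#' @param oxygen_fraction Oxygenated fraction of hemoglobin, \[0, 1\].
#' @param glycation_pct Percent HbA1c, >= 0 (annotation only here).
#' @param plasma_fraction Relative plasma/water content, \[0, 1\].
#' @param lifecycle_phase `"young"`, `"mature"` or `"old"`; scales
#'   overall fluorescence (young > mature > old).
#' @param noise_sd Additive Gaussian noise sd (a.u.), >= 0.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(hemoglobin_gdl = 14, oxygen_fraction = 0.95,
                            glycation_pct = 5, plasma_fraction = 0.55,
                            lifecycle_phase = c("mature", "young", "old"),
                            noise_sd = 0, seed = NULL) {
  lifecycle_phase <- match.arg(lifecycle_phase)
  if (hemoglobin_gdl <= 0) stop("hemoglobin_gdl must be > 0")
  if (oxygen_fraction < 0 || oxygen_fraction > 1) {
    stop("oxygen_fraction must lie in [0, 1]")
  }
  if (plasma_fraction < 0 || plasma_fraction > 1) {
    stop("plasma_fraction must lie in [0, 1]")
  }
  if (glycation_pct < 0) stop("glycation_pct must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(hemoglobin_gdl = hemoglobin_gdl, oxygen_fraction = oxygen_fraction,
         glycation_pct = glycation_pct, plasma_fraction = plasma_fraction,
         lifecycle_phase = lifecycle_phase, noise_sd = noise_sd,
         seed = seed),
    class = "patient_profile"
  )
}

lifecycle_multiplier <- function(phase) {
  c(young = 1.25, mature = 1.0, old = 0.65)[[phase]]
}

#' Generate a full-range synthetic patient spectrum
#'
#' Superimposes three diagnostic band components on the 200-900 nm
#' grid: oxyhemoglobin (Gaussian at 540 nm, amplitude proportional to
#' `hemoglobin_gdl * oxygen_fraction`), deoxyhemoglobin (650 nm,
#' proportional to `hemoglobin_gdl * (1 - oxygen_fraction)`) and
#' plasma/water (850 nm, proportional to `plasma_fraction`), each
#' scaled by the lamp power at its band and by the lifecycle multiplier
#' (young > mature > old).  Under UV excitation the deoxyhemoglobin
#' component enters with negative sign, emulating the downward
#' (background-subtracted) absorption excursions seen under UV, and
#' noise is not clipped; under the other lamps noise-perturbed
#' intensities are clipped at zero.
#'
#' @param profile A [patient_profile()].
#' @param source An [excitation_source()].
#' @param grid Wavelength grid (nm) spanning 200-900.
#' @return A [spectrum1d()] with role `"emission"`.
#' @export
generate_patient_spectrum <- function(profile,
                                      source = excitation_source(),
                                      grid = seq(200, 900, by = 0.5)) {
  stopifnot(inherits(profile, "patient_profile"))
  if (min(grid) > 200 || max(grid) < 900) stop("grid must span 200-900 nm")
  life <- lifecycle_multiplier(profile$lifecycle_phase)
  is_uv <- source$kind == "UV"

  bands <- list(
    oxy = list(center = 540, sigma = 30,
               amp = 0.06 * profile$hemoglobin_gdl * profile$oxygen_fraction),
    deoxy = list(center = 650, sigma = 20,
                 amp = 0.06 * profile$hemoglobin_gdl *
                   (1 - profile$oxygen_fraction)),
    plasma = list(center = 850, sigma = 25,
                  amp = 0.8 * profile$plasma_fraction)
  )
  # the lamp modulates each band by its power at the band center, so a
  # halogen-rich source boosts the NIR plasma band as observed
  intensity <- rep(0, length(grid))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    sgn <- if (is_uv && nm == "deoxy") -1 else 1
    lamp <- max(source$power(b$center), 0.05)  # floor: stray/2nd-order light
    intensity <- intensity +
      sgn * life * lamp * b$amp * gauss(grid, b$center, b$sigma)
  }
  if (profile$noise_sd > 0) {
    intensity <- intensity +
      with_seed(profile$seed,
                stats::rnorm(length(grid), 0, profile$noise_sd))
    if (!is_uv) intensity <- pmax(intensity, 0)
  }
  spectrum1d(grid, intensity, role = "emission",
             source = source_label(source),
             meta = list(profile = unclass(profile), lifecycle_mult = life))
}

# MCH reference bins by age (pg).  Left-closed, right-open; ages >= 45
# reuse the adult 18-44 range.
mch_bins <- function() {
  data.frame(
    lo_age = c(0.5, 9, 12, 18),
    hi_age = c(9, 12, 18, Inf),
    mch_lo = c(24, 26, 26, 27),
    mch_hi = c(30, 32, 34, 34)
  )
}

#' Generate a synthetic CBC record
#'
#' MCH is drawn uniformly within the age-appropriate reference range
#' (see [mch_reference_range()]); iron deficiency shifts it below the
#' bin's lower bound, B12 deficiency above the upper bound
#' (direction-only modifiers).  RBC count and MCV are drawn from
#' physiologic ranges, and Hb and Hct are then derived so the record is
#' exactly self-consistent: `Hb (g/dL) = RBC (10^6/uL) x MCH (pg) / 10`
#' and `Hct (%) = RBC x MCV (fL) / 10`.  Sex carries no quantitative
#' effect (reference ranges overlap almost fully); it is recorded as an
#' annotation.
#'
#' @param age_years Age, >= 0.5.
#' @param sex `"M"` or `"F"`.
#' @param condition `"none"`, `"iron_deficiency"` or `"b12_deficiency"`.
#' @param seed Integer seed; fixed seed gives a reproducible record.
#' @return A [cbc_record()] with `mch_pg` filled in.
#' @export
generate_cbc <- function(age_years, sex = c("M", "F"),
                         condition = c("none", "iron_deficiency",
                                       "b12_deficiency"),
                         seed = NULL) {
  sex <- match.arg(sex)
  condition <- match.arg(condition)
  rng <- unname(mch_reference_range(age_years))
  with_seed(seed, {
    mch <- switch(condition,
      none = stats::runif(1, rng[1], rng[2]),
      iron_deficiency = rng[1] - stats::runif(1, 1, 5),
      b12_deficiency = rng[2] + stats::runif(1, 1, 5))
    rbc <- stats::runif(1, 4.2, 5.9)
    mcv <- stats::runif(1, 80, 96)
    wbc <- local({
      n <- stats::runif(1, 40, 70)
      l <- stats::runif(1, 20, min(40, 95 - n))
      e <- stats::runif(1, 1, 5)
      b <- stats::runif(1, 0.2, 1.5)
      c(n, l, e, b)
    })
    cbc_record(
      hb_gdl = rbc * mch / 10,
      rbc_1e6_per_ul = rbc,
      hct_pct = rbc * mcv / 10,
      mch_pg = mch,
      age_years = age_years, sex = sex,
      neutrophils_pct = wbc[1], lymphocytes_pct = wbc[2],
      eosinophils_pct = wbc[3], basophils_pct = wbc[4],
      meta = list(condition = condition, mcv_fl = mcv, seed = seed)
    )
  })
}

#' Generate a synthetic light-scattering profile
#'
#' A single-peaked scattering trace whose peak wavelength encodes the
#' cell diameter through the empirical calibration
#' `lambda_peak = diameter / k` (the inverse of the sizing relation
#' `R = k * lambda_peak`).  The peak lands on the grid point nearest
#' `lambda_peak`.
#'
#' @param true_diameter Mean erythrocyte diameter, um (> 0).
#' @param k Calibration constant, um/nm (> 0); default 0.009 maps the
#'   6-8 um physiologic range into 667-889 nm.
#' @param grid Wavelength grid (nm); must contain `lambda_peak`.
#' @param peak_height Peak intensity (a.u.).
#' @param peak_sigma Peak width sigma (nm).
#' @param noise_sd Additive Gaussian noise sd, >= 0; clipped at zero.
#' @param seed Integer seed.
#' @return A [spectrum1d()] with role `"scattering"`.
#' @export
generate_scattering_profile <- function(true_diameter, k = 0.009,
                                        grid = seq(200, 900, by = 0.5),
                                        peak_height = 100, peak_sigma = 40,
                                        noise_sd = 0, seed = NULL) {
  if (true_diameter <= 0 || k <= 0) stop("true_diameter and k must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lambda_peak <- true_diameter / k
  if (lambda_peak < min(grid) || lambda_peak > max(grid)) {
    stop(sprintf("peak wavelength %.1f nm falls outside the grid span",
                 lambda_peak))
  }
  center <- grid[which.min(abs(grid - lambda_peak))]
  intensity <- peak_height * gauss(grid, center, peak_sigma)
  if (noise_sd > 0) {
    intensity <- pmax(0, intensity +
      with_seed(seed, stats::rnorm(length(grid), 0, noise_sd)))
  }
  spectrum1d(grid, intensity, role = "scattering",
             meta = list(true_diameter = true_diameter, k = k,
                         lambda_peak = center, seed = seed))
}
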