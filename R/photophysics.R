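#' Photophysical parameter set
#'
#' @param quantum_yield Fluorescence quantum yield, \[0, 1\].
#' @param epsilon Molar absorptivity, L mol^-1 cm^-1, >= 0.
#' @param concentration mol/L, >= 0.
#' @param path_length cm, >= 0.
#' @param incident_intensity Excitation intensity I0, a.u., >= 0.
#' @return An object of class `photophysical_params`.
#' @export
photophysical_params <- function(quantum_yield, epsilon, concentration,
                                 path_length = 1, incident_intensity = 1) {
  if (quantum_yield < 0 || quantum_yield > 1) {
    stop("quantum_yield must lie in [0, 1]")
  }
  if (epsilon < 0 || concentration < 0 || path_length < 0 ||
      incident_intensity < 0) {
    stop("epsilon, concentration, path_length and incident_intensity must be >= 0")
  }
  structure(list(quantum_yield = quantum_yield, epsilon = epsilon,
                 concentration = concentration, path_length = path_length,
                 incident_intensity = incident_intensity),
            class = "photophysical_params")
}

#' Fluorescence intensity
#'
#' `I = Phi * I0 * C * epsilon`: emitted intensity is the product of
#' quantum yield, excitation intensity, concentration and molar
#' absorptivity, linear in each factor.
#'
#' @param p A [photophysical_params()].
#' @return Intensity, a.u.
#' @export
fluorescence_intensity <- function(p) {
  stopifnot(inherits(p, "photophysical_params"))
  p$quantum_yield * p$incident_intensity * p$concentration * p$epsilon
}

#' Beer-Lambert absorbance
#'
#' `A = epsilon * C * l`, with the transmitted fraction `I/I0 =
#' 10^(-A)` so that `log10(I0/I) = A`.
#'
#' @param epsilon Molar absorptivity, L mol^-1 cm^-1, >= 0.
#' @param concentration mol/L, >= 0.
#' @param path_length cm, >= 0.
#' @return A list with `absorbance` (dimensionless) and
#'   `transmitted_fraction`.
#' @export
absorbance <- function(epsilon, concentration, path_length) {
  if (epsilon < 0 || concentration < 0 || path_length < 0) {
    stop("absorbance inputs must be non-negative")
  }
  a <- epsilon * concentration * path_length
  list(absorbance = a, transmitted_fraction = 10^(-a))
}

#' Hemoglobin mass concentration from absorbance at 540 nm
#'
#' Inverts Beer-Lambert at the hemoglobin absorption wavelength and
#' converts the molar concentration to g/L with hemoglobin's molar mass
#' (64 500 g/mol): `c_gL = A540 / (epsilon540 * l) * 64500`.
#'
#' The default `epsilon540` of 54 000 L mol^-1 cm^-1 is a configurable
#' placeholder of the right order of magnitude for (oxy)hemoglobin on a
#' per-tetramer basis, not a literature constant; calibrate it for
#' quantitative work.
#'
#' @param a540 Absorbance at 540 nm, >= 0.
#' @param epsilon540 Molar absorptivity at 540 nm, > 0.
#' @param path_length cm, > 0.
#' @param molar_mass_g_mol Hemoglobin molar mass, g/mol.
#' @return Hemoglobin concentration, g/L.
#' @export
hemoglobin_gL_from_absorbance <- function(a540, epsilon540 = 54000,
                                          path_length = 1,
                                          molar_mass_g_mol = 64500) {
  if (epsilon540 <= 0 || path_length <= 0) {
    stop("epsilon540 and path_length must be > 0")
  }
  if (a540 < 0) stop("a540 must be >= 0")
  a540 / (epsilon540 * path_length) * molar_mass_g_mol
}

#' Stokes shift
#'
#' `delta_lambda = lambda_emission - lambda_absorption`.  A negative
#' result (anti-Stokes) is rejected: the shift presumes emission
#' red-shifted relative to absorption.
#'
#' @param emission_peak,absorption_peak Peak wavelengths, nm, > 0.
#' @return Shift in nm, >= 0.
#' @export
stokes_shift <- function(emission_peak, absorption_peak) {
  if (emission_peak <= 0 || absorption_peak <= 0) {
    stop("peak wavelengths must be positive")
  }
  shift <- emission_peak - absorption_peak
  if (shift < 0) {
    stop("anti-Stokes configuration: emission peak blue of absorption peak")
  }
  shift
}

#' Integrated intensity over a wavelength window
#'
#' Trapezoidal integral of I(lambda) over \[lambda_min, lambda_max\] on
#' the spectrum's native grid (no resampling).  Additive over adjacent
#' disjoint windows.
#'
#' @param s A [spectrum1d()].
#' @param lambda_min,lambda_max Integration bounds, nm, inside the grid
#'   span.
#' @return Integral, a.u. nm.
#' @export
integrate_intensity <- function(s, lambda_min = min(s$wavelength),
                                lambda_max = max(s$wavelength)) {
  stopifnot(inherits(s, "spectrum1d"))
  if (lambda_min >= lambda_max) stop("lambda_min must be < lambda_max")
  if (lambda_min < min(s$wavelength) || lambda_max > max(s$wavelength)) {
    stop("integration bounds fall outside the wavelength grid")
  }
  w <- s$wavelength
  y <- s$intensity
  # interpolated endpoint samples keep partial-step bounds exact for the
  # trapezoid rule
  inside <- w > lambda_min & w < lambda_max
  xs <- c(lambda_min, w[inside], lambda_max)
  ys <- c(stats::approx(w, y, lambda_min)$y, y[inside],
          stats::approx(w, y, lambda_max)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Optical penetration depth
#'
#' `d = 1 / (epsilon * C)`, returned verbatim in the units implied by
#' the inputs (cm when epsilon is in L mol^-1 cm^-1 and C in mol/L).
#' Note this simple reciprocal omits the ln(10) ~ 2.303 factor that a
#' base-e 1/e attenuation depth would carry; it is an index of relative
#' penetration, not a radiometric depth.
#'
#' @param epsilon Molar absorptivity, L mol^-1 cm^-1.
#' @param concentration mol/L.
#' @return Depth, cm.
#' @export
penetration_depth <- function(epsilon, concentration) {
  if (!(epsilon * concentration > 0)) {
    stop("epsilon * concentration must be > 0")
  }
  1 / (epsilon * concentration)
}
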