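#' Scattering profile of an erythrocyte suspension
#'
#' Bundles a scattering-role spectrum with its peak descriptors and the
#' size calibration: `Ipeak` and `lambda_peak` are taken at the
#' spectrum's maximum, and the mean diameter `R` defaults to the
#' empirical sizing relation `R = k * lambda_peak`.
#'
#' @param spectrum A [spectrum1d()] with role `"scattering"`.
#' @param k Calibration constant, um/nm (> 0).
#' @param mean_diameter Optional mean diameter in um; defaults to
#'   `k * lambda_peak`.
#' @return An object of class `scattering_profile` with fields
#'   `spectrum`, `i_peak`, `lambda_peak`, `mean_diameter`, `k`.
#' @export
scattering_profile <- function(spectrum, k = 0.009, mean_diameter = NULL) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (spectrum$role != "scattering") {
    stop("spectrum role must be 'scattering'")
  }
  if (k <= 0) stop("k must be > 0")
  i_max <- which.max(spectrum$intensity)
  lambda_peak <- spectrum$wavelength[i_max]
  if (is.null(mean_diameter)) {
    mean_diameter <- diameter_from_scattering(lambda_peak, k)
  }
  if (mean_diameter <= 0) stop("mean_diameter must be > 0")
  structure(
    list(spectrum = spectrum, i_peak = spectrum$intensity[i_max],
         lambda_peak = lambda_peak, mean_diameter = mean_diameter, k = k),
    class = "scattering_profile"
  )
}

#' Erythrocyte shape factor
#'
#' `shape factor = Ipeak / R`: peak scattering intensity over mean cell
#' diameter (a.u./um).  Lower values indicate a more biconcave disc;
#' higher values indicate spherical or distorted cells.
#'
#' @param p A [scattering_profile()].
#' @return A number with attribute `interpretation` (`"more biconcave"`
#'   or `"spherical or distorted"`, split at the physiologic midpoint).
#' @export
shape_factor <- function(p) {
  stopifnot(inherits(p, "scattering_profile"))
  if (p$mean_diameter <= 0) stop("mean diameter must be > 0")
  sf <- p$i_peak / p$mean_diameter
  attr(sf, "interpretation") <-
    if (sf <= 15) "more biconcave" else "spherical or distorted"
  sf
}

#' Deformability index from a scattering profile
#'
#' The integral of the scattering intensity over a wavelength window,
#' divided by the mean cell diameter (a.u. nm / um).  Higher values
#' indicate more flexible cells.
#'
#' @param p A [scattering_profile()].
#' @param lambda_min,lambda_max Integration bounds, nm; default the
#'   full grid.
#' @return Deformability index.
#' @export
deformability_from_scattering <- function(p,
                                          lambda_min = min(p$spectrum$wavelength),
                                          lambda_max = max(p$spectrum$wavelength)) {
  stopifnot(inherits(p, "scattering_profile"))
  integrate_intensity(p$spectrum, lambda_min, lambda_max) / p$mean_diameter
}

#' Deformability-vs-zeta-potential model
#'
#' Two single-parameter-family models of how the deformability index
#' responds to zeta potential (mV): exponential
#' `DI = a * exp(b * zeta) + c` and logarithmic
#' `DI = a * ln(-zeta) + c` (the log argument is the numeric mV
#' magnitude, so the logarithmic model requires `zeta < 0`).  Defaults
#' `a = 1.5` (responsiveness), `b = -0.05` per mV (sensitivity),
#' `c = 0.5` (baseline deformability).
#'
#' @param kind `"exponential"` or `"logarithmic"`.
#' @param a Scaling constant, > 0.
#' @param b Sensitivity to zeta potential, per mV (exponential model).
#' @param c Baseline deformability, >= 0.
#' @return An object of class `deformability_model`.
#' @export
deformability_model <- function(kind = c("exponential", "logarithmic"),
                                a = 1.5, b = -0.05, c = 0.5) {
  kind <- match.arg(kind)
  if (a <= 0) stop("a must be > 0")
  if (c < 0) stop("c must be >= 0")
  structure(list(kind = kind, a = a, b = b, c = c),
            class = "deformability_model")
}

#' Deformability index at a given zeta potential
#'
#' @param zeta_mv Zeta potential in mV (vectorized).  The logarithmic
#'   model requires strictly negative values.
#' @param model A [deformability_model()].
#' @return Deformability index (dimensionless).
#' @export
di_zeta <- function(zeta_mv, model = deformability_model()) {
  stopifnot(inherits(model, "deformability_model"))
  if (model$kind == "logarithmic") {
    if (any(zeta_mv >= 0)) {
      stop("logarithmic model requires zeta < 0 (mV)")
    }
    model$a * log(-zeta_mv) + model$c
  } else {
    model$a * exp(model$b * zeta_mv) + model$c
  }
}

#' DLVO parameter set (SI units)
#'
#' @param permittivity Medium permittivity, F/m (> 0).
#' @param radius Erythrocyte radius, m (> 0).
#' @param zeta Zeta potential, V (any sign).
#' @param inverse_debye Inverse Debye length kappa, 1/m (> 0).
#' @param separation Surface-to-surface distance, m (> 0).
#' @param hamaker Hamaker constant, J (>= 0).
#' @return An object of class `dlvo_params`.
#' @export
dlvo_params <- function(permittivity = 7.08e-10, radius = 3.5e-6,
                        zeta = -0.015, inverse_debye = 1.04e9,
                        separation = 5e-9, hamaker = 5e-21) {
  if (permittivity <= 0 || radius <= 0 || inverse_debye <= 0 ||
      separation <= 0) {
    stop("permittivity, radius, inverse_debye and separation must be > 0")
  }
  if (hamaker < 0) stop("hamaker must be >= 0")
  structure(list(permittivity = permittivity, radius = radius, zeta = zeta,
                 inverse_debye = inverse_debye, separation = separation,
                 hamaker = hamaker),
            class = "dlvo_params")
}

#' DLVO interaction energy between two erythrocytes
#'
#' Total energy is the screened electrostatic repulsion plus the van
#' der Waals attraction:
#' `E_rep = pi * eps_m * R * zeta^2 * exp(-kappa * d)` and
#' `E_vdw = -A_H * R / (12 * d)`.  A positive total means repulsion
#' dominates (aggregation prevented); negative means attraction
#' dominates (aggregation promoted).  The exact-zero boundary is
#' classified as repulsion-dominated.
#'
#' @param p A [dlvo_params()].
#' @return A list of class `energy_decomposition` with `e_rep`,
#'   `e_vdw`, `e_total` (J) and `regime`.
#' @export
dlvo_energy <- function(p) {
  stopifnot(inherits(p, "dlvo_params"))
  e_rep <- pi * p$permittivity * p$radius * p$zeta^2 *
    exp(-p$inverse_debye * p$separation)
  e_vdw <- -p$hamaker * p$radius / (12 * p$separation)
  e_total <- e_rep + e_vdw
  structure(
    list(e_rep = e_rep, e_vdw = e_vdw, e_total = e_total,
         regime = if (e_total >= 0) "repulsion_dominates"
                  else "attraction_dominates"),
    class = "energy_decomposition"
  )
}

#' Erythrocyte diameter from the scattering peak
#'
#' Empirical sizing relation `R = k * lambda_peak` (um from nm through
#' the calibration constant k in um/nm).
#'
#' @param lambda_peak Scattering peak wavelength, nm (> 0).
#' @param k Calibration constant, um/nm (> 0).
#' @return Diameter in um.
#' @export
diameter_from_scattering <- function(lambda_peak, k = 0.009) {
  if (any(lambda_peak <= 0) || k <= 0) {
    stop("lambda_peak and k must be > 0")
  }
  k * lambda_peak
}

#' Internal composition index
#'
#' Full-grid trapezoidal integral of an emission spectrum (a.u. nm).
#' Higher values indicate a higher load of fluorescent components
#' (NADH, flavins, proteins) and hence higher metabolic activity.
#'
#' @param s A [spectrum1d()] with role `"emission"`.
#' @return The index, a.u. nm.
#' @export
internal_composition_index <- function(s) {
  stopifnot(inherits(s, "spectrum1d"))
  if (s$role != "emission") {
    stop("internal composition index is defined for emission spectra")
  }
  integrate_intensity(s)
}
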