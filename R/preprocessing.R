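#' Maximum-intensity normalization
#'
#' Divides every intensity by the maximum absolute intensity, so the
#' strongest feature has magnitude 1.  Using the absolute maximum (not
#' the signed maximum) keeps UV-difference spectra with negative lobes
#' stable under normalization.
#'
#' @param s A [spectrum1d()] with at least one non-zero point.
#' @return The normalized [spectrum1d()].
#' @export
normalize_max <- function(s) {
  stopifnot(inherits(s, "spectrum1d"))
  m <- max(abs(s$intensity))
  if (m == 0) stop("cannot normalize an all-zero spectrum")
  s$intensity <- s$intensity / m
  s$meta$normalized <- TRUE
  s
}

# rolling min / max over a centered window of `half` points each side,
# truncated at the edges
roll_extreme <- function(y, half, fun) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- fun(y[max(1, i - half):min(n, i + half)])
  }
  out
}

#' Baseline correction
#'
#' Estimates a slowly varying background by morphological opening
#' (rolling minimum followed by rolling maximum over the same window)
#' and smooths the estimate with a Gaussian kernel before subtracting
#' it.  Opening follows constant and linear backgrounds exactly while
#' ignoring peaks narrower than the window, so a baseline-free spectrum
#' plus a constant offset comes back essentially unchanged.
#'
#' @param s A [spectrum1d()].
#' @param window Baseline window in nm (default 50); must be at least 3
#'   grid steps and no wider than the spectrum span.
#' @return The corrected [spectrum1d()].
#' @export
baseline_correct <- function(s, window = 50) {
  stopifnot(inherits(s, "spectrum1d"))
  step <- stats::median(diff(s$wavelength))
  span <- diff(range(s$wavelength))
  if (window < 3 * step) stop("window must cover at least 3 grid steps")
  if (window > span) stop("window exceeds the spectrum span")
  half <- max(1L, as.integer(round(window / (2 * step))))
  opened <- roll_extreme(roll_extreme(s$intensity, half, min), half, max)
  baseline <- gaussian_kernel_smooth(opened, sigma_pts = half / 2)
  s$intensity <- s$intensity - baseline
  s$meta$baseline_window_nm <- window
  s
}

# dense discrete Gaussian convolution with reflective padding; kernel
# normalized to sum 1 so constants pass through exactly
gaussian_kernel_smooth <- function(y, sigma_pts) {
  if (sigma_pts <= 0) return(y)
  r <- max(1L, as.integer(ceiling(4 * sigma_pts)))
  k <- exp(-((-r:r)^2) / (2 * sigma_pts^2))
  k <- k / sum(k)
  n <- length(y)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))  # reflect
  ypad <- y[pmin(pmax(idx, 1L), n)]
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(ypad[i:(i + 2L * r)] * k)
  }
  out
}

#' Gaussian smoothing
#'
#' Convolves the intensities with a discrete Gaussian kernel (radius
#' 4 sigma) using reflective boundary handling.  `sigma_nm = 0` is the
#' identity, and constant spectra are preserved exactly because the
#' kernel is normalized.
#'
#' @param s A [spectrum1d()].
#' @param sigma_nm Kernel sigma in nm, >= 0.
#' @return The smoothed [spectrum1d()].
#' @export
gaussian_smooth <- function(s, sigma_nm = 2) {
  stopifnot(inherits(s, "spectrum1d"))
  if (sigma_nm < 0) stop("sigma_nm must be >= 0")
  if (sigma_nm == 0) return(s)
  step <- stats::median(diff(s$wavelength))
  s$intensity <- gaussian_kernel_smooth(s$intensity, sigma_nm / step)
  s$meta$smooth_sigma_nm <- sigma_nm
  s
}

#' Run the standard preprocessing chain
#'
#' Applies maximum-intensity normalization, baseline correction, and
#' Gaussian smoothing, in that order, recording parameters in the
#' spectrum metadata.
#'
#' @param s A [spectrum1d()].
#' @param baseline_window Baseline window, nm.
#' @param smooth_sigma Smoothing sigma, nm.
#' @return The preprocessed [spectrum1d()].
#' @export
preprocess_spectrum <- function(s, baseline_window = 50, smooth_sigma = 2) {
  s <- normalize_max(s)
  s <- baseline_correct(s, window = baseline_window)
  s <- gaussian_smooth(s, sigma_nm = smooth_sigma)
  s$meta$preprocessing <- list(order = c("normalize", "baseline", "smooth"),
                               baseline_window_nm = baseline_window,
                               smooth_sigma_nm = smooth_sigma)
  s
}

# single-Gaussian least-squares refinement around index i0; returns
# c(center, sigma, height).  Falls back to moment estimates when nls
# fails to converge.
fit_gaussian_local <- function(w, y, i0, half_pts) {
  lo <- max(1L, i0 - half_pts)
  hi <- min(length(w), i0 + half_pts)
  wi <- w[lo:hi]
  yi <- y[lo:hi]
  h0 <- y[i0]
  # moment (weighted mean/sd) initializer on the positive part
  yp <- pmax(yi - min(yi), 0)
  if (sum(yp) == 0) return(c(center = w[i0], sigma = NA_real_, height = h0))
  c0 <- sum(wi * yp) / sum(yp)
  s0 <- sqrt(sum((wi - c0)^2 * yp) / sum(yp))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(wi)) / 6
  fallback <- c(center = c0, sigma = s0, height = h0)
  fit <- tryCatch({
    m <- suppressWarnings(
      stats::nls(yi ~ h * exp(-(wi - c)^2 / (2 * s^2)),
                 start = list(h = h0, c = c0, s = s0),
                 control = stats::nls.control(warnOnly = TRUE)))
    p <- stats::coef(m)
    c(center = unname(p["c"]), sigma = abs(unname(p["s"])),
      height = unname(p["h"]))
  }, error = function(e) fallback)
  # reject divergent fits (center outside the window, absurd width)
  if (!all(is.finite(fit)) ||
      fit["center"] < min(wi) || fit["center"] > max(wi) ||
      fit["sigma"] <= 0 || fit["sigma"] > diff(range(wi)) ||
      fit["height"] <= 0) {
    fit <- fallback
  }
  fit
}

#' Detect and fit peaks in a spectrum
#'
#' Finds local maxima exceeding a prominence threshold (relative to the
#' maximum absolute intensity) and refines each by a local
#' least-squares single-Gaussian fit.  Results are sorted by descending
#' height, ties broken by ascending wavelength.  A flat spectrum yields
#' an empty table.
#'
#' @param s A [spectrum1d()], ideally preprocessed.
#' @param max_peaks Maximum number of peaks returned.
#' @param prominence Minimum height as a fraction of the absolute
#'   maximum (default 0.05).
#' @param window_nm Half-width of the local fit window, nm.
#' @return A data.frame with columns `center`, `sigma`, `height`,
#'   `assigned_fluorophore` (NA here; filled by EEM mapping).
#' @export
fit_peaks <- function(s, max_peaks = 5, prominence = 0.05, window_nm = 25) {
  stopifnot(inherits(s, "spectrum1d"))
  w <- s$wavelength
  y <- s$intensity
  n <- length(y)
  m <- max(abs(y))
  empty <- data.frame(center = numeric(0), sigma = numeric(0),
                      height = numeric(0),
                      assigned_fluorophore = character(0))
  if (m == 0) return(empty)
  thr <- prominence * m
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y > thr)
  if (length(cand) == 0) return(empty)
  step <- stats::median(diff(w))
  half_pts <- max(3L, as.integer(round(window_nm / step)))
  fits <- t(vapply(cand, function(i) fit_gaussian_local(w, y, i, half_pts),
                   numeric(3)))
  out <- data.frame(center = fits[, 1], sigma = fits[, 2],
                    height = fits[, 3],
                    assigned_fluorophore = NA_character_)
  out <- out[is.finite(out$height) & out$height > 0, , drop = FALSE]
  out <- out[order(-out$height, out$center), , drop = FALSE]
  utils::head(out, max_peaks)
}

#' Map EEM peaks to a fluorophore library
#'
#' For each library entry, restricts the EEM to a window around the
#' nominal (excitation, emission) center (`window_sigmas` fluorophore
#' widths each side), locates the local maximum there, and refines the
#' two coordinates by separable 1-D Gaussian fits along the excitation
#' and emission slices through that maximum.  An entry whose window
#' holds no positive local maximum is reported unassigned (NA
#' coordinates).
#'
#' @param e An [eem()].
#' @param library List of [fluorophore_spec()] objects (non-empty).
#' @param window_sigmas Search half-window in units of the
#'   fluorophore's widths (default 3).
#' @return A data.frame with one row per library entry: `fluorophore`,
#'   `ex`, `em`, `height`, `assigned`.
#' @export
eem_peak_map <- function(e, library = blood_fluorophores(),
                         window_sigmas = 3) {
  stopifnot(inherits(e, "eem"))
  if (length(library) == 0) stop("fluorophore library must be non-empty")
  res <- lapply(library, function(f) {
    exw <- which(abs(e$ex - f$ex_center) <= window_sigmas * f$ex_width)
    emw <- which(abs(e$em - f$em_center) <= window_sigmas * f$em_width)
    if (length(exw) == 0 || length(emw) == 0) {
      return(data.frame(fluorophore = f$name, ex = NA_real_, em = NA_real_,
                        height = NA_real_, assigned = FALSE))
    }
    sub <- e$intensity[exw, emw, drop = FALSE]
    if (max(sub) <= 0) {
      return(data.frame(fluorophore = f$name, ex = NA_real_, em = NA_real_,
                        height = NA_real_, assigned = FALSE))
    }
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i0 <- exw[ij[1]]
    j0 <- emw[ij[2]]
    step_ex <- stats::median(diff(e$ex))
    step_em <- stats::median(diff(e$em))
    fex <- fit_gaussian_local(e$ex, e$intensity[, j0], i0,
                              max(3L, as.integer(round(
                                window_sigmas * f$ex_width / step_ex))))
    fem <- fit_gaussian_local(e$em, e$intensity[i0, ], j0,
                              max(3L, as.integer(round(
                                window_sigmas * f$em_width / step_em))))
    data.frame(fluorophore = f$name, ex = unname(fex["center"]),
               em = unname(fem["center"]),
               height = e$intensity[i0, j0], assigned = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
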