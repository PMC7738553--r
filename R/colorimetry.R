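# CIE 1931 2-degree colour-matching functions via the multi-lobe Gaussian
# analytic representation of Wyman, Sloan & Shirley (2013, JCGT 2:1-11).
# Each lobe is a piecewise Gaussian with separate left/right widths.
pw_gauss <- function(x, mu, tau1, tau2) {
  t <- ifelse(x < mu, tau1, tau2) * (x - mu)
  exp(-0.5 * t * t)
}

cmf_raw <- function(wl) {
  xbar <- 0.362 * pw_gauss(wl, 442.0, 0.0624, 0.0374) +
    1.056 * pw_gauss(wl, 599.8, 0.0264, 0.0323) -
    0.065 * pw_gauss(wl, 501.1, 0.0490, 0.0382)
  ybar <- 0.821 * pw_gauss(wl, 568.8, 0.0213, 0.0247) +
    0.286 * pw_gauss(wl, 530.9, 0.0613, 0.0322)
  zbar <- 1.217 * pw_gauss(wl, 437.0, 0.0845, 0.0278) +
    0.681 * pw_gauss(wl, 459.0, 0.0385, 0.0725)
  cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
}

# Normalization: the 1931 observer has equal x/y/z integrals over its
# support (equal-energy white at exactly (1/3, 1/3)); enforce that property
# on the analytic fit over the package's 380-780 nm band.
cmf_norm_constants <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- seq(380, 780, by = 1)
      cache <<- colSums(cmf_raw(grid))
    }
    cache
  }
})

#' CIE 1931 2-degree colour-matching functions
#'
#' Analytic representation of the 1931 standard observer (multi-lobe
#' piecewise-Gaussian fit; Wyman, Sloan & Shirley 2013), renormalized to
#' equal integrals over 380--780 nm so a flat spectrum under the
#' equal-energy illuminant maps to chromaticity (1/3, 1/3) exactly, as with
#' the true observer.
#'
#' @param wavelength wavelengths in nm.
#' @return Matrix with columns `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function(wavelength) {
  k <- cmf_norm_constants()
  raw <- cmf_raw(wavelength)
  sweep(raw, 2, k / mean(k), "/")
}

# CIE standard illuminant D65, relative spectral power at 10 nm steps,
# 380-780 nm (normalized to 100 at 560 nm); interpolated linearly.
d65_table <- data.frame(
  wl = seq(380, 780, by = 10),
  power = c(49.98, 54.65, 82.75, 91.49, 93.43, 86.68, 104.86, 117.01,
            117.81, 114.86, 115.92, 108.81, 109.35, 107.80, 104.79, 107.69,
            104.41, 104.05, 100.00, 96.33, 95.79, 88.69, 90.01, 89.60,
            87.70, 83.29, 83.70, 80.03, 80.21, 82.28, 78.28, 69.72, 71.61,
            74.35, 61.60, 69.89, 75.09, 63.59, 46.42, 66.81, 63.38)
)

illuminant_power <- function(illuminant, wavelength) {
  switch(illuminant,
         equal_energy = rep(1, length(wavelength)),
         D65 = stats::approx(d65_table$wl, d65_table$power, wavelength,
                             rule = 2)$y,
         stop("unknown illuminant: ", illuminant))
}

#' Smooth a spectrum with a centered running average
#'
#' Centered moving average of the reflectance; window 3 is the convention
#' used for all peak readouts in this package. Edges use shrinking windows
#' (the first/last points average over the available neighbours only), so
#' wavelengths are unchanged and a constant spectrum is a fixed point.
#'
#' @param spectrum an `"irido_spectrum"` (or any data frame with
#'   `wavelength_nm` and `reflectance`).
#' @param window odd window length, >= 1.
#' @return Smoothed spectrum of the same class and length.
#' @examples
#' s <- data.frame(wavelength_nm = 1:5, reflectance = c(0, 0, 1, 0, 0))
#' smooth_spectrum(s)$reflectance  # 0 1/3 1/3 1/3 0
#' @export
smooth_spectrum <- function(spectrum, window = 3) {
  r <- spectrum$reflectance
  n <- length(r)
  if (window %% 2 != 1 || window < 1) stop("'window' must be odd and >= 1")
  if (window > n) stop("'window' exceeds spectrum length")
  if (window == 1 || n == 1L) return(spectrum)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, r))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  out <- spectrum
  out$reflectance <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Peak wavelength of a spectrum
#'
#' Wavelength of the global maximum of the smoothed spectrum (window-3
#' running average by default, matching the package's smoothing convention).
#' Plateaus of equal maxima resolve to the shortest wavelength. A spectrum
#' with no structure (all reflectance zero) returns `NA` with a warning.
#'
#' @inheritParams smooth_spectrum
#' @param smooth_window smoothing window applied before the argmax
#'   (1 disables smoothing).
#' @return Peak wavelength in nm, or `NA_real_` if there is no peak.
#' @export
peak_wavelength <- function(spectrum, smooth_window = 3) {
  if (nrow(spectrum) == 0L) stop("empty spectrum")
  s <- smooth_spectrum(spectrum, min(smooth_window, max_odd(nrow(spectrum))))
  if (all(s$reflectance <= 0)) {
    warning("spectrum has no peak (all reflectance <= 0)")
    return(NA_real_)
  }
  s$wavelength_nm[which.max(s$reflectance)]
}

max_odd <- function(n) if (n %% 2 == 1) n else n - 1L

#' Full width at half maximum of a spectral band
#'
#' Width of the (smoothed) spectrum at half its peak height, with the
#' crossing positions located by linear interpolation between grid points.
#' If the spectrum never falls below half maximum on one side, the band
#' edge is used and the result is flagged as truncated.
#'
#' @inheritParams peak_wavelength
#' @return FWHM in nm with attribute `truncated` (logical); `NA` if the
#'   spectrum has no peak.
#' @export
spectrum_fwhm <- function(spectrum, smooth_window = 3) {
  if (nrow(spectrum) == 0L) stop("empty spectrum")
  s <- smooth_spectrum(spectrum, min(smooth_window, max_odd(nrow(spectrum))))
  r <- s$reflectance
  wl <- s$wavelength_nm
  if (all(r <= 0)) {
    warning("spectrum has no peak; FWHM undefined")
    return(structure(NA_real_, truncated = NA))
  }
  ip <- which.max(r)
  half <- r[ip] / 2
  truncated <- FALSE
  # walk left from the peak to the first crossing below half maximum
  left <- wl[1L]
  i <- ip
  while (i > 1L && r[i - 1L] >= half) i <- i - 1L
  if (i == 1L) truncated <- TRUE
  else left <- wl[i - 1L] + (half - r[i - 1L]) / (r[i] - r[i - 1L]) * (wl[i] - wl[i - 1L])
  right <- wl[length(wl)]
  i <- ip
  n <- length(r)
  while (i < n && r[i + 1L] >= half) i <- i + 1L
  if (i == n) truncated <- TRUE
  else right <- wl[i] + (half - r[i]) / (r[i + 1L] - r[i]) * (wl[i + 1L] - wl[i])
  structure(right - left, truncated = truncated)
}

#' CIE 1931 chromaticity of a reflectance spectrum
#'
#' Tristimulus integration of reflectance times illuminant against the
#' 1931 2-degree colour-matching functions ([cie_cmf()]), normalized to
#' x + y + z = 1. The default equal-energy illuminant reports the intrinsic
#' chromaticity of the reflectance itself; D65 is available for a daylight
#' viewing condition.
#'
#' @inheritParams smooth_spectrum
#' @param illuminant `"equal_energy"` (default) or `"D65"`.
#' @return A `"chromaticity_point"`: named numeric `c(x = , y = )`.
#' @examples
#' flat <- data.frame(wavelength_nm = 380:780, reflectance = 1)
#' cie_xy(flat)  # (1/3, 1/3)
#' @export
cie_xy <- function(spectrum, illuminant = c("equal_energy", "D65")) {
  illuminant <- match.arg(illuminant)
  wl <- spectrum$wavelength_nm
  keep <- wl >= 380 & wl <= 780
  if (!any(keep)) stop("spectrum does not overlap the 380-780 nm CMF support")
  wl <- wl[keep]
  refl <- spectrum$reflectance[keep]
  cmf <- cie_cmf(wl)
  power <- refl * illuminant_power(illuminant, wl)
  # trapezoidal quadrature handles non-uniform grids
  w <- trapz_weights(wl)
  XYZ <- as.numeric(crossprod(cmf, power * w))
  total <- sum(XYZ)
  if (total <= 0) stop("spectrum carries no power within the CMF support")
  structure(c(x = XYZ[1] / total, y = XYZ[2] / total),
            class = "chromaticity_point")
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  dx <- diff(x)
  c(dx[1] / 2, (dx[-(n - 1)] + dx[-1]) / 2, dx[n - 1] / 2)
}

#' @export
print.chromaticity_point <- function(x, ...) {
  cat(sprintf("CIE 1931 chromaticity (x, y) = (%.4f, %.4f)\n", x[["x"]], x[["y"]]))
  invisible(x)
}

#' Chromatic contrast between two spectra or chromaticity points
#'
#' Euclidean distance in the CIE 1931 (x, y) plane; used as the
#' stripe/interstripe colour-contrast metric.
#'
#' @param a,b `"chromaticity_point"` objects (from [cie_xy()]).
#' @return Non-negative distance (0 for identical points).
#' @export
chromaticity_contrast <- function(a, b) {
  sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
}

#' Spectral summary
#'
#' Peak wavelength, FWHM (with truncation flag) and CIE chromaticity of a
#' spectrum, as one record suitable for JSON export.
#'
#' @inheritParams cie_xy
#' @return List with `peak_nm`, `fwhm_nm`, `truncated_fwhm`, `cie_x`, `cie_y`.
#' @export
spectrum_summary <- function(spectrum, illuminant = "equal_energy") {
  pk <- suppressWarnings(peak_wavelength(spectrum))
  fw <- suppressWarnings(spectrum_fwhm(spectrum))
  xy <- cie_xy(spectrum, illuminant)
  list(peak_nm = pk,
       fwhm_nm = as.numeric(fw),
       truncated_fwhm = isTRUE(attr(fw, "truncated")),
       cie_x = xy[["x"]], cie_y = xy[["y"]])
}
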