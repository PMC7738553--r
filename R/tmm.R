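#' Characteristic matrix of a single dielectric layer
#'
#' The 2x2 complex matrix relating tangential field amplitudes across a
#' lossless layer of index `n` and thickness `d`:
#' `[[cos b, -(i/eta) sin b], [-i eta sin b, cos b]]` with phase thickness
#' `b = (2 pi / lambda) n d cos(theta)` and effective index `eta` equal to
#' `n cos(theta)` for s polarization and `n / cos(theta)` for p. At normal
#' incidence both reduce to `eta = n`. The matrix is unimodular
#' (determinant 1) for any real-index layer.
#'
#' @param n refractive index (>= 1).
#' @param d thickness, nm (>= 0; `d = 0` gives the identity).
#' @param wavelength vacuum wavelength, nm (> 0).
#' @param cos_theta cosine of the propagation angle inside the layer
#'   (1 at normal incidence).
#' @param polarization `"s"` or `"p"` (irrelevant at normal incidence).
#' @return A 2x2 complex matrix.
#' @examples
#' layer_matrix(1.83, 500 / (4 * 1.83), 500)  # quarter-wave guanine layer
#' @export
layer_matrix <- function(n, d, wavelength, cos_theta = 1,
                         polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  if (wavelength <= 0) stop("'wavelength' must be > 0")
  if (n < 1) stop("'n' must be >= 1")
  if (d < 0) stop("'d' must be >= 0")
  b <- 2 * pi * n * d * cos_theta / wavelength
  eta <- if (polarization == "s") n * cos_theta else n / cos_theta
  matrix(c(cos(b), -1i * eta * sin(b),
           -1i * sin(b) / eta, cos(b)),
         nrow = 2L)
}

# cos(theta_j) inside a layer of index n for ambient (n = 1) incidence angle
# theta0 (radians), by Snell's law.
snell_cos <- function(n, theta0) {
  s <- sin(theta0) / n
  sqrt(pmax(1 - s^2, 0))
}

#' Characteristic matrix of a whole layer stack
#'
#' Ordered product of [layer_matrix()] over every layer (top first), with
#' per-layer propagation angles obtained from Snell's law for light incident
#' from an ambient medium of index 1 at `angle` degrees. An empty stack
#' returns the identity matrix.
#'
#' @param stack a `"layer_stack"` data frame (see [layer_stack()]).
#' @param wavelength vacuum wavelength, nm.
#' @param angle angle of incidence in the ambient medium, degrees.
#' @param polarization `"s"` or `"p"`.
#' @return A 2x2 complex matrix (unimodular for lossless stacks).
#' @export
stack_matrix <- function(stack, wavelength, angle = 0,
                         polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  M <- diag(2) + 0i
  if (nrow(stack) == 0L) return(M)
  theta0 <- angle * pi / 180
  for (j in seq_len(nrow(stack))) {
    nj <- stack$refractive_index[j]
    ct <- snell_cos(nj, theta0)
    M <- M %*% layer_matrix(nj, stack$thickness_nm[j], wavelength, ct,
                            polarization)
  }
  M
}

#' Reflectance from a characteristic matrix
#'
#' The default convention evaluates the amplitude-modulus formula
#' `R = |((m11 + m12) - (m21 + m22)) / ((m11 + m12) + (m21 + m22))|`
#' with implicit unit-index ambient and exit media. The
#' `"standard_intensity"` convention returns the intensity reflectance
#' `|r|^2` of the textbook expression
#' `r = (eta_in (m11 + m12 eta_out) - (m21 + m22 eta_out)) /
#'      (eta_in (m11 + m12 eta_out) + (m21 + m22 eta_out))`
#' with configurable effective admittances of the bounding media. For
#' `eta_in = eta_out = 1` the two conventions differ only by the square.
#'
#' @param M 2x2 complex characteristic matrix.
#' @param convention `"amplitude"` (default, modulus of r) or
#'   `"standard_intensity"` (`|r|^2`).
#' @param eta_in,eta_out effective admittances of the incidence and exit
#'   media (both 1 by default).
#' @return Reflectance in `[0, 1]` for lossless stacks.
#' @examples
#' reflectivity(layer_matrix(1.83, 500 / (4 * 1.83), 500))  # 0.5401
#' @export
reflectivity <- function(M, convention = c("amplitude", "standard_intensity"),
                         eta_in = 1, eta_out = 1) {
  convention <- match.arg(convention)
  num <- eta_in * (M[1, 1] + M[1, 2] * eta_out) - (M[2, 1] + M[2, 2] * eta_out)
  den <- eta_in * (M[1, 1] + M[1, 2] * eta_out) + (M[2, 1] + M[2, 2] * eta_out)
  if (Mod(den) == 0) stop("zero denominator in reflectance (singular matrix)")
  r <- Mod(num / den)
  if (convention == "amplitude") r else r^2
}

# Vectorized-over-wavelength reflectance of one stack.
# Exploits the two-material structure: cos(theta) and eta are constant per
# material, so only the phase vectors vary per layer.
stack_reflectance_vec <- function(stack, wavelengths, angle = 0,
                                  polarization = "s",
                                  convention = "amplitude") {
  nw <- length(wavelengths)
  if (nrow(stack) == 0L) return(numeric(nw))
  theta0 <- angle * pi / 180
  ct0 <- cos(theta0)
  eta0 <- if (polarization == "s") ct0 else 1 / ct0
  # ambient admittance; at normal incidence eta0 = 1 and the amplitude
  # convention reproduces the unit-media formula verbatim
  m11 <- rep(1 + 0i, nw); m12 <- rep(0i, nw)
  m21 <- rep(0i, nw);     m22 <- rep(1 + 0i, nw)
  two_pi_over_lambda <- 2 * pi / wavelengths
  for (j in seq_len(nrow(stack))) {
    nj <- stack$refractive_index[j]
    ct <- snell_cos(nj, theta0)
    eta <- if (polarization == "s") nj * ct else nj / ct
    b <- (nj * ct * stack$thickness_nm[j]) * two_pi_over_lambda
    cb <- cos(b)
    sb <- sin(b)
    a12 <- -1i * sb / eta
    a21 <- -1i * eta * sb
    t11 <- m11 * cb + m12 * a21
    t12 <- m11 * a12 + m12 * cb
    t21 <- m21 * cb + m22 * a21
    t22 <- m21 * a12 + m22 * cb
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  num <- eta0 * (m11 + m12 * eta0) - (m21 + m22 * eta0)
  den <- eta0 * (m11 + m12 * eta0) + (m21 + m22 * eta0)
  r <- Mod(num / den)
  if (convention == "amplitude") r else r^2
}

new_spectrum <- function(wavelengths, reflectance, meta = list()) {
  out <- data.frame(wavelength_nm = wavelengths, reflectance = reflectance)
  class(out) <- c("irido_spectrum", "data.frame")
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

default_grid <- function() seq(380, 780, by = 1)

#' Reflectance spectrum of a fixed layer stack
#'
#' Sweeps the characteristic-matrix reflectance of one stack over a
#' wavelength grid. Unpolarized reflectance is the mean of the s and p
#' results (identical at normal incidence).
#'
#' @param stack a `"layer_stack"`.
#' @param wavelengths ascending wavelength grid, nm (default 380--780 at 1 nm).
#' @param angle angle of incidence, degrees.
#' @param polarization `"unpolarized"` (default), `"s"` or `"p"`.
#' @param convention reflectance convention, see [reflectivity()].
#' @return An `"irido_spectrum"` data frame (`wavelength_nm`, `reflectance`)
#'   with the run settings stored as attributes.
#' @examples
#' sp <- stack_spectrum(mean_stack(default_presets("ordered"), 25))
#' sp$wavelength_nm[which.max(sp$reflectance)]
#' @export
stack_spectrum <- function(stack, wavelengths = default_grid(), angle = 0,
                           polarization = c("unpolarized", "s", "p"),
                           convention = c("amplitude", "standard_intensity")) {
  polarization <- match.arg(polarization)
  convention <- match.arg(convention)
  check_grid(wavelengths)
  R <- if (polarization == "unpolarized") {
    (stack_reflectance_vec(stack, wavelengths, angle, "s", convention) +
       stack_reflectance_vec(stack, wavelengths, angle, "p", convention)) / 2
  } else {
    stack_reflectance_vec(stack, wavelengths, angle, polarization, convention)
  }
  new_spectrum(wavelengths, R,
               list(angle = angle, polarization = polarization,
                    convention = convention, n_runs = 1L))
}

check_grid <- function(wavelengths) {
  if (length(wavelengths) < 1L || any(wavelengths <= 0))
    stop("wavelength grid must be positive")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelength grid must be strictly ascending")
  invisible(TRUE)
}

#' Monte Carlo mean reflectance spectrum of a crystallotype
#'
#' Averages the reflectance spectra of `n_runs` independently sampled layer
#' stacks ([sample_stack()]), emulating cell-to-cell and layer-to-layer
#' variability in platelet thickness, spacing and layer count. The default
#' 500 runs reproduces the averaging used for the crystallotype spectra.
#'
#' @param preset a [crystallotype_preset()].
#' @param n_runs number of sampled stacks to average (>= 1).
#' @param wavelengths ascending wavelength grid, nm.
#' @param angle angle of incidence, degrees.
#' @param polarization,convention see [stack_spectrum()].
#' @param seed optional integer seed for reproducibility.
#' @return An `"irido_spectrum"` with metadata (`preset`, `n_runs`, `seed`,
#'   `angle`, `polarization`, `convention`).
#' @examples
#' sp <- monte_carlo_spectrum(default_presets("ordered"), n_runs = 50, seed = 1)
#' peak_wavelength(sp)
#' @export
monte_carlo_spectrum <- function(preset, n_runs = 500,
                                 wavelengths = default_grid(), angle = 0,
                                 polarization = c("unpolarized", "s", "p"),
                                 convention = c("amplitude", "standard_intensity"),
                                 seed = NULL) {
  polarization <- match.arg(polarization)
  convention <- match.arg(convention)
  if (!is.numeric(n_runs) || n_runs < 1) stop("'n_runs' must be >= 1")
  check_grid(wavelengths)
  n_runs <- as.integer(n_runs)
  with_seed_(seed, {
    acc <- numeric(length(wavelengths))
    for (r in seq_len(n_runs)) {
      stk <- sample_stack(preset)
      acc <- acc + if (polarization == "unpolarized") {
        (stack_reflectance_vec(stk, wavelengths, angle, "s", convention) +
           stack_reflectance_vec(stk, wavelengths, angle, "p", convention)) / 2
      } else {
        stack_reflectance_vec(stk, wavelengths, angle, polarization, convention)
      }
    }
    new_spectrum(wavelengths, acc / n_runs,
                 list(preset = preset$name, n_runs = n_runs, seed = seed,
                      angle = angle, polarization = polarization,
                      convention = convention))
  })
}

#' Angle-of-incidence scan of the Monte Carlo spectrum
#'
#' Computes the Monte Carlo mean spectrum at each requested angle using the
#' same set of sampled stacks at every angle (common random numbers), so
#' angle-to-angle differences reflect geometry rather than sampling noise.
#' Unpolarized reflectance is the s/p mean.
#'
#' @inheritParams monte_carlo_spectrum
#' @param angles angles of incidence in degrees, each within `[0, 70]`.
#' @return Named list of `"irido_spectrum"` objects, one per angle.
#' @export
angular_scan <- function(preset, angles, n_runs = 500,
                         wavelengths = default_grid(),
                         polarization = c("unpolarized", "s", "p"),
                         convention = c("amplitude", "standard_intensity"),
                         seed = NULL) {
  polarization <- match.arg(polarization)
  convention <- match.arg(convention)
  if (any(angles < 0 | angles > 70))
    stop("angles must lie within [0, 70] degrees")
  check_grid(wavelengths)
  n_runs <- as.integer(n_runs)
  stacks <- with_seed_(seed, lapply(seq_len(n_runs), function(i) sample_stack(preset)))
  out <- lapply(angles, function(a) {
    acc <- numeric(length(wavelengths))
    for (stk in stacks) {
      acc <- acc + if (polarization == "unpolarized") {
        (stack_reflectance_vec(stk, wavelengths, a, "s", convention) +
           stack_reflectance_vec(stk, wavelengths, a, "p", convention)) / 2
      } else {
        stack_reflectance_vec(stk, wavelengths, a, polarization, convention)
      }
    }
    new_spectrum(wavelengths, acc / n_runs,
                 list(preset = preset$name, n_runs = n_runs, seed = seed,
                      angle = a, polarization = polarization,
                      convention = convention))
  })
  names(out) <- paste0("angle_", angles)
  out
}

#' @export
print.irido_spectrum <- function(x, ...) {
  cat(sprintf("Reflectance spectrum: %d points, %g-%g nm", nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  if (!is.null(attr(x, "preset")))
    cat(sprintf(" [%s, %d runs, %g deg]", attr(x, "preset"),
                attr(x, "n_runs"), attr(x, "angle")))
  cat("\n")
  pk <- peak_wavelength(x)
  if (!is.na(pk))
    cat(sprintf("  peak %g nm (R = %.3f)\n", pk,
                max(smooth_spectrum(x)$reflectance)))
  invisible(x)
}

#' @export
summary.irido_spectrum <- function(object, ...) {
  spectrum_summary(object)
}

#' @export
plot.irido_spectrum <- function(x, ..., col = "black") {
  graphics::plot(x$wavelength_nm, x$reflectance, type = "l", col = col,
                 xlab = "wavelength (nm)", ylab = "reflectance",
                 ylim = c(0, max(1, x$reflectance)), ...)
  pk <- peak_wavelength(x)
  if (!is.na(pk)) graphics::abline(v = pk, lty = 3, col = "grey50")
  invisible(x)
}
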