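# Shared fixtures for the suite. Everything is generated in code.

# spectrum data frame on an integer grid
make_spectrum <- function(wl, r) data.frame(wavelength_nm = wl, reflectance = r)

# Gaussian band of amplitude 1
gaussian_spectrum <- function(center, sigma, wl = 380:780) {
  make_spectrum(wl, exp(-(wl - center)^2 / (2 * sigma^2)))
}

# zero-variance preset: every stack identical with L crystal layers
degenerate_preset <- function(L = 25, d_cry = 27, d_cyt = 131) {
  crystallotype_preset("degenerate", d_cry, 0, d_cyt, 0, L, L)
}

# complex 2x2 determinant (base det() refuses complex matrices)
cdet <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]

# random physical stack for property loops
random_stack <- function(L = 8, n1 = 1.83, n2 = 1.33) {
  layer_stack(stats::runif(L, 10, 120), stats::runif(L - 1, 20, 300), n1, n2)
}
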