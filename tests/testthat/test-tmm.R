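test_that("single-layer characteristic matrices match hand evaluations", {
  # zero thickness: identity
  expect_equal(layer_matrix(1.5, 0, 500), diag(2) + 0i)
  # quarter-wave guanine layer at 500 nm: [[0, -i/n], [-i n, 0]]
  n <- 1.83
  M <- layer_matrix(n, 500 / (4 * n), 500)
  expect_equal(M, matrix(c(0, -1i * n, -1i / n, 0), 2), tolerance = 1e-12)
  # half-wave layer: -identity, and inserting it anywhere leaves R unchanged
  H <- layer_matrix(1.33, 500 / (2 * 1.33), 500)
  expect_equal(H, -diag(2) + 0i, tolerance = 1e-12)
  Mb <- stack_matrix(layer_stack(c(27, 27), 131), 500)
  expect_equal(reflectivity(Mb %*% H), reflectivity(Mb), tolerance = 1e-12)
  expect_error(layer_matrix(1.5, 10, -1), "wavelength")
})

test_that("every layer and stack matrix is unimodular to 1e-9", {
  set.seed(8)
  for (i in 1:25) {
    wl <- runif(1, 380, 780)
    ang <- runif(1, 0, 70)
    pol <- sample(c("s", "p"), 1)
    n <- runif(1, 1, 2.5)
    ct <- sqrt(1 - (sin(ang * pi / 180) / n)^2)
    expect_lt(Mod(cdet(layer_matrix(n, runif(1, 0, 300), wl, ct, pol)) - 1), 1e-9)
    expect_lt(Mod(cdet(stack_matrix(random_stack(), wl, ang, pol)) - 1), 1e-9)
  }
})

test_that("stack matrix composes layer matrices in order", {
  one <- layer_stack(50)
  expect_equal(stack_matrix(one, 500), layer_matrix(1.83, 50, 500))
  # empty stack: identity matrix and zero reflectance
  empty <- layer_stack(numeric(0))
  expect_equal(stack_matrix(empty, 500), diag(2) + 0i)
  expect_equal(reflectivity(stack_matrix(empty, 500)), 0)
  # a layer times its phase-conjugate (beta -> -beta) is the identity
  M <- layer_matrix(1.5, 80, 500)
  Minv <- matrix(c(M[1, 1], -M[2, 1], -M[1, 2], M[2, 2]), 2)
  expect_equal(M %*% Minv, diag(2) + 0i, tolerance = 1e-12)
})

test_that("k-pair quarter-wave Bragg stack matches its closed form to 1e-8", {
  n1 <- 1.83; n2 <- 1.33; wl0 <- 550; k <- 5
  d1 <- wl0 / (4 * n1); d2 <- wl0 / (4 * n2)
  # k full double layers (crystal-first), plus a trailing crystal layer with
  # a closing cytoplasm quarter-wave so the pairing is exact: build 2k layers
  stk <- layer_stack(rep(d1, k + 1), rep(d2, k), n1, n2)
  # drop the final crystal row to leave exactly k (crystal, cytoplasm) pairs
  stk2k <- stk[-nrow(stk), , drop = FALSE]
  M <- stack_matrix(stk2k, wl0)
  a <- (n2 / n1)^k
  closed <- matrix(c((-n2 / n1)^k, 0, 0, (-n1 / n2)^k), 2) + 0i
  expect_equal(M, closed, tolerance = 1e-8)
  expect_equal(reflectivity(M), (1 - a^2) / (1 + a^2), tolerance = 1e-8)
})

test_that("reflectance conventions agree on the quarter-wave benchmark", {
  n <- 1.83
  M <- layer_matrix(n, 500 / (4 * n), 500)
  r_amp <- reflectivity(M)
  expect_equal(r_amp, (n^2 - 1) / (n^2 + 1), tolerance = 1e-9)
  expect_equal(reflectivity(M, "standard_intensity"), r_amp^2, tolerance = 1e-12)
})

test_that("reflectance is bounded in [0, 1] for lossless stacks", {
  set.seed(12)
  for (i in 1:20) {
    stk <- random_stack(L = sample(2:12, 1))
    wl <- runif(1, 380, 780)
    ang <- runif(1, 0, 70)
    for (conv in c("amplitude", "standard_intensity")) {
      for (pol in c("s", "p")) {
        ct0 <- cos(ang * pi / 180)
        eta0 <- if (pol == "s") ct0 else 1 / ct0
        R <- reflectivity(stack_matrix(stk, wl, ang, pol), conv, eta0, eta0)
        expect_gte(R, 0)
        expect_lte(R, 1 + 1e-12)
      }
    }
  }
})

test_that("deterministic ordered-stack spectrum peaks at the quarter-wave prediction", {
  sp <- stack_spectrum(mean_stack(default_presets("ordered"), 25))
  expect_lt(abs(peak_wavelength(sp) - quarter_wave_peak(27, 131)), 5)
  # empty stack: all-zero spectrum
  sp0 <- stack_spectrum(layer_stack(numeric(0)))
  expect_true(all(sp0$reflectance == 0))
})

test_that("spectrum is invariant under reversing a symmetric stack", {
  stk <- layer_stack(c(27, 30, 27), c(131, 131))
  rev_stk <- stk[rev(seq_len(nrow(stk))), , drop = FALSE]
  expect_equal(stack_spectrum(rev_stk)$reflectance,
               stack_spectrum(stk)$reflectance, tolerance = 1e-12)
})

test_that("Monte Carlo spectrum is seeded, degenerate-consistent and stable", {
  pre <- default_presets("ordered")
  grid <- seq(380, 780, by = 2)
  s1 <- monte_carlo_spectrum(pre, n_runs = 25, wavelengths = grid, seed = 3)
  s2 <- monte_carlo_spectrum(pre, n_runs = 25, wavelengths = grid, seed = 3)
  expect_identical(s1$reflectance, s2$reflectance)
  # zero-variance preset: MC mean equals the deterministic spectrum exactly
  dp <- degenerate_preset(25)
  mc <- monte_carlo_spectrum(dp, n_runs = 4, wavelengths = grid, seed = 1)
  det_sp <- stack_spectrum(mean_stack(dp, 25), wavelengths = grid)
  expect_equal(mc$reflectance, det_sp$reflectance, tolerance = 1e-12)
  mc1 <- monte_carlo_spectrum(dp, n_runs = 1, wavelengths = grid, seed = 9)
  expect_equal(mc1$reflectance, det_sp$reflectance, tolerance = 1e-12)
  # doubling the run count at the same seed moves the peak < 5 nm
  p500 <- peak_wavelength(monte_carlo_spectrum(pre, 500, seed = 2))
  p1000 <- peak_wavelength(monte_carlo_spectrum(pre, 1000, seed = 2))
  expect_lt(abs(p1000 - p500), 5)
})

test_that("angle scan blue-shifts the ordered peak and validates its inputs", {
  pre <- default_presets("ordered")
  expect_error(angular_scan(pre, c(0, 80), n_runs = 2), "\\[0, 70\\]")
  grid <- seq(380, 780, by = 2)
  sc <- angular_scan(pre, c(0, 15, 30, 45, 60), n_runs = 60,
                     wavelengths = grid, seed = 6)
  peaks <- vapply(sc, peak_wavelength, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # 0 degree scan result identical to monte_carlo_spectrum at the same seed
  mc <- monte_carlo_spectrum(pre, n_runs = 60, wavelengths = grid, seed = 6)
  expect_equal(sc[["angle_0"]]$reflectance, mc$reflectance, tolerance = 1e-12)
  # analytic oracle: Bragg peak 2(n1 d1 cos t1 + n2 d2 cos t2) decreases in angle
  bragg <- function(a) {
    t1 <- asin(sin(a * pi / 180) / 1.83); t2 <- asin(sin(a * pi / 180) / 1.33)
    2 * (1.83 * 27 * cos(t1) + 1.33 * 131 * cos(t2))
  }
  expect_true(all(diff(vapply(c(0, 15, 30, 45, 60), bragg, numeric(1))) < 0))
})
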