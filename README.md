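# iridoptics

Monte Carlo transfer-matrix optics and behavioural statistics for zebrafish
iridophore crystallotypes.

Adult zebrafish stripes and interstripes owe much of their colour to
iridophores — pigment cells that reflect light from stacks of guanine
reflecting platelets rather than absorbing it. The two iridophore subtypes
differ in platelet architecture: stripe iridophores carry highly **ordered**
stacks (20–30 parallel crystals of 27 ± 7 nm separated by 131 ± 24 nm of
cytoplasm) while interstripe iridophores carry **disordered** arrays
(30–40 crystals of 25 ± 8 nm with widely varying 186 ± 81 nm spacings).
`iridoptics` models the optical and statistical consequences of that
difference:

- **Transfer-matrix reflectance.** Each layer *j* (index *n<sub>j</sub>*,
  thickness *d<sub>j</sub>*) is represented by the characteristic matrix

  ```
  m_j = [ cos(b_j)          -(i/n_j) sin(b_j) ]      b_j = (2*pi/lambda) n_j d_j
        [ -i n_j sin(b_j)    cos(b_j)         ]
  ```

  the stack matrix is the ordered product `M = prod_j m_j`, and reflectance
  follows `R = |((m11 + m12) - (m21 + m22)) / ((m11 + m12) + (m21 + m22))|`
  (an `|r|^2` intensity convention with configurable bounding media is
  available behind a flag). Oblique incidence up to 70° uses Snell
  refraction with s/p-averaged polarization.
- **Monte Carlo averaging.** Spectra are means over 500 stacks whose layer
  counts and thicknesses are drawn from the crystallotype's measured
  distributions — disorder enters purely through those distributions.
- **Colorimetry.** Peak wavelength (after 3-point running-average
  smoothing), FWHM, CIE 1931 chromaticity, and a stripe/interstripe
  chromatic contrast metric.
- **Norepinephrine (NE) response.** A calibrated spacing-dilation model:
  NE multiplies the ordered type's cytoplasm spacing by 1.35 (disordered
  iridophores are refractory), red-shifting the ordered peak from ~450 to
  ~570 nm, consistent with the analytic quarter-wave relation
  `lambda = 2 (n1 d1 + n2 d2)`.
- **Cell dynamics.** Seeded synthetic time-lapse tracks plus axial
  (doubled-angle) division-plane statistics with a Rayleigh uniformity
  test, migration-bias reports with bootstrap CIs, and per-class
  proliferation rates with exact Poisson intervals.

## Worked example

```r
library(iridoptics)

sp <- monte_carlo_spectrum(default_presets("ordered"), n_runs = 500, seed = 1)
sp
#> Reflectance spectrum: 401 points, 380-780 nm [ordered, 500 runs, 0 deg]
#>   peak 453 nm (R = 0.959)
```

The ordered (stripe) crystallotype reflects a near-unity blue peak close to
the quarter-wave prediction `quarter_wave_peak(27, 131)` = 447.3 nm.

```r
ne_response(n_runs = 500, seed = 1)
#> Norepinephrine response report
#>   ordered    peak 451 -> 575 nm (shift +124 nm)
#>   disordered peak 380 -> 380 nm (shift +0 nm)
#>   chromatic contrast: 0.0737 -> 0.0468
```

NE shifts only the ordered type (~120 nm red-shift to the yellow-green) and
the chromatic contrast between the two cell types collapses — the optical
signature of the fading stripe pattern.

```r
summarize_morphometry(
  sample_morphometry(3.9, 0.4, 1.9, 0.2, n = 60, crystallotype = "stripe", seed = 1),
  sample_morphometry(5.3, 0.9, 2.5, 0.3, n = 57, crystallotype = "interstripe", seed = 2))
#> Morphometry comparison (aspect ratio rank-sum test)
#>   a (stripe, n=60): length 3.94 +/- 0.04 um, AR 1.92 +/- 0.02
#>   b (interstripe, n=57): length 5.33 +/- 0.14 um, AR 2.50 +/- 0.05
#>   p = 3.191e-16
```

Synthetic crystal morphometry reproduces the measured group means and the
decisive aspect-ratio separation between crystallotypes.

## Command line

```sh
Rscript inst/cli/irido.R simulate-spectrum --preset ordered --runs 500 --seed 1 --out spectrum.csv
Rscript inst/cli/irido.R ne-response --runs 500 --seed 1 --out ne_report.json
Rscript inst/cli/irido.R generate-tracks --dense 50 --loose 50 --seed 1
Rscript inst/cli/irido.R analyze-tracks tracks.csv divisions.csv --class loose --out report.json
Rscript inst/cli/irido.R run-all --seed 1 --out outdir
```

Every run writes a manifest (seed, config snapshot, output MD5s) so any
output can be regenerated exactly.

See `vignettes/iridophore-optics.Rmd` for the full model description,
parameter choices and limitations.
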