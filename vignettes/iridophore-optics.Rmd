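---
title: "Modelling iridophore structural colour: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling iridophore structural colour: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iridoptics)
```

# The physical model

Iridophores colour the zebrafish skin by thin-film interference on stacks of
guanine reflecting platelets. `iridoptics` treats a platelet stack as a
one-dimensional multilayer of alternating guanine crystal and cytoplasm.
Each layer $j$ with refractive index $n_j$ and thickness $d_j$ contributes
the characteristic matrix

$$
m_j \;=\;
\begin{pmatrix}
\cos\beta_j & -\tfrac{i}{\eta_j}\sin\beta_j\\[2pt]
-i\,\eta_j\sin\beta_j & \cos\beta_j
\end{pmatrix},
\qquad
\beta_j = \frac{2\pi}{\lambda}\, n_j d_j \cos\theta_j ,
$$

where $\eta_j = n_j\cos\theta_j$ (s polarization) or $n_j/\cos\theta_j$
(p polarization) and $\theta_j$ follows from Snell's law for light arriving
from an ambient medium of index 1. At normal incidence $\eta_j = n_j$. The
stack matrix is the ordered product $M = \prod_j m_j$ and the default
reflectance readout is the amplitude modulus

$$
R \;=\;
\left|\frac{(m_{11}+m_{12}) - (m_{21}+m_{22})}
           {(m_{11}+m_{12}) + (m_{21}+m_{22})}\right| ,
$$

i.e. $|r|$ with implicit unit-index bounding media. A conventional
intensity readout $|r|^2$ with configurable admittances of the bounding
media is available via `reflectivity(..., convention =
"standard_intensity")`. Peak positions — the quantities all downstream
summaries key on — are identical under the two conventions, so the choice
affects only the height and width of the bands. Which convention (and which
exit medium) underlies any particular published spectrum is rarely stated;
providing both, with the amplitude form as the default, keeps the package's
outputs directly comparable to either.

Assumptions inherited by every simulation:

- **Lossless, isotropic, non-dispersive layers.** Guanine is kept at
  $n = 1.83$ and cytoplasm at $n = 1.33$ across the whole band; absorption
  and the birefringence of crystalline guanine are ignored.
- **Parallel interfaces.** Orientational disorder of platelets is *not*
  modelled; disorder enters only through the thickness and spacing
  distributions. This mirrors how the disordered crystallotype differs from
  the ordered one in the underlying measurements (spacing spread 81 nm vs
  24 nm), and it means the model will understate angular diffusion caused by
  platelet tilt.
- **Incoherent averaging across cells.** A measured spectrum integrates
  many stacks; the model averages reflectance (not field amplitudes) over
  independently sampled stacks.

## Monte Carlo stack sampling

`sample_stack()` draws the number of crystal layers uniformly from the
preset's integer range and every thickness from the preset's normal
distribution, rejection-resampled below a hard floor of 5 nm (a thinner
layer is physically implausible and numerically irrelevant). Stacks begin
and end with a crystal layer — with $L$ crystals there are $L-1$ spacings —
because the platelet membrane, not cytoplasm, bounds the organelle. For the
ordered cytoplasm distribution the floor truncates a negligible fraction of
draws; for the broad disordered distribution (186 ± 81 nm) it affects
roughly 1–2 % of draws and biases the realized mean upward by well under one
standard error at the sample sizes used anywhere in the package; the test
suite bounds this bias with a numerical-integration oracle.

`monte_carlo_spectrum()` averages 500 sampled stacks by default. At that
run count the smoothed-peak readout for the ordered preset has a
seed-to-seed standard deviation of a few nanometres, comfortably inside the
±15 nm window used for the blue-peak check. `angular_scan()` evaluates the
*same* sampled stacks at every requested angle (common random numbers), so
angular trends are not confounded with sampling noise; this is why the
monotone blue-shift of the ordered peak is stable even at reduced run
counts.

## Built-in crystallotype presets

| parameter | ordered (stripe) | disordered (interstripe) | units |
|---|---|---|---|
| crystal thickness | 27 ± 7 | 25 ± 8 | nm |
| cytoplasm spacing | 131 ± 24 | 186 ± 81 | nm |
| crystal layers | 20–30 | 30–40 | count |
| $n$ crystal / cytoplasm | 1.83 / 1.33 | 1.83 / 1.33 | — |

The cytoplasm index is not part of the measured parameter set; 1.33
(aqueous cytoplasm) is the standard value in the structural-colour
literature and is configurable in every preset. The ideal-multilayer
quarter-wave relation $\lambda = 2(n_1 d_1 + n_2 d_2)$ puts the ordered
stack's first-order peak at $2(1.83\cdot 27 + 1.33\cdot 131) = 447.3$ nm —
the Monte Carlo mean spectrum peaks within a few nanometres of this.

# Colorimetry

All peak readouts first apply a centered 3-point running average
(`smooth_spectrum()`), the same smoothing convention used for measured
hyperspectral data; edge points average over the available neighbours so
wavelengths never change. Plateau maxima resolve to the shortest
wavelength — an arbitrary but fixed tie-break. An all-zero spectrum has no
peak and returns `NA` rather than a fabricated wavelength.

`cie_xy()` integrates reflectance × illuminant against the CIE 1931
2° colour-matching functions. The CMFs are computed from the published
multi-lobe piecewise-Gaussian analytic representation of the 1931 observer
(Wyman, Sloan & Shirley 2013, *JCGT*), renormalized to equal integrals over
380–780 nm. The renormalization restores a defining property of the true
observer — the equal-energy white maps to exactly (1/3, 1/3) — and the fit
is accurate to about 1 % of each function's peak, far inside the tolerances
of any chromaticity comparison the package makes. The default illuminant is
equal-energy (E) because the quantity of interest is the intrinsic
reflectance chromaticity of a cell, not its appearance under daylight; D65
(standard 10 nm table, interpolated) is available by flag. The
stripe/interstripe **contrast** metric is the Euclidean distance between
the two chromaticities in the (x, y) plane — deliberately simple, monotone
in any perceptual distance for the small excursions involved.

# The norepinephrine response model

NE leaves disordered-crystal (interstripe) iridophores refractory but
reorganizes ordered-crystal (stripe) iridophores, red-shifting their
reflectance peak from roughly 450 to roughly 570 nm. The package models
this as a multiplicative dilation of the cytoplasm-spacing distribution:

- `dilation_ordered = 1.35` (default). The post-NE spacing is not a
  measured quantity anywhere; 1.35 is **calibrated** from the quarter-wave
  inverse: a 570 nm peak with 27 nm crystals requires
  `invert_spacing_for_peak(570, 27)` = 177.1 nm of cytoplasm, and
  177.1/131.0 ≈ 1.35. It is labelled a model parameter throughout.
- `dilation_disordered = 1.0` encodes the observed refractoriness directly,
  rather than hypothesizing an optical insensitivity.
- SDs scale with the mean (constant coefficient of variation) — the
  simplest assumption; an absolute-SD alternative can be had by building a
  preset explicitly and passing it to `monte_carlo_spectrum()`.
- Crystal thicknesses are untouched: guanine crystals are rigid; only the
  cytoplasmic gaps can plausibly change on physiological timescales.
  Whether NE also tilts platelets is unresolved; tilt is outside this
  model.

`ne_response()` reuses one random-number stream per crystallotype for the
pre- and post-NE simulations, so a null model (`ne_model(1, 1)`) yields
*exactly* zero shift rather than Monte Carlo noise, and the reported shifts
are paired comparisons with reduced variance.

# Cell-behaviour statistics

The track generator (`generate_tracks()`) emulates 15 h time-lapse movies
sampled every 5 min: dense (interstripe) cells as low-jitter stationary
walkers whose division planes concentrate on the anterior–posterior axis
(von Mises in doubled-angle space, default κ = 4), loose (stripe) cells as
random walks with an optional ventral drift and uniformly oriented division
planes, and Poisson division events with class-specific rates (defaults
0.005 and 0.01 per cell-hour — order-of-magnitude realistic for these cells
and preserving the loose > dense ordering). Defaults for jitter (0.3 / 2 µm
per frame) and drift (−0.5 µm per frame) were fixed once as plausible
magnitudes; every analysis function re-estimates them from data, so their
exact values only set the difficulty of the recovery tests.

Division-plane angles are **axial** (defined modulo 180°), so
`division_angle_stats()` doubles them before computing the mean direction
and resultant length, then halves the mean back. Uniformity is assessed
with the Rayleigh test (small-sample corrected p-value); no circular
statistics package ships in the dependency set, so both the test and the
Best–Fisher von Mises sampler are implemented here and calibrated by Monte
Carlo (type-I error 5 ± 1.5 % at n = 100 over 2000 replicates in the test
suite). `migration_bias()` uses a configurable qualification threshold of
20 µm (one nominal cell diameter; the true diameter is not pinned down) and
a percentile bootstrap for the dorso-ventral drift CI — note the threshold
conditions on displacement magnitude and therefore biases drift estimates;
parameter-recovery checks set it to zero. `proliferation_rates()` uses
exact Poisson intervals and an exact two-sample rate-ratio test
(`stats::poisson.test`), with observation time defined as each track's
timestamp span so that splitting a track into contiguous pieces changes
nothing.

# Numerical choices and degenerate inputs

- Unimodularity of every characteristic matrix is maintained to well below
  1e−9; it is asserted, not renormalized.
- A zero-thickness layer is the identity matrix; an empty stack returns the
  identity and reflectance 0 by convention (documented rather than an
  error, because Monte Carlo presets with a degenerate layer range can
  produce it deliberately).
- Zero-variance presets short-circuit nothing: the sampler returns the
  exact mean stack, so `monte_carlo_spectrum()` on a degenerate preset
  equals the deterministic spectrum bit-for-bit — a useful end-to-end
  identity that the tests exploit.
- FWHM uses linear interpolation between grid points; a band still above
  half maximum at a grid edge reports the edge and sets a `truncated` flag
  instead of silently returning a plausible-looking width. The broad,
  near-unity disordered and ordered bands do trip this flag on the default
  380–780 nm window — the flag is information, not an error.
- The rank-sum comparison enumerates the exact permutation distribution for
  tiny samples (≤ 12 observations combined), where the normal approximation
  with tie correction is badly wrong, and uses `stats::wilcox.test`
  otherwise.
- Seeds: every sampling function takes an explicit seed and restores the
  RNG state afterwards (`withr::with_seed`); `derive_seed()` maps a single
  pipeline seed to fixed per-stage seeds below $2^{31}$.

# Problem sizes used by the test suite

Full-size simulations (500 runs, 1 nm grid) back the headline checks: the
ordered blue peak, the NE shift, and their acceptance-script counterparts.
Property suites that need many replicates scale down to keep the whole
suite fast while leaving the tested signs and calibrations unambiguous:
sign comparisons (ordered vs disordered FWHM; angular peak range) use 100
seeds at 30–60 runs on 2–4 nm grids, Rayleigh calibration uses 2000
replicates of n = 100, and parameter recovery uses 1000 cells per class.
These sizes are the package's own trade-off between statistical resolution
and turnaround; all of them can be rerun at larger n by changing the
corresponding arguments.

# What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analyses consume:
normal thickness/spacing distributions, uniform layer counts, truncation
floors, von Mises or uniform division angles, Poisson divisions, Gaussian
jitter walks. They do not emulate optical measurement noise, platelet tilt,
spatial correlation between neighbouring layers, cell–cell interactions,
stage-dependent behaviour, or segmentation/tracking artefacts. Green tests
therefore certify the pipeline's internal correctness and calibration on
data matching its assumptions — not the fidelity of those assumptions to
any particular imaging experiment.

# Known limitations

- The amplitude-modulus reflectance convention saturates near 1 for strong
  stacks; FWHM comparisons between conventions are not interchangeable.
- No second-order Bragg peaks are ever inside the 380–780 nm window for
  these presets, but for much thicker stacks the single-peak summaries
  (`peak_wavelength`, `spectrum_fwhm`) would need care.
- The NE model is a statics model: no kinetics, no pigment-granule
  aggregation in neighbouring cell types, spacing-only reorganization.
- Chromaticity uses an analytic CMF representation (≈1 % of peak accuracy),
  adequate for contrast and peak-colour readouts, not for colorimetric
  standards work.
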