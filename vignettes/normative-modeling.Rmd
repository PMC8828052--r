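---
title: "Warped Bayesian normative models for regional brain measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warped Bayesian normative models for regional brain measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuronorm)
```

## The problem

Reference ("growth chart") models for brain structure regress a regional
measure — cortical thickness, subcortical volume — on age, sex and scan site
in a large healthy cohort, and then score individuals by how far they fall
from the prediction. The scientific payoff is individual-level inference:
instead of asking whether a diagnostic group differs on average, one asks
which regions of *this* person are outside the reference range, and how
clinical groups distribute their extremes across the brain.

Three features of real multi-site lifespan data drive the design:

* age effects are strongly nonlinear over ages 2–100;
* residuals are skewed and non-Gaussian, so Gaussian centiles miscover;
* pooled MRI data carry large per-scanner offsets and scale differences.

## Model

Per ROI, the response is centred and scaled by its training mean/SD and
mapped through the sinh-arcsinh (SHASH) warp
$z = W(y) = \sinh(b\,\mathrm{asinh}(y) - a)$, the Jones–Pewsey form in which
$a$ controls skew, $b > 0$ tailweight, and $(a,b) = (0,1)$ is the exact
identity. In the latent space a conjugate Bayesian linear regression applies,

$$z = w^\top\phi(x) + \varepsilon,\qquad
  \varepsilon \sim \mathcal N(0, 1/\beta),\qquad
  w \sim \mathcal N(0, \alpha^{-1} I),$$

with design $\phi(x)$ = intercept, clamped cubic B-spline basis of age with
five evenly spaced knots over the training range (boundary knots among the
five, replicated to degree for the basis), a 0/1 sex column (sex effects are
modelled as a global offset; a sensitivity option fits the sexes separately),
and treatment-coded site dummies against the first training site.

Hyperparameters $(\log\alpha, \log\beta, a, \log b)$ minimise the negative
log marginal likelihood of the warped model — the Gaussian evidence of the
latent regression minus the summed warp log-Jacobian
$\log b + \log\cosh(b\,\mathrm{asinh}(y)-a) - \tfrac12\log(1+y^2)$ — jointly
by bounded L-BFGS with analytic gradients. Positivity of $\beta,\alpha,b$ is
enforced by the log parameterisation; warp and regression hyperparameters are
optimised jointly rather than profiled, which keeps the objective smooth and
lets curvature trade off between the spline and the warp.

Deviation scores for new subjects are computed where the model's Gaussian
assumptions hold — in the latent space:

$$Z = \frac{W(y_{\text{std}}) - \hat\mu}
           {\sqrt{\sigma^2 + \sigma_*^2}},\qquad
  \sigma^2 = 1/\beta,\quad \sigma_*^2 = \phi^\top\Sigma\,\phi .$$

Under the model $Z \sim \mathcal N(0,1)$, so strict $|Z| > 2$ defines extreme
deviations and centile curves follow by pushing normal quantiles back through
$W^{-1}$ and the training de-standardisation. The median curve equals the
point prediction: the predictive *median* is used in measurement space
because the predictive mean has no closed form under SHASH. Centile variance
uses the total $\sigma^2 + \sigma_*^2$ (consistent with the Z denominator); a
`total_variance = FALSE` switch gives noise-only bands.

## Design choices that were genuinely open

* **Knot reading.** "Five evenly spaced knots" is read as five knots spanning
  the observed training range, boundaries included. The knots are serialized
  with the model, so the convention is explicit and reproducible at
  prediction time.
* **Intercept vs. partition of unity.** The complete clamped basis sums to
  one, so the intercept is linearly dependent on the spline block. The
  explicit intercept is kept anyway: the Gaussian prior on $w$ makes the
  posterior proper, the fit well-conditioned, and site/sex coefficients
  identifiable; this mirrors how the field's reference implementations build
  the design.
* **Out-of-range ages are clamped** to the training boundary with a warning,
  never extrapolated: cubic-spline extrapolation is unstable exactly where
  reference data are thinnest (very young and very old ages).
* **Warp form.** The minimal two-parameter SHASH warp, with no affine
  pre/post-composition — location and scale are carried by response
  standardization and the regression itself, keeping $(a,b)$ identifiable.
* **Evaluation space.** Explained variance is computed in measurement units
  with the predictive median (the latent-space alternative is available but
  not the default); MSLL uses the global training mean/variance of the
  warped-standardized responses as its baseline, the standard definition.
* **Transfer estimator.** The adjustment for an unseen site is moment
  matching of latent residuals against the zero-dummy baseline: offset
  $\mu_s = \overline{r}$ and scale
  $s_s = \mathrm{SD}(r)/\sqrt{\sigma^2 + \overline{\sigma_*^2}}$, chosen for
  its closed form and testability. Below 25 calibration subjects the variance
  ratio is too unstable and the scale is fixed at 1 (offset-only), with a
  warning; the threshold is configurable. Scoring stays in the latent space —
  equivalent under the monotone warp to adjusting and re-warping. A leakage
  guard refuses to score the calibration subjects themselves.
* **Resampling.** Test-set stability is assessed by resampling the *test*
  half against the fixed fitted models (10 replicates by default); a
  `refit = TRUE` option repeats the whole split+fit cycle instead.
* **QC.** The Euler characteristic is averaged over hemispheres and
  standardized per site with median and normalized IQR (robust by default —
  EC distributions are heavy-tailed; mean/SD available), then excluded only
  on the bad side at a conservative 5 robust-SD units. Sites with fewer than
  5 subjects fall back to pooled statistics and are flagged; a zero-spread
  site is flagged with everyone retained.
* **Clinical tests.** Welch's unequal-variance t-test per ROI (safer than
  pooled-variance under group variance differences), controls matched by
  site only, and BH-FDR applied per map (per group × input space), matching
  how such maps are reported.

## The synthetic cohort generator

The generator is the package's study population, not a test fixture. Each
ROI follows $f(\mathrm{age}) = c_0 + c_1 e^{-\mathrm{age}/\tau} + c_2\,
\mathrm{age}$ — a decaying-exponential childhood phase plus linear adult
decline, four interpretable parameters that reproduce the qualitative shapes
of lifespan thickness/volume trajectories. Noise is additive SHASH:
$y = f(\mathrm{age}) + \beta_{\mathrm{sex}}\,\mathrm{sex} + \delta_{\mathrm{site}}
+ s_{\mathrm{site}}\,\sigma_0\,W^{-1}(\epsilon;a,b)$.

Defaults (drawn reproducibly from the config seed) emulate a pooled
multi-site study at desk scale: 2,000 subjects over 10 unequally sized sites
(exponential size weights, minimum 20), ages uniform on 2–100, 16
thickness-like ROIs ($c_0 \sim$ 2.0–2.9 mm, thinning 2–8 µm/year in
adulthood, noise $\sigma_0 = 0.12$ mm) and 4 volume-like ROIs (3,500–8,000
mm³ with childhood growth and 6–18 mm³/year adult loss, noise scaled by a
per-ROI factor of 1,500–3,500 — the one extension to a single global noise
scale, needed because the cohort mixes mm and mm³ units), sex offsets of
0–0.05 mm (thickness) and 100–400 mm³ (volume), per-site mean offsets of
SD 0.5 noise units, per-site noise scales 0.8–1.25, and mildly non-Gaussian
noise $a = 0.1$, $b = 1.05$. Clinical groups apply a signed shift, expressed
in noise-SD units (converted through the SHASH noise SD by quadrature), to a
stated ROI subset for a stated prevalence of subjects — effects in clinical
cohorts are heterogeneous, so prevalence < 1 is the realistic default.
Euler characteristics are integers per hemisphere with per-site locations
(−150 to −20) and scales (15–40), and planted outliers at −10 per-site SDs.

One deliberate mismatch matters for interpretation: the generator adds SHASH
noise *outside* the warp, whereas the fitted model places the Gaussian noise
*inside* $W^{-1}$. The model class is therefore an approximation to the
generator (as it would be to real data). Consequently calibration, coverage
and exact parameter-recovery checks draw held-out data from the *fitted*
model class (`simulate_from_model()`), while generator-based fits are
checked for approximate recovery. Passing tests show the machinery is
correct and well-calibrated under its own assumptions and robust to this
mild misspecification; they cannot show that real cortical measures follow
either law.

## Numerical choices

* Optimiser: L-BFGS-B over box bounds $\log\alpha,\log\beta \in [-20,20]$,
  $a \in [-5,5]$, $\log b \in [-3,3]$ (the bounds keep every objective
  evaluation finite); gradient tolerance $10^{-5}$, at most 500 iterations,
  default start $(0,0,0,0)$ plus seeded random restarts, ties broken by
  first occurrence.
* A $10^{-8}$ diagonal jitter is added to the posterior precision on
  Cholesky failure and recorded in the fit report.
* $\log\cosh$ is evaluated as $|u| + \log(1+e^{-2|u|}) - \log 2$ to avoid
  overflow; the exact-identity warp parameter pair short-circuits to the
  identity map so that $(a,b)=(0,1)$ is exact to the bit.
* Model files are JSON with 17-significant-digit numerics, which round-trips
  IEEE doubles exactly: save → load → predict is bit-identical.
* All randomness flows from explicit integer seeds; derived sub-seeds are
  hashed into the 32-bit range.

## Problem sizes used by the tests and scripts

The test suite and the analysis scripts run the study at desk scale, chosen
as the smallest sizes at which the statistical checks have sensible power:
2,000 subjects × 20 ROIs × 10 sites for the end-to-end pipeline; n = 10,000
with 10 replicate fits for warp-parameter recovery; n = 20,000 model-class
draws for Z-calibration, tail-rate and centile-coverage checks; 100
calibration / 400 held-out subjects for site transfer; 4,000 subjects with
5% planted outliers for QC operating characteristics; a six-site N = 546
transfer set in the analysis scripts. Monte-Carlo assertions use fixed seeds
and 3-standard-error (or stated) bands.

## Limitations

* Site enters as a fixed mean effect; per-site noise scales in the generator
  are *not* modelled by the regression (no random effects, no per-site
  variance), so site heterogeneity inflates the single $\beta$ — visible as
  slightly conservative per-site calibration, and one reason the transfer
  stage re-estimates a variance scale.
* One model per ROI: no spatial pooling across regions.
* Cross-sectional only; repeated visits are out of scope.
* The QC rule is a reimplementation of the published idea (scale, centre,
  cut the tail) with its own configurable threshold, not a port of any
  specific heuristic.
* Synthetic cohorts cannot certify behaviour on real scanner data — they
  certify the statistics, given data of the assumed structure.
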