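---
title: "Models and methods behind trailuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trailuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trailuse analyses multi-array camera-trap surveys of large mammals along
gradients of outdoor recreation and land-use disturbance. This vignette
describes the statistical machinery: the detection-event conventions, the
two-level count model, the circular overlap analysis, the samplers, and the
synthetic-data generator used to validate all of it. It also records the
design decisions taken where the analysis admitted more than one reasonable
implementation.

## From photographs to detection events

Camera traps record bursts of photographs. Counting every frame would
conflate one animal lingering in front of a camera with many independent
visits, so consecutive photographs of the same group at the same station are
collapsed into one *independent detection event* whenever the gap to the
previous photograph is below an independence interval of 30 minutes.

Two conventions matter and both are pinned by tests:

* the gap is measured to the *previous photograph*, not to the event's first
  photograph (a sliding rule, the standard in camera-trap practice);
* a gap exactly equal to the interval starts a new event — "at least 30
  minutes apart" defines independence inclusively.

`filter_independent()` implements this rule; it is idempotent, monotone in
the interval, and exact against a brute-force quadratic oracle in the test
suite. Detection rates are events per 100 active camera days
(`detection_rate()`), which makes stations with unequal effort comparable.

Stations enter the seasonal (April–September) analysis by their local civil
date. When a station table with longitudes is available, local time is
approximated as UTC + longitude/15 hours; exact civil-timezone politics are
deliberately out of scope for a field dataset spanning two provinces.

A species is analysed only with at least 500 independent detections spread
over at least 5 arrays (`species_inclusion()`): multi-array inference is
meaningless for species effectively absent from most landscapes.

## Covariates

Continuous covariates (recreation rate, NDVI, camera days, detection
counts) are standardized to mean 0 and sample SD 1. Logging and road
density are dichotomized — high logging is a logged fraction ≥ 0.10 in a
500-m buffer, high road density ≥ 1 km/km² — because the underlying field
distributions are strongly bimodal and the binary coding aids MCMC
convergence. The inclusive "≥" convention at the threshold is a deliberate
choice (sources describing these cut points disagree between "≥" and ">");
it only matters for values exactly at the boundary.

Recreation × logging and recreation × road interactions are products of the
*standardized* recreation rate with the binary indicators. The
landscape-scale recreation covariate for array *j* is the mean of its
stations' local recreation rates, standardized *across arrays* — the natural
pooling when nothing finer is specified.

`correlation_screen()` reports Pearson r and p for every covariate pair and
flags |r| ≥ 0.6 with p < .05 for manual exclusion; in the bundled synthetic
data, percent forest cover is generated collinear with NDVI so the screen
has something real to catch.

## The two-level site-use model

Counts of independent detections per station are overdispersed, so the
response is negative binomial in its NB2 parameterization: mean μ, size r,
variance μ + μ²/r. ("Negative binomial" alone is ambiguous; NB2 is the
overdispersion-motivated form and the one count-regression software
defaults to.) For station *i* in array *j*:

$$y_i \sim \mathrm{NB2}(\exp(\eta_i),\ r), \qquad
\eta_i = \beta_1 \mathrm{rec}_i + \beta_2 \mathrm{logging}_i +
\beta_3 \mathrm{road}_i + \beta_4 \mathrm{days}_i + \beta_5 \mathrm{NDVI}_i +
\beta_6 \mathrm{rec{\times}logging}_i + \beta_7 \mathrm{rec{\times}road}_i +
\epsilon_{j(i)}$$

$$\epsilon_j \sim \mathrm{Normal}(\beta_8 \cdot \mathrm{rec}^{land}_j,\
\sigma_{array}^2)$$

The array random intercept is itself regressed on landscape-scale
recreation: β8 captures whether whole landscapes with more human activity
support more or less site use, over and above the station-level effect β1.

Three structural choices deserve comment:

* **No fixed intercept.** The model's linear predictor carries no global
  intercept; the array effects absorb the grand mean. Because the
  landscape covariate is centred, β8 — a through-origin regression slope of
  the array effects on centred recreation — remains estimable and unbiased.
  The cost is interpretive: a species' overall detectability loads onto the
  ε's, and σ_array then measures array spread *around the landscape trend*,
  not pure between-array noise.
* **A stochastic second level.** The landscape equation is written with a
  residual: ε_j is Normal around β8·rec_j with free SD σ_array. A degenerate
  (noise-free) random effect would not be a random effect, and would make
  the model singular.
* **Effort as a covariate, not an offset.** Camera days enter as a
  standardized fixed effect (β4). An offset would force a proportional
  effort–count relationship; estimating the effect instead is a fidelity
  choice to the field analysis this package reproduces, and the two differ
  empirically when detection saturates with effort.

Priors are deliberately flat: β ~ Uniform(−10, 10) (log-scale effects
beyond ±10 are biologically absurd for detection rates), σ_array ~
Uniform(0, 10), r ~ Uniform(0.01, 50). All are configurable in source; none
of the validation results are sensitive to widening them.

### Sampling and diagnostics

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
written in C++: each scalar parameter gets a Gaussian random-walk update
whose step size adapts toward ≈ 44% acceptance during burn-in only, so the
retained draws come from a fixed-kernel Markov chain. The NB likelihood is
evaluated with a lookup table over the unique counts, making one sweep
O(n + u) rather than O(n log n) in special-function calls.

Two MCMC profiles are bundled: the survey-scale profile (3 chains ×
100,000 iterations, burn-in 5,000, thinning 5 — thinning 3 for the overlap
model) and a reduced test profile (10,000 / 1,000 / 2) used throughout the
simulation studies, where posteriors are simple enough for short adaptive
chains to mix well. Convergence is monitored with the split-chain
Gelman–Rubin factor; fits with any R-hat above 1.1 are returned *flagged*
with a warning rather than silently. Chains start from dispersed random
initial values.

Evidence is classified from equal-tailed posterior intervals: a 95%
credible interval excluding zero is *strong* evidence for a covariate, an
80% interval excluding zero is *weak* evidence, anything else is *none*.
The sampler is validated three independent ways in the tests: its
likelihood against direct NB2 log-pmf summation (to 1e-8), its posterior
means against a maximum-likelihood NB regression when the truth has no
random effect (±0.1), and its full posterior against an independent Gibbs
sampler (JAGS) on a small instance.

## Diel activity and overlap

Detection timestamps are mapped to *sun-anchored time*: radians in
[0, 2π) with sunrise fixed at π/2 and sunset at 3π/2, daytime stretched
linearly between them and night-time between sunset and the next sunrise
(double anchoring). Single-anchor alternatives (shifting by sunrise only)
were rejected because they leave day length varying across latitude and
season, which is the very nuisance the transform exists to remove. Sunrise
and sunset come from the NOAA solar-position equations with the standard
refraction zenith of 90.833°; latitudes beyond ±66.5° are rejected because
polar day/night has no anchors.

Activity densities are estimated with a von Mises kernel:
$$\hat f(\theta) = \frac{1}{n}\sum_i
\mathrm{vM}(\theta;\ \mu = t_i,\ \kappa = \kappa_{kernel}),$$
where the kernel concentration follows the circular rule of thumb
$\kappa_{kernel} = [3 n \hat\kappa^2 I_2(2\hat\kappa) / (4 \sqrt{\pi}
I_1(\hat\kappa)^2)]^{2/5}$ with $\hat\kappa$ the ML concentration of the
sample. Samples with numerically zero concentration fall back to the
uniform density with a warning. Bessel ratios are computed with
exponentially scaled functions, so the estimator is stable at
concentrations where naive $I_k(\kappa)$ overflows.

Overlap between two samples is the Δ̂4 estimator:
$$\hat\Delta_4 = \tfrac12\Big[\tfrac{1}{n_1}\sum_i \min\{\hat g(x_i)/\hat
f(x_i), 1\} + \tfrac{1}{n_2}\sum_j \min\{\hat f(y_j)/\hat g(y_j), 1\}\Big]$$
which estimates ∫ min(f, g) and is the recommended form when both samples
are large. Stations contribute an overlap coefficient only with ≥ 25
detections of *both* groups (all seasons pooled); the package records
whether pooled totals reach the ≥ 75 guideline that justifies Δ̂4 over its
small-sample sibling. Δ̂4 is exactly 1 for identical samples, symmetric to
machine precision, and within 0.05 of a numerical-integration oracle across
a 3 × 3 grid of von Mises shapes at n = 2,000 — all asserted in tests.

Station-level overlap coefficients are then modelled with a Gaussian linear
mixed model: fixed effects for disturbance and detection-count covariates,
an array random intercept (mean zero — again no fixed intercept, with the
same absorption caveat), and flat priors as above. The response lives on
[0, 1] but is modelled on its natural scale with an input guard rather
than a logit link; that mirrors the field analysis being reproduced, and
for responses concentrated well inside the interval the approximation is
benign. Parameters are stored by name (`beta_road`, `beta_carnivore_rate`,
…), not by equation position, so the differing covariate sets of the two
model forms cannot collide.

## The synthetic-data generator

Every validation runs on data from `simulation_truth()` /
`simulate_dataset()`, which emulate the study conditions rather than any
convenient configuration:

* 10 arrays × 40 stations (400 stations) for spatial-model studies; 64
  stations in 6 arrays for overlap-model studies — the sizes of the real
  analyses these defaults mirror;
* log-normal local recreation rates, with the log-scale variance split
  evenly between an array-level and a station-level component so that
  landscape recreation genuinely varies between arrays;
* NB2 counts generated from exactly the two-level model above, with
  effect sizes for validation taken from reported field estimates
  (local recreation +0.72 elk-like and −0.49 moose-like, landscape +0.59,
  overlap road effect +0.13);
* diel times from group-specific von Mises mixtures: crepuscular deer
  (peaks at π/2 and 3π/2, κ = 2), diurnal recreation (peak π, κ = 3),
  nocturnal-leaning carnivores (peak 0, κ = 1.2).

Field estimates never report σ_array or r, so the generator's defaults
(σ_array = 0.5, dispersion r = 1) are conventions chosen to be realistic —
moderate array heterogeneity and strong overdispersion — not calibrations,
and the recovery studies hold under them.

Two honest simplifications: simulated event timestamps place the diel
radian directly as clock time-of-day (the solar transform then runs on
them as it would on real data, but the planted diel shape is defined in
clock time); and the generator emits independent events rather than photo
bursts, so the independence filter is validated on purpose-built photo
streams instead. The generator also takes an optional `baseline_log_rate`
(default 0): with no intercept anywhere, mean counts at the null would be
e⁰ = 1 per station, far too sparse for the ≥ 25-detection overlap stage, so
end-to-end demos raise the baseline. Because the landscape covariate is
centred this shifts the array effects wholesale without biasing any slope;
all parameter-recovery studies use baseline 0.

What passing these simulations does *not* show about real data: the
generator has no spatially explicit movement, no imperfect detection
(counts are site-use indices, not abundance), no multi-year trend, and its
covariates are independent by construction except where collinearity is
planted. Recovery under the generator validates the estimation machinery,
not the ecological model's adequacy for any particular landscape.

## Numerical and degenerate-input policy

* Standardization refuses constant covariates (zero variance) with advice
  to drop them; the design matrix is rejected if rank-deficient or with
  condition number above 1e8.
* The simulator refuses linear predictors with |η| > 30, naming the
  offending station, rather than overflowing exp().
* Quantile-based intervals use R's default linear-interpolation (type 7)
  quantiles; the Gelman–Rubin factor uses split chains and errors on zero
  within-chain variance.
* Δ̂4 is clipped to [0, 1]; tests assert the clip never acts by more than
  numerical dust.
* Problem sizes in the validation suite (20 replicates per recovery study,
  n = 2,000 per overlap sample, reduced MCMC profile) were chosen so the
  whole suite runs comfortably on a single CPU while keeping Monte-Carlo
  error well inside the asserted tolerances.

## Known limitations

* The MwG sampler is tuned for the moderate dimensionalities of these
  models (tens of parameters); for hundreds of arrays a gradient-based
  sampler would mix better.
* The Gaussian LMM on a bounded response can in principle predict outside
  [0, 1]; with overlap values near the boundary a beta or logit-normal
  model would be preferable.
* The solar transform assumes timestamps are UTC (or carry their zone) and
  approximates station-local dates by longitude; sub-minute accuracy of
  sunrise/sunset is not attempted beyond the NOAA equations' ~1 minute.
* Hunting-season effects, occupancy-style detection modelling and GIS
  derivation of covariates are out of scope; covariates are consumed as
  station-table columns.
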