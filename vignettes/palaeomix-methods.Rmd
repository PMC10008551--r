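---
title: "Models and methods behind palaeomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind palaeomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeomix)
```

palaeomix reconstructs diet and residential mobility from the stable
isotope chemistry of archaeological bone and tooth samples. This vignette
explains each model in the pipeline, the assumptions behind it, the
defaults and why they were chosen, and what the synthetic-data tests do
and do not demonstrate about real assemblages.

## Collagen quality control

Bone collagen degrades in burial environments, and degraded collagen gives
isotope values that no longer reflect diet. The standard preservation
screen is the atomic C/N ratio: well-preserved collagen falls in a narrow
window, and palaeomix uses the conventional 2.9–3.6 acceptance range
(configurable via `qc_config()`). A minimum collagen yield of 1% by weight
is applied when a yield was recorded; a sample that produced too little
collagen for measurement fails with reason `insufficient_collagen`.

One propagation rule matters downstream: a sample whose collagen failed is
excluded *entirely*, including its bioapatite carbonate values, because
poor collagen preservation flags diagenetic alteration of the whole
specimen. `apply_qc()` therefore drops such samples from the accepted set
rather than masking individual columns, and the tests assert that no
collagen-failed sample can reach a carbonate summary.

Group comparisons use the Mann–Whitney U test with the `min(U1, U2)`
convention and midrank handling of ties. The exact null distribution is
used whenever the data are tie-free and `n1 * n2 <= 10000`; otherwise a
tie-corrected normal approximation with continuity correction. The
min convention is deliberate: rank-sum-style statistics reported under
other conventions can exceed `n1 * n2` and become uninterpretable, a
reporting pitfall the min convention makes structurally impossible.

## The oxygen conversion chain

Bioapatite carbonate δ¹⁸O is measured on the VPDB scale but drinking-water
comparisons live on the VSMOW scale. The chain applies three published
affine regressions in sequence:

1. scale conversion: δ¹⁸O_VSMOW = 1.03092 · δ¹⁸O_VPDB + 30.92
2. carbonate → phosphate: δ¹⁸O_p = 1.0322 · δ¹⁸O_c − 9.6849
3. phosphate → drinking water: δ¹⁸O_w = 1.55 · δ¹⁸O_p − 33.49

All arithmetic is done at full double precision; values are rounded to one
decimal only at report time. Each converted individual carries a
conservative 2‰ uncertainty by default, reflecting cumulative regression
error plus cultural and taphonomic perturbations (cooking and brewing of
ingested liquids, bone diagenesis). When a *cluster mean* is assigned to
the isoscape, the standard error of the cluster mean is used instead —
individual noise partially averages out at the group level.

The chain is a bijection, and `water_to_carbonate_vpdb()` is its exact
algebraic inverse. The synthetic-data generator exploits this: planted
water values are back-converted to carbonate so the pipeline's forward
conversion reproduces them exactly, which makes round-trip errors
detectable at the 1e-9 ‰ level.

Regression-chain conversions of this kind are only as good as their
calibration sets, and published human data sometimes report water ranges
that are not the literal image of the reported carbonate ranges (different
QC subsets, enamel-vs-bone choices). palaeomix deliberately reports
per-sample converted values and does not attempt to reconcile such
subset discrepancies.

## The Bayesian dietary mixing model

The model estimates the caloric contribution vector α (on the simplex)
of food groups to a consumer group's diet, in the FRUITS tradition:
concentration-dependent, macronutrient-routed, with diet-to-tissue
offsets and optional inequality priors.

For proxy $i$ the forward model is

$$\mathrm{pred}_i = \Delta_i + \sum_f r_{if}
  \frac{\sum_k \alpha_k\, c_{kf}\, s_{kfi}}{\sum_k \alpha_k\, c_{kf}}$$

where $f$ indexes macronutrient fractions (protein, energy), $c_{kf}$ is
the caloric concentration of fraction $f$ in source $k$, $s_{kfi}$ the
fraction's isotopic signal, $r_{if}$ the routing weight of fraction $f$
into tissue proxy $i$, and $\Delta_i$ the diet-to-tissue offset. Default
routing encodes standard isotope systematics: collagen carbon 75% from
dietary protein and 25% from the energy pool, collagen nitrogen 100% from
protein, bioapatite carbonate carbon 100% from the energy (whole-diet
caloric) pool. Default offsets are +4.8 ± 0.5‰ (collagen δ¹³C),
+5.5 ± 0.5‰ (δ¹⁵N) and +10.1 ± 1.0‰ (carbonate δ¹³C). These are
documented literature defaults, not data: every number is overridable
through `food_source()`, `mixing_proxy()` and `build_problem()`.

The likelihood is Gaussian per proxy with the consumer group's target sd.
Source signals, caloric concentrations and offsets are *latent nuisance
parameters*: rather than inflating the likelihood variance, each MCMC
iteration refreshes them by an independence Metropolis step whose
proposal is the prior, so their full uncertainty propagates into the
posterior. The base prior on α is uniform on the simplex; user-declared
linear inequality constraints (e.g. "C3 plants contribute at least 30% of
calories") are enforced by rejection at proposal time, and
`build_problem()` rejects constraint systems that no simplex point
satisfies (checked by seeded uniform sampling).

Sampling is random-walk Metropolis on softmax-transformed coordinates
(with the last coordinate pinned, plus the log-Jacobian
$\sum_k \log \alpha_k$ that makes the base prior uniform on the simplex),
with step-size adaptation toward 30% acceptance during burn-in only. The
dimension is small (seven sources) and constraint rejection is cheap, so
this simple kernel mixes well; the compiled core makes a 4-chain,
10,000-iteration run take well under a second. Convergence is monitored
with split-chain potential scale reduction; any α with R-hat above 1.05
triggers a loud warning with diagnostics attached, and the command-line
pipeline exits nonzero in that case.

Because published group-level applications of this model family rarely
restate their full source/offset/prior configuration, numeric credible
intervals from any particular study are not a meaningful reproduction
target. The package instead validates the machinery itself:

- every retained draw lies on the simplex (1e-9) and satisfies every
  declared constraint;
- an identifiable noise-free two-source problem recovers the analytic
  mixing proportion within 3 Monte-Carlo standard errors;
- simulation-based calibration: with truth drawn from the
  uniform-simplex prior and targets simulated from the model's own
  generative process (`simulate_targets()`), nominal 95% intervals
  attain 90–99% empirical coverage over 100 seeded replicates.

## Mixture clustering

Two clustering problems arise: grouping individuals in the
(δ¹³C_collagen, δ¹⁵N) plane into dietary clusters, and splitting water
δ¹⁸O values into residence groups while flagging rare extreme values.

`fit_gmm_bic()` fits 2-D Gaussian mixtures by EM over a grid of component
counts (default 1–5) and covariance families (spherical, diagonal, full —
a deliberately small family set, sufficient for low-k problems in 2-D),
each from 20 seeded k-means++ restarts, and selects the minimum of
BIC = −2 logL + p ln n. Ties break toward fewer components, then the
simpler family. EM stops at a relative log-likelihood change of 1e-8 or
500 iterations. Two numerical guards matter: covariance eigenvalues are
floored at 1e-6 to step around singular updates, and a component whose
effective size falls below dimension + 1 marks the run degenerate — such
components otherwise collapse onto single points and inflate the
likelihood without limit, which would bias BIC toward spurious extra
clusters. Cluster labels are reported sorted by first-coordinate mean so
solutions are deterministic given the seed.

`fit_trimmed_1d()` is classification EM with a concentration step: each
iteration assigns points to their best component, sets aside the
`ceiling(trim * n)` points of lowest mixture density as outliers, and
re-estimates parameters from the untrimmed points only. The default trim
fraction is 5%. The ceiling convention was chosen over floor so that the
outlier budget never understates the requested fraction (with 66
individuals and 5% trimming, four points are set aside); for sample sizes
divisible by 20 the two conventions coincide. Outliers are excluded from
all cluster parameter estimates but reported alongside the solution, and
the trimmed classification log-likelihood trace is stored so monotonicity
is testable. Measurement-uncertainty weighting of points is not applied;
the 2‰ conversion uncertainty is common to all points and would not
change relative densities appreciably.

## Isoscape smoothing and residence assignment

The drinking-water baseline is built from point predictions (longitude,
latitude, mean δ¹⁸O_water, standard error) by Gaussian-process regression:
Matérn-5/2 covariance on Euclidean degree distances, a constant mean
profiled out by generalized least squares, per-point observation noise
equal to the squared standard errors plus a fitted nugget, and
hyperparameters (signal sd, range, nugget) by marginal-likelihood
maximization from multiple seeded starts. The design contract is the
behaviour, not the kernel: the surface must reproduce a constant field
exactly, interpolate low-noise observations to within 0.01‰, and recover
a known smooth field sampled at 200 points with grid RMSE below 0.5‰ —
any smoother passing those properties would be conformant. Predictions
are laid on a cell-centred lon/lat lattice (default 0.5°) and
`local_estimate()` interpolates the lattice bilinearly.

Residence probability for a measured (converted) water value $m$ with
uncertainty $\sigma_m$ is computed cell by cell:

$$w_c \propto \frac{1}{\sqrt{\sigma_m^2 + \sigma_c^2}}
  \exp\!\left(-\frac{(m - \mu_c)^2}{2(\sigma_m^2 + \sigma_c^2)}\right)$$

normalized to sum to one over the grid — a posterior-style surface under
a uniform spatial prior. Individuals use the conservative 2‰ default;
cluster means use the cluster standard error. No land mask is applied by
default (coastal cells carry meaningful probability), and the normalized
map is preferred over raw likelihood surfaces because cell sets with
given cumulative probability (`map_summary()`) are then directly
interpretable.

## The synthetic assemblage

`population_spec()` encodes the study conditions the generators emulate:
134 humans and 21 fauna across three sites; a 12% collagen QC failure
rate injected by pushing C/N ratios above the acceptance window; two
dietary clusters — roughly one fifth of individuals on a C3→C4 (millet)
mixing line with negatively correlated (δ¹³C, δ¹⁵N), the rest on a
C3→marine line with positively correlated values; a resident water-δ¹⁸O
component at −7.7 ± 0.8‰ holding about 92% of mobility-assessed adults,
a migrant component at −12.9 ± 0.9‰, and four planted extreme outliers;
elevated and variable faunal δ¹⁵N baselines; and an optional +1.5‰
nursing offset on neonatal δ¹⁵N. Dietary archetypes over the seven food
groups were calibrated once against the forward model so that the
generated population sits at realistic medieval southern-European levels
(collagen δ¹³C near −19‰, δ¹⁵N near 10‰) with the two mixing lines
diverging at their extremes, and then frozen.

Every generator is a pure function of (spec, seed); ground-truth tables
(true α vectors, cluster labels, origin classes) are written alongside
the data and no pipeline stage reads them. Mobility values are drawn in
water space and back-converted through the exact inverse chain.

What passing tests on this assemblage show: the pipeline recovers planted
structure of realistic effect size under Gaussian noise, the mixing model
is calibrated against its own generative process, and every deterministic
contract holds. What they do not show: robustness to non-Gaussian
measurement error, to diagenetic drift that correlates across proxies, to
reference-value misspecification in the food-source table, or to spatial
autocorrelation structures unlike the smooth synthetic field. Real-data
conclusions still require the usual archaeological cross-checks.

## Problem sizes and numerical choices

Default problem sizes were chosen to match the scale of a single-site
skeletal assemblage: n in the low hundreds for clustering, 66 individuals
for the mobility mixture, 200 calibration points and a ~1000–4000-cell
grid for the isoscape, 4 chains × 10,000 iterations for production
mixing-model runs (2 × 4,000 for the 100-replicate calibration study,
which keeps the whole study under a minute of CPU). Tolerances: simplex
and normalization identities at 1e-9; EM convergence at 1e-8 relative;
variance floors at 1e-6; GP predictive sd floored at 1e-4‰. Degenerate
inputs fail loudly with named reasons (duplicate sample ids, infeasible
constraint sets, coincident isoscape designs, all-degenerate EM restarts).

## Known limitations

- Consumer targets are group means; individual-level diet estimation with
  informative individual priors is out of scope.
- Exactly two macronutrient fractions (protein, energy) are modelled;
  lipid/carbohydrate splits within the energy pool are not.
- The 1-D trimmed clustering fixes the trim fraction; it is a screening
  device, not an outlier test with controlled error rates.
- Euclidean degree distances in the GP ignore meridian convergence; over
  a ~20°×14° window at mid-latitudes the distortion is absorbed by the
  fitted range parameter but the kernel is not formally isotropic on the
  sphere.
- No multi-isotope (e.g. strontium + oxygen) joint assignment, and no
  intra-tooth time series.
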