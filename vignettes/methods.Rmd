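---
title: "Evaluating forest conservation with matching and an event study: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating forest conservation with matching and an event study: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defoeval)
```

## The problem

Community forest management (CFM) contracts and state protected areas are
the two dominant instruments for slowing tropical deforestation, and
Madagascar deploys both at scale. Asking which performed better through the
2009–2014 political crisis is a causal question with two obstacles. First,
the instruments are not assigned at random: community forests sit closer to
roads, villages and cart tracks, at lower elevation and on gentler slopes,
where clearing pressure is highest, while national parks occupy remote,
high-elevation land. A naive comparison of deforestation rates therefore
confounds management with location. Second, the crisis coincided with
droughts, cyclones and rice-price swings that could themselves move
deforestation differently in the two systems.

`defoeval` implements the standard quasi-experimental answer — statistical
matching of forest grid cells on time-invariant confounders, followed by an
event-study panel regression with grid-cell fixed effects and site-clustered
errors — as reusable, tested components, and couples them to a synthetic
landscape generator with known ground truth so that every stage of the
pipeline can be validated end to end.

## Outcome construction

Forest cover is a per-cell percentage, binary (0/100) at the 30 m base
resolution. Annual deforestation in year $t$ is

$$\mathrm{Deforestation}_{it} = \mathrm{cover}_{i,t-1} - \mathrm{cover}_{i,t},$$

non-negative because loss is absorbing: the package represents no regrowth,
as natural regeneration after clearing is negligible in this system and
available global tree-gain products conflate plantations with natural
regrowth. Annual (not cumulative) loss is used because it is stationary,
which the panel regression assumes.

Cover is aggregated to the 90 m (and, for robustness, 270 m) analysis
resolution by exact block means, which conserves total forest area across
resolutions to rounding error and turns the binary outcome into a
quasi-continuous percentage. Because block means commute with differencing,
deforestation computed after aggregation equals aggregated base-resolution
deforestation exactly; both identities are asserted in the test suite.

The annually updated distance to the forest edge — a time-variant control —
is the center-to-center Euclidean distance from each forested cell
(cover > 0, the same threshold as sampling eligibility) to the nearest
non-forest cell, computed with an exact Euclidean distance transform
(`EBImage::distmap`) and verified against an all-pairs scan in the tests.
Non-forest cells get 0; a fully forested grid gets the grid diagonal as a
sentinel. For outcome year $t$ the distance of year $t-1$ is used, so the
covariate predates the loss it helps explain. The edge definition
(nearest non-forest cell center, planar distance) is a declared convention;
grids here are synthetic and carry no projection.

## Sampling

Analysis cells are forested (cover > 0) cells of the 2005 baseline inside
units established before 2005, with cells claimed by both a CFM and an MNP
designation excluded. The spatially balanced draw is a recursive
quadrant-stratified scheme: split the bounding box into four quadrants,
apportion the sample by largest-remainder rounding of eligible-cell counts,
recurse, and sample uniformly inside leaves. The tool used by the original
analysis is proprietary; this scheme is a stand-in with the same stated
property — sample shares track area shares — which the tests demonstrate a
plain uniform draw does not deliver on clustered landscapes.

## Matching

Matching is 1:1 with replacement, exact within vegetation zones (eastern
humid, western deciduous, southern spiny), on the Table-3-style covariate
set: rice suitability, elevation, slope, precipitation, 2005 edge distance,
distances to village/urban center/road/cart track, and 2005 population
density. Balance is measured by the standardized mean difference

$$\mathrm{SMD} = \frac{\bar{x}_T - \bar{x}_{C,w}}{s_T},$$

with reuse-weighted control means and the *pre-matching treated* SD as
denominator (the ATT convention; the treated group never changes under 1:1
matching with replacement). 0.1 SD is the usual yardstick for "balanced".

Genetic matching searches the family of weighted generalized distances

$$d(x_i, x_j) = \sqrt{(x_i - x_j)^\top S^{-1/2\top} W S^{-1/2} (x_i - x_j)}$$

($S$ the covariance of standardized pooled covariates, $W$ diagonal) with a
genetic algorithm over $W$. Two design choices depart from common software
defaults and are deliberate:

* **Fitness is the maximum post-match |SMD| across covariates**, minimized,
  rather than a balance-test p-value. It is distribution-free and directly
  targets the 0.1-SD yardstick the balance assessment uses.
* **The initial population always contains $W = I$** and elitism preserves
  the best candidates, so genetic matching can never end worse than plain
  Mahalanobis matching — an invariant the tests assert on every fixture.

Ties in nearest-neighbour search go to the lowest control index, making
every matching deterministic given its seed. Binary covariates are
standardized like continuous ones. The GA defaults (population 50, 100
generations, per-gene mutation 0.1, uniform crossover, log-uniform weights
in [0.1, 10], elitism 2) are configuration, not doctrine; the test suite
uses smaller populations on smaller fixtures. Propensity-score and
Mahalanobis alternatives are provided for comparison; the propensity model
is a logistic regression fit by `stats::glm`, cross-checked in the tests
against an independent damped-Newton solver.

## The event study

The estimating equation, on the matched cell-year panel 2005–2020, is

$$Y_{it} = \tau_1\,\mathrm{year}_t + \tau_2\,\mathrm{year}_t\,\mathrm{CFM}_i
  + \sum_{s=2010}^{2020}\gamma_s\,\mathbf{1}[t=s]
  + \sum_{s=2010}^{2020}\delta_s\,\mathrm{CFM}_i\,\mathbf{1}[t=s]
  + \psi X_{it} + \mu_i + \varepsilon_{it}$$

with $Y_{it}$ annual deforestation (0–100 scale), cell fixed effects
$\mu_i$, time-variant controls $X_{it}$ (edge distance, population density,
national rice price mean and SD, drought severity, maximum precipitation,
temperature and wind speed), and the crisis/post-crisis years 2010–2020
carrying event dummies. The pre-crisis years 2005–2009 are the reference
period, controlled linearly through $\tau_1$ and $\tau_2$; because every
post-2009 year has its own dummy, $\tau_2$ is identified from the
pre-crisis years alone and a Wald test of $\tau_2 = 0$ is the
parallel-trends check. The CFM main effect is time-invariant and absorbed
by $\mu_i$, which fixed-effects software reports as absorbed rather than
estimating — this package does the same. The $\delta_s$ are the quantities
of interest: the yearly differential effect of the crisis on CFM relative
to matched protected areas.

Estimation is the within transformation (weighted demeaning by cell,
matched-control reuse as weights) followed by weighted least squares; the
tests prove coefficient-level identity with dummy-variable OLS. Variance is
the CR1 cluster-robust sandwich with clusters at the site (management-unit)
level,
$$\hat V = \frac{G}{G-1}\,\frac{N-1}{N-K}\, (X^\top WX)^{-1}
  \Big(\sum_g S_g S_g^\top\Big) (X^\top WX)^{-1},$$
optionally two-way (site and region) by inclusion–exclusion with each term
CR1-corrected and any non-PSD result repaired by zeroing negative
eigenvalues (flagged). Two-way clustering changes standard errors but never
point estimates, asserted exactly. Inference uses $t(G-1)$ with $G$ the
smaller clustering dimension — the conventional conservative choice;
p-value conventions at this margin are not settled and the choice is
recorded here. Confidence intervals default to 90%, two-sided.

The two-period difference-in-differences collapses the panel to
cell-by-period means (pre-crisis 2005–2009 vs crisis 2010–2014) and
estimates the CFM-by-crisis interaction with the same machinery; it is the
conventional cross-check, invariant to common additive shocks by
construction. Heterogeneity analyses add moderator × CFM × year-dummy
triple interactions, with continuous moderators standardized or
median-split (ties resolved by position, `ceiling(n/2)` cells below).

Converting a yearly coefficient $\delta$ (percentage points of cell area)
to hectares multiplies $\delta/100$ by the forest area it applies to; on
the published pre-crisis CFM forest area of 475,333 ha, effects of 1.7–2.4
pp/yr correspond to roughly 8,100–11,500 ha/yr of excess loss.

## The synthetic landscape

The generator's defaults define the study conditions under which the
estimators are validated; they emulate the real setting qualitatively, not
cartographically.

* **Confounder fields.** Static covariates are Gaussian-kernel-smoothed
  white noise (correlation length 300 m, the kernel bandwidth), transformed
  to plausible ranges (distances log-normal, rice suitability a thresholded
  field at 30% prevalence). Vegetation zones are three contiguous bands;
  regions a 2 × 3 partition.
* **Assignment.** An accessibility score (negative loadings on distances to
  road/village/cart track and elevation/slope, positive on population
  density) weights unit placement: CFM centers are drawn with probability
  $\propto e^{score + u}$, MNP centers with $\propto e^{-0.4\,score + u}$,
  where $u$ is unobserved cell-level placement noise (one score-SD by
  default) standing for siting drivers outside the measured covariates.
  The MNP exponent is softer because large parks span accessibility
  gradients, and MNP units rotate across the vegetation zones as the real
  park system does. All three choices protect *common support*: selection
  shifts the covariate means while the distributions still overlap —
  without which exact-within-zone matching with replacement collapses onto
  a handful of heavily reused comparison cells and both its balance and
  the clustered inference degrade. A scale knob multiplies all loadings;
  imbalance increases monotonically in it (a tested property), and at the
  default scale the pre-match pattern mirrors the real one: CFM closer to
  roads and villages, denser, lower, drier.
  Units are rectangles — MNP larger (30 × 36 base cells vs 21 × 21) —
  snapped to the analysis-cell lattice so unit boundaries never split a
  90 m cell, and CFM rectangles may clip into MNP footprints, producing
  genuinely overlapping designations that the sampling stage must exclude.
  The default 24 CFM and 12 MNP units on a 270 × 180 grid keep roughly
  2,000 analysis cells and 36 sites: enough clusters per arm for
  site-clustered CR1 inference to hold its nominal size, which a
  scaled-down design with very few comparison sites does not.
* **Dynamics.** Each forested 30 m cell clears in year $t$ with probability
  $\mathrm{logit}^{-1}(\alpha + c_i + \psi X_{it} + \eta_t)$: intercept
  $\alpha$ calibrated so background rates sit near the observed 0.2–1%/yr;
  a per-cell effect $c_i$ loading 0.45 on the standardized assignment score
  (true confounding) plus N(0, 0.45) noise (something real for the fixed
  effects to absorb); true covariate effects on edge distance, drought and
  precipitation; and common crisis/post-crisis log-odds shocks (+0.55 in
  2010–2014, +1.0 in 2015–2020) reproducing the observed acceleration.
  Rice prices are national scalars, identical across cells within a year.
* **Ground-truth effects.** `delta_true` (defaults 1.79, 1.70, 1.75, 2.43
  pp in 2014–2017, the magnitudes reported for the real post-crisis
  window) is defined as the year-$t$ *causal contrast*: expected annual
  deforestation of a treated analysis cell minus the same cell under the
  never-treated counterfactual, in percentage points of cell area. Because
  loss is absorbing, a naive constant hazard boost under-delivers in later
  years — earlier treatment removes forest that would otherwise have been
  available and drags edges closer. The simulator therefore evolves the
  counterfactual landscape alongside the realized one with common random
  numbers and sets the per-subcell boost so the expected block-level
  contrast equals `delta` exactly in every year once histories diverge
  (including configured-zero years, where the depletion echo is offset).
  This makes the configured schedule the estimand on the outcome scale,
  which is what parameter-recovery experiments require of a generator.

What the generator does **not** emulate: real geography or park shapes,
cloud-contaminated remote sensing, selective logging invisible to canopy
products, spatial autocorrelation of errors *between* sites, or
leakage/spillovers beyond the mechanical edge-distance channel. Passing
recovery tests therefore validates the estimators under the stated model,
not the remote-sensing pipeline of a real analysis.

## Monte Carlo validation and problem sizes

The validation experiments repeat the full simulate → outcomes → sample →
match → estimate cycle with independent seeds:

* **Recovery** (200 repetitions, default scenario, Mahalanobis matching
  before fitting): mean $\hat\delta_s$ within two Monte Carlo standard
  errors of each configured effect, and pooled 90% CI coverage inside
  [0.84, 0.96]. Matching is part of the validated estimator for a reason
  beyond fidelity to the pipeline: common *logit-scale* year shocks
  interact with the confounded heterogeneity in baseline hazards, so cells
  with higher baselines respond more to a common shock on the probability
  scale. Fixed effects absorb levels, not differential shock responses;
  aligning the hazard distributions by matching is exactly the design's
  answer to that confound, and without it the unmatched event study shows
  a small but real bias in shocked years.
* **Placebo** (200 repetitions, zero effects): the 10%-level rejection
  rate of the yearly interaction coefficients, pooled across the eleven
  coefficients (the maximal-precision estimate of the per-coefficient
  rate), must lie in [0.06, 0.14].
* **Matching efficacy** (10 confounded scenarios, scaled-down genetic
  matching): the worst |SMD| must improve in every scenario, and most
  covariates must average below 0.1 SD. Per-covariate balance is averaged
  over the 10 seeds because a single SMD at the scaled-down sample size
  (300 treated cells) carries ~0.08 SD of pure sampling noise.

Problem sizes are deliberate choices: 270 × 180 base cells keep a
repetition near a second so 400 full-pipeline repetitions plus the unit
tests complete in minutes; the per-seed matching samples (300 treated
against up to 800 pooled cells, GA population 30 × 60 generations) keep the
genetic search meaningful while the balance criterion is evaluated where it
has statistical power. The paper-scale sample sizes (12,000 treated points,
36,000-point pool) remain the orchestrator's configuration defaults.

## Numerical conventions and degenerate inputs

Covariance matrices for generalized distances are ridge-regularized when
near-singular; the inverse square root is by symmetric eigendecomposition.
Distance ties round at 1e-10 before argmin so floating-point dust cannot
flip matches; all tie-breaks go to the lowest index. Within-transformed
columns with no residual variation are reported as absorbed (scaled 1e-10
threshold); collinear columns are dropped by pivoted least squares and
named. An SMD with zero treated spread is 0 by convention. Single-year
cover series, empty eligibility sets, strata with treated cells but no
controls, single clusters, and non-finite covariates all raise typed
errors rather than propagating nonsense. Every stochastic component —
generator, sampler, GA, Monte Carlo — draws from an explicit seed through
one derivation function, and identical seeds reproduce scenarios and
pipeline artifacts bit for bit.

## Known limitations

Site-level inference rests on CR1 with a moderate number of clusters; no
wild-cluster bootstrap is provided, and spatial correlation between nearby
cells in *different* sites is not addressed (the same caveat the real
analysis carries). The annual edge-distance control is affected by past
treatment, a post-treatment-variable subtlety inherent to the original
specification and reproduced here. The two-period DiD averages over a
window the event study shows to be heterogeneous; it is included as a
cross-check, not a headline estimator. Hectare conversions inherit the
printed precision of the area totals they use.
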