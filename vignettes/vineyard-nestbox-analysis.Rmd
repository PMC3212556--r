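---
title: "Quantifying avian pest-control services with nest-box augmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying avian pest-control services with nest-box augmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinebirds)
```

## The experiment this package analyses

Instead of excluding predators with net cages, a predator-*augmentation*
experiment increases the local density of insectivorous songbirds by
provisioning artificial nest cavities, and measures two things: how the bird
community responds (point-count surveys) and whether pest pressure actually
changes (removal rates of sentinel prey — live lepidopteran larvae pinned in
the field). The design this package assumes is a split-vineyard layout: each
of two vineyards is divided into a nest-box half and a control half, with five
observation points per half surveyed in 30-minute samples (six 1-minute counts
at 5-minute spacing, 85 m detection radius), biweekly across three 4-week
phenological periods (early, middle, late breeding season). Detected species
are classified into diet guilds — insectivore (I), omnivore (O), granivore
(G) — because only insectivores are expected to respond to nesting
opportunities with increased pest consumption, while some omnivores and
granivores are themselves potential grape pests.

The package implements the full analysis chain: survey aggregation into
replicate means, a pooled-bootstrap null test of treatment differences, a
binomial logit mixed model for sentinel removal counts with likelihood-ratio
tests and multiplicity-adjusted contrasts, foraging-distance profiles around
active nests, and the provisioning arithmetic that converts brood sizes into
daily arthropod demand. A calibrated synthetic-data generator reproduces the
design so everything is testable end to end.

## Response variables and replicate means

From raw records, `replicate_means()` computes per 30-minute sample either
species richness (distinct species across the six intervals, optionally
restricted to a guild) or per-interval abundance (summed counts divided by
six, so silent intervals count). Per-sample statistics are then averaged
within each treatment × site × period cell, giving 6 replicates per treatment
in the full design (2 sites × 3 periods). Seven responses are built in:
richness, insectivore richness, and the abundance of all birds, the focal
bluebird, non-bluebird insectivores, omnivores and granivores.

Two choices here were genuinely open:

* **Cell means weight observation samples equally** rather than pooling raw
  intervals. With a balanced design the two coincide; with missing visits
  (surveys were weather-dependent) equal sample weighting keeps each sample's
  influence constant. Empty cells are reported as `NA` with a warning, never
  imputed or dropped silently.
* **A "sighting" in the species × area tabulation is a summed interval
  count.** The repeated-interval protocol cannot deduplicate individuals, so
  the same bird re-detected in several intervals contributes several
  sightings. Tabulations therefore match the survey totals, not a
  mark-recapture abundance.

## The pooled-bootstrap treatment test

Survey-derived replicate means (n = 6 per treatment) rarely satisfy ANOVA
assumptions, so treatment differences are tested against a resampling null.
Under H0 the 12 replicate means are exchangeable: `pooled_bootstrap_null()`
pools them, draws `B = 1000` bootstrap means of size `m = 6` (with
replacement) twice independently, and differences the paired draws, giving the
null law of "difference between two treatment means of size six when there is
no treatment effect". `empirical_p()` places the observed difference in that
null with the add-one rule

\[ p = \frac{1 + \#\{|d^\*_b| \ge |d_{obs}|\}}{B + 1}, \]

so p is never 0, always a multiple of 1/(B+1), and `<0.001`-style reporting at
B = 1000 corresponds to the floor 1/1001. Ties count as exceedances
(conservative). Numerical details worth knowing:

* **Sidedness is not dictated by the method**; the default is two-sided on
  |difference|, with `one_sided_greater` exposed. Neither is asserted to be
  "the" original analysis.
* The pooled vector is sorted before resampling, which leaves the bootstrap
  law untouched but makes the null vector invariant to swapping the group
  labels under a fixed seed — a property the test suite checks.
* `run_bootstrap_suite()` derives an RNG substream per response from the
  master seed and the response *name*, so adding or reordering responses
  never changes another response's p-value.

Calibration of the test (type-I error at nominal α) is verified by simulation
in the acceptance suite: 500 synthetic null seasons (all nest-box multipliers
set to 1) are generated and tested at α ∈ {0.01, 0.05, 0.10}; the rejection
rate must fall inside the binomial 99% Monte-Carlo band around α.

## The sentinel-prey mixed model

Each transect exposes five larvae; the count removed is modelled as

\[ y_t \mid u_b \sim \mathrm{Binomial}(5,\ \mathrm{logit}^{-1}(x_t^\top\beta + u_{b(t)})), \qquad u_b \sim N(0, \sigma_b^2), \]

with treatment group (control / random nest-box points / adjacent to active
nests), site, and optionally their interaction as fixed effects, and a random
intercept per spatial block. The marginal likelihood integrates each block's
intercept out by **adaptive Gauss–Hermite quadrature**: the integrand is
recentred at its mode (found by Newton steps on the strictly concave
conditional log-density) and rescaled by the curvature there, then evaluated
on 15 Hermite nodes by default (order 1 reproduces the Laplace approximation
exactly; the log-likelihood changes by < 1e-6 between orders 15 and 25 on the
synthetic defaults, which the tests assert).

Numerical and design choices:

* **Random-effect grouping** defaults to one intercept per site × vineyard
  half (4 blocks in the original design), reading "nested by spatial location"
  as the vineyard halves. One observation per transect under Binomial(5) makes
  transect-level intercepts unidentifiable except as overdispersion, which is
  available via `re = "transect"`.
* **σ_b is parameterized on the log scale**, and every fit is profiled
  against the boundary σ_b = 0 (a plain independent-binomial fit, computed to
  high precision from an IRLS start): whichever likelihood is higher is
  returned, with `boundary = TRUE` flagged. This avoids optimizer failure as
  log σ → −∞.
* **Optimization** is a Nelder–Mead sweep followed by a BFGS polish with
  tight relative tolerance; the σ_b = 0 fit at a saturated design matches the
  closed-form group-logit MLE to ~1e-8.
* **Covariance** of the fixed effects is the inverse observed information of
  the joint (β, log σ_b) fit, so β standard errors account for uncertainty in
  σ_b (except at the boundary, where the σ term is dropped).
* **Estimation is ML, not REML-like**, because the inferential tool is the
  likelihood-ratio test between nested fixed-effect specifications:
  χ² = deviance(null) − deviance(full) on df = parameter difference. Dropping
  the 3-level treatment gives df = 2. Comparing a fit with itself is allowed
  as the degenerate identity (χ² = 0, p = 1).
* **Complete separation** (a group with all five larvae removed on every
  transect, or none) makes the group's logit infinite; the fitter refuses
  with an error naming the group rather than returning a divergent estimate.

`pairwise_contrasts()` computes the three pairwise group differences on the
logit scale, averaging over site levels with equal weights when site terms are
present. Because the three contrasts have rank 2, the single-step adjustment
draws coefficient vectors from N(0, V̂) directly (10^5 seeded draws), maps
them through the contrast matrix, and estimates P(max_k |Z_k| ≥ |z|) — the
max-|z| analogue of a Tukey adjustment, always ≤ Bonferroni and ≥ the
unadjusted p. The adjustment method of the original analysis is not
recoverable; `single_step` (default), `bonferroni` and `none` are all exposed.

## Foraging distances and energetics

`distance_profile()` bins focal-species detections in the nest-box half by
distance from the observation point (which is an active nest box there). The
text of the underlying study names "intermediate distances (21–42 m)" and a
far field "over 65 m", so the default bins are 0–20, 21–42, 43–64 and
65–85 m, configurable because the exact histogram binning is not printed.
Distances recorded between bin edges (e.g. 20.3 m) are assigned by rounding at
the half-meter boundary. Heard-only records without a distance estimate are
excluded from profiles (and their number reported), but retained in all
abundance summaries.

`daily_requirement()` is deliberately plain linear arithmetic: 78 g/day feeds
a brood of five (15.6 g per nestling) and each adult needs 23 g/day, so a pair
with five nestlings needs 124 g of arthropods daily. The 65 kJ/day per-nestling
energy figure is carried as metadata only: the implied energy-density
conversion (≈4.17 kJ/g) is not documented well enough to expose a kJ-based
path.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the split-vineyard design. Detection counts per
species × interval cell are Poisson with rate λ (per interval per point),
multiplied in the nest-box half by a species multiplier; negative-binomial
overdispersion is available as an option. The defaults are calibrated once,
to the published guild-level means: the focal bluebird at λ = 0.18 with
multiplier 1.82/0.18 ≈ 10, and the three guilds scaled so control/nest-box
expected abundances per interval are 0.47/0.84 (non-bluebird insectivores),
0.18/0.14 (omnivores) and 1.23/1.20 (granivores), with within-guild rates
proportional to each species' total sighting count. Two consequences are
worth stating plainly:

* The published total-abundance means are internally inconsistent with the
  sum of their guild components (3.71 printed vs 4.00 summed for the nest-box
  half); the generator is calibrated to the components, so its expected total
  is the component sum.
* Richness means are *emergent*, not calibrated: under a Poisson pool the
  expected per-sample richness is Σ_s (1 − exp(−6λ_s)), which lands above the
  printed richness means. Tests therefore check the Poisson law and the
  treatment contrast machinery on richness, not the printed richness values.

Sentinel transects are Binomial(5) draws with group effects on the logit
scale calibrated to the published group means (1.2, 2.9 and 4.14 larvae
removed of 5 → control logit qlogis(0.24), effects +1.48 and +2.72) and a
block random intercept with σ_b = 0.25 by default — a modest spatial
heterogeneity chosen once as realistic for adjacent vineyard halves; no
empirical σ is recoverable. Nest records emulate 76.1% bluebird occupancy of
box pairs and clutch sizes on 3–6 eggs with mean 4.91.

Features of real data the generator does *not* emulate: interval-to-interval
dependence (the same bird re-sighted — intervals are independent here),
within-season population dynamics, distance-dependent detectability (distances
are uniform on [0, 85] m), and weather-driven missing visits. Passing tests on
synthetic data therefore validate the statistical machinery under the assumed
laws, not the field realism of those laws.

## Problem sizes and reproducibility

All stochastic paths — the generator, the bootstrap, and the Monte-Carlo
contrast integral — are pure functions of a master seed; per-stage substreams
are derived by hashing a stage label with the seed, and repeated runs produce
byte-identical CSV output. The packaged checks use: 500 synthetic null
seasons for bootstrap calibration; 500 simulated sentinel datasets for Wald
coverage of the fixed effects, run on an enlarged layout (20 sites × 15
transects: 40 blocks of 5–10 transects) because interval coverage is an
asymptotic property and, more specifically, the SEs depend on σ_b being
estimable — with the original 4 blocks (or with many blocks of only 2–4
transects), ML σ̂_b is biased toward zero and hits the boundary often, which
shortens the intervals and puts coverage a few points below nominal for the
high-removal group; that is expected behaviour for small mixed designs, not an
implementation defect (an lme4 fit of the same data shows the same pattern).
Quadrature orders 15/25 are compared for likelihood stability. These sizes keep the full suite within a few minutes on one CPU
while leaving Monte-Carlo error well below the tolerances being asserted.

## Known limitations

* Only binomial/logit models with a single random-intercept grouping and
  categorical fixed effects are supported — this is not a general
  mixed-model engine.
* The bootstrap test applies no multiple-testing correction across the seven
  responses, mirroring the analysis it implements.
* No detection-probability or distance-sampling correction is applied to
  point counts.
* Wald intervals from small block counts (the original design has 4) should
  be read with the usual small-sample caution; the likelihood-ratio test is
  the primary inferential tool for the sentinel model.
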