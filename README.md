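# vinebirds

Statistical pipeline for **avian predator-augmentation experiments in
vineyards**: field designs where one half of each vineyard is provisioned with
songbird nest boxes (raising the local density of insectivorous birds, chiefly
Western Bluebird, *Sialia mexicana*) and the other half is left as a control,
and the response is measured both as bird community change (point-count
surveys) and as realized pest-control service (removal rates of sentinel prey
— live lepidopteran larvae pinned along transects).

The package is aimed at agroecologists and biostatisticians who need the
analysis chain for such experiments to be reproducible and testable:

* **Survey aggregation** — point-count records → per-sample species richness
  and per-interval abundance by diet guild (insectivore / omnivore /
  granivore) → treatment × site × period replicate means
  (`replicate_means()`, `tabulate_sightings()`).
* **Pooled-bootstrap treatment test** — replicate means (n = 6 per
  treatment) rarely satisfy ANOVA assumptions, so treatment differences are
  referred to a resampling null: pool the two groups, draw B = 1000 pairs of
  bootstrap means of size m = 6, difference each pair, and compute
  `p = (1 + #{|d*| ≥ |d_obs|}) / (B + 1)`
  (`pooled_bootstrap_null()`, `empirical_p()`, `run_bootstrap_suite()`).
* **Sentinel-prey mixed model** — larvae removed out of 5 per transect:
  `y_t | u_b ~ Binomial(5, logit⁻¹(x_tᵀβ + u_b))`, `u_b ~ N(0, σ_b²)` over
  spatial blocks, fitted by maximum likelihood with adaptive Gauss–Hermite
  quadrature (order 15 by default; order 1 = Laplace), with likelihood-ratio
  tests between nested fits and single-step (max-|z|) adjusted pairwise
  contrasts (`fit_binomial_glmm()`, `likelihood_ratio_test()`,
  `pairwise_contrasts()`).
* **Foraging-distance profiles** around active nests and the far-field
  fraction beyond 64 m (`distance_profile()`).
* **Provisioning arithmetic** — daily arthropod demand of a nest from brood
  size: 15.6 g per nestling plus 23 g per adult (`daily_requirement()`).
* **Synthetic-data generator** (`sim_config()`, `simulate_pointcounts()`,
  `simulate_sentinel()`, `simulate_nests()`) calibrated to the published
  guild-level abundances and sentinel removal means, so the entire pipeline
  runs end to end with no field data.

See the methods vignette (`vignettes/vineyard-nestbox-analysis.Rmd`) for the
models, their assumptions, and every numerical choice.

## Worked example

```r
library(vinebirds)

cfg  <- sim_config(seed = 42)                 # the split-vineyard design
pc   <- simulate_pointcounts(cfg)
reps <- replicate_means(pc)                   # 6 replicates per treatment
run_bootstrap_suite(reps, B = 1000, seed = 42)
#>                           response nestbox_mean control_mean observed_diff p_value
#>                           richness        5.717        5.383       0.33333  0.1279
#>               insectivore_richness        2.217        1.700       0.51667  0.0020
#>                    total_abundance        3.964        1.967       1.99722  <0.001
#>                 bluebird_abundance        1.767        0.178       1.58889  <0.001
#>  nonbluebird_insectivore_abundance        0.958        0.500       0.45833  <0.001
#>                 omnivore_abundance        0.111        0.164      -0.05278  0.0500
#>                granivore_abundance        1.128        1.125       0.00278  0.9820
```

The focal-species abundance contrast (1.77 vs 0.18 birds per 5-minute
interval, a tenfold difference) sits at the bootstrap floor `p = 1/1001`,
while omnivores and granivores — the guilds containing potential grape pests —
show no treatment effect: the generator reproduces the study conditions and
the test recovers them.

```r
tr   <- simulate_sentinel(cfg)
tapply(tr$removed, tr$group, mean)
#>        control nestbox_random    active_nest
#>           1.60           3.10           4.43

full <- fit_binomial_glmm(tr, ~ group + site)   # AGHQ, block random intercept
null <- fit_binomial_glmm(tr, ~ site)
likelihood_ratio_test(full, null)
#>       chi2 df            p
#> 1 18.28162  2 0.0001072007

pairwise_contrasts(fit_binomial_glmm(tr, ~ group), seed = 42)
#>                       contrast estimate    se    z p_unadjusted p_adjusted
#> 1     nestbox_random - control     1.24 0.420 2.96     3.11e-03   8.68e-03
#> 2        active_nest - control     2.80 0.612 4.58     4.65e-06   4.65e-06
#> 3 active_nest - nestbox_random     1.56 0.606 2.57     1.01e-02   2.67e-02

daily_requirement(5, 2)   # pair feeding a brood of five
#> [1] 124
```

Removing the 3-level treatment term costs 2 degrees of freedom and is
decisively rejected; removal is highest immediately below occupied boxes, and
a pair provisioning five nestlings must deliver 124 g of arthropods per day —
the scale of the service being measured.

A thin command-line wrapper over the same functions ships in
`inst/scripts/vinebirds` (subcommands `simulate`, `summarize`, `boot-test`,
`sentinel-fit`, `distance`, `energetics`, `report`; every run writes a JSON
manifest with input digests and the master seed).

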