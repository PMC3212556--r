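Package: vinebirds
Title: Avian Predator Augmentation Analysis for Vineyard Nest-Box Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing avian predator-augmentation field experiments
    in vineyards. Summarises point-count surveys into species richness and
    guild-level abundance replicate means, tests treatment differences with a
    pooled-bootstrap null distribution, fits a binomial logit mixed model with
    a spatial-block random intercept (adaptive Gauss-Hermite quadrature) to
    sentinel-prey removal counts with likelihood-ratio tests and
    multiplicity-adjusted pairwise contrasts, profiles focal-species foraging
    distances from active nests, and computes nestling provisioning
    requirements. Includes a calibrated synthetic-data generator emulating the
    two-site split-vineyard design so the full pipeline runs end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mvtnorm
Config/testthat/edition: 3
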