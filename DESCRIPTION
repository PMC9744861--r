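Package: occutrends
Title: Occupancy-Detection Trend Estimation and Driver Attribution for
    Opportunistic Insect Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate long-term distribution trends of insect
    species from opportunistic (citizen-science) records and to attribute
    those trends to climate and land-use change.  Implements the full
    workflow: simulation of a virtual study system with known ground
    truth; record filtering and visit construction with list-length and
    observer-class detection covariates; per-species hierarchical
    Bayesian occupancy-detection models with zone-wise random-walk year
    effects (fitted with JAGS); derivation of annual mean occupancy and
    window-based trends with highest-density-interval summaries;
    computation of standardized climate-change (BIO1, BIO4, BIO18) and
    land-use-change covariates and of species traits (temperature niche,
    habitat specialisation); a hierarchical Gaussian regression of
    sign-root transformed short-term trends on drivers, traits and their
    interactions (blocked Gibbs sampler); and counterfactual scenario
    predictions that decompose explained variance of long-term trends by
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
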