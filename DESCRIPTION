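Package: mtmegp
Title: Multi-Trait Multi-Environment Genomic Prediction for Replicated
    Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian GBLUP-family genomic prediction for multi-trait,
    multi-environment plant-breeding trials. Computes per-environment
    adjusted means (BLUEs) and broad-sense heritabilities from plot-level
    data, builds genome-wide (VanRaden) and target-gene relationship
    kernels, fits single-environment (SE), multi-trait (MT),
    multi-environment (ME) and multi-trait multi-environment (MTME)
    models by Gibbs sampling with data augmentation for masked cells,
    evaluates them under CV1/CV2 cross-validation with prediction-ability
    ranking, and performs site-regression (SREG/GGE) biplot analysis.
    Includes a synthetic-trial generator emulating a replicated
    sowing-by-season durum wheat design so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
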