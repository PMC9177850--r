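Package: quiltfuse
Title: Multimodal Image-Quilt and Clinical Fusion Models for Prostate Cancer Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale multimodal prognostication pipeline for localized
    prostate cancer. Tiles digitized biopsy slides into fixed-size patches,
    filters non-tissue patches, assembles per-patient image quilts, learns
    128-dimensional patch embeddings by momentum-contrast self-supervised
    training, fuses mean-pooled image features with numeric clinical
    variables (Gleason, T-stage, PSA, age) in gradient-boosted risk models,
    and evaluates risk markers against NCCN risk groups using time-dependent
    ROC/AUC under censoring and competing risks with inverse
    probability-of-censoring weighting. Includes a synthetic-cohort
    generator that renders slide images whose morphology encodes a latent
    risk, with correlated clinical covariates and competing-risks outcomes,
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    survival,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
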