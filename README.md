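# quiltfuse

Multimodal image-quilt + clinical fusion models for prostate-cancer
prognosis, at desk scale.

Risk stratification for localized prostate cancer still leans on the
three-tier NCCN groups (T-stage, combined Gleason score, PSA), which have
well-documented discrimination limits. quiltfuse implements, end to end and
at workstation scale, a multimodal alternative: digitized biopsy slides are
tiled into 256-pixel patches, non-tissue patches are filtered out, each
patient's usable patches are assembled into a fixed-capacity **image
quilt**, a 128-dimensional patch representation is learned **without outcome
labels** by momentum-contrast self-supervised training, and the mean-pooled
patient image feature is concatenated with six numeric clinical variables
and fed to a gradient-boosted classifier that outputs a risk score per
clinical endpoint. Markers are compared against the NCCN baseline with the
**time-dependent AUC under censoring and competing risks** (cumulative/
dynamic definition, inverse probability-of-censoring weighting):

    AUC(t) = sum_ij W_i W_j [ 1{M_i > M_j} + 1/2 1{M_i = M_j} ]
             / (sum_i W_i)(sum_j W_j)

with cases i (primary-cause event by t, weight 1/S_C(T_i^-)) and controls j
(event-free at t, weight 1/S_C(t), or competing event by t, weight
1/S_C(T_j^-)), where S_C is the Kaplan-Meier censoring survival. Standard
errors are a seeded patient-level bootstrap; two-model contrasts use a
paired bootstrap.

Because the clinical cohorts behind this design are not publicly
deposited, the package ships a **synthetic-cohort generator**: slide images
whose texture statistics encode a latent risk component, correlated clinical
covariates, and competing-risks outcomes with censoring — so every stage,
from tissue filtering to the final AUC table, is testable from a seed alone.

The package is intended for methodologists who want a fully inspectable,
reproducible desk-scale replica of this class of multimodal pipeline — not
as a clinical tool.

## Worked example

```r
library(quiltfuse)

cfg <- run_config(n_patients = 60, seed = 7,
                  cohort  = cohort_config(60, image_size_px = 512),
                  imaging = imaging_config(quilt_rows = 4, quilt_cols = 4),
                  encoder = encoder_config(epochs = 2, queue_size = 128,
                                           pretrain_filter = FALSE),
                  split = split_spec(auc_range = c(0, 1)),
                  endpoints = data.frame(family = "competing", horizon = 5),
                  variants = c("path", "path+NCCN+3", "clinical"),
                  bootstrap_B = 100)
res <- run_pipeline(cfg)
#> [quiltfuse] simulating cohort (n = 60) and filtering patches
#> [quiltfuse] tissue filter: 100.0% agreement with ground truth over 464 patches
#> [quiltfuse] training SSL encoder on 417 patches (2 epochs)
#> [quiltfuse] extracting patient image features
#> [quiltfuse] split accepted after 1 tries (validation NCCN AUC 0.949)
#> [quiltfuse] done; outputs in /tmp/RtmpRbQEpX/quiltfuse_run_a7344a943ba

res$metrics[, c("marker", "auc", "ci_low", "ci_high", "rel_improvement")]
#>        marker       auc     ci_low   ci_high rel_improvement
#> 1        nccn 0.9494949 0.85658235 1.0424075              NA
#> 2        path 0.8845599 0.65547422 1.1136455     -0.06838906
#> 3 path+NCCN+3 0.7691198 0.44400439 1.0942351     -0.18996960
#> 4    clinical 0.4372294 0.06766978 0.8067891     -0.53951368
```

Each metrics row is one (endpoint, marker) cell: the IPCW time-dependent
AUC on the validation side with its bootstrap CI, the paired difference and
p-value against the NCCN ordinal baseline, and the relative improvement
(AUC_model − AUC_NCCN) / AUC_NCCN. This 60-patient toy run makes the
small-sample point by itself: with a 12-patient validation side the NCCN
baseline lands at 0.95 by luck and every contrast is swamped by its CI.
The package defaults (`run_config()` targets n = 400) and the repeated-split
and held-out-cohort evaluators (`mc_split_eval()`, the acceptance script)
exist precisely because single small validation sides behave like this; at
those sizes the full model reliably recovers the planted signal (held-out
AUC ≈ 0.70 vs ≈ 0.66 for NCCN, ordering path < path+NCCN < path+NCCN+3).

The pieces are available individually: `generate_cohort()` /
`render_slide()` (synthetic slides + ground-truth sidecars), `tile_image()`
/ `classify_patch_rule()` / `build_quilt()` (patch pipeline), `train_ssl()`
/ `embed_patch()` / `augment()` / `infonce_loss()` (encoder),
`embed_quilt()` / `aggregate_quilt()` (features), `nccn_risk_group()` /
`assemble_features()` / `train_risk_model()` (fusion), `timedep_auc()` /
`compare_auc()` / `constrained_split()` / `evaluate_all()` (evaluation).
A thin CLI lives at `inst/cli/quiltfuse.R` (`simulate`, `run`, `evaluate`).

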