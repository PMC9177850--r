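# Clinical encoding, NCCN risk groups, endpoint labels, ablation feature
# assembly, and the gradient-boosted risk model on concatenated
# clinical + image features.

#' Encode clinical T-stage as an ordinal code
#'
#' Fixed monotone table T1a=1, T1b=2, T1c=3, T2a=4, T2b=5, T2c=6, T3a=7,
#' T3b=8, T4=9.
#'
#' @param stage character vector of T-stage labels.
#' @return integer codes 1..9.
#' @export
encode_tstage <- function(stage) {
  code <- match(as.character(stage), TSTAGE_LEVELS)
  if (anyNA(code))
    stop("unknown T-stage: ", paste(unique(stage[is.na(code)]), collapse = ", "),
         "; valid stages are ", paste(TSTAGE_LEVELS, collapse = ", "))
  code
}

#' NCCN risk group from T-stage, combined Gleason score and PSA
#'
#' Three-tier rule: high risk if stage >= T3a, or Gleason 8-10, or
#' PSA > 20 ng/mL; otherwise low risk if stage <= T2a and Gleason <= 6 and
#' PSA < 10 ng/mL; otherwise intermediate.
#'
#' @param t_stage T-stage labels (see [encode_tstage()]).
#' @param gleason_combined combined Gleason score, 6-10.
#' @param psa baseline PSA in ng/mL (> 0).
#' @return factor with ordered levels low < intermediate < high.
#' @export
nccn_risk_group <- function(t_stage, gleason_combined, psa) {
  code <- encode_tstage(t_stage)
  if (any(psa <= 0)) stop("psa must be > 0")
  if (any(gleason_combined < 6 | gleason_combined > 10))
    stop("gleason_combined must lie in [6, 10]")
  high <- code >= 7 | gleason_combined >= 8 | psa > 20
  low <- !high & code <= 4 & gleason_combined <= 6 & psa < 10
  grp <- ifelse(high, "high", ifelse(low, "low", "intermediate"))
  factor(grp, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' @rdname nccn_risk_group
#' @return `nccn_risk_code` returns the ordinal code 1/2/3, the three-level
#'   marker used as the baseline comparator in AUC evaluation.
#' @export
nccn_risk_code <- function(t_stage, gleason_combined, psa) {
  as.integer(nccn_risk_group(t_stage, gleason_combined, psa))
}

#' Binary endpoint label at a horizon
#'
#' 1 if the case-defining event occurred by the horizon; 0 if the patient was
#' followed event-free beyond the horizon or had a competing event by the
#' horizon; NA (indeterminate) if censored before the horizon. Indeterminate
#' patients are excluded from classifier training but fully retained in IPCW
#' evaluation.
#'
#' @param time,event follow-up times and event codes (0/1/2).
#' @param horizon horizon in years.
#' @param family "competing" (primary cause is the case event, competing
#'   events are controls) or "all_cause" (any event is a case).
#' @return integer vector of 1, 0, NA.
#' @export
binary_label <- function(time, event, horizon, family = c("competing", "all_cause")) {
  family <- match.arg(family)
  is_case <- if (family == "all_cause") event %in% c(1L, 2L) else event == 1L
  out <- rep(NA_integer_, length(time))
  out[time <= horizon & is_case] <- 1L
  out[time > horizon] <- 0L
  if (family == "competing") out[time <= horizon & event == 2L] <- 0L
  out
}

#' Numeric clinical vector in fixed order
#'
#' Order: gleason_combined, t_stage_code, psa, age, gleason_primary,
#' gleason_secondary (all treated as numerical variables).
#'
#' @param clinical data.frame with columns gleason_combined, t_stage, psa,
#'   age, gleason_primary, gleason_secondary.
#' @return numeric matrix, one row per patient, 6 columns.
#' @export
clinical_vector <- function(clinical) {
  m <- cbind(gleason_combined = as.numeric(clinical$gleason_combined),
             t_stage_code = as.numeric(encode_tstage(clinical$t_stage)),
             psa = as.numeric(clinical$psa),
             age = as.numeric(clinical$age),
             gleason_primary = as.numeric(clinical$gleason_primary),
             gleason_secondary = as.numeric(clinical$gleason_secondary))
  if (any(!is.finite(m))) stop("clinical variables must be finite")
  m
}

FEATURE_VARIANTS <- c("path", "path+NCCN", "path+NCCN+3", "clinical")

#' Assemble the feature matrix for an ablation variant
#'
#' Fixed concatenation order: the 128 image dimensions first, then clinical
#' variables restricted to the variant. Variants: `"path"` (image only, 128),
#' `"path+NCCN"` (+ gleason_combined, t_stage_code, psa; 131),
#' `"path+NCCN+3"` (+ age, gleason_primary, gleason_secondary; 134), and
#' `"clinical"` (the 6 clinical variables only, no image; 6).
#'
#' @param image_features n x 128 matrix of patient image features (may be
#'   NULL for the "clinical" variant).
#' @param clinical clinical data.frame (see [clinical_vector()]); may be NULL
#'   for the "path" variant.
#' @param variant one of `r paste(FEATURE_VARIANTS, collapse=", ")`.
#' @return numeric feature matrix.
#' @export
assemble_features <- function(image_features, clinical, variant = "path+NCCN+3") {
  variant <- match.arg(variant, FEATURE_VARIANTS)
  if (variant != "clinical") {
    if (is.null(image_features)) stop("variant ", variant, " requires image features")
    image_features <- as.matrix(image_features)
    if (ncol(image_features) != 128) stop("image features must have 128 columns")
  }
  if (variant != "path" && is.null(clinical))
    stop("variant ", variant, " requires clinical data")
  cv <- if (variant == "path") NULL else clinical_vector(clinical)
  switch(variant,
    "path" = image_features,
    "path+NCCN" = cbind(image_features, cv[, c("gleason_combined", "t_stage_code", "psa"),
                                           drop = FALSE]),
    "path+NCCN+3" = cbind(image_features, cv),
    "clinical" = cv)
}

#' Risk model configuration (gradient-boosted decision trees)
#'
#' Defaults are the full-scale boosted-tree settings: learning rate 0.003,
#' depth 5, L2 leaf regularization 10, 2000 iterations.
#'
#' @param learning_rate shrinkage per boosting iteration.
#' @param depth maximum tree depth.
#' @param l2_leaf_reg L2 regularization on leaf weights.
#' @param iterations number of boosting rounds (>= 1).
#' @param seed RNG seed; training is deterministic under it (single thread).
#' @return object of class `risk_model_config`.
#' @export
risk_model_config <- function(learning_rate = 0.003, depth = 5L,
                              l2_leaf_reg = 10, iterations = 2000L, seed = 1L) {
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(learning_rate = learning_rate, depth = as.integer(depth),
                 l2_leaf_reg = l2_leaf_reg, iterations = as.integer(iterations),
                 seed = as.integer(seed)), class = "risk_model_config")
}

#' Train a gradient-boosted binary risk model
#'
#' Fits a gradient-boosted decision-tree classifier (logistic objective) on a
#' feature matrix and binary labels. Rows with NA labels (indeterminate at
#' the horizon) are excluded from training.
#'
#' @param features numeric feature matrix (rows = patients).
#' @param labels integer 0/1/NA labels from [binary_label()].
#' @param config a [risk_model_config()].
#' @return object of class `risk_model` wrapping the booster.
#' @export
train_risk_model <- function(features, labels, config = risk_model_config()) {
  features <- as.matrix(features)
  keep <- !is.na(labels)
  x <- features[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) < 2)
    stop("degenerate labels: need both classes among non-indeterminate patients")
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    eta = config$learning_rate,
    max_depth = config$depth,
    lambda = config$l2_leaf_reg,
    nthread = 1,
    seed = config$seed)
  booster <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(x, label = y),
                                nrounds = config$iterations, verbose = 0)
  structure(list(booster = booster, n_features = ncol(features), config = config),
            class = "risk_model")
}

#' Predict risk scores
#'
#' @param model a trained [train_risk_model()] model.
#' @param features feature matrix with the same columns as at training.
#' @return probability-scale risk scores in \[0, 1\].
#' @export
predict_risk <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature length mismatch: model expects ", model$n_features,
         " columns, got ", ncol(features))
  as.numeric(predict(model$booster, features))
}
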