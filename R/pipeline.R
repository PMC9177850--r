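# End-to-end orchestration: simulate -> tile/filter/quilt -> self-supervised
# training -> feature extraction -> fusion -> evaluation, with per-stage
# derived seeds so any stage can be rerun independently.

#' Pipeline run configuration
#'
#' The `desk` profile runs the full architecture at reduced scale (small
#' backbone, 8 x 8 quilt, short SSL schedule); the `paper` profile loads the
#' full-scale hyperparameters (256-px patches, 200 x 200 quilt, lr 0.03
#' cosine over 200 epochs, batch 256, queue 65536, boosted trees
#' 0.003/depth 5/L2 10/2000 rounds) and is provided for completeness — it is
#' compute-bound far beyond interactive use.
#'
#' @param profile "desk" or "paper".
#' @param n_patients cohort size.
#' @param seed global seed; all stage seeds derive from it deterministically.
#' @param out_dir output directory (created); NULL for a temp dir.
#' @param cohort a [cohort_config()] (seed is re-derived from the global
#'   seed).
#' @param imaging an [imaging_config()].
#' @param encoder an [encoder_config()], or a pre-trained `quilt_encoder` to
#'   reuse (the SSL stage is then skipped).
#' @param risk a [risk_model_config()].
#' @param variants ablation feature variants to train.
#' @param endpoints endpoint grid (see [default_endpoints()]).
#' @param split a [split_spec()].
#' @param n_ssl_patches cap on pretraining patches.
#' @param bootstrap_B bootstrap resamples in evaluation.
#' @param keep_slides write slide PNGs under `out_dir` (off by default at
#'   desk scale: slides are streamed through tiling and dropped).
#' @return object of class `run_config`.
#' @export
run_config <- function(profile = c("desk", "paper"), n_patients = 120L, seed = 1L,
                       out_dir = NULL,
                       cohort = NULL, imaging = NULL, encoder = NULL, risk = NULL,
                       variants = c("path", "path+NCCN", "path+NCCN+3", "clinical"),
                       endpoints = default_endpoints(),
                       split = split_spec(),
                       n_ssl_patches = 2000L, bootstrap_B = 500L,
                       keep_slides = FALSE) {
  profile <- match.arg(profile)
  cohort <- cohort %||% cohort_config(n_patients, seed = seed)
  cohort$n_patients <- as.integer(n_patients)
  if (is.null(imaging)) {
    imaging <- if (profile == "paper")
      imaging_config(patch_size = 256L, quilt_rows = 200L, quilt_cols = 200L)
    else imaging_config(quilt_rows = 8L, quilt_cols = 8L)
  }
  if (is.null(encoder)) encoder <- encoder_config(profile)
  if (is.null(risk)) risk <- risk_model_config()
  structure(list(profile = profile, n_patients = as.integer(n_patients),
                 seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, imaging = imaging, encoder = encoder, risk = risk,
                 variants = variants, endpoints = endpoints, split = split,
                 n_ssl_patches = as.integer(n_ssl_patches),
                 bootstrap_B = as.integer(bootstrap_B),
                 keep_slides = keep_slides), class = "run_config")
}

#' Simulate a cohort and extract patient image features
#'
#' Runs the image side of the pipeline: simulates the cohort (streaming: each
#' slide is rendered, tiled, rule-filtered and dropped), applies the seeded
#' quilt-capacity selection per patient, trains the momentum-contrast encoder
#' on usable patches of pretraining-eligible patients (Gleason primary >= 4
#' by default), and mean-pools patch embeddings into one 128-d feature per
#' patient. Patches are cached at the encoder's working resolution.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `patients` (clinical + outcome rows for patients with
#'   usable tissue), `features` (n x 128 matrix), `encoder`, `filter_stats`
#'   (rule-filter agreement with generator ground truth), `selected`
#'   (per-patient selected patches incl. ground-truth labels),
#'   `excluded_patients`, `stage_seeds`.
#' @export
build_patient_features <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[quiltfuse] ", ...)
  stage_seeds <- list(cohort = derive_seed(config$seed, "cohort"),
                      ssl = derive_seed(config$seed, "ssl"),
                      split = derive_seed(config$seed, "split"),
                      eval = derive_seed(config$seed, "eval"))
  ccfg <- config$cohort
  ccfg$seed <- stage_seeds$cohort
  ic <- config$imaging
  work_size <- if (inherits(config$encoder, "quilt_encoder"))
    config$encoder$config$aug_size else config$encoder$aug_size
  patch_store <- new.env(parent = emptyenv())
  filter_ok <- 0L; filter_n <- 0L
  cb <- function(patient_id, slide_id, pixels, sidecar) {
    patches <- tile_image(pixels, ic, slide_id)
    for (p in patches) {
      truth <- sidecar$truth_label[sidecar$row == p$grid_row & sidecar$col == p$grid_col]
      cls <- classify_patch_rule(p, ic)
      filter_n <<- filter_n + 1L
      filter_ok <<- filter_ok + as.integer(cls$usable == (truth %in% c("tissue_a", "tissue_b")))
      if (cls$usable) {
        small <- resize_bilinear(p$pixels, work_size, work_size)
        lst <- patch_store[[patient_id]] %||% list()
        lst[[length(lst) + 1]] <- list(pixels = small, source_slide = slide_id,
                                       grid_row = p$grid_row, grid_col = p$grid_col,
                                       truth = truth)
        patch_store[[patient_id]] <- lst
      }
    }
  }
  say("simulating cohort (n = ", ccfg$n_patients, ") and filtering patches")
  out_dir <- if (config$keep_slides) {
    d <- config$out_dir %||% tempfile("quiltfuse_run_")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  } else NULL
  cohort <- generate_cohort(ccfg, dir = out_dir, slide_callback = cb,
                            keep_slides = FALSE)
  patients <- cohort$patients
  filter_stats <- list(accuracy = filter_ok / filter_n, n_patches = filter_n)
  say(sprintf("tissue filter: %.1f%% agreement with ground truth over %d patches",
              100 * filter_stats$accuracy, filter_stats$n_patches))

  capacity <- ic$quilt_rows * ic$quilt_cols
  selected <- list()
  excluded <- character(0)
  for (pid in patients$patient_id) {
    lst <- patch_store[[pid]] %||% list()
    if (length(lst) == 0) {
      warning("patient ", pid, " has no usable tissue; excluded")
      excluded <- c(excluded, pid)
      next
    }
    sel <- select_quilt_patches(lst, capacity, ic$subsample_seed, pid)
    selected[[pid]] <- lst[sel]
  }
  patients <- patients[!(patients$patient_id %in% excluded), ]

  if (inherits(config$encoder, "quilt_encoder")) {
    encoder <- config$encoder
    say("reusing pre-trained encoder")
  } else {
    ecfg <- config$encoder
    ecfg$seed <- stage_seeds$ssl
    elig <- if (isTRUE(ecfg$pretrain_filter)) {
      patients$patient_id[patients$gleason_primary >= 4]
    } else patients$patient_id
    if (length(elig) == 0)
      stop("no patients pass the pretraining filter (Gleason primary >= 4)")
    pool <- unlist(lapply(selected[elig], function(l) lapply(l, `[[`, "pixels")),
                   recursive = FALSE)
    if (length(pool) > config$n_ssl_patches)
      pool <- pool[with_seed(stage_seeds$ssl, sample(length(pool), config$n_ssl_patches))]
    say("training SSL encoder on ", length(pool), " patches (", ecfg$epochs, " epochs)")
    encoder <- train_ssl(pool, ecfg)
  }

  say("extracting patient image features")
  feats <- matrix(0, nrow(patients), 128L,
                  dimnames = list(patients$patient_id, NULL))
  for (pid in patients$patient_id) {
    emb <- embed_patches(encoder, lapply(selected[[pid]], `[[`, "pixels"))
    feats[pid, ] <- pool_patient_feature(emb)
  }
  list(patients = patients, features = feats, encoder = encoder,
       filter_stats = filter_stats, selected = selected,
       excluded_patients = excluded, stage_seeds = stage_seeds,
       out_dir = out_dir)
}

#' Run the full pipeline
#'
#' [build_patient_features()] followed by the constrained 80/20 split, one
#' boosted risk model per endpoint and ablation variant, and evaluation of
#' every marker against the NCCN ordinal baseline on the validation side.
#' All tabular stage outputs and a manifest (config hash + derived stage
#' seeds) are written to the output directory.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `metrics` (the evaluation table), `patients`,
#'   `features`, `split`, `encoder`, `models`, `filter_stats`,
#'   `excluded_patients`, `out_dir`, `stage_seeds`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[quiltfuse] ", ...)
  out_dir <- config$out_dir %||% tempfile("quiltfuse_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir <- out_dir
  fx <- build_patient_features(config, quiet = quiet)
  patients <- fx$patients; feats <- fx$features
  stage_seeds <- fx$stage_seeds

  sp <- config$split
  sp$seed <- stage_seeds$split
  split <- constrained_split(patients, sp)
  say(sprintf("split accepted after %d tries (validation NCCN AUC %.3f)",
              split$tries, split$achieved_auc))

  tr <- split$train_idx; va <- split$val_idx
  nccn <- nccn_risk_code(patients$t_stage, patients$gleason_combined, patients$psa)
  metrics <- list()
  models <- list()
  for (e in seq_len(nrow(config$endpoints))) {
    fam <- config$endpoints$family[e]; hz <- config$endpoints$horizon[e]
    labels <- binary_label(patients$time, patients$event, hz, fam)
    markers <- list(nccn = nccn[va])
    for (v in config$variants) {
      X <- assemble_features(feats, patients, v)
      rcfg <- config$risk
      rcfg$seed <- derive_seed(config$seed, paste("risk", fam, hz, v))
      model <- tryCatch(train_risk_model(X[tr, , drop = FALSE], labels[tr], rcfg),
                        error = function(err) err)
      if (inherits(model, "error")) {
        warning("endpoint ", fam, "@", hz, " variant ", v, ": ",
                conditionMessage(model))
        next
      }
      models[[paste(fam, hz, v, sep = "|")]] <- model
      markers[[v]] <- predict_risk(model, X[va, , drop = FALSE])
    }
    metrics[[e]] <- evaluate_all(markers, patients$time[va], patients$event[va],
                                 endpoints = data.frame(family = fam, horizon = hz),
                                 baseline = "nccn", B = config$bootstrap_B,
                                 seed = stage_seeds$eval)
  }
  metrics <- do.call(rbind, metrics)

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(patients, file.path(out_dir, "patients.csv"), row.names = FALSE)
  fdf <- as.data.frame(feats)
  names(fdf) <- sprintf("e%03d", seq_len(128))
  utils::write.csv(cbind(patient_id = rownames(feats), fdf),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = patients$patient_id,
                              set = ifelse(seq_len(nrow(patients)) %in% va,
                                           "validation", "train")),
                   file.path(out_dir, "split.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(config[c("profile", "n_patients", "seed", "variants",
                                        "n_ssl_patches", "bootstrap_B")],
                               auto_unbox = TRUE)
  manifest <- list(config_hash = hash_id(as.character(cfg_json)),
                   stage_seeds = stage_seeds,
                   split_achieved_auc = split$achieved_auc,
                   filter_accuracy = fx$filter_stats$accuracy,
                   n_excluded = length(fx$excluded_patients),
                   package_version = as.character(utils::packageVersion("quiltfuse")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format_report(metrics, split, fx$filter_stats),
             file.path(out_dir, "report.md"))
  say("done; outputs in ", out_dir)

  list(metrics = metrics, patients = patients, features = feats, split = split,
       encoder = fx$encoder, models = models, filter_stats = fx$filter_stats,
       excluded_patients = fx$excluded_patients, out_dir = out_dir,
       stage_seeds = stage_seeds, patch_store = fx$selected)
}

format_report <- function(metrics, split, filter_stats) {
  c("# quiltfuse run report", "",
    sprintf("- tissue filter accuracy vs ground truth: %.3f (%d patches)",
            filter_stats$accuracy, filter_stats$n_patches),
    sprintf("- constrained split: validation NCCN AUC %.3f after %d tries",
            split$achieved_auc, split$tries),
    "", "## Validation metrics", "",
    paste("|", paste(names(metrics), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(metrics)), collapse = " | "), "|"),
    vapply(seq_len(nrow(metrics)), function(i) {
      row <- vapply(metrics[i, ], function(x)
        if (is.numeric(x)) sprintf("%.4f", x) else as.character(x), character(1))
      paste("|", paste(row, collapse = " | "), "|")
    }, character(1)))
}

#' Monte-Carlo repeated-split evaluation
#'
#' Held-out evaluation that averages over repeated seeded stratified 80/20
#' splits instead of conditioning on a single draw: at desk-scale cohort
#' sizes a single 20% validation side holds only a handful of events, so
#' single-split AUC contrasts are noise-dominated. For each split, one
#' boosted model per variant is trained on the 80% side and all markers are
#' evaluated on the 20% side; the summary reports per-marker mean AUCs and
#' paired mean differences against the baseline with their Monte-Carlo
#' standard errors across splits.
#'
#' @param patients patient table (clinical + outcomes, as returned by
#'   [build_patient_features()]).
#' @param features n x 128 patient image feature matrix.
#' @param variants ablation variants to train.
#' @param family,horizon endpoint (see [binary_label()]).
#' @param n_splits number of repeated splits.
#' @param train_frac training fraction.
#' @param risk a [risk_model_config()].
#' @param seed split seed; split k uses a seed derived from (seed, k).
#' @return list with `per_split` (long data.frame: split, marker, auc) and
#'   `summary` (marker, mean_auc, and for non-baseline markers the paired
#'   mean difference vs the baseline with its Monte-Carlo se).
#' @export
mc_split_eval <- function(patients, features,
                          variants = c("path", "path+NCCN", "path+NCCN+3", "clinical"),
                          family = "competing", horizon = 5, n_splits = 6L,
                          train_frac = 0.8, risk = risk_model_config(),
                          seed = 1L) {
  labels <- binary_label(patients$time, patients$event, horizon, family)
  nccn <- nccn_risk_code(patients$t_stage, patients$gleason_combined, patients$psa)
  strata <- split(seq_len(nrow(patients)), nccn)
  cause <- if (family == "all_cause") "all" else 1
  Xs <- lapply(stats::setNames(variants, variants), function(v)
    assemble_features(features, patients, v))
  rows <- list()
  for (k in seq_len(n_splits)) {
    va <- with_seed(derive_seed(seed, paste0("mcsplit", k)), {
      sort(unlist(lapply(strata, function(ix) {
        nv <- max(1L, round((1 - train_frac) * length(ix)))
        if (length(ix) == 1) ix else sample(ix, nv)
      })))
    })
    tr <- setdiff(seq_len(nrow(patients)), va)
    aucs <- c(nccn = timedep_auc(nccn[va], patients$time[va], patients$event[va],
                                 horizon, cause = cause, se = FALSE)$auc)
    for (v in variants) {
      rcfg <- risk
      rcfg$seed <- derive_seed(seed, paste("mc", k, v))
      m <- train_risk_model(Xs[[v]][tr, , drop = FALSE], labels[tr], rcfg)
      sc <- predict_risk(m, Xs[[v]][va, , drop = FALSE])
      aucs[v] <- timedep_auc(sc, patients$time[va], patients$event[va],
                             horizon, cause = cause, se = FALSE)$auc
    }
    rows[[k]] <- data.frame(split = k, marker = names(aucs), auc = unname(aucs),
                            stringsAsFactors = FALSE)
  }
  per_split <- do.call(rbind, rows)
  wide <- do.call(cbind, lapply(split(per_split, per_split$marker), `[[`, "auc"))
  summary <- data.frame(marker = colnames(wide),
                        mean_auc = colMeans(wide),
                        diff_vs_nccn = colMeans(wide - wide[, "nccn"]),
                        se_diff = apply(wide - wide[, "nccn"], 2, stats::sd) /
                          sqrt(nrow(wide)),
                        row.names = NULL, stringsAsFactors = FALSE)
  summary$diff_vs_nccn[summary$marker == "nccn"] <- NA
  summary$se_diff[summary$marker == "nccn"] <- NA
  list(per_split = per_split, summary = summary)
}

#' Run the ablation study
#'
#' Trains and evaluates the sequence of feature variants (image-only,
#' + NCCN variables, + remaining clinical variables) on one cohort and
#' returns the comparison table including the NCCN baseline row per
#' endpoint.
#'
#' @param config a [run_config()].
#' @param variants variants to compare.
#' @return the metrics table (one row per endpoint x marker).
#' @export
run_ablation <- function(config, variants = c("path", "path+NCCN", "path+NCCN+3")) {
  config$variants <- variants
  res <- run_pipeline(config)
  res$metrics
}
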