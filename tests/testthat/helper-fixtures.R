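# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no stored image data.

# n texture patches of the two morphology classes, alternating A/B.
make_texture_patches <- function(n, ps = 128L, seed = 42L) {
  quiltfuse:::with_seed(seed, {
    patches <- vector("list", n)
    labels <- logical(n)
    for (i in seq_len(n)) {
      labels[i] <- (i %% 2 == 0)
      patches[[i]] <- quiltfuse:::render_cell_tissue(ps, labels[i])
    }
    list(patches = patches, labels = labels)   # labels TRUE = class B
  })
}

# labeled usable/reject patches for the artifact classifier: tissue A/B are
# usable; whitespace and pen-marked patches are not.
make_labeled_patches <- function(n, ps = 64L, seed = 7L) {
  quiltfuse:::with_seed(seed, {
    patches <- vector("list", n)
    usable <- logical(n)
    for (i in seq_len(n)) {
      kind <- (i %% 4)
      if (kind == 0) {
        patches[[i]] <- array(1, c(ps, ps, 3))              # whitespace
      } else if (kind == 1) {
        patches[[i]] <- quiltfuse:::apply_pen_stroke(
          quiltfuse:::render_cell_tissue(ps, TRUE))          # pen artifact
      } else {
        patches[[i]] <- quiltfuse:::render_cell_tissue(ps, kind == 2)
        usable[i] <- TRUE
      }
    }
    list(patches = patches, usable = usable)
  })
}

# small tabular cohort (no images): clinical + outcomes + latents.
make_tabular_cohort <- function(n, seed = 1L, config = cohort_config(n, seed = seed)) {
  set.seed(seed)
  z_img <- rnorm(n); z_clin <- rnorm(n)
  cl <- sample_clinical(z_img, z_clin, config)
  su <- sample_survival(z_img, z_clin, config)
  cbind(data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   z_img = z_img, z_clin = z_clin), cl, su)
}

# independent O(n^2) IPCW AUC oracle: explicit double loop over case/control
# pairs with product-limit censoring weights computed from first principles.
oracle_ipcw_auc <- function(marker, time, event, horizon) {
  n <- length(time)
  # product-limit estimate of censoring survival, computed by hand
  ut <- sort(unique(time[event == 0]))
  km_t <- c(); km_s <- c(); s <- 1
  for (t in ut) {
    d <- sum(time == t & event == 0)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
    km_t <- c(km_t, t); km_s <- c(km_s, s)
  }
  surv <- function(t) { i <- which(km_t <= t); if (length(i)) km_s[max(i)] else 1 }
  surv_left <- function(t) { i <- which(km_t < t); if (length(i)) km_s[max(i)] else 1 }
  cases <- which(time <= horizon & event == 1)
  ctrls <- c(which(time > horizon), which(time <= horizon & event == 2))
  w_case <- vapply(cases, function(i) 1 / surv_left(time[i]), numeric(1))
  w_ctrl <- vapply(ctrls, function(j) {
    if (time[j] > horizon) 1 / surv(horizon) else 1 / surv_left(time[j])
  }, numeric(1))
  num <- 0
  for (a in seq_along(cases)) for (b in seq_along(ctrls)) {
    mi <- marker[cases[a]]; mj <- marker[ctrls[b]]
    num <- num + w_case[a] * w_ctrl[b] * (as.numeric(mi > mj) + 0.5 * (mi == mj))
  }
  num / (sum(w_case) * sum(w_ctrl))
}
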