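# Synthetic cohort generator: renders slide images whose morphology encodes a
# latent risk component, draws correlated clinical covariates, and simulates
# cause-specific event times with censoring, so the whole pipeline can be
# exercised without clinical data.
#
# Latent model: each patient carries independent standard-normal risk
# components z_img (expressed in slide morphology) and z_clin (expressed in
# the clinical covariates); the total log-hazard of the primary cause is
# beta_img * z_img + beta_clin * z_clin on top of an exponential baseline.

TSTAGE_LEVELS <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed; the full cohort (images included) is a pure
#'   function of the configuration and this seed.
#' @param slides_per_patient_probs probabilities of 1, 2, 3 slides per
#'   patient. The default puts the mode at 2 slides, matching typical biopsy
#'   submissions.
#' @param image_size_px slide edge length in pixels; must be a multiple of
#'   `patch_size`.
#' @param patch_size patch edge length in pixels, used to lay out the
#'   ground-truth label grid.
#' @param beta_img,beta_clin log-hazard effects of the image-expressed and
#'   clinically-expressed risk components.
#' @param lambda1,lambda2 baseline cause-specific exponential hazard rates
#'   per year (primary cause; competing cause). `lambda1 > 0`, `lambda2 >= 0`.
#' @param lambda_cens exponential censoring rate per year (>= 0).
#' @param t_admin administrative follow-up cutoff in years.
#' @param artifact_rate probability that a tissue region is overlaid with an
#'   artifact (pen stroke, blur, or whitespace gap).
#' @param c0,c1 intercept and slope linking `z_img` to the per-patch
#'   probability of aggressive-like (class B) texture via a logistic link.
#' @param psa_a0,psa_a1,psa_sigma parameters of log(PSA) ~
#'   Normal(a0 + a1 * z_clin, sigma).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          slides_per_patient_probs = c(0.25, 0.5, 0.25),
                          image_size_px = 1024L, patch_size = 256L,
                          beta_img = 0.7, beta_clin = 0.7,
                          lambda1 = 0.025, lambda2 = 0.02,
                          lambda_cens = 0.03, t_admin = 15,
                          artifact_rate = 0.1,
                          c0 = 0, c1 = 1.2,
                          psa_a0 = 2.2, psa_a1 = 0.7, psa_sigma = 0.3) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("invalid configuration: n_patients must be >= 1")
  if (lambda1 <= 0) stop("invalid configuration: lambda1 must be > 0")
  if (lambda2 < 0) stop("invalid configuration: lambda2 must be >= 0")
  if (lambda_cens < 0) stop("invalid configuration: lambda_cens must be >= 0")
  if (t_admin <= 0) stop("invalid configuration: t_admin must be > 0")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("invalid configuration: artifact_rate must lie in [0, 1]")
  if (image_size_px %% patch_size != 0)
    stop("invalid configuration: image_size_px must be a multiple of patch_size")
  if (length(slides_per_patient_probs) != 3 || any(slides_per_patient_probs < 0))
    stop("invalid configuration: slides_per_patient_probs must be 3 nonnegative weights")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    slides_per_patient_probs = slides_per_patient_probs / sum(slides_per_patient_probs),
    image_size_px = as.integer(image_size_px), patch_size = as.integer(patch_size),
    beta_img = beta_img, beta_clin = beta_clin,
    lambda1 = lambda1, lambda2 = lambda2, lambda_cens = lambda_cens,
    t_admin = t_admin, artifact_rate = artifact_rate,
    c0 = c0, c1 = c1, psa_a0 = psa_a0, psa_a1 = psa_a1, psa_sigma = psa_sigma
  ), class = "cohort_config")
}

#' Sample clinical covariates given latent risk components
#'
#' Gleason grades follow an ordered-logit model in the mixed score
#' `0.8 * z_clin + 0.2 * z_img`, so grade partially reflects morphology;
#' log(PSA) is Gaussian in `z_clin`; T-stage bins `z_clin` plus noise into the
#' nine clinical categories; age is independent of risk.
#'
#' @param z_img,z_clin numeric vectors of latent components (equal length).
#' @param config a [cohort_config()]. Draws use the current RNG state.
#' @return data.frame with columns age, psa, t_stage, gleason_primary,
#'   gleason_secondary, gleason_combined.
#' @export
sample_clinical <- function(z_img, z_clin, config = cohort_config(1)) {
  n <- length(z_clin)
  s <- 0.8 * z_clin + 0.2 * z_img
  u1 <- 2.4 * s + rlogis(n)
  primary <- 3L + (u1 > 2.0) + (u1 > 5.4)
  u2 <- 1.7 * s + rlogis(n)
  secondary <- 3L + (u2 > 1.7) + (u2 > 5.1)
  psa <- exp(rnorm(n, config$psa_a0 + config$psa_a1 * z_clin, config$psa_sigma))
  v <- 1.3 * z_clin + rnorm(n, 0, 0.45)
  th <- c(-2.6, -2.2, -0.1, 0.7, 1.3, 1.9, 2.5, 3.1)
  t_stage <- TSTAGE_LEVELS[1L + findInterval(v, th)]
  age <- rnorm(n, 68, 6)
  data.frame(age = age, psa = psa, t_stage = t_stage,
             gleason_primary = as.integer(primary),
             gleason_secondary = as.integer(secondary),
             gleason_combined = as.integer(primary + secondary))
}

#' Sample competing-risks survival outcomes given latent risk
#'
#' Latent times: primary cause T1 ~ Exp(lambda1 * exp(beta_img * z_img +
#' beta_clin * z_clin)); competing cause T2 ~ Exp(lambda2); censoring
#' C ~ Exp(lambda_cens). Observed time is the minimum of these and the
#' administrative cutoff; the event code records which occurred first
#' (0 = censored/administrative, 1 = primary, 2 = competing).
#'
#' @param z_img,z_clin latent components.
#' @param config a [cohort_config()].
#' @return data.frame with columns time (years) and event (0/1/2).
#' @export
sample_survival <- function(z_img, z_clin, config) {
  n <- length(z_img)
  rate1 <- config$lambda1 * exp(config$beta_img * z_img + config$beta_clin * z_clin)
  t1 <- rexp(n, rate1)
  t2 <- if (config$lambda2 > 0) rexp(n, config$lambda2) else rep(Inf, n)
  cc <- if (config$lambda_cens > 0) rexp(n, config$lambda_cens) else rep(Inf, n)
  time <- pmin(t1, t2, cc, config$t_admin)
  event <- ifelse(time == t1, 1L, ifelse(time == t2, 2L, 0L))
  data.frame(time = time, event = as.integer(event))
}

# --- slide rendering --------------------------------------------------------

# Draw n random ellipses onto an RGB cell canvas (ps x ps x 3). Each ellipse
# is rasterized only within its bounding box for speed.
draw_ellipses <- function(cell, n, ax_range, ecc_range, margin, base_col, noise_sd) {
  ps <- dim(cell)[1]
  for (i in seq_len(n)) {
    cy <- runif(1, margin, ps - margin)
    cx <- runif(1, margin, ps - margin)
    a <- runif(1, ax_range[1], ax_range[2])
    b <- a * runif(1, ecc_range[1], ecc_range[2])
    th <- runif(1, 0, pi)
    ri <- max(1L, floor(cy - a)):min(ps, ceiling(cy + a))
    ci <- max(1L, floor(cx - a)):min(ps, ceiling(cx + a))
    dy <- matrix(ri - cy, length(ri), length(ci))
    dx <- matrix(ci - cx, length(ri), length(ci), byrow = TRUE)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- (u * u + v * v) <= 1
    npx <- sum(mask)
    if (npx == 0) next
    col <- clip01(base_col + rnorm(3, 0, 0.04))
    noise <- rnorm(npx, 0, noise_sd)
    for (ch in 1:3) {
      m <- cell[ri, ci, ch]
      m[mask] <- clip01(col[ch] + noise)
      cell[ri, ci, ch] <- m
    }
  }
  cell
}

render_cell_tissue <- function(ps, class_b) {
  cell <- array(1, c(ps, ps, 3))
  sc <- ps / 256
  if (class_b) {
    # aggressive-like: dense small irregular dark clusters
    cell <- draw_ellipses(cell, n = sample(75:110, 1),
                          ax_range = c(5, 14) * sc, ecc_range = c(0.35, 1),
                          margin = 14 * sc, base_col = c(0.45, 0.25, 0.55),
                          noise_sd = 0.03)
  } else {
    # benign-like: sparse large regular glands
    cell <- draw_ellipses(cell, n = sample(4:6, 1),
                          ax_range = c(42, 66) * sc, ecc_range = c(0.75, 1),
                          margin = 64 * sc, base_col = c(0.91, 0.64, 0.79),
                          noise_sd = 0.03)
  }
  cell
}

apply_pen_stroke <- function(cell) {
  ps <- dim(cell)[1]
  rr <- matrix(seq_len(ps), ps, ps)
  cc <- matrix(seq_len(ps), ps, ps, byrow = TRUE)
  th <- runif(1, 0, pi)
  w <- runif(1, 34, 52) * ps / 256
  # stroke through the cell centre: covers >= 10% of pixels by construction
  dist <- abs((cc - ps / 2) * sin(th) - (rr - ps / 2) * cos(th))
  mask <- dist < w / 2
  cols <- list(c(0.02, 0.62, 0.08), c(0.02, 0.10, 0.80), c(0.85, 0.03, 0.08))
  col <- cols[[sample(3, 1)]]
  for (ch in 1:3) {
    m <- cell[, , ch]
    m[mask] <- col[ch]
    cell[, , ch] <- m
  }
  cell
}

# Core renderer; consumes the current RNG stream.
render_slide_core <- function(z_img, config) {
  ps <- config$patch_size
  g <- config$image_size_px %/% ps
  n_cells <- g * g
  slide <- array(1, c(config$image_size_px, config$image_size_px, 3))
  labels <- matrix("background", g, g)

  n_regions <- sample(2:5, 1)
  n_regions <- min(n_regions, n_cells)
  region_of <- rep(0L, n_cells)   # cell index (row-major, 1-based) -> region id
  seeds <- sample(n_cells, n_regions)
  region_of[seeds] <- seq_len(n_regions)
  # grow each region by a short random walk over free 4-neighbours
  for (rg in seq_len(n_regions)) {
    cur <- seeds[rg]
    extra <- rbinom(1, 4, 0.5)
    for (k in seq_len(extra)) {
      r0 <- (cur - 1) %/% g; c0 <- (cur - 1) %% g
      nb <- rbind(c(r0 - 1, c0), c(r0 + 1, c0), c(r0, c0 - 1), c(r0, c0 + 1))
      nb <- nb[nb[, 1] >= 0 & nb[, 1] < g & nb[, 2] >= 0 & nb[, 2] < g, , drop = FALSE]
      if (nrow(nb) == 0) break
      cand <- nb[, 1] * g + nb[, 2] + 1
      cand <- cand[region_of[cand] == 0L]
      if (length(cand) == 0) break
      cur <- if (length(cand) == 1) cand else sample(cand, 1)
      region_of[cur] <- rg
    }
  }

  p_b <- plogis(config$c0 + config$c1 * z_img)
  for (idx in which(region_of > 0L)) {
    r0 <- (idx - 1) %/% g; c0 <- (idx - 1) %% g
    class_b <- runif(1) < p_b
    cell <- render_cell_tissue(ps, class_b)
    slide[(r0 * ps + 1):((r0 + 1) * ps), (c0 * ps + 1):((c0 + 1) * ps), ] <- cell
    labels[r0 + 1, c0 + 1] <- if (class_b) "tissue_b" else "tissue_a"
  }
  # region-level artifacts overwrite tissue cells
  for (rg in seq_len(n_regions)) {
    if (runif(1) >= config$artifact_rate) next
    type <- sample(c("pen", "blur", "white"), 1)
    for (idx in which(region_of == rg)) {
      r0 <- (idx - 1) %/% g; c0 <- (idx - 1) %% g
      ri <- (r0 * ps + 1):((r0 + 1) * ps); ci <- (c0 * ps + 1):((c0 + 1) * ps)
      cell <- slide[ri, ci, , drop = FALSE][, , , drop = TRUE]
      dim(cell) <- c(ps, ps, 3)
      cell <- switch(type,
        pen = apply_pen_stroke(cell),
        blur = {
          # defocus simulated at quarter resolution: blur + bilinear upsample
          s4 <- max(16L, ps %/% 4L)
          resize_bilinear(gaussian_blur_img(resize_bilinear(cell, s4, s4),
                                            runif(1, 9, 13) * s4 / 256), ps, ps)
        },
        white = array(1, c(ps, ps, 3)))
      slide[ri, ci, ] <- cell
      labels[r0 + 1, c0 + 1] <- "artifact"
    }
  }
  sidecar <- data.frame(
    row = rep(0:(g - 1), each = g), col = rep(0:(g - 1), times = g),
    truth_label = as.vector(t(labels)), stringsAsFactors = FALSE)
  # row-major order: row varies slowest
  sidecar <- sidecar[order(sidecar$row, sidecar$col), ]
  rownames(sidecar) <- NULL
  list(pixels = slide, sidecar = sidecar)
}

#' Render one synthetic slide
#'
#' Renders a white-background slide with 2 to 5 tissue regions. Each tissue
#' patch cell carries one of two texture classes: class A (sparse, large,
#' regular pale glands; benign-like) or class B (dense, small, irregular dark
#' clusters; aggressive-like), with per-cell class-B probability
#' `plogis(c0 + c1 * z_img)`. With probability `artifact_rate` a region is
#' overlaid with a pen stroke, Gaussian blur, or a whitespace gap. Per-cell
#' ground-truth labels (tissue_a / tissue_b / artifact / background) are
#' returned as a sidecar table with 0-based row-major grid coordinates.
#'
#' @param z_img image-expressed latent risk component (scalar).
#' @param config a [cohort_config()].
#' @param seed integer; the output is a pure function of (z_img, config, seed).
#' @return list with `pixels` (H x W x 3 array in \[0,1\]) and `sidecar`
#'   (data.frame: row, col, truth_label).
#' @export
render_slide <- function(z_img, config, seed = 1L) {
  with_seed(seed, render_slide_core(z_img, config))
}

#' Generate a synthetic cohort
#'
#' Draws latent risk components, clinical covariates, competing-risks
#' outcomes and per-patient slide images. Deterministic: the same
#' configuration (including its seed) reproduces the cohort byte-for-byte.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory. When given, slides are written as
#'   8-bit RGB PNG under `dir/slides/` and four CSV tables are written:
#'   `clinical.csv`, `outcomes.csv`, `manifest.csv` (patient_id, slide_id,
#'   slide_path), and `sidecar.csv` (slide_id, row, col, truth_label).
#' @param slide_callback optional `function(patient_id, slide_id, pixels,
#'   sidecar)` invoked as each slide is rendered. When supplied and
#'   `keep_slides = FALSE`, pixel arrays are not retained in the return value,
#'   which keeps memory flat for large cohorts.
#' @param keep_slides logical; retain rendered pixel arrays in the returned
#'   object (default TRUE when neither `dir` nor `slide_callback` is given).
#' @return object of class `quilt_cohort`: list with `patients` (one row per
#'   patient: ids, latent components, clinical covariates, outcomes, slide
#'   count), `manifest`, `sidecar`, `slides` (named list of pixel arrays or
#'   NULL), `config`, `dir`.
#' @export
generate_cohort <- function(config, dir = NULL, slide_callback = NULL,
                            keep_slides = is.null(dir) && is.null(slide_callback)) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (!is.null(dir)) {
    dir.create(file.path(dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  }
  set.seed(config$seed)
  z_img <- rnorm(n); z_clin <- rnorm(n)
  clinical <- sample_clinical(z_img, z_clin, config)
  outcomes <- sample_survival(z_img, z_clin, config)
  n_slides <- sample(1:3, n, replace = TRUE, prob = config$slides_per_patient_probs)
  ids <- sprintf("P%04d", seq_len(n))

  manifest <- list(); sidecar <- list(); slides <- list()
  for (i in seq_len(n)) {
    for (s in seq_len(n_slides[i])) {
      slide_id <- sprintf("%s_S%d", ids[i], s)
      rend <- render_slide_core(z_img[i], config)
      path <- if (!is.null(dir)) file.path(dir, "slides", paste0(slide_id, ".png")) else NA_character_
      if (!is.null(dir)) png::writePNG(rend$pixels, path)
      if (!is.null(slide_callback)) slide_callback(ids[i], slide_id, rend$pixels, rend$sidecar)
      if (keep_slides) slides[[slide_id]] <- rend$pixels
      manifest[[slide_id]] <- data.frame(patient_id = ids[i], slide_id = slide_id,
                                         slide_path = path, stringsAsFactors = FALSE)
      sc <- rend$sidecar
      sc$slide_id <- slide_id
      sidecar[[slide_id]] <- sc[, c("slide_id", "row", "col", "truth_label")]
    }
  }
  manifest <- do.call(rbind, manifest); rownames(manifest) <- NULL
  sidecar <- do.call(rbind, sidecar); rownames(sidecar) <- NULL
  patients <- cbind(data.frame(patient_id = ids, z_img = z_img, z_clin = z_clin,
                               n_slides = n_slides, stringsAsFactors = FALSE),
                    clinical, outcomes)
  if (!is.null(dir)) {
    utils::write.csv(cbind(patients["patient_id"], clinical), file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(patients["patient_id"], outcomes), file.path(dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(sidecar, file.path(dir, "sidecar.csv"), row.names = FALSE)
  }
  structure(list(config = config, patients = patients, manifest = manifest,
                 sidecar = sidecar, slides = if (keep_slides) slides else NULL,
                 dir = dir),
            class = "quilt_cohort")
}
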