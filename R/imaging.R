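# Patch pipeline: tile slides into fixed-size patches, filter out whitespace
# and artifact patches, assemble a patient's usable patches into a
# fixed-capacity image quilt.

#' Imaging configuration
#'
#' @param patch_size patch edge length in pixels (>= 16).
#' @param quilt_rows,quilt_cols quilt grid size in patches. The full-scale
#'   profile is 200 x 200; the desk default is 8 x 8.
#' @param subsample_seed seed mixed (XOR) with a patient-id hash when a
#'   patient has more usable patches than the quilt holds.
#' @param white_level per-channel value above which a pixel counts as
#'   near-white.
#' @param white_frac fraction of near-white pixels above which a patch is
#'   rejected as whitespace.
#' @param sat_spread max-minus-min channel spread above which a pixel counts
#'   as saturated-hue (pen ink).
#' @param sat_frac fraction of saturated pixels above which a patch is
#'   rejected as artifact.
#' @param blur_var Laplacian-variance threshold below which a patch is
#'   rejected as blurred artifact.
#' @return object of class `imaging_config`.
#' @export
imaging_config <- function(patch_size = 256L, quilt_rows = 8L, quilt_cols = 8L,
                           subsample_seed = 0L,
                           white_level = 0.88, white_frac = 0.85,
                           sat_spread = 0.5, sat_frac = 0.10,
                           blur_var = 2e-4) {
  if (patch_size < 16) stop("patch_size must be >= 16")
  if (quilt_rows * quilt_cols < 1) stop("quilt capacity must be >= 1")
  structure(list(patch_size = as.integer(patch_size),
                 quilt_rows = as.integer(quilt_rows), quilt_cols = as.integer(quilt_cols),
                 subsample_seed = as.integer(subsample_seed),
                 white_level = white_level, white_frac = white_frac,
                 sat_spread = sat_spread, sat_frac = sat_frac, blur_var = blur_var),
            class = "imaging_config")
}

#' Tile an image into fixed-size patches
#'
#' Lays a contiguous, non-overlapping grid over the image in raster order.
#' Partial tiles at the right/bottom edges are dropped so every patch has the
#' exact configured shape.
#'
#' @param image H x W x 3 array with values in \[0, 1\].
#' @param config an [imaging_config()].
#' @param slide_id identifier recorded in each patch's provenance.
#' @return list of patches; each is a list with `pixels`
#'   (patch_size x patch_size x 3), `source_slide`, and 0-based `grid_row`,
#'   `grid_col`. An image smaller than one patch yields an empty list with a
#'   warning.
#' @export
tile_image <- function(image, config = imaging_config(), slide_id = "slide") {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be an H x W x 3 array")
  ps <- config$patch_size
  nr <- d[1] %/% ps; nc <- d[2] %/% ps
  if (nr == 0 || nc == 0) {
    warning("image smaller than one patch; no patches produced")
    return(list())
  }
  patches <- vector("list", nr * nc)
  k <- 1L
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
    px <- image[(r * ps + 1):((r + 1) * ps), (c * ps + 1):((c + 1) * ps), , drop = FALSE]
    dim(px) <- c(ps, ps, 3)
    patches[[k]] <- list(pixels = clip01(px), source_slide = slide_id,
                         grid_row = r, grid_col = c)
    k <- k + 1L
  }
  patches
}

# Variance of the 4-neighbour Laplacian of the grayscale patch; sharp tissue
# edges give values orders of magnitude above heavily blurred tissue.
laplacian_variance <- function(pixels) {
  g <- rgb_to_gray(pixels)
  n <- nrow(g); m <- ncol(g)
  if (n < 3 || m < 3) return(0)
  core <- g[2:(n - 1), 2:(m - 1)]
  lap <- g[1:(n - 2), 2:(m - 1)] + g[3:n, 2:(m - 1)] +
         g[2:(n - 1), 1:(m - 2)] + g[2:(n - 1), 3:m] - 4 * core
  stats::var(as.vector(lap))
}

#' Rule-based patch usability filter
#'
#' Classifies a patch as usable tissue or rejects it as whitespace or
#' artifact, using three deterministic rules: (1) whitespace if the fraction
#' of near-white pixels exceeds `white_frac`; (2) artifact if the fraction of
#' saturated-hue pixels (pen ink) exceeds `sat_frac`; (3) artifact if the
#' Laplacian variance falls below `blur_var` (out-of-focus). All thresholds
#' live in [imaging_config()].
#'
#' @param patch a patch from [tile_image()] or a bare pixel array.
#' @param config an [imaging_config()].
#' @return list with `usable` (logical) and `reason` (NA, "whitespace" or
#'   "artifact").
#' @export
classify_patch_rule <- function(patch, config = imaging_config()) {
  px <- if (is.list(patch)) patch$pixels else patch
  npx <- dim(px)[1] * dim(px)[2]
  near_white <- (px[, , 1] > config$white_level) & (px[, , 2] > config$white_level) &
                (px[, , 3] > config$white_level)
  if (mean(near_white) > config$white_frac)
    return(list(usable = FALSE, reason = "whitespace"))
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  if (mean((mx - mn) > config$sat_spread) > config$sat_frac)
    return(list(usable = FALSE, reason = "artifact"))
  if (laplacian_variance(px) < config$blur_var)
    return(list(usable = FALSE, reason = "artifact"))
  list(usable = TRUE, reason = NA_character_)
}

#' Filter a list of patches, keeping usable tissue
#'
#' @param patches list of patches from [tile_image()].
#' @param config an [imaging_config()].
#' @param classifier optional trained [train_artifact_classifier()] model;
#'   by default the deterministic rule filter is used.
#' @return list of usable patches; rejected patches are dropped. The reject
#'   reasons are attached as attribute `"reasons"` (one per input patch,
#'   NA for kept patches).
#' @export
filter_patches <- function(patches, config = imaging_config(), classifier = NULL) {
  if (length(patches) == 0) return(patches)
  if (is.null(classifier)) {
    cls <- lapply(patches, classify_patch_rule, config = config)
    keep <- vapply(cls, `[[`, logical(1), "usable")
    reasons <- vapply(cls, `[[`, character(1), "reason")
  } else {
    keep <- predict_artifact(classifier, patches)
    reasons <- ifelse(keep, NA_character_, "rejected")
  }
  out <- patches[keep]
  attr(out, "reasons") <- reasons
  out
}

# --- trainable artifact classifier -----------------------------------------

#' Configuration for the trainable artifact classifier
#'
#' Defaults follow a standard step-decay SGD recipe: 25 epochs, learning rate
#' 0.001, multiplied by `gamma` every `step_every` epochs. `gamma = 0.1` is
#' the conventional step decay; a literal multiply-by-0.9 reading is available
#' by setting `gamma = 0.9`.
#'
#' @param epochs training epochs (>= 1).
#' @param lr SGD learning rate.
#' @param gamma multiplicative learning-rate decay factor in (0, 1].
#' @param step_every apply the decay every this many epochs.
#' @param batch_size minibatch size.
#' @param input_size patches are resized to this edge length before entering
#'   the network.
#' @param widths channel widths of the convolutional blocks.
#' @param val_frac held-out fraction for the reported validation accuracy.
#' @param seed RNG seed; training is deterministic under it.
#' @return object of class `artifact_classifier_config`.
#' @export
artifact_classifier_config <- function(epochs = 25L, lr = 0.001, gamma = 0.1,
                                       step_every = 7L, batch_size = 64L,
                                       input_size = 32L, widths = c(8L, 16L, 32L),
                                       val_frac = 0.2, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  structure(list(epochs = as.integer(epochs), lr = lr, gamma = gamma,
                 step_every = as.integer(step_every), batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), widths = as.integer(widths),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "artifact_classifier_config")
}

#' Train a small convolutional patch usability classifier
#'
#' Supervised alternative to [classify_patch_rule()], for settings where
#' labeled patches are available. Trains a small conv net (grouped
#' normalization, ReLU, global average pooling, linear head) by SGD with
#' momentum and step-decayed learning rate.
#'
#' @param patches list of patches (or bare pixel arrays).
#' @param labels logical vector: TRUE = usable tissue, FALSE = whitespace or
#'   artifact.
#' @param config an [artifact_classifier_config()].
#' @return object of class `artifact_classifier` with elements `net`,
#'   `config`, `val_accuracy` (held-out accuracy), `loss_history`.
#' @export
train_artifact_classifier <- function(patches, labels, config = artifact_classifier_config()) {
  labels <- as.logical(labels)
  stopifnot(length(patches) == length(labels))
  if (length(unique(labels)) < 2) stop("need both classes present in labels")
  px <- lapply(patches, function(p) {
    pix <- if (is.list(p)) p$pixels else p
    resize_bilinear(pix, config$input_size, config$input_size)
  })
  with_seed(config$seed, {
    n <- length(px)
    idx <- sample(n)
    n_val <- max(1L, floor(config$val_frac * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    net <- cnn_init(config$input_size, 3L, widths = config$widths,
                    head_dims = 2L, groups = min(4L, min(config$widths)),
                    seed = sample.int(2^31 - 1, 1))
    state <- sgd_state(net$params)
    y <- as.integer(labels) + 1L   # 1 = reject, 2 = usable
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr * config$gamma^((ep - 1) %/% config$step_every)
      ord <- sample(tr_idx)
      losses <- c()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        if (length(bi) < 2) next
        x <- stack_images(px[bi])
        fw <- cnn_forward(net$params, net$arch, x)
        logits <- fw$out
        p <- exp(logits - apply(logits, 1, max))
        p <- p / rowSums(p)
        yb <- y[bi]
        losses <- c(losses, mean(-log(pmax(p[cbind(seq_along(bi), yb)], 1e-12))))
        dlog <- p
        dlog[cbind(seq_along(bi), yb)] <- dlog[cbind(seq_along(bi), yb)] - 1
        dlog <- dlog / length(bi)
        gr <- cnn_backward(net$params, net$arch, fw$cache, dlog)
        upd <- sgd_step(net$params, gr, state, lr)
        net$params <- upd$params; state <- upd$state
      }
      loss_hist[ep] <- mean(losses)
    }
    model <- structure(list(net = net, config = config), class = "artifact_classifier")
    val_pred <- predict_artifact(model, px[val_idx])
    model$val_accuracy <- mean(val_pred == labels[val_idx])
    model$loss_history <- loss_hist
    model
  })
}

#' Predict patch usability with a trained artifact classifier
#'
#' @param model an `artifact_classifier`.
#' @param patches list of patches or pixel arrays.
#' @return logical vector, TRUE = usable.
#' @export
predict_artifact <- function(model, patches) {
  s <- model$config$input_size
  px <- lapply(patches, function(p) {
    pix <- if (is.list(p)) p$pixels else p
    resize_bilinear(pix, s, s)
  })
  out <- logical(length(px))
  for (b0 in seq(1, length(px), by = 256)) {
    bi <- b0:min(b0 + 255, length(px))
    x <- stack_images(px[bi])
    logits <- cnn_forward(model$net$params, model$net$arch, x, keep_cache = FALSE)$out
    out[bi] <- logits[, 2] > logits[, 1]
  }
  out
}

# --- quilt assembly ---------------------------------------------------------

# Canonical patch order: slides by id, patches within a slide by
# (grid_row, grid_col); returns the ordered indices of the patches that go
# into a quilt of the given capacity (seeded uniform subsample on overflow).
select_quilt_patches <- function(patches, capacity, subsample_seed, patient_id) {
  ord <- order(vapply(patches, `[[`, character(1), "source_slide"),
               vapply(patches, function(p) p$grid_row, numeric(1)),
               vapply(patches, function(p) p$grid_col, numeric(1)))
  if (length(ord) <= capacity) return(ord)
  seed <- bitwXor(as.integer(subsample_seed), hash_id(patient_id))
  sel <- with_seed(seed, sample(length(ord), capacity))
  ord[sort(sel)]
}

#' Assemble a patient's usable patches into an image quilt
#'
#' Patches are placed in raster order: slides ordered by slide id, patches
#' within a slide by (grid_row, grid_col). If the patient has more usable
#' patches than the quilt holds, a uniform random subsample of exactly the
#' capacity is taken, seeded by `subsample_seed` XOR a hash of the patient
#' id (so the selection is reproducible per patient). If fewer, the trailing
#' cells are pure-white padding with `usable_mask = FALSE`.
#'
#' @param patches list of usable patches sharing one patch size.
#' @param config an [imaging_config()].
#' @param patient_id patient identifier (seeds the overflow subsample).
#' @return object of class `image_quilt`: `pixels`
#'   ((quilt_rows * patch_size) x (quilt_cols * patch_size) x 3),
#'   `usable_mask` (quilt_rows x quilt_cols), and `provenance` (data.frame
#'   with cell_row, cell_col, source_slide, grid_row, grid_col; PAD cells
#'   have NA provenance).
#' @export
build_quilt <- function(patches, config = imaging_config(), patient_id = "patient") {
  if (length(patches) == 0) stop("no usable tissue for patient ", patient_id)
  ps <- config$patch_size
  stopifnot(all(vapply(patches, function(p) all(dim(p$pixels)[1:2] == ps), logical(1))))
  capacity <- config$quilt_rows * config$quilt_cols
  sel <- select_quilt_patches(patches, capacity, config$subsample_seed, patient_id)
  pix <- array(1, c(config$quilt_rows * ps, config$quilt_cols * ps, 3))
  mask <- matrix(FALSE, config$quilt_rows, config$quilt_cols)
  prov <- data.frame(cell_row = rep(0:(config$quilt_rows - 1), each = config$quilt_cols),
                     cell_col = rep(0:(config$quilt_cols - 1), times = config$quilt_rows),
                     source_slide = NA_character_, grid_row = NA_integer_,
                     grid_col = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(sel)) {
    p <- patches[[sel[k]]]
    r <- (k - 1) %/% config$quilt_cols; c <- (k - 1) %% config$quilt_cols
    pix[(r * ps + 1):((r + 1) * ps), (c * ps + 1):((c + 1) * ps), ] <- p$pixels
    mask[r + 1, c + 1] <- TRUE
    prov[k, c("source_slide", "grid_row", "grid_col")] <-
      list(p$source_slide, p$grid_row, p$grid_col)
  }
  structure(list(pixels = pix, usable_mask = mask, provenance = prov,
                 patch_size = ps, patient_id = patient_id),
            class = "image_quilt")
}
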