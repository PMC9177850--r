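# Momentum-contrast self-supervised patch encoder. Two augmented views of
# each patch are pushed through a query and a key network; the InfoNCE loss
# contrasts the positive pair against a FIFO queue of negative key
# embeddings; the key network trails the query network by an exponential
# moving average (momentum update). Embeddings are 128-d and L2-normalized.
#
# The desk backbone is a small grouped-normalization conv net (~10^5
# parameters) trained single-threaded for determinism; the full-scale
# profile mirrors a 50-layer residual network recipe (lr 0.03, cosine
# schedule, 200 epochs, batch 256, queue 65536) and is configuration only.

#' Self-supervised encoder configuration
#'
#' @param profile "desk" (default; small backbone, short schedule) or
#'   "paper" (full-scale hyperparameters; compute-bound, not used in tests).
#' @param feature_dim embedding dimension; fixed at 128.
#' @param temperature InfoNCE temperature (> 0), default 0.2.
#' @param momentum key-network momentum in \[0, 1\], default 0.999.
#' @param queue_size number of negative embeddings held (>= batch_size).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr SGD learning rate, cosine-annealed over training.
#' @param input_size patch edge length fed to the network.
#' @param aug_size working resolution at which views are augmented.
#' @param widths conv block widths of the desk backbone.
#' @param groups group-normalization groups.
#' @param pretrain_filter logical: restrict pretraining patches to patients
#'   with Gleason primary >= 4 (class-imbalance guard); configurable off for
#'   small cohorts.
#' @param seed training seed.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(profile = c("desk", "paper"), feature_dim = 128L,
                           temperature = 0.2, momentum = 0.999,
                           queue_size = NULL, batch_size = NULL, epochs = NULL,
                           lr = 0.03, input_size = 32L, aug_size = 64L,
                           widths = c(12L, 24L, 48L, 96L), groups = 4L,
                           pretrain_filter = TRUE, seed = 1L) {
  profile <- match.arg(profile)
  if (feature_dim != 128L) stop("feature_dim is fixed at 128")
  if (temperature <= 0) stop("temperature must be > 0")
  if (momentum < 0 || momentum > 1) stop("momentum must lie in [0, 1]")
  queue_size <- queue_size %||% if (profile == "desk") 1024L else 65536L
  batch_size <- batch_size %||% if (profile == "desk") 64L else 256L
  epochs <- epochs %||% if (profile == "desk") 10L else 200L
  if (queue_size < batch_size) stop("queue_size must be >= batch_size")
  structure(list(profile = profile, feature_dim = 128L, temperature = temperature,
                 momentum = momentum, queue_size = as.integer(queue_size),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, input_size = as.integer(input_size),
                 aug_size = as.integer(aug_size), widths = as.integer(widths),
                 groups = as.integer(groups), pretrain_filter = pretrain_filter,
                 seed = as.integer(seed)), class = "encoder_config")
}

#' Augmentation policy for contrastive views
#'
#' The standard contrastive recipe: random resized crop (area scale
#' \[0.2, 1\]), horizontal flip, color jitter (brightness/contrast/
#' saturation), random grayscale, Gaussian blur.
#'
#' @param crop_scale area-scale range of the random resized crop.
#' @param flip_p horizontal flip probability.
#' @param jitter_p,jitter_strength color-jitter probability and maximum
#'   relative perturbation of brightness, contrast and saturation.
#' @param gray_p random-grayscale probability.
#' @param blur_p,blur_sigma Gaussian-blur probability and sigma range (in
#'   pixels at the working resolution).
#' @return object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(crop_scale = c(0.2, 1.0), flip_p = 0.5,
                                jitter_p = 0.8, jitter_strength = 0.4,
                                gray_p = 0.2, blur_p = 0.5,
                                blur_sigma = c(0.1, 2.0)) {
  structure(list(crop_scale = crop_scale, flip_p = flip_p, jitter_p = jitter_p,
                 jitter_strength = jitter_strength, gray_p = gray_p,
                 blur_p = blur_p, blur_sigma = blur_sigma),
            class = "augmentation_policy")
}

# Draw one augmented view at resolution out_size, consuming the current RNG.
make_view <- function(img, policy, out_size) {
  d <- dim(img)
  # random resized crop
  scale <- runif(1, policy$crop_scale[1], policy$crop_scale[2])
  ratio <- exp(runif(1, log(3 / 4), log(4 / 3)))
  ch <- min(d[1], round(sqrt(scale * d[1] * d[2] / ratio)))
  cw <- min(d[2], round(sqrt(scale * d[1] * d[2] * ratio)))
  ch <- max(ch, 2L); cw <- max(cw, 2L)
  r0 <- if (d[1] > ch) sample.int(d[1] - ch + 1L, 1L) else 1L
  c0 <- if (d[2] > cw) sample.int(d[2] - cw + 1L, 1L) else 1L
  v <- img[r0:(r0 + ch - 1), c0:(c0 + cw - 1), , drop = FALSE]
  v <- resize_bilinear(v, out_size, out_size)
  if (runif(1) < policy$flip_p) v <- v[, out_size:1, , drop = FALSE]
  if (runif(1) < policy$jitter_p) {
    s <- policy$jitter_strength
    v <- v * runif(1, 1 - s, 1 + s)                       # brightness
    v <- (v - mean(v)) * runif(1, 1 - s, 1 + s) + mean(v) # contrast
    g <- rgb_to_gray(v)
    alpha <- runif(1, 1 - s, 1 + s)                       # saturation
    for (c in 1:3) v[, , c] <- alpha * v[, , c] + (1 - alpha) * g
    v <- clip01(v)
  }
  if (runif(1) < policy$gray_p) {
    g <- rgb_to_gray(v)
    for (c in 1:3) v[, , c] <- g
  }
  if (runif(1) < policy$blur_p)
    v <- gaussian_blur_img(v, runif(1, policy$blur_sigma[1], policy$blur_sigma[2]))
  clip01(v)
}

#' Draw a random augmented view of a patch
#'
#' Deterministic under `seed`; the view has the same shape as the input.
#' With all transform probabilities 0 and crop scale fixed at 1 the view
#' equals the input exactly.
#'
#' @param patch H x W x 3 pixel array (or a patch list from [tile_image()]).
#' @param policy an [augmentation_policy()].
#' @param seed integer seed for this draw.
#' @return augmented H x W x 3 array with values in \[0, 1\].
#' @export
augment <- function(patch, policy = augmentation_policy(), seed = 1L) {
  px <- if (is.list(patch)) patch$pixels else patch
  with_seed(seed, make_view(px, policy, dim(px)[1]))
}

#' InfoNCE contrastive loss
#'
#' \deqn{-\log \frac{\exp(q \cdot k_+ / \tau)}{\exp(q \cdot k_+ / \tau) +
#' \sum_{k \in queue} \exp(q \cdot k / \tau)}}
#' With uniform logits (all dot products equal) the loss is
#' \eqn{\ln(K + 1)} for a queue of size K.
#'
#' @param q query embedding (length-128 unit vector, or B x 128 matrix).
#' @param k_pos positive key embedding, same shape as `q`.
#' @param queue K x 128 matrix of negative embeddings.
#' @param tau temperature (> 0).
#' @return mean loss (nonnegative scalar).
#' @export
infonce_loss <- function(q, k_pos, queue, tau = 0.2) {
  if (tau <= 0) stop("temperature must be > 0")
  if (is.null(dim(q))) q <- matrix(q, 1)
  if (is.null(dim(k_pos))) k_pos <- matrix(k_pos, 1)
  logits <- cbind(rowSums(q * k_pos), q %*% t(queue)) / tau
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[, 1])
}

#' Momentum update of the key network parameters
#'
#' Each key parameter moves to `m * key + (1 - m) * query`; with m = 1 the
#' key is unchanged, with m = 0 it copies the query. Every updated value lies
#' between the previous key value and the query value (convex combination).
#'
#' @param query_params,key_params congruent (nested) lists of numeric arrays.
#' @param m momentum in \[0, 1\].
#' @return updated key parameter list.
#' @export
momentum_update <- function(query_params, key_params, m) {
  if (m < 0 || m > 1) stop("momentum must lie in [0, 1]")
  if (is.numeric(query_params)) {
    if (length(query_params) != length(key_params)) stop("parameter shape mismatch")
    return(m * key_params + (1 - m) * query_params)
  }
  if (length(query_params) != length(key_params) ||
      !identical(names(query_params), names(key_params)))
    stop("parameter shape mismatch")
  mapply(momentum_update, query_params, key_params,
         MoreArgs = list(m = m), SIMPLIFY = FALSE)
}

# Forward pass to normalized embeddings; returns cache for backprop.
encode_batch <- function(params, arch, x, keep_cache = FALSE) {
  fw <- cnn_forward(params, arch, x, keep_cache = keep_cache)
  u <- fw$out
  nrm <- sqrt(rowSums(u * u))
  list(emb = u / nrm, u = u, nrm = nrm, cache = fw$cache)
}

#' Train the momentum-contrast patch encoder
#'
#' Maintains a FIFO queue of negative key embeddings (seeded before the first
#' step by embedding random batches with the key network), updates the key
#' network by [momentum_update()] after every SGD step on the query network,
#' and anneals the learning rate on a cosine schedule. Deterministic under
#' the config seed on a single worker. The per-epoch mean InfoNCE loss is
#' recorded.
#'
#' @param patches list of patch pixel arrays (or patch lists); these should
#'   already be the usable-tissue patches of the pretraining patients.
#' @param config an [encoder_config()].
#' @param policy an [augmentation_policy()].
#' @return object of class `quilt_encoder` with elements `arch`, `params`,
#'   `config`, `loss_history` (per-epoch mean loss).
#' @export
train_ssl <- function(patches, config = encoder_config(), policy = augmentation_policy()) {
  if (length(patches) == 0) stop("empty patch store (after pretraining filter)")
  px <- lapply(patches, function(p) {
    pix <- if (is.list(p)) p$pixels else p
    resize_bilinear(pix, config$aug_size, config$aug_size)
  })
  n <- length(px)
  with_seed(config$seed, {
    net <- cnn_init(config$input_size, 3L, widths = config$widths,
                    head_dims = c(128L, 128L), groups = config$groups,
                    seed = sample.int(2^31 - 1, 1))
    k_params <- net$params
    state <- sgd_state(net$params)
    # queue warm-up: key embeddings of random batches
    queue <- matrix(0, config$queue_size, 128L)
    filled <- 0L
    while (filled < config$queue_size) {
      bi <- sample.int(n, min(config$batch_size, config$queue_size - filled), replace = TRUE)
      xv <- stack_images(lapply(px[bi], make_view, policy = policy,
                                out_size = config$input_size))
      ek <- encode_batch(k_params, net$arch, xv)
      queue[(filled + 1):(filled + length(bi)), ] <- ek$emb
      filled <- filled + length(bi)
    }
    steps_per_epoch <- max(1L, n %/% config$batch_size)
    total_steps <- config$epochs * steps_per_epoch
    step <- 0L
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_losses <- numeric(0)
      for (b in seq_len(steps_per_epoch)) {
        bi <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
        B <- length(bi)
        lr <- config$lr * 0.5 * (1 + cos(pi * step / total_steps))
        step <- step + 1L
        x_q <- stack_images(lapply(px[bi], make_view, policy = policy,
                                   out_size = config$input_size))
        x_k <- stack_images(lapply(px[bi], make_view, policy = policy,
                                   out_size = config$input_size))
        eq <- encode_batch(net$params, net$arch, x_q, keep_cache = TRUE)
        ek <- encode_batch(k_params, net$arch, x_k)
        logits <- cbind(rowSums(eq$emb * ek$emb), eq$emb %*% t(queue)) / config$temperature
        mx <- apply(logits, 1, max)
        p <- exp(logits - mx)
        p <- p / rowSums(p)
        ep_losses <- c(ep_losses, mean(-log(pmax(p[, 1], 1e-12))))
        dlogit <- p
        dlogit[, 1] <- dlogit[, 1] - 1
        dlogit <- dlogit / (B * config$temperature)
        demb <- dlogit[, 1] * ek$emb + dlogit[, -1, drop = FALSE] %*% queue
        # through L2 normalization: q = u / |u|
        du <- (demb - eq$emb * rowSums(demb * eq$emb)) / eq$nrm
        gr <- cnn_backward(net$params, net$arch, eq$cache, du)
        upd <- sgd_step(net$params, gr, state, lr)
        net$params <- upd$params; state <- upd$state
        k_params <- momentum_update(net$params, k_params, config$momentum)
        # FIFO enqueue of this step's key embeddings
        queue <- rbind(queue[-(seq_len(B)), , drop = FALSE], ek$emb)
      }
      loss_hist[ep] <- mean(ep_losses)
    }
    structure(list(arch = net$arch, params = net$params, config = config,
                   loss_history = loss_hist), class = "quilt_encoder")
  })
}

#' Embed one patch
#'
#' Inference-mode forward pass: deterministic, unit L2 norm, 128 dimensions.
#'
#' @param encoder a trained [train_ssl()] encoder.
#' @param patch pixel array (any square size >= the encoder input; resized
#'   internally) or a patch list.
#' @return length-128 unit-norm numeric vector.
#' @export
embed_patch <- function(encoder, patch) {
  as.numeric(embed_patches(encoder, list(patch)))
}

#' Embed a list of patches (batched)
#'
#' @param encoder a trained encoder.
#' @param patches list of pixel arrays or patch lists.
#' @param batch_size forward-pass batch size.
#' @return n x 128 matrix of unit-norm embeddings.
#' @export
embed_patches <- function(encoder, patches, batch_size = 256L) {
  s <- encoder$config$input_size
  px <- lapply(patches, function(p) {
    pix <- if (is.list(p)) p$pixels else p
    d <- dim(pix)
    if (length(d) != 3 || d[3] != 3) stop("patch must be an H x W x 3 array")
    resize_bilinear(pix, s, s)
  })
  out <- matrix(0, length(px), 128L)
  for (b0 in seq(1, length(px), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, length(px))
    e <- encode_batch(encoder$params, encoder$arch, stack_images(px[bi]))
    out[bi, ] <- e$emb
  }
  out
}

#' Linear probe on frozen embeddings
#'
#' Fits a ridge-regularized logistic regression on frozen patch embeddings
#' and reports held-out accuracy — the standard check that a self-supervised
#' embedding captures the relevant structure (here: texture class) without
#' labels having entered training.
#'
#' @param embeddings n x 128 embedding matrix.
#' @param labels binary labels (logical or 0/1).
#' @param train_frac fraction used to fit the probe.
#' @param seed split seed.
#' @return list with `accuracy` (held-out), `train_idx`.
#' @export
linear_probe <- function(embeddings, labels, train_frac = 0.7, seed = 1L) {
  y <- as.integer(as.logical(labels))
  n <- nrow(embeddings)
  with_seed(seed, {
    idx <- sample(n)
    ntr <- floor(train_frac * n)
    tr <- idx[seq_len(ntr)]; te <- idx[-seq_len(ntr)]
    fit <- glmnet::glmnet(embeddings[tr, ], y[tr], family = "binomial",
                          alpha = 0, lambda = 1e-3)
    pred <- as.numeric(predict(fit, embeddings[te, ], type = "response")) > 0.5
    list(accuracy = mean(pred == (y[te] == 1)), train_idx = tr)
  })
}
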