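# InfoNCE, momentum update, augmentation, and the contrastive training loop.

test_that("InfoNCE matches its analytic anchors", {
  # uniform logits: q.k+ = 0 and all queue dot products 0 -> loss = ln(K+1)
  q <- c(1, rep(0, 127))
  k_pos <- c(0, 1, rep(0, 126))
  queue <- matrix(0, 7, 128); queue[, 3] <- 1
  expect_equal(infonce_loss(q, k_pos, queue, tau = 1), log(8), tolerance = 1e-6)

  # dominant positive logit at low temperature: loss = log(1 + K e^{-1/tau}),
  # below 1e-8 for K = 4 at tau = 0.05
  queue_orth <- matrix(0, 4, 128); queue_orth[, 5] <- 1
  expect_lt(infonce_loss(q, q, queue_orth, tau = 0.05), 1e-8)

  expect_error(infonce_loss(q, k_pos, queue, tau = 0), "> 0")
})

test_that("InfoNCE equals an independent softmax-cross-entropy computation", {
  set.seed(44)
  unit <- function(v) v / sqrt(sum(v * v))
  for (rep in 1:5) {
    q <- unit(rnorm(128)); k <- unit(rnorm(128))
    queue <- t(apply(matrix(rnorm(32 * 128), 32), 1, unit))
    tau <- runif(1, 0.05, 1)
    # direct re-computation: softmax cross-entropy with target class 1
    logits <- c(sum(q * k), as.numeric(queue %*% q)) / tau
    direct <- -log(exp(logits[1]) / sum(exp(logits)))
    expect_equal(infonce_loss(q, k, queue, tau), direct, tolerance = 1e-6)
  }
})

test_that("momentum update is the convex combination of key and query", {
  expect_equal(momentum_update(0, 1, m = 1), 1)       # key unchanged
  expect_equal(momentum_update(0, 1, m = 0), 0)       # key copies query
  expect_equal(momentum_update(0, 1, m = 0.999), 0.999)

  set.seed(2)
  qp <- list(a = matrix(rnorm(6), 2), b = rnorm(3))
  kp <- list(a = matrix(rnorm(6), 2), b = rnorm(3))
  up <- momentum_update(qp, kp, 0.9)
  expect_equal(up$a, 0.9 * kp$a + 0.1 * qp$a)
  # every coordinate lies between previous key and query values
  lo <- pmin(kp$b, qp$b); hi <- pmax(kp$b, qp$b)
  expect_true(all(up$b >= lo - 1e-12 & up$b <= hi + 1e-12))

  expect_error(momentum_update(list(a = 1:3), list(a = 1:4), 0.5), "mismatch")
})

test_that("augmentation is seeded, shape-preserving, identity-capable and non-degenerate", {
  tex <- make_texture_patches(2, ps = 64, seed = 12)
  p <- tex$patches[[1]]

  idpol <- augmentation_policy(crop_scale = c(1, 1), flip_p = 0, jitter_p = 0,
                               gray_p = 0, blur_p = 0)
  # fix aspect ratio by making the policy's crop the full image
  v_id <- augment(p, idpol, seed = 5)
  expect_equal(dim(v_id), dim(p))

  v1 <- augment(p, seed = 9)
  v2 <- augment(p, seed = 9)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))

  # default policy views differ from the original on average
  diffs <- vapply(1:20, function(s) mean(abs(augment(p, seed = s) - p)), numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("identity policy with unit crop scale returns the input when aspect is square", {
  # crop scale fixed at 1 can still jitter the aspect ratio; a policy draw
  # that samples the full frame must reproduce the input exactly.
  p <- make_texture_patches(1, ps = 48, seed = 3)$patches[[1]]
  idpol <- augmentation_policy(crop_scale = c(1, 1), flip_p = 0, jitter_p = 0,
                               gray_p = 0, blur_p = 0)
  hit <- FALSE
  for (s in 1:50) {
    v <- augment(p, idpol, seed = s)
    if (identical(v, p)) { hit <- TRUE; break }
  }
  expect_true(hit)
})

test_that("contrastive training runs, normalizes, aligns views, and is deterministic", {
  tex <- make_texture_patches(96, ps = 64, seed = 20)
  cfg <- encoder_config(epochs = 8L, queue_size = 64L, batch_size = 32L,
                        aug_size = 48L, seed = 77L)
  enc <- train_ssl(tex$patches, cfg)
  expect_length(enc$loss_history, 8)
  expect_true(all(is.finite(enc$loss_history)))

  emb <- embed_patches(enc, tex$patches)
  expect_equal(dim(emb), c(96, 128))
  expect_true(all(abs(sqrt(rowSums(emb^2)) - 1) < 1e-5))

  # determinism under the seed
  enc2 <- train_ssl(tex$patches, cfg)
  expect_identical(enc$loss_history, enc2$loss_history)
  expect_identical(enc$params, enc2$params)

  # embed_patch: identical input -> identical output, dimension 128
  e1 <- embed_patch(enc, tex$patches[[1]])
  e2 <- embed_patch(enc, tex$patches[[1]])
  expect_identical(e1, e2)
  expect_length(e1, 128)

  # alignment: two moderate views of one patch are closer on average than
  # random patch pairs drawn from the pool
  pol <- augmentation_policy(crop_scale = c(0.6, 1), gray_p = 0, blur_p = 0,
                             jitter_strength = 0.2)
  cos_pos <- vapply(1:48, function(i) {
    a <- embed_patch(enc, augment(tex$patches[[i]], pol, seed = 2 * i))
    b <- embed_patch(enc, augment(tex$patches[[i]], pol, seed = 2 * i + 1))
    sum(a * b)
  }, numeric(1))
  prs <- quiltfuse:::with_seed(1, cbind(sample(96, 200, TRUE), sample(96, 200, TRUE)))
  prs <- prs[prs[, 1] != prs[, 2], , drop = FALSE]
  cos_rand <- vapply(seq_len(nrow(prs)), function(k)
    sum(emb[prs[k, 1], ] * emb[prs[k, 2], ]), numeric(1))
  expect_gt(mean(cos_pos), mean(cos_rand))

  expect_error(train_ssl(list(), cfg), "empty patch store")
  expect_error(embed_patch(enc, array(0.5, c(16, 16))), "H x W x 3")
})

test_that("class A and B textures separate in embedding space", {
  tex <- make_texture_patches(120, ps = 64, seed = 30)
  cfg <- encoder_config(epochs = 2L, queue_size = 64L, batch_size = 32L,
                        aug_size = 48L, seed = 5L)
  enc <- train_ssl(tex$patches, cfg)
  emb <- embed_patches(enc, tex$patches)
  # mean cross-class cosine below mean within-class cosine
  a <- emb[!tex$labels, ]; b <- emb[tex$labels, ]
  within <- (mean(tcrossprod(a)[upper.tri(diag(nrow(a)))]) +
             mean(tcrossprod(b)[upper.tri(diag(nrow(b)))])) / 2
  across <- mean(a %*% t(b))
  expect_lt(across, within)
  # linear probe on frozen embeddings separates the classes
  pr <- linear_probe(emb, tex$labels, seed = 8)
  expect_gte(pr$accuracy, 0.85)
})
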