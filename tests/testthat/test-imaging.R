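# Tiling, rule filter, artifact classifier, quilt assembly.

test_that("tiling produces the exact raster grid and drops partial tiles", {
  cfg <- imaging_config(patch_size = 256L)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  p <- tile_image(img, cfg, "s1")
  expect_length(p, 4)
  expect_equal(t(vapply(p, function(x) c(x$grid_row, x$grid_col), numeric(2))),
               rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))

  img600 <- array(runif(600 * 600 * 3), c(600, 600, 3))
  expect_length(tile_image(img600, cfg, "s1"), 4)   # partials dropped

  expect_warning(p0 <- tile_image(array(0.5, c(100, 90, 3)), cfg), "smaller")
  expect_length(p0, 0)
})

test_that("reassembling tiles reproduces the cropped source image pixel-exactly", {
  cfg <- imaging_config(patch_size = 256L)
  set.seed(4)
  img <- array(runif(1024 * 768 * 3), c(1024, 768, 3))
  patches <- tile_image(img, cfg, "s1")
  expect_length(patches, 4 * 3)
  rec <- array(NA_real_, c(1024, 768, 3))
  for (p in patches) {
    r <- p$grid_row * 256; c <- p$grid_col * 256
    rec[(r + 1):(r + 256), (c + 1):(c + 256), ] <- p$pixels
  }
  expect_identical(rec, img)
})

test_that("rule filter identifies whitespace, tissue and pen artifacts", {
  cfg <- imaging_config()
  white <- array(1, c(256, 256, 3))
  expect_false(classify_patch_rule(white, cfg)$usable)
  expect_equal(classify_patch_rule(white, cfg)$reason, "whitespace")

  tex <- make_texture_patches(4, ps = 256, seed = 2)
  for (p in tex$patches) {
    cl <- classify_patch_rule(p, cfg)
    expect_true(cl$usable)
  }
  pen <- quiltfuse:::with_seed(3, quiltfuse:::apply_pen_stroke(tex$patches[[1]]))
  cl <- classify_patch_rule(pen, cfg)
  expect_false(cl$usable)
  expect_equal(cl$reason, "artifact")
})

test_that("rule filter agrees with generator ground truth on default fixtures", {
  cfg <- cohort_config(n_patients = 6, seed = 17, artifact_rate = 0.3)
  coh <- generate_cohort(cfg)
  ic <- imaging_config()
  ok <- 0L; n <- 0L
  for (sid in names(coh$slides)) {
    sc <- coh$sidecar[coh$sidecar$slide_id == sid, ]
    for (p in tile_image(coh$slides[[sid]], ic, sid)) {
      truth <- sc$truth_label[sc$row == p$grid_row & sc$col == p$grid_col]
      got <- classify_patch_rule(p, ic)$usable
      ok <- ok + (got == (truth %in% c("tissue_a", "tissue_b")))
      n <- n + 1L
    }
  }
  expect_gte(ok / n, 0.95)
})

test_that("trainable artifact classifier reaches high held-out accuracy and is seeded", {
  d <- make_labeled_patches(360, ps = 64, seed = 5)
  # short-schedule desk configuration: higher lr than the full-scale default
  cfg <- artifact_classifier_config(epochs = 10L, lr = 0.01, step_every = 4L,
                                    batch_size = 32L, seed = 11L)
  m <- train_artifact_classifier(d$patches, d$usable, cfg)
  expect_gte(m$val_accuracy, 0.9)
  m2 <- train_artifact_classifier(d$patches, d$usable, cfg)
  expect_identical(m$net$params, m2$net$params)    # deterministic under seed
  expect_identical(m$val_accuracy, m2$val_accuracy)
  expect_error(train_artifact_classifier(d$patches, rep(TRUE, 360), cfg),
               "both classes")
})

test_that("quilt assembly pads underflow, subsamples overflow reproducibly, and conserves patches", {
  mk <- function(i, slide = "s1") list(pixels = array(i / 10, c(16, 16, 3)),
                                       source_slide = slide, grid_row = i %/% 3,
                                       grid_col = i %% 3)
  cfg <- imaging_config(patch_size = 16L, quilt_rows = 2L, quilt_cols = 2L,
                        subsample_seed = 9L)

  # underflow: 2 usable patches in capacity 4 -> 2 PAD cells, pure white
  q <- build_quilt(lapply(0:1, mk), cfg, "patA")
  expect_equal(sum(q$usable_mask), 2)
  expect_equal(sum(!is.na(q$provenance$source_slide)), 2)
  pad_px <- q$pixels[17:32, 1:32, ]
  expect_true(all(pad_px == 1))

  # overflow: deterministic seeded subsample of exactly the capacity
  patches9 <- lapply(0:8, mk)
  q1 <- build_quilt(patches9, cfg, "patB")
  q2 <- build_quilt(patches9, cfg, "patB")
  expect_identical(q1$provenance, q2$provenance)
  expect_equal(sum(q1$usable_mask), 4)
  # no patch placed twice
  placed <- q1$provenance[!is.na(q1$provenance$source_slide),
                          c("source_slide", "grid_row", "grid_col")]
  expect_equal(nrow(unique(placed)), 4)

  # oracle replay of the seeded sampler
  seed <- bitwXor(9L, quiltfuse:::hash_id("patB"))
  expected_sel <- sort(quiltfuse:::with_seed(seed, sample(9, 4)))
  got_rows <- placed$grid_row * 3 + placed$grid_col + 1
  expect_setequal(got_rows, expected_sel)

  # different patient id -> (almost surely) different but valid selection
  q3 <- build_quilt(patches9, cfg, "patC")
  expect_equal(sum(q3$usable_mask), 4)

  expect_error(build_quilt(list(), cfg, "patD"), "no usable tissue")
})

test_that("quilt placement follows slide id then grid order", {
  mk <- function(slide, r, c, v) list(pixels = array(v, c(16, 16, 3)),
                                      source_slide = slide, grid_row = r, grid_col = c)
  cfg <- imaging_config(patch_size = 16L, quilt_rows = 2L, quilt_cols = 2L)
  patches <- list(mk("s2", 0, 0, 0.3), mk("s1", 1, 0, 0.2), mk("s1", 0, 1, 0.1))
  q <- build_quilt(patches, cfg, "p")
  pr <- q$provenance[1:3, ]
  expect_equal(pr$source_slide, c("s1", "s1", "s2"))
  expect_equal(pr$grid_row, c(0L, 1L, 0L))
})
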