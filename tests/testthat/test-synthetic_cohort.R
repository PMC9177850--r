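# Synthetic cohort generator: determinism, outcome structure, clinical links,
# slide rendering and ground-truth sidecars.

test_that("configuration validation names the offending field", {
  expect_error(cohort_config(0), "n_patients")
  expect_error(cohort_config(5, lambda1 = 0), "lambda1")
  expect_error(cohort_config(5, lambda2 = -1), "lambda2")
  expect_error(cohort_config(5, artifact_rate = 1.5), "artifact_rate")
  expect_error(cohort_config(5, image_size_px = 1000), "multiple of patch_size")
})

test_that("the cohort is a pure function of config and seed", {
  cfg <- cohort_config(4, seed = 7, image_size_px = 512L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$sidecar, c2$sidecar)
  expect_identical(c1$slides, c2$slides)   # pixel-identical
})

test_that("written cohorts produce readable PNGs and consistent CSV tables", {
  dir <- tempfile("cohort_")
  cfg <- cohort_config(3, seed = 2, image_size_px = 512L)
  coh <- generate_cohort(cfg, dir = dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), sum(coh$patients$n_slides))
  expect_true(all(file.exists(man$slide_path)))
  img <- read_slide(man$slide_path[1])
  expect_equal(dim(img), c(512, 512, 3))
  # in-memory render under the same seed is pixel-identical to the PNG (8-bit)
  mem <- generate_cohort(cfg)
  expect_lt(max(abs(img - mem$slides[[man$slide_id[1]]])), 1 / 255)
  for (f in c("clinical.csv", "outcomes.csv", "sidecar.csv"))
    expect_true(file.exists(file.path(dir, f)))
})

test_that("no censoring mechanism means no censored records", {
  cfg <- cohort_config(300, seed = 3, lambda_cens = 0, t_admin = 1e6)
  set.seed(1)
  su <- sample_survival(rnorm(300), rnorm(300), cfg)
  expect_true(all(su$event != 0))
  # and lambda2 = 0 removes competing events
  cfg2 <- cohort_config(300, seed = 3, lambda2 = 0, lambda_cens = 0, t_admin = 1e6)
  su2 <- sample_survival(rnorm(300), rnorm(300), cfg2)
  expect_true(all(su2$event == 1))
})

test_that("observed times never exceed the administrative cutoff", {
  cfg <- cohort_config(500, seed = 4, t_admin = 8)
  set.seed(2)
  su <- sample_survival(rnorm(500), rnorm(500), cfg)
  expect_true(all(su$time <= 8))
  expect_true(all(su$time > 0))
  expect_true(all(su$event[su$time == 8] == 0))
})

test_that("cause-1 share among events matches the competing-exponentials closed form", {
  cfg <- cohort_config(1e5, seed = 5, beta_img = 0, beta_clin = 0,
                       lambda_cens = 0, t_admin = 1e6)
  set.seed(3)
  su <- sample_survival(rnorm(1e5), rnorm(1e5), cfg)
  frac <- mean(su$event == 1)
  p <- cfg$lambda1 / (cfg$lambda1 + cfg$lambda2)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("Gleason grade probability increases with the latent score", {
  cfg <- cohort_config(1)
  set.seed(6)
  hi <- sample_clinical(rep(0, 1e4), rep(4, 1e4), cfg)
  set.seed(6)
  lo <- sample_clinical(rep(0, 1e4), rep(-4, 1e4), cfg)
  expect_gt(mean(hi$gleason_primary >= 4), mean(lo$gleason_primary >= 4))
  expect_true(all(hi$gleason_combined >= 6 & hi$gleason_combined <= 10))
  expect_true(all(lo$gleason_combined >= 6 & lo$gleason_combined <= 10))
  expect_true(all(hi$psa > 0))
  expect_true(all(hi$t_stage %in% quiltfuse:::TSTAGE_LEVELS))
})

test_that("degenerate PSA distribution collapses to exp(a0)", {
  cfg <- cohort_config(1, psa_a1 = 0, psa_sigma = 1e-12)
  set.seed(7)
  cl <- sample_clinical(rnorm(50), rnorm(50), cfg)
  expect_equal(cl$psa, rep(exp(cfg$psa_a0), 50), tolerance = 1e-9)
})

test_that("slide rendering is seed-deterministic with faithful sidecar labels", {
  cfg <- cohort_config(1, image_size_px = 1024L, artifact_rate = 0.5)
  s1 <- render_slide(0.5, cfg, seed = 9)
  s2 <- render_slide(0.5, cfg, seed = 9)
  expect_identical(s1$pixels, s2$pixels)
  expect_equal(nrow(s1$sidecar), 16)
  expect_setequal(unique(s1$sidecar$truth_label),
                  intersect(c("background", "tissue_a", "tissue_b", "artifact"),
                            s1$sidecar$truth_label))
  # background patches are >= 99% pure white pixels
  ps <- cfg$patch_size
  for (k in which(s1$sidecar$truth_label == "background")) {
    r <- s1$sidecar$row[k]; c <- s1$sidecar$col[k]
    cell <- s1$pixels[(r * ps + 1):((r + 1) * ps), (c * ps + 1):((c + 1) * ps), ]
    expect_gte(mean(cell == 1), 0.99)
  }
})

test_that("artifact_rate 0 yields no artifact labels", {
  cfg <- cohort_config(1, artifact_rate = 0)
  for (s in 1:5) {
    sd <- render_slide(rnorm(1), cfg, seed = s)$sidecar
    expect_false("artifact" %in% sd$truth_label)
  }
})

test_that("class-B fraction tracks z_img when c1 > 0 and not when c1 = 0", {
  frac_b <- function(cfg, z, seed) {
    sc <- render_slide(z, cfg, seed = seed)$sidecar
    tis <- sc$truth_label %in% c("tissue_a", "tissue_b")
    if (!any(tis)) return(NA_real_)
    mean(sc$truth_label[tis] == "tissue_b")
  }
  cfg <- cohort_config(1, artifact_rate = 0)
  set.seed(8)
  z <- rnorm(40, sd = 1.5)
  f <- vapply(seq_along(z), function(i) frac_b(cfg, z[i], i), numeric(1))
  ct <- suppressWarnings(stats::cor.test(z, f, method = "spearman"))
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 0.01)

  cfg0 <- cohort_config(1, artifact_rate = 0, c1 = 0)
  f0 <- vapply(seq_along(z), function(i) frac_b(cfg0, z[i], i + 100), numeric(1))
  ct0 <- suppressWarnings(stats::cor.test(z, f0, method = "spearman"))
  expect_gt(ct0$p.value, 0.05)   # no dependence left
})

test_that("slide counts follow the configured distribution with mode 2", {
  cfg <- cohort_config(60, seed = 10, image_size_px = 512L)
  coh <- generate_cohort(cfg, keep_slides = FALSE)
  expect_equal(nrow(coh$patients), 60)
  expect_true(all(coh$patients$n_slides %in% 1:3))
  expect_equal(unname(which.max(table(coh$patients$n_slides))), 2L)
  expect_equal(nrow(coh$manifest), sum(coh$patients$n_slides))
})
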