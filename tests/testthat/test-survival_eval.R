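# IPCW time-dependent AUC, censoring KM, comparisons, splits.

test_that("censoring KM matches hand-computed product-limit values", {
  # no censored records -> S_C identically 1
  km <- km_censoring_survival(c(1, 2, 3), c(1, 1, 2))
  expect_equal(sc_at(km, c(0.5, 2, 10)), c(1, 1, 1))

  # all censored at t = 5 -> step from 1 to 0 at 5
  km <- km_censoring_survival(rep(5, 4), rep(0, 4))
  expect_equal(sc_at(km, 4.999), 1)
  expect_equal(sc_at(km, 5), 0)
  expect_equal(sc_at_left(km, 5), 1)

  # 6-record mixed instance, hand-computed:
  # censoring events at t=2 (x2, risk set 5) and t=4 (risk set 2)
  # S(2) = 1 * (1 - 2/5) = 3/5 ; S(4) = 3/5 * (1 - 1/2) = 3/10
  km <- km_censoring_survival(c(1, 2, 2, 3, 4, 5), c(1, 0, 0, 1, 0, 2))
  expect_equal(sc_at(km, 1.9), 1)
  expect_equal(sc_at(km, 2), 3 / 5)
  expect_equal(sc_at(km, 3.99), 3 / 5)
  expect_equal(sc_at(km, 4), 3 / 10)
  expect_equal(sc_at_left(km, 2), 1)
  expect_equal(sc_at_left(km, 4), 3 / 5)
})

test_that("with no censoring or competing events the estimator is the plain rank-sum AUC", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    marker <- rnorm(n)
    time <- rexp(n, 0.2)
    event <- rep(1L, n)
    horizon <- stats::median(time)
    est <- timedep_auc(marker, time, event, horizon, se = FALSE)
    # independent O(n^2) oracle: unweighted case/control double loop
    cases <- which(time <= horizon); ctrls <- which(time > horizon)
    num <- 0
    for (i in cases) for (j in ctrls)
      num <- num + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
    expect_identical(est$auc, num / (length(cases) * length(ctrls)))
  }
})

test_that("a perfectly separating marker attains AUC 1 under any weighting", {
  set.seed(7)
  n <- 60
  time <- rexp(n, 0.15)
  event <- rbinom(n, 1, 0.8)
  event[sample(n, 5)] <- 2L
  horizon <- stats::median(time)
  # marker = indicator of being a case, plus jitter below the gap
  is_case <- time <= horizon & event == 1
  skip_if_not(any(is_case) && any(!is_case))
  marker <- ifelse(is_case, 10 + runif(n), runif(n))
  expect_equal(timedep_auc(marker, time, event, horizon, se = FALSE)$auc, 1)
})

test_that("8-record censored instance with a competing event matches the hand-expanded sum", {
  # records: (time, event, marker); horizon 5
  time <- c(1, 2, 3, 4, 6, 7, 8, 10)
  event <- c(1, 0, 1, 2, 1, 0, 2, 0)
  marker <- c(0.9, 0.3, 0.7, 0.2, 0.8, 0.4, 0.1, 0.6)
  # hand derivation of the censoring KM:
  #   censoring events at t=2 (risk 7) and t=7 (risk 3):
  #   S_C(2) = 6/7, S_C(7) = 6/7 * 2/3 = 4/7
  # cases (T<=5, d=1): t=1 w=1/S(1-)=1 ; t=3 w=1/S(3-)=7/6
  # controls: T>5: t=6,7,8,10 each w=1/S(5)=7/6 ; competing t=4 w=1/S(4-)=7/6
  # numerator = 1*(7/6)*5 [m=.9 beats all] + (7/6)^2*4 [m=.7 beats .4,.1,.6,.2]
  #           = 35/6 + 49/9 = 203/18
  # denominator = (1 + 7/6) * 5*(7/6) = 455/36  ->  AUC = 406/455 = 58/65
  est <- timedep_auc(marker, time, event, horizon = 5, se = FALSE)
  expect_equal(est$auc, 58 / 65, tolerance = 1e-12)
  expect_equal(est$n_cases, 2L)
  expect_equal(est$n_controls, 5L)
  # and the generic O(n^2) oracle agrees
  expect_equal(est$auc, oracle_ipcw_auc(marker, time, event, 5), tolerance = 1e-12)
})

test_that("estimator matches the O(n^2) oracle on censored competing-risks instances", {
  set.seed(33)
  for (rep in 1:8) {
    n <- 80
    marker <- rnorm(n)
    t1 <- rexp(n, 0.12 * exp(0.6 * marker))
    t2 <- rexp(n, 0.05)
    cc <- rexp(n, 0.06)
    time <- pmin(t1, t2, cc, 12)
    event <- ifelse(time == t1, 1L, ifelse(time == t2, 2L, 0L))
    est <- timedep_auc(marker, time, event, 5, se = FALSE)
    expect_equal(est$auc, oracle_ipcw_auc(marker, time, event, 5), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing marker transforms", {
  set.seed(5)
  n <- 150
  marker <- rnorm(n)
  t1 <- rexp(n, 0.1 * exp(0.5 * marker))
  cc <- rexp(n, 0.08)
  time <- pmin(t1, cc, 15)
  event <- ifelse(time == t1, 1L, 0L)
  a0 <- timedep_auc(marker, time, event, 5, se = FALSE)$auc
  expect_identical(timedep_auc(exp(marker), time, event, 5, se = FALSE)$auc, a0)
  expect_identical(timedep_auc(100 + 3 * marker, time, event, 5, se = FALSE)$auc, a0)
})

test_that("with no censoring and no competing cause the estimator reduces to the classical AUC", {
  set.seed(6)
  n <- 200
  marker <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.7 * marker))
  event <- rep(1L, n)
  y <- as.integer(time <= 6)
  skip_if_not(any(y == 1) && any(y == 0))
  # classical empirical AUC of the binary classification 1{T <= t}
  r <- rank(marker)
  n1 <- sum(y); n0 <- n - n1
  classical <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(timedep_auc(marker, time, event, 6, se = FALSE)$auc, classical,
               tolerance = 1e-12)
})

test_that("undefined AUCs raise explicit errors", {
  expect_error(timedep_auc(c(1, 2), c(1, 2), c(0, 0), horizon = 5, se = FALSE),
               "no cases")
  expect_error(timedep_auc(c(1, 2), c(1, 6), c(1, 1), horizon = 0.5, se = FALSE),
               "no cases")
  # every control censored before the horizon -> S_C(t) = 0 in the tail
  expect_error(
    timedep_auc(c(3, 1, 2), c(1, 2, 3), c(1, 0, 0), horizon = 5, se = FALSE),
    "no controls|zero")
})

test_that("case weights recover the cause-1 cumulative incidence", {
  set.seed(12)
  n <- 5000
  l1 <- 0.08; l2 <- 0.05; lc <- 0.07; t <- 5
  t1 <- rexp(n, l1); t2 <- rexp(n, l2); cc <- rexp(n, lc)
  time <- pmin(t1, t2, cc)
  event <- ifelse(time == t1, 1L, ifelse(time == t2, 2L, 0L))
  core <- quiltfuse:::ipcw_auc_core(rnorm(n), time, event, t)
  cif1 <- l1 / (l1 + l2) * (1 - exp(-(l1 + l2) * t))     # closed form
  mc_se <- sqrt(cif1 * (1 - cif1) / n)
  # IPCW inflates the variance; 3 MC SEs with a conservative factor of 2
  expect_lt(abs(core$sum_w_cases / n - cif1), 3 * 2 * mc_se)
})

test_that("compare_auc is symmetric, handles identical markers, and detects real gaps", {
  set.seed(21)
  n <- 300
  m <- rnorm(n)
  t1 <- rexp(n, 0.1 * exp(0.8 * m))
  time <- pmin(t1, 12); event <- ifelse(time == t1, 1L, 0L)

  same <- compare_auc(m, m, time, event, 5, B = 50, seed = 2)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)

  ab <- compare_auc(m, rev(m), time, event, 5, B = 100, seed = 3)
  ba <- compare_auc(rev(m), m, time, event, 5, B = 100, seed = 3)
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$p, ba$p)

  # perfect vs pure-noise marker, n=500, no censoring
  set.seed(22)
  n <- 500
  time2 <- rexp(n, 0.15); event2 <- rep(1L, n)
  perfect <- -time2                      # exactly orders the event times
  noise <- rnorm(n)
  cmp <- compare_auc(perfect, noise, time2, event2, stats::median(time2),
                     B = 200, seed = 4)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$diff, 0.3)
})

test_that("relative improvement reproduces printed AUC contrasts", {
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_equal(relative_improvement(0.84, 0.74), 0.10 / 0.74)
  expect_equal(relative_improvement(0.77, 0.67), 0.10 / 0.67)
  expect_error(relative_improvement(0.5, 0), "> 0")
})

test_that("constrained split partitions the cohort and honors a vacuous constraint", {
  d <- make_tabular_cohort(200, seed = 9)
  sp <- constrained_split(d, split_spec(auc_range = c(0, 1), seed = 3))
  expect_equal(sp$tries, 1L)
  expect_length(sp$val_idx, length(intersect(sp$val_idx, seq_len(200))))
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx), seq_len(200))
  # stratified 80/20: validation share close to 20%
  expect_lt(abs(length(sp$val_idx) / 200 - 0.2), 0.05)
})

test_that("constrained split achieves the NCCN AUC window on a default cohort", {
  d <- make_tabular_cohort(400, seed = 11)
  sp <- constrained_split(d, split_spec(seed = 5))
  expect_gte(sp$achieved_auc, 0.70)
  expect_lte(sp$achieved_auc, 0.75)
})

test_that("evaluate_all reports one row per endpoint and marker, matching direct AUC calls", {
  d <- make_tabular_cohort(300, seed = 13)
  markers <- list(nccn = nccn_risk_code(d$t_stage, d$gleason_combined, d$psa),
                  latent = d$z_img + d$z_clin)
  tab <- evaluate_all(markers, d$time, d$event, B = 30, seed = 1)
  expect_equal(nrow(tab), nrow(default_endpoints()) * 2)
  for (i in which(tab$marker == "latent" & tab$family == "competing")) {
    direct <- timedep_auc(markers$latent, d$time, d$event, tab$horizon[i],
                          se = FALSE)$auc
    expect_equal(tab$auc[i], direct)
  }
  expect_true(all(is.na(tab$rel_improvement[tab$marker == "nccn"])))
  expect_error(evaluate_all(markers, d$time, d$event, subset = integer(0)),
               "empty")
})
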