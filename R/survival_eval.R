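# Time-dependent ROC/AUC for censored event times with competing risks,
# estimated with inverse probability-of-censoring weighting (IPCW), plus
# bootstrap standard errors, paired model comparison, relative improvement,
# and the constrained train/validation split.
#
# Cumulative/dynamic definition at horizon t, primary cause 1:
#   cases    i : T_i <= t and delta_i = 1, weight 1 / S_C(T_i^-)
#   controls j : T_j > t                  weight 1 / S_C(t)
#            or T_j <= t and delta_j = 2, weight 1 / S_C(T_j^-)
#   AUC(t) = sum_ij W_i W_j [1{M_i > M_j} + 1/2 1{M_i = M_j}]
#            / (sum_i W_i)(sum_j W_j)
# where S_C is the Kaplan-Meier survival of the censoring distribution.
# Left limits S_C(T^-) at event times are the standard IPCW convention:
# evaluating at T instead silently biases the estimator at jump points.

#' Kaplan-Meier censoring survival function
#'
#' Product-limit estimate of the censoring distribution's survival
#' \eqn{\hat S_C(t)}: the roles of events and censorings are swapped, so the
#' "event" indicator is `event == 0`.
#'
#' @param time follow-up times (> 0).
#' @param event event codes: 0 censored, 1 primary cause, 2 competing cause.
#' @return object of class `censor_km` with jump `times` and `surv` values.
#'   Evaluate with [sc_at()] (right-continuous) or [sc_at_left()] (left
#'   limit).
#' @export
km_censoring_survival <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event == 0) ~ 1)
  structure(list(times = fit$time, surv = fit$surv), class = "censor_km")
}

#' Evaluate a censoring survival curve
#'
#' @param km a `censor_km` object.
#' @param t evaluation times.
#' @return `sc_at` gives \eqn{\hat S_C(t)} (right-continuous);
#'   `sc_at_left` gives the left limit \eqn{\hat S_C(t^-)}.
#' @export
sc_at <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$times) + 1L]
}

#' @rdname sc_at
#' @export
sc_at_left <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$times, left.open = TRUE) + 1L]
}

# Weighted concordance of cases vs controls with tie weight 1/2, computed in
# O(n log n) by sorting controls and accumulating weights.
weighted_concordance <- function(m_case, w_case, m_ctrl, w_ctrl) {
  o <- order(m_ctrl)
  ms <- m_ctrl[o]
  cw <- c(0, cumsum(w_ctrl[o]))
  w_lt <- cw[findInterval(m_case, ms, left.open = TRUE) + 1L]  # ctrl strictly below
  w_le <- cw[findInterval(m_case, ms) + 1L]                    # ctrl at or below
  num <- sum(w_case * (w_lt + 0.5 * (w_le - w_lt)))
  num / (sum(w_case) * sum(w_ctrl))
}

# Point estimate; stops with an explicit error when undefined.
ipcw_auc_core <- function(marker, time, event, horizon, cause = 1,
                          controls = c("competing", "eventfree")) {
  controls <- match.arg(controls)
  if (identical(cause, "all")) {
    is_case_event <- event %in% c(1L, 2L)
    is_competing <- rep(FALSE, length(event))
  } else {
    is_case_event <- event == cause
    is_competing <- event == (if (cause == 1) 2L else 1L)
  }
  cases <- which(time <= horizon & is_case_event)
  ctrl_late <- which(time > horizon)
  ctrl_comp <- if (controls == "competing") which(time <= horizon & is_competing) else integer(0)
  if (length(cases) == 0) stop("undefined AUC: no cases at horizon ", horizon)
  if (length(ctrl_late) + length(ctrl_comp) == 0)
    stop("undefined AUC: no controls at horizon ", horizon)
  km <- km_censoring_survival(time, event)
  s_cases <- sc_at_left(km, time[cases])
  s_t <- sc_at(km, horizon)
  s_comp <- sc_at_left(km, time[ctrl_comp])
  if (any(c(s_cases, s_t, s_comp) <= 0))
    stop("undefined AUC: censoring survival reaches zero in the tail, ",
         "IPCW weights are infinite at horizon ", horizon)
  m_case <- marker[cases];   w_case <- 1 / s_cases
  m_ctrl <- c(marker[ctrl_late], marker[ctrl_comp])
  w_ctrl <- c(rep(1 / s_t, length(ctrl_late)), 1 / s_comp)
  list(auc = weighted_concordance(m_case, w_case, m_ctrl, w_ctrl),
       n_cases = length(cases), n_controls = length(m_ctrl),
       sum_w_cases = sum(w_case))
}

#' Time-dependent AUC under censoring and competing risks
#'
#' Cumulative/dynamic IPCW estimator of the area under the time-dependent ROC
#' curve at a fixed horizon. Cases are subjects with a primary-cause event by
#' the horizon; controls are subjects still event-free at the horizon plus
#' (by default) subjects with a competing event by the horizon. Subjects are
#' weighted by the inverse Kaplan-Meier censoring survival; ties in the
#' marker count one half. The standard error is a nonparametric bootstrap
#' over patients and the 95% CI is `auc +/- 1.96 * se`.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param time,event follow-up times and event codes (0/1/2).
#' @param horizon evaluation horizon in years.
#' @param cause `1` for the primary cause under competing risks, or `"all"`
#'   to treat any event (code 1 or 2) as the case-defining event.
#' @param controls `"competing"` includes competing-event subjects as
#'   controls (the competing-risks cumulative/dynamic definition);
#'   `"eventfree"` restricts controls to event-free survivors.
#' @param se compute a bootstrap standard error?
#' @param B number of bootstrap resamples.
#' @param seed bootstrap seed.
#' @return object of class `auc_estimate`: auc, se, ci_low, ci_high, horizon,
#'   n_cases, n_controls.
#' @export
timedep_auc <- function(marker, time, event, horizon, cause = 1,
                        controls = c("competing", "eventfree"),
                        se = TRUE, B = 500L, seed = 1L) {
  controls <- match.arg(controls)
  stopifnot(length(marker) == length(time), length(time) == length(event))
  pt <- ipcw_auc_core(marker, time, event, horizon, cause, controls)
  se_val <- NA_real_
  if (se) {
    n <- length(marker)
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(ipcw_auc_core(marker[idx], time[idx], event[idx],
                               horizon, cause, controls)$auc,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 2) se_val <- stats::sd(boots)
  }
  structure(list(auc = pt$auc, se = se_val,
                 ci_low = pt$auc - 1.96 * se_val, ci_high = pt$auc + 1.96 * se_val,
                 horizon = horizon, cause = cause,
                 n_cases = pt$n_cases, n_controls = pt$n_controls),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("time-dependent AUC at %g yr: %.4f", x$horizon, x$auc))
  if (!is.na(x$se))
    cat(sprintf(" (se %.4f, 95%% CI %.4f-%.4f)", x$se, x$ci_low, x$ci_high))
  cat(sprintf(" [%d cases / %d controls]\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired comparison of two risk markers' time-dependent AUCs
#'
#' Both markers are evaluated on the same patients; the difference
#' `auc_a - auc_b` gets a paired-bootstrap standard error (same resamples for
#' both markers) and a two-sided normal-approximation p-value.
#'
#' @inheritParams timedep_auc
#' @param marker_a,marker_b paired risk markers on identical patients.
#' @return object of class `auc_comparison`: auc_a, auc_b, diff, se_diff, p.
#' @export
compare_auc <- function(marker_a, marker_b, time, event, horizon, cause = 1,
                        controls = c("competing", "eventfree"),
                        B = 500L, seed = 1L) {
  controls <- match.arg(controls)
  stopifnot(length(marker_a) == length(marker_b),
            length(marker_a) == length(time))
  a <- ipcw_auc_core(marker_a, time, event, horizon, cause, controls)$auc
  b <- ipcw_auc_core(marker_b, time, event, horizon, cause, controls)$auc
  n <- length(time)
  diffs <- with_seed(seed, {
    vapply(seq_len(B), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch({
        aa <- ipcw_auc_core(marker_a[idx], time[idx], event[idx], horizon, cause, controls)$auc
        bb <- ipcw_auc_core(marker_b[idx], time[idx], event[idx], horizon, cause, controls)$auc
        aa - bb
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  diffs <- diffs[!is.na(diffs)]
  se_diff <- if (length(diffs) >= 2) stats::sd(diffs) else NA_real_
  d <- a - b
  p <- if (is.na(se_diff) || se_diff == 0) {
    if (isTRUE(all.equal(d, 0)) || d == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(d) / se_diff)
  }
  structure(list(auc_a = a, auc_b = b, diff = d, se_diff = se_diff, p = p,
                 horizon = horizon), class = "auc_comparison")
}

#' Relative improvement of one AUC over another
#'
#' `(auc_a - auc_b) / auc_b`, the improvement of a candidate model over a
#' baseline, on the baseline's scale.
#'
#' @param auc_a candidate AUC.
#' @param auc_b baseline AUC (> 0).
#' @return relative improvement (unitless; multiply by 100 for percent).
#' @export
relative_improvement <- function(auc_a, auc_b) {
  if (any(auc_b <= 0)) stop("baseline AUC must be > 0")
  (auc_a - auc_b) / auc_b
}

#' Split specification for the constrained train/validation split
#'
#' @param train_frac training fraction (default 0.8).
#' @param auc_range acceptance interval for the validation-side NCCN
#'   risk-group AUC at `horizon` (default the clinically observed 0.70-0.75).
#' @param horizon constraint horizon in years.
#' @param max_tries maximum number of seeded resplits.
#' @param seed RNG seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.8, auc_range = c(0.70, 0.75),
                       horizon = 5, max_tries = 200L, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  structure(list(train_frac = train_frac, auc_range = auc_range,
                 horizon = horizon, max_tries = as.integer(max_tries),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Constrained 80/20 train/validation split
#'
#' Draws repeated seeded random splits, stratified by NCCN risk group so
#' group proportions match across sides, until the validation-side AUC of the
#' ordinal NCCN marker (low/intermediate/high coded 1/2/3) at the constraint
#' horizon falls inside `spec$auc_range`. Mirrors selecting a validation set
#' whose baseline discrimination matches clinically reported values.
#'
#' @param data data.frame with columns t_stage, gleason_combined, psa, time,
#'   event.
#' @param spec a [split_spec()].
#' @return list with `train_idx`, `val_idx` (disjoint, exhaustive row
#'   indices), `achieved_auc`, `tries`.
#' @export
constrained_split <- function(data, spec = split_spec()) {
  need <- c("t_stage", "gleason_combined", "psa", "time", "event")
  if (!all(need %in% names(data))) stop("data must contain: ", paste(need, collapse = ", "))
  nccn <- nccn_risk_code(data$t_stage, data$gleason_combined, data$psa)
  n <- nrow(data)
  strata <- split(seq_len(n), nccn)
  best <- Inf
  for (k in seq_len(spec$max_tries)) {
    sp <- with_seed(derive_seed(spec$seed, paste0("split", k)), {
      val <- unlist(lapply(strata, function(ix) {
        nv <- max(1L, round((1 - spec$train_frac) * length(ix)))
        if (length(ix) == 1) ix else sample(ix, nv)
      }))
      sort(unname(val))
    })
    auc <- tryCatch(
      ipcw_auc_core(nccn[sp], data$time[sp], data$event[sp], spec$horizon)$auc,
      error = function(e) NA_real_)
    if (!is.na(auc)) {
      if (auc >= spec$auc_range[1] && auc <= spec$auc_range[2]) {
        return(list(train_idx = setdiff(seq_len(n), sp), val_idx = sp,
                    achieved_auc = auc, tries = k))
      }
      best <- min(best, max(spec$auc_range[1] - auc, auc - spec$auc_range[2]))
    }
  }
  stop(sprintf(
    "constrained split failed after %d tries; best achieved distance to [%.2f, %.2f] was %.4f",
    spec$max_tries, spec$auc_range[1], spec$auc_range[2], best))
}

#' Evaluate a set of risk markers across endpoints
#'
#' One row per (endpoint family, horizon, marker): the IPCW time-dependent
#' AUC with bootstrap CI, the paired comparison against the baseline marker,
#' and the relative improvement over the baseline. Undefined AUCs are
#' reported as NA rows with the failure reason, never dropped silently.
#'
#' @param markers named list of numeric marker vectors (all on the same
#'   patients); must include `baseline`.
#' @param time,event follow-up and event codes for those patients.
#' @param endpoints data.frame with columns `family` ("competing" for the
#'   primary cause under competing risks, "all_cause" for any event) and
#'   `horizon` (years).
#' @param baseline name of the baseline marker (default "nccn").
#' @param subset optional logical/integer subset of patients (plumbing for
#'   subgroup analyses).
#' @param B,seed bootstrap settings.
#' @return data.frame with columns family, horizon, marker, auc, se, ci_low,
#'   ci_high, n_cases, n_controls, diff_vs_baseline, p_vs_baseline,
#'   rel_improvement, note.
#' @export
evaluate_all <- function(markers, time, event, endpoints = default_endpoints(),
                         baseline = "nccn", subset = NULL, B = 500L, seed = 1L) {
  stopifnot(is.list(markers), baseline %in% names(markers))
  if (!is.null(subset)) {
    time <- time[subset]; event <- event[subset]
    markers <- lapply(markers, `[`, subset)
  }
  if (length(time) == 0) stop("evaluation subset is empty")
  rows <- list()
  for (e in seq_len(nrow(endpoints))) {
    fam <- endpoints$family[e]; hz <- endpoints$horizon[e]
    cause <- if (fam == "all_cause") "all" else 1
    base_name <- baseline
    for (nm in names(markers)) {
      est <- tryCatch(
        timedep_auc(markers[[nm]], time, event, hz, cause = cause,
                    se = TRUE, B = B, seed = derive_seed(seed, paste(fam, hz, nm))),
        error = function(err) err)
      if (inherits(est, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          family = fam, horizon = hz, marker = nm, auc = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, n_cases = NA_integer_,
          n_controls = NA_integer_, diff_vs_baseline = NA_real_,
          p_vs_baseline = NA_real_, rel_improvement = NA_real_,
          note = conditionMessage(est), stringsAsFactors = FALSE)
        next
      }
      dvb <- pvb <- ri <- NA_real_
      if (nm != base_name) {
        cmp <- tryCatch(
          compare_auc(markers[[nm]], markers[[base_name]], time, event, hz,
                      cause = cause, B = B, seed = derive_seed(seed, paste("cmp", fam, hz, nm))),
          error = function(err) NULL)
        if (!is.null(cmp)) {
          dvb <- cmp$diff; pvb <- cmp$p
          ri <- relative_improvement(cmp$auc_a, cmp$auc_b)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, horizon = hz, marker = nm, auc = est$auc, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, n_cases = est$n_cases,
        n_controls = est$n_controls, diff_vs_baseline = dvb, p_vs_baseline = pvb,
        rel_improvement = ri, note = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default synthetic endpoint grid
#'
#' Two endpoint families at two horizons: the competing-risks primary cause
#' (a stand-in for distant metastasis, with other-cause death competing) at 5
#' and 10 years, and all-cause events (a stand-in for overall survival) at 5
#' and 10 years.
#'
#' @return data.frame with columns family, horizon.
#' @export
default_endpoints <- function() {
  data.frame(family = c("competing", "competing", "all_cause", "all_cause"),
             horizon = c(5, 10, 5, 10), stringsAsFactors = FALSE)
}
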