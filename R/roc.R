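# product-limit survival probability at a single time point; 1 when the
# subgroup has no events (no factor ever leaves 1)
km_surv_at <- function(time, event, t) {
  ut <- unique(time[event == 1 & time <= t])
  if (!length(ut)) return(1)
  prod(vapply(ut, function(u)
    1 - sum(time == u & event == 1) / sum(time >= u), numeric(1)))
}

#' Time-dependent ROC curve for a risk score under right censoring
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects with an event by the horizon, controls are subjects surviving
#' past it. Censoring before the horizon is handled by Kaplan-Meier
#' weighting: for threshold c,
#' sensitivity(c) = (1 - S(t | score > c)) P(score > c) / (1 - S(t)) and
#' specificity(c) = S(t | score <= c) P(score <= c) / S(t), with all
#' survival probabilities estimated by the product-limit method. On fully
#' uncensored data this reduces exactly to the binary ROC for the
#' event-by-horizon label. AUC is the trapezoid integral over the threshold
#' sweep.
#'
#' @param scores numeric risk scores or a `risk_scores` data.frame.
#' @param time,event survival records aligned to `scores`.
#' @param horizon evaluation time (same unit as `time`, typically days).
#' @return object of class `roc_curve`: `horizon`, `thresholds` (sorted
#'   attained score values, preceded by -Inf for the all-high corner),
#'   `sensitivity`, `specificity`, `auc`.
#' @export
time_dependent_roc <- function(scores, time, event, horizon) {
  x <- if (is.data.frame(scores)) scores$risk_score else as.numeric(scores)
  if (length(x) != length(time))
    pairsig_input_error("scores and survival records are misaligned")
  if (!any(event == 1 & time <= horizon))
    pairsig_input_error("no events before the horizon")
  S_all <- km_surv_at(time, event, horizon)
  thr <- c(-Inf, sort(unique(x)))
  sens <- spec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    hi <- x > thr[k]
    p_hi <- mean(hi)
    sens[k] <- if (p_hi > 0)
      (1 - km_surv_at(time[hi], event[hi], horizon)) * p_hi / (1 - S_all)
    else 0
    spec[k] <- if (p_hi < 1)
      km_surv_at(time[!hi], event[!hi], horizon) * (1 - p_hi) / S_all
    else 0
  }
  # KM products leave ~1e-16 dust; snap to the exact endpoints so that
  # ties sort correctly in the trapezoid sweep (true values are >= 1/n away)
  snap <- function(v) {
    v <- pmin(pmax(v, 0), 1)
    v[abs(v) < 1e-9] <- 0
    v[abs(v - 1) < 1e-9] <- 1
    v
  }
  sens <- snap(sens)
  spec <- snap(spec)
  # integrate in threshold order (fpr sweeps 1 -> 0 as the threshold
  # rises); signed trapezoids keep the sweep exact even where the
  # KM-weighted curve is locally non-monotone
  fpr <- 1 - spec
  k <- length(thr)
  auc <- sum((fpr[-k] - fpr[-1]) * (sens[-k] + sens[-1]) / 2)
  out <- list(horizon = horizon, thresholds = thr, sensitivity = sens,
              specificity = spec, auc = auc)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("time-dependent ROC at horizon %g: AUC = %.4f (%d thresholds)\n",
              x$horizon, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Returns the finite threshold maximizing the Youden index
#' J = sensitivity + specificity - 1. Ties are broken toward the smallest
#' threshold, i.e. the most inclusive high-risk group.
#'
#' @param roc a `roc_curve`.
#' @return list with `cutoff` and `J`.
#' @export
youden_cutoff <- function(roc) {
  keep <- is.finite(roc$thresholds)
  if (!any(keep)) pairsig_input_error("degenerate ROC curve")
  thr <- roc$thresholds[keep]
  J <- roc$sensitivity[keep] + roc$specificity[keep] - 1
  best <- which(J >= max(J) - 1e-12)
  pick <- best[which.min(thr[best])]
  list(cutoff = thr[pick], J = J[pick])
}
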