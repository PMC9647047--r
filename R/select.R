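#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox model per pair and keeps pairs with Wald
#' p < `alpha`. No multiplicity adjustment is applied. A fit that fails to
#' converge is treated as p = 1 (excluded) rather than aborting the screen.
#'
#' @param pm a `pair_matrix`.
#' @param time,event survival records aligned to the pair-matrix samples.
#' @param alpha significance cut (default 0.05).
#' @return list with `pm` (the screened `pair_matrix`), `p` (all Wald
#'   p-values) and `coef` (all univariate log hazard ratios).
#' @export
univariate_screen <- function(pm, time, event, alpha = 0.05) {
  if (!inherits(pm, "pair_matrix") || nrow(pm$indicators) == 0)
    pairsig_input_error("empty pair matrix")
  if (ncol(pm$indicators) != length(time))
    pairsig_input_error("pair matrix and survival records are misaligned")
  np <- nrow(pm$indicators)
  pv <- rep(1, np); cf <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    x <- pm$indicators[i, ]
    if (max(x) == min(x)) next           # uninformative, leave p = 1
    fit <- tryCatch(cox_fit(x, time, event), error = function(e) NULL)
    if (is.null(fit) || fit$flagged) next
    pv[i] <- fit$p[[1L]]
    cf[i] <- fit$coef[[1L]]
  }
  keep <- pv < alpha
  list(pm = subset_pairs(pm, keep), p = pv, coef = cf)
}

#' L1-penalized Cox path over pair indicators
#'
#' Thin wrapper around the coordinate-descent Cox LASSO (glmnet): fits the
#' whole regularization path (or a user-supplied decreasing lambda grid)
#' and reports the active set per lambda. `lambda = 0` recovers the
#' unpenalized partial-likelihood fit; a lambda beyond the data's maximal
#' penalty shrinks every coefficient to zero.
#'
#' @param pm a `pair_matrix`.
#' @param time,event survival records aligned to the samples.
#' @param lambda optional decreasing penalty grid (default: glmnet's own
#'   log-spaced path).
#' @return list with `lambda`, `n_active` (active-set size per lambda) and
#'   `coef` (pairs x lambda coefficient matrix).
#' @export
lasso_cox_path <- function(pm, time, event, lambda = NULL) {
  x <- t(pm$indicators)
  y <- cbind(time = time, status = event)
  fit <- if (is.null(lambda))
    glmnet::glmnet(x, y, family = "cox")
  else
    glmnet::glmnet(x, y, family = "cox", lambda = lambda, thresh = 1e-14)
  cf <- as.matrix(stats::coef(fit))
  list(lambda = fit$lambda, n_active = colSums(cf != 0), coef = cf)
}

#' Stability selection by repeated cross-validated LASSO-Cox
#'
#' Runs an L1-penalized Cox regression (via glmnet) on the screened pair
#' indicators over a log-spaced lambda path. The penalty is chosen per
#' repetition by k-fold cross-validated partial-likelihood deviance at its
#' minimum; folds are re-randomized across `n_repetitions` repetitions, and
#' the final active set is the pairs selected (nonzero coefficient at the
#' chosen lambda) in more than `stability_threshold` of repetitions.
#'
#' @param pm screened `pair_matrix` with >= 2 pairs.
#' @param time,event survival records aligned to the samples.
#' @param n_repetitions number of fold re-randomizations (default 1000; the
#'   result is a selection frequency, so smaller values trade stability
#'   resolution for speed).
#' @param n_folds cross-validation folds (default 10).
#' @param stability_threshold selection-frequency cut (default 0.5,
#'   exclusive: a pair must be picked in more than half the repetitions).
#' @param seed integer seed making the fold randomization reproducible.
#' @return list of class `lasso_selection`: `selected` (pair ids),
#'   `frequency` (per-pair selection frequency), `lambda` (chosen lambda per
#'   repetition), `pm` (the `pair_matrix` restricted to the active set).
#' @export
lasso_cox_select <- function(pm, time, event, n_repetitions = 1000,
                             n_folds = 10, stability_threshold = 0.5,
                             seed = 1L) {
  if (!inherits(pm, "pair_matrix") || nrow(pm$indicators) < 2)
    pairsig_input_error("LASSO selection needs >= 2 screened pairs")
  n_events <- sum(event == 1)
  if (n_events < 20)
    pairsig_input_error("fewer than 20 events: selection would be unstable")
  if (n_events < n_folds)
    pairsig_input_error("fewer events than cross-validation folds")
  x <- t(pm$indicators)
  y <- cbind(time = time, status = event)
  n <- nrow(x)
  hits <- integer(nrow(pm$indicators))
  lambdas <- numeric(n_repetitions)
  set.seed(seed)
  for (r in seq_len(n_repetitions)) {
    foldid <- sample(rep_len(seq_len(n_folds), n))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lambdas[r] <- cv$lambda.min
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    hits <- hits + (cf != 0)
  }
  freq <- hits / n_repetitions
  keep <- freq > stability_threshold
  out <- list(selected = pm$pairs$pair_id[keep],
              frequency = setNames(freq, pm$pairs$pair_id),
              lambda = lambdas,
              path = lasso_cox_path(pm, time, event),
              pm = subset_pairs(pm, keep))
  class(out) <- "lasso_selection"
  out
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("LASSO-Cox stability selection: %d pair(s) selected of %d\n",
              length(x$selected), length(x$frequency)))
  invisible(x)
}
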