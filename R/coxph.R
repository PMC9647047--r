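# reverse cumulative sum down the rows (risk-set aggregation for data
# sorted by increasing time)
revcumsum <- function(x) {
  if (is.matrix(x)) {
    x[] <- apply(x, 2L, function(v) rev(cumsum(rev(v))))
    x
  } else rev(cumsum(rev(x)))
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @return object of class `km_estimate`: event times, number at risk,
#'   number of events, survival probabilities, and `sfun`, the
#'   right-continuous step function t -> S(t) with S(0) = 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) pairsig_input_error("need at least one record")
  if (length(time) != length(event) || !all(event %in% c(0, 1)))
    pairsig_input_error("time and 0/1 event must be aligned")
  if (any(time < 0)) pairsig_input_error("negative survival time")
  if (!any(event == 1)) {
    warning("no events observed; survival estimate is identically 1",
            call. = FALSE)
    out <- list(time = numeric(0), n.risk = integer(0), n.event = integer(0),
                surv = numeric(0), sfun = function(t) rep(1, length(t)))
    class(out) <- "km_estimate"
    return(out)
  }
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1])
  n.risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n.event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n.event / n.risk)
  out <- list(time = ut, n.risk = n.risk, n.event = n.event, surv = surv,
              sfun = stepfun(ut, c(1, surv), right = FALSE))
  class(out) <- "km_estimate"
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d event time(s)\n", length(x$time)))
  if (length(x$time))
    print(data.frame(time = x$time, n.risk = x$n.risk, n.event = x$n.event,
                     surv = signif(x$surv, 4)), row.names = FALSE)
  invisible(x)
}

#' Mantel-Haenszel log-rank test
#'
#' Compares the survival experience of two or more groups; the statistic is
#' chi-square distributed with (number of groups - 1) degrees of freedom
#' under the null of identical hazards.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2 || any(table(group) == 0))
    pairsig_input_error("need >= 2 non-empty groups")
  K <- nlevels(group)
  ut <- sort(unique(time[event == 1]))
  O <- E <- numeric(K)
  V <- matrix(0, K, K)
  gi <- as.integer(group)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    if (n <= 1) next
    nk <- tabulate(gi[at_risk], nbins = K)
    dk <- tabulate(gi[time == t & event == 1], nbins = K)
    O <- O + dk
    E <- E + d * nk / n
    frac <- nk / n
    Vt <- d * (n - d) / (n - 1) * (diag(frac, nrow = K) - outer(frac, frac))
    V <- V + Vt
  }
  q <- (O - E)[-K]
  Vq <- V[-K, -K, drop = FALSE]
  stat <- if (sum(abs(q)) < 1e-12) 0 else
    drop(crossprod(q, solve(Vq, q)))
  list(statistic = stat, df = K - 1,
       p.value = pchisq(stat, df = K - 1, lower.tail = FALSE),
       observed = setNames(O, levels(group)),
       expected = setNames(E, levels(group)))
}

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Breslow log partial likelihood with step-halving. Standard
#' errors come from the inverse observed information; Wald z and p-values
#' are reported per covariate. The score test at beta = 0 is also returned
#' (for a single binary covariate it coincides with the log-rank statistic
#' computed without the hypergeometric small-sample factor, and the two
#' agree exactly on tie-free data).
#'
#' @param X covariate matrix (or vector), rows aligned to `time`/`event`.
#' @param time,event follow-up times and 0/1 event indicators.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `cox_fit` with `coef`, `se`, `z`, `p`,
#'   `loglik` (null and final), `loglik_trace`, `score_chisq`, `score_p`,
#'   `converged`, `flagged` (non-convergence or separation suspicion),
#'   `info` (observed information at the optimum).
#' @export
cox_fit <- function(X, time, event, max_iter = 25, tol = 1e-9) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(time) != n || length(event) != n)
    pairsig_input_error("covariates and survival records are misaligned")
  if (any(apply(X, 2L, function(v) max(v) == min(v))))
    pairsig_input_error("constant covariate column")
  if (sum(event) == 0)
    pairsig_input_error("no events: partial likelihood is flat")

  o <- order(time)
  Xs <- X[o, , drop = FALSE]
  ts <- time[o]; ev <- event[o] == 1
  tiefirst <- match(ts, ts)            # first index of each time-tie group
  evf <- tiefirst[ev]                  # risk-set anchor per event
  Xev <- Xs[ev, , drop = FALSE]
  # index pairs for the p x p cumulative cross-product matrix
  ii <- rep(seq_len(p), times = p); jj <- rep(seq_len(p), each = p)

  pl_parts <- function(beta) {
    eta <- drop(Xs %*% beta)
    c0 <- max(eta)
    w <- exp(eta - c0)
    S0 <- revcumsum(w)
    WX <- w * Xs
    S1 <- revcumsum(WX)
    Z <- WX[, ii, drop = FALSE] * Xs[, jj, drop = FALSE]
    S2 <- revcumsum(Z)
    S0e <- S0[evf]
    ll <- sum(eta[ev] - c0 - log(S0e))
    Mu <- S1[evf, , drop = FALSE] / S0e
    U <- colSums(Xev - Mu)
    H <- matrix(colSums(S2[evf, , drop = FALSE] / S0e), p, p) - crossprod(Mu)
    list(ll = ll, U = U, H = H)
  }

  beta <- rep(0, p)
  parts <- pl_parts(beta)
  null_ll <- parts$ll
  score_chisq <- tryCatch(drop(crossprod(parts$U, solve(parts$H, parts$U))),
                          error = function(e) NA_real_)
  trace <- parts$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(parts$H, parts$U), error = function(e) NULL)
    if (is.null(step)) break
    fac <- 1
    repeat {
      cand <- beta + fac * step
      cand_parts <- tryCatch(pl_parts(cand), error = function(e) NULL)
      if (!is.null(cand_parts) && is.finite(cand_parts$ll) &&
          cand_parts$ll >= parts$ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { cand <- beta; cand_parts <- parts; break }
    }
    done <- abs(cand_parts$ll - parts$ll) < tol * (abs(parts$ll) + 0.1)
    beta <- cand; parts <- cand_parts
    trace <- c(trace, parts$ll)
    if (done) { converged <- TRUE; break }
  }
  separation <- any(abs(beta) > 15)
  cov <- tryCatch(solve(parts$H), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  fit <- list(coef = setNames(beta, colnames(X)),
              se = setNames(se, colnames(X)),
              z = setNames(z, colnames(X)),
              p = setNames(2 * pnorm(-abs(z)), colnames(X)),
              loglik = c(null = null_ll, final = parts$ll),
              loglik_trace = trace,
              score_chisq = score_chisq,
              score_p = pchisq(score_chisq, df = p, lower.tail = FALSE),
              info = parts$H,
              converged = converged,
              flagged = !converged || separation || anyNA(se))
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit",
      if (x$flagged) "(flagged)" else "", "\n")
  print(data.frame(coef = signif(x$coef, 5), se = signif(x$se, 4),
                   z = signif(x$z, 4), p = signif(x$p, 4)))
  cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
              x$loglik["final"], x$loglik["null"]))
  invisible(x)
}
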