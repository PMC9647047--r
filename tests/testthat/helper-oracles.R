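# Independent brute-force oracles. These deliberately share no code with
# the package implementation: double loops and explicit formulas only.

# pair indicators by naive enumeration: all i < j, 1 iff expr[i,s] > expr[j,s]
brute_pair_matrix <- function(expr, genes) {
  rows <- list()
  ids <- character(0)
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      a <- genes[i]; b <- genes[j]
      row <- integer(ncol(expr))
      for (s in seq_len(ncol(expr)))
        row[s] <- if (expr[a, s] > expr[b, s]) 1L else 0L
      rows[[length(rows) + 1L]] <- row
      ids <- c(ids, paste(a, b, sep = "|"))
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, colnames(expr))
  m
}

# Breslow log partial likelihood, written out term by term
brute_breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# AUC of a binary label via the rank-sum (Mann-Whitney) formula, ties -> 1/2
brute_binary_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden cutoff for an uncensored binary outcome by exhaustive sweep over
# attained score values; ties toward the smallest threshold
brute_youden <- function(score, label) {
  best <- list(J = -Inf, cutoff = NA_real_)
  for (c in sort(unique(score))) {
    sens <- mean(score[label == 1] > c)
    spec <- mean(score[label == 0] <= c)
    J <- sens + spec - 1
    if (J > best$J + 1e-12) best <- list(J = J, cutoff = c)
  }
  best
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
brute_wilcox_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(nx)])
  combos <- combn(n, nx)
  stats <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# small tie-free survival data set used across tests
toy_surv <- function(n = 40, seed = 1) {
  set.seed(seed)
  list(time = sort(sample(seq(10, 3000, by = 7), n)),
       event = rbinom(n, 1, 0.7),
       x = rbinom(n, 1, 0.5))
}

# expression matrix covering the packaged signature's genes
signature_expr <- function(n_samples, seed = 1) {
  sig <- load_signature("table2")
  genes <- unique(c(sig$gene_a, sig$gene_b))
  set.seed(seed)
  expression_matrix(matrix(rnorm(length(genes) * n_samples, 6, 2),
                           nrow = length(genes),
                           dimnames = list(genes,
                                           sprintf("S%03d", 1:n_samples))))
}
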