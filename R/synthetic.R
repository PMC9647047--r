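# Category counts of the published NSCLC training cohort (unknowns
# excluded); normalized to probabilities at config construction.
default_clinical_counts <- list(
  gender    = c(Female = 399, Male = 600),
  stage     = c(I = 512, II = 278, III = 164, IV = 33),
  histology = c(LUAD = 504, LUSC = 495),
  t_stage   = c(T1 = 282, T2 = 557, T3 = 115, T4 = 42),
  n_stage   = c(N0 = 641, N1 = 222, N2 = 111, N3 = 7),
  m_stage   = c(M0 = 742, M1 = 32)
)

#' Configuration for the synthetic survival cohort generator
#'
#' The generator emulates the data structure of a bulk-expression NSCLC
#' survival study: ~90 marker genes plus background genes on a log2
#' abundance scale, right-censored overall survival driven by a planted
#' Cox model on gene-pair indicators, clinicopathologic covariates with
#' realistic category proportions, and per-sample mutation counts.
#'
#' @param n_samples cohort size (>= 2).
#' @param n_marker_genes marker genes, named `BRG001...` (default 90).
#' @param n_background_genes additional background genes `BG001...`.
#' @param planted_pairs data.frame with columns `gene_a`, `gene_b`, `beta`
#'   (log hazard per unit indicator); genes must be distinct marker genes.
#'   `NULL` plants nothing (a null cohort).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters,
#'   time in days (defaults 1.2 and 1800: median survival around 3.6 years
#'   at zero linear predictor).
#' @param censor_rate target fraction censored, in `[0, 1]`; realized by
#'   independent exponential censoring whose rate is tuned by root finding.
#' @param expression_location,expression_spread length-2 ranges for the
#'   per-gene log2-scale location and spread (defaults U\[2,10\] and
#'   U\[0.3,1.5\]).
#' @param planted_spread_range spread range for genes in planted pairs
#'   (default U\[0.9,1.5\], above the usual MAD > 0.5 screen so that planted
#'   pairs test the selection machinery rather than the variability filter).
#' @param pair_shift mean log2 offset separating the two genes of a planted
#'   pair (default 1, i.e. a two-fold expression flip).
#' @param noise_spread spread of the per-sample location shift applied to
#'   all genes of a sample (library-size-like; rank-preserving).
#' @param clinical_proportions named list of category->probability vectors
#'   for gender, stage, histology, t_stage, n_stage, m_stage; each must sum
#'   to 1. Defaults reproduce the published training-cohort proportions.
#' @param mutation_rate_by_group mean mutation count for the high/low
#'   latent-risk strata (negative binomial, size 2).
#' @param seed integer seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples,
                              n_marker_genes = 90,
                              n_background_genes = 10,
                              planted_pairs = NULL,
                              baseline_shape = 1.2,
                              baseline_scale = 1800,
                              censor_rate = 0.3,
                              expression_location = c(2, 10),
                              expression_spread = c(0.3, 1.5),
                              planted_spread_range = c(0.9, 1.5),
                              pair_shift = 1.0,
                              noise_spread = 0.2,
                              clinical_proportions = NULL,
                              mutation_rate_by_group = c(high = 250,
                                                         low = 120),
                              seed = 1L) {
  if (n_samples < 2) pairsig_input_error("n_samples must be >= 2")
  if (n_marker_genes < 1 || n_background_genes < 0)
    pairsig_input_error("invalid gene counts")
  if (censor_rate < 0 || censor_rate > 1)
    pairsig_input_error("censor_rate must lie in [0, 1]")
  if (baseline_shape <= 0 || baseline_scale <= 0 || noise_spread <= 0 ||
      any(expression_spread <= 0))
    pairsig_input_error("shape, scale and spreads must be positive")
  marker_ids <- sprintf("BRG%03d", seq_len(n_marker_genes))
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    if (!all(c("gene_a", "gene_b", "beta") %in% names(planted_pairs)))
      pairsig_input_error("planted_pairs needs gene_a, gene_b, beta")
    g <- c(planted_pairs$gene_a, planted_pairs$gene_b)
    if (!all(g %in% marker_ids))
      pairsig_input_error("planted pair references a gene outside the marker set")
    if (anyDuplicated(g))
      pairsig_input_error("planted pairs must reference distinct genes")
  }
  if (is.null(clinical_proportions))
    clinical_proportions <- lapply(default_clinical_counts,
                                   function(v) v / sum(v))
  for (nm in names(clinical_proportions)) {
    p <- clinical_proportions[[nm]]
    if (abs(sum(p) - 1) > 1e-9)
      pairsig_input_error(sprintf("proportions for '%s' do not sum to 1", nm))
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_marker_genes = as.integer(n_marker_genes),
              n_background_genes = as.integer(n_background_genes),
              planted_pairs = planted_pairs,
              baseline_shape = baseline_shape,
              baseline_scale = baseline_scale,
              censor_rate = censor_rate,
              expression_location = expression_location,
              expression_spread = expression_spread,
              planted_spread_range = planted_spread_range,
              pair_shift = pair_shift,
              noise_spread = noise_spread,
              clinical_proportions = clinical_proportions,
              mutation_rate_by_group = mutation_rate_by_group,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic survival cohort with planted pair effects
#'
#' Expression is drawn per gene from a normal location/spread model on the
#' log2 scale plus a per-sample location shift. For each planted pair the
#' indicator is realized by construction: a latent Bernoulli(1/2) decides
#' the sign of a strictly positive offset separating gene A from gene B, so
#' the per-sample truth is controlled exactly. Event times follow a Weibull
#' proportional-hazards model with linear predictor
#' `sum(beta * indicator)` (inverse-transform sampling); censoring is
#' independent exponential with its rate tuned so that the expected
#' censored fraction matches `censor_rate`. Clinical categories are drawn
#' from the configured proportions, and mutation counts from a negative
#' binomial whose mean is tied to the latent-risk stratum (above/below the
#' median linear predictor). Fully reproducible given the config seed.
#'
#' @param config a `simulation_config`.
#' @return list of class `synthetic_cohort` with `expression` (matrix),
#'   `clinical` (data.frame), `mutations` (named vector) and `truth` (list:
#'   `pairs`, `indicators`, `linear_predictor`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    pairsig_input_error("config must come from simulation_config()")
  set.seed(config$seed)
  n <- config$n_samples
  gene_ids <- c(sprintf("BRG%03d", seq_len(config$n_marker_genes)),
                if (config$n_background_genes > 0)
                  sprintf("BG%03d", seq_len(config$n_background_genes)))
  G <- length(gene_ids)
  sample_ids <- sprintf("S%04d", seq_len(n))
  loc <- runif(G, config$expression_location[1], config$expression_location[2])
  spr <- runif(G, config$expression_spread[1], config$expression_spread[2])
  pp <- config$planted_pairs
  if (!is.null(pp)) {
    pg <- match(c(pp$gene_a, pp$gene_b), gene_ids)
    spr[pg] <- runif(length(pg), config$planted_spread_range[1],
                     config$planted_spread_range[2])
  }
  expr <- matrix(rnorm(G * n, mean = loc, sd = spr), nrow = G,
                 dimnames = list(gene_ids, sample_ids))
  lp <- rep(0, n)
  truth_ind <- NULL
  if (!is.null(pp)) {
    truth_ind <- matrix(0L, nrow(pp), n,
                        dimnames = list(paste(pp$gene_a, pp$gene_b,
                                              sep = "|"), sample_ids))
    for (k in seq_len(nrow(pp))) {
      a <- match(pp$gene_a[k], gene_ids)
      b <- match(pp$gene_b[k], gene_ids)
      I <- rbinom(n, 1L, 0.5)
      delta <- config$pair_shift + abs(rnorm(n, 0, 0.25)) + 0.05
      expr[a, ] <- expr[b, ] + ifelse(I == 1L, delta, -delta)
      truth_ind[k, ] <- I
      lp <- lp + pp$beta[k] * I
    }
  }
  expr <- sweep(expr, 2L, rnorm(n, 0, config$noise_spread), `+`)

  u <- runif(n)
  t_event <- config$baseline_scale *
    (-log(u) / exp(lp))^(1 / config$baseline_shape)
  if (config$censor_rate > 0) {
    target <- config$censor_rate
    f <- function(logr) mean(1 - exp(-exp(logr) * t_event)) - target
    logr <- uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
    t_cens <- rexp(n, rate = exp(logr))
    os <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    os <- t_event
    event <- rep(1L, n)
  }

  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  cp <- config$clinical_proportions
  clinical <- data.frame(sample_id = sample_ids,
                         os_days = os, event = event,
                         age_years = round(rnorm(n, 66, 9)),
                         gender = draw_cat(cp$gender),
                         stage = draw_cat(cp$stage),
                         t_stage = draw_cat(cp$t_stage),
                         n_stage = draw_cat(cp$n_stage),
                         m_stage = draw_cat(cp$m_stage),
                         histology = draw_cat(cp$histology),
                         stringsAsFactors = FALSE)
  stratum <- ifelse(lp > median(lp), "high", "low")
  mutations <- setNames(
    rnbinom(n, size = 2, mu = config$mutation_rate_by_group[stratum]),
    sample_ids)

  cohort <- list(expression = expression_matrix(expr),
                 clinical = clinical,
                 mutations = mutations,
                 truth = list(pairs = pp, indicators = truth_ind,
                              linear_predictor = setNames(lp, sample_ids)),
                 config = config)
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples, %d genes, %d planted pair(s), %.0f%% censored\n",
    ncol(x$expression), nrow(x$expression),
    if (is.null(x$truth$pairs)) 0L else nrow(x$truth$pairs),
    100 * mean(x$clinical$event == 0)))
  invisible(x)
}

#' Apply a strictly monotone per-sample distortion to an expression matrix
#'
#' Emulates a platform shift: each sample's values are passed through a
#' strictly increasing function with randomly drawn parameters, so every
#' within-sample pairwise ordering (and hence every pair indicator) is
#' preserved exactly on tie-free input. Kinds: `affine_positive`
#' (`scale * x + offset`, scale in U\[0.5,3\]), `power`
#' (`(x - min(x) + 1)^e`, exponent in U\[0.4,2.5\], the shift keeping the
#' base positive for arbitrary log-scale input) and `rank_quantile`
#' (values mapped in rank order onto normal quantiles with a random
#' location/scale).
#'
#' @param expr expression matrix.
#' @param kind one of `"affine_positive"`, `"power"`, `"rank_quantile"`.
#' @param seed integer seed for the per-sample parameter draws.
#' @return distorted expression matrix, same dimnames.
#' @export
apply_monotone_distortion <- function(expr,
                                      kind = c("affine_positive", "power",
                                               "rank_quantile"),
                                      seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  n <- ncol(expr)
  out <- expr
  if (kind == "affine_positive") {
    sc <- runif(n, 0.5, 3); off <- runif(n, -2, 2)
    out <- sweep(sweep(expr, 2L, sc, `*`), 2L, off, `+`)
  } else if (kind == "power") {
    e <- runif(n, 0.4, 2.5)
    for (j in seq_len(n))
      out[, j] <- (expr[, j] - min(expr[, j]) + 1)^e[j]
  } else {
    m <- runif(n, -5, 5); s <- runif(n, 0.5, 4)
    for (j in seq_len(n)) {
      r <- rank(expr[, j], ties.method = "first")
      out[, j] <- qnorm((r - 0.375) / (nrow(expr) + 0.25), m[j], s[j])
    }
  }
  # monotonicity must hold by construction; violating it is a bug
  for (j in seq_len(min(n, 3L))) {
    if (!identical(order(out[, j]), order(expr[, j])))
      stop("internal error: distortion broke within-sample ordering")
  }
  out
}

#' Export a synthetic cohort as plain-text files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutations.tsv` and
#' `truth.json` to `directory`; the text files round-trip losslessly (12
#' significant digits) through [read_expression()], [read_clinical()] and
#' [read_mutations()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
export_cohort <- function(cohort, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2) != 0)
    pairsig_input_error(sprintf("directory not writable: %s", directory))
  paths <- c(expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             mutations = file.path(directory, "mutations.tsv"),
             truth = file.path(directory, "truth.json"))
  write_expression(cohort$expression, paths["expression"])
  cl <- cohort$clinical
  cl$os_days <- sprintf("%.12g", cl$os_days)
  write.table(cl, paths["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = names(cohort$mutations),
                         mutation_count = as.integer(cohort$mutations)),
              paths["mutations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(pairs = cohort$truth$pairs,
                linear_predictor = as.list(cohort$truth$linear_predictor))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read an exported cohort back from a directory
#'
#' @param directory directory written by [export_cohort()].
#' @return list with `expression`, `clinical`, `mutations`, `truth`.
#' @export
read_cohort <- function(directory) {
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::fromJSON(truth_path)
    if (!is.null(tr$pairs)) tr$pairs$beta <- as.numeric(tr$pairs$beta)
    list(pairs = tr$pairs,
         linear_predictor = unlist(tr$linear_predictor))
  } else NULL
  list(expression = read_expression(file.path(directory, "expression.tsv")),
       clinical = read_clinical(file.path(directory, "clinical.tsv")),
       mutations = read_mutations(file.path(directory, "mutations.tsv")),
       truth = truth)
}
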