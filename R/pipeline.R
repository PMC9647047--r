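#' Build a gene-pair prognostic signature from a training cohort
#'
#' Runs the construction funnel: MAD variability screen, restriction to
#' genes available in every validation cohort, exhaustive 0-or-1 pairing,
#' prevalence filter, univariate Cox screen (p < alpha), repeated
#' cross-validated LASSO-Cox stability selection, and an unpenalized
#' multivariate Cox refit providing the signature coefficients. Per-stage
#' counts are logged via `message()`; any stage emptying its output aborts
#' with a stage-named error.
#'
#' @param expr training expression matrix.
#' @param time,event training survival records aligned to the samples.
#' @param genes candidate gene list (default: all genes in `expr`); defines
#'   pair orientation (earlier gene = gene A).
#' @param validation optional list of validation expression matrices; genes
#'   absent from any of them are dropped before pairing.
#' @param mad_threshold,mad_constant see [mad_filter()].
#' @param prevalence_low,prevalence_high see [prevalence_filter()].
#' @param screen_alpha see [univariate_screen()].
#' @param lasso_repetitions,lasso_folds,lasso_threshold see
#'   [lasso_cox_select()].
#' @param seed integer seed for the LASSO fold randomization.
#' @param verbose emit per-stage counts (default TRUE).
#' @return list with `signature` (a [signature_model()]), `funnel` (named
#'   stage counts), `refit` (the multivariate [cox_fit()]), `selection`
#'   (the [lasso_cox_select()] result) and `screen` p-values.
#' @export
build_signature <- function(expr, time, event, genes = rownames(expr),
                            validation = list(),
                            mad_threshold = 0.5, mad_constant = 1,
                            prevalence_low = 0.2, prevalence_high = 0.8,
                            screen_alpha = 0.05,
                            lasso_repetitions = 1000, lasso_folds = 10,
                            lasso_threshold = 0.5, seed = 1L,
                            verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  funnel <- c(genes_input = length(genes))
  say("stage genes_input: %d genes", length(genes))

  keep <- mad_filter(expr[genes, , drop = FALSE], threshold = mad_threshold,
                     constant = mad_constant)
  funnel["genes_mad"] <- length(keep)
  say("stage mad_filter: %d genes with MAD > %g", length(keep), mad_threshold)
  if (length(keep) < 2)
    pairsig_stage_error("mad_filter", "fewer than 2 genes survive")

  if (length(validation)) {
    keep <- intersect_available_genes(keep, validation)
    say("stage gene_availability: %d genes present in all cohorts",
        length(keep))
    if (length(keep) < 2)
      pairsig_stage_error("gene_availability",
                          "fewer than 2 genes shared across cohorts")
  }
  funnel["genes_available"] <- length(keep)

  pm <- build_pair_matrix(expr, keep)
  funnel["pairs_all"] <- nrow(pm$indicators)
  say("stage pairing: %d pairs", nrow(pm$indicators))

  pm <- prevalence_filter(pm, prevalence_low, prevalence_high)
  funnel["pairs_prevalent"] <- nrow(pm$indicators)
  say("stage prevalence_filter: %d pairs with prevalence in [%g, %g]",
      nrow(pm$indicators), prevalence_low, prevalence_high)
  if (nrow(pm$indicators) == 0)
    pairsig_stage_error("prevalence_filter", "no pair survives")

  scr <- univariate_screen(pm, time, event, alpha = screen_alpha)
  funnel["pairs_prognostic"] <- nrow(scr$pm$indicators)
  say("stage univariate_screen: %d pairs with p < %g",
      nrow(scr$pm$indicators), screen_alpha)
  if (nrow(scr$pm$indicators) == 0)
    pairsig_stage_error("univariate_screen", "no prognostic pair at alpha")

  if (nrow(scr$pm$indicators) == 1) {
    sel <- list(selected = scr$pm$pairs$pair_id,
                frequency = setNames(1, scr$pm$pairs$pair_id),
                lambda = numeric(0), pm = scr$pm)
    class(sel) <- "lasso_selection"
  } else {
    sel <- lasso_cox_select(scr$pm, time, event,
                            n_repetitions = lasso_repetitions,
                            n_folds = lasso_folds,
                            stability_threshold = lasso_threshold,
                            seed = seed)
  }
  funnel["pairs_selected"] <- length(sel$selected)
  say("stage lasso_selection: %d pairs selected in > %g%% of %d repetitions",
      length(sel$selected), 100 * lasso_threshold, lasso_repetitions)
  if (!length(sel$selected))
    pairsig_stage_error("lasso_selection", "empty active set")

  refit <- cox_fit(t(sel$pm$indicators), time, event)
  ok <- abs(refit$coef) > 1e-12
  sig <- signature_model(sel$pm$pairs$gene_a[ok], sel$pm$pairs$gene_b[ok],
                         refit$coef[ok],
                         provenance = "trained by build_signature")
  say("stage refit: %d pairs with nonzero multivariate coefficients", sum(ok))
  list(signature = sig, funnel = funnel, refit = refit, selection = sel,
       screen = scr)
}

# cox_fit -> plain coefficient table for reports
cox_table <- function(fit) {
  data.frame(term = names(fit$coef), coef = unname(fit$coef),
             hr = exp(unname(fit$coef)), se = unname(fit$se),
             p = unname(fit$p), row.names = NULL)
}

#' Score and evaluate a signature across one or more cohorts
#'
#' Computes risk scores per cohort, derives the optimal cutoff from the
#' Youden index of the training cohort's time-dependent ROC at
#' `cutoff_horizon` (or re-derives it per cohort under the `per_cohort`
#' policy), stratifies patients into high/low risk, and reports ROC AUCs at
#' each horizon, Kaplan-Meier summaries with the log-rank test between risk
#' groups, univariate/multivariate Cox models with clinical covariates,
#' clinicopathologic association tests, and TMB comparisons when mutation
#' counts are supplied.
#'
#' @param sig a `signature_model`.
#' @param cohorts named list of cohorts, each a list with `expression`,
#'   `clinical` and optionally `mutations`; the first cohort is the
#'   training cohort.
#' @param horizons ROC horizons in days (default 1/2/3 years).
#' @param cutoff_horizon horizon whose ROC defines the Youden cutoff
#'   (default 1095, the 3-year curve).
#' @param cutoff_policy `"train_transfer"` (one training-derived cutoff for
#'   all cohorts, the default) or `"per_cohort"` (re-optimized per cohort).
#' @param covariates clinical covariates for the multivariate Cox model.
#' @param exome_megabases TMB denominator (default 38 Mb).
#' @return report list: `cutoff`, `cutoff_policy`, and one entry per cohort
#'   with `auc` (per horizon), `youden`, `cutoff`, `n_high`/`n_low`,
#'   `logrank`, `km` (per-group medians), `cox`, `associations`, `tmb`,
#'   and the `scores` table.
#' @export
evaluate_signature <- function(sig, cohorts,
                               horizons = c(365, 730, 1095),
                               cutoff_horizon = 1095,
                               cutoff_policy = c("train_transfer",
                                                 "per_cohort"),
                               covariates = c("age_years", "gender",
                                              "histology", "stage"),
                               exome_megabases = 38.0) {
  cutoff_policy <- match.arg(cutoff_policy)
  if (!length(cohorts)) pairsig_input_error("no cohort supplied")
  if (is.null(names(cohorts)))
    names(cohorts) <- c("training",
                        paste0("validation", seq_along(cohorts)[-1]))

  score_one <- function(co) {
    s <- compute_risk_scores(co$expression, sig)
    m <- match(s$sample_id, co$clinical$sample_id)
    if (anyNA(m))
      pairsig_input_error("expression and clinical sample ids disagree")
    list(scores = s, clinical = co$clinical[m, , drop = FALSE])
  }
  scored <- lapply(cohorts, score_one)

  train <- scored[[1L]]
  train_roc <- time_dependent_roc(train$scores, train$clinical$os_days,
                                  train$clinical$event, cutoff_horizon)
  train_cut <- youden_cutoff(train_roc)

  report <- list(cutoff = train_cut$cutoff, youden_J = train_cut$J,
                 cutoff_policy = cutoff_policy, horizons = horizons,
                 cohorts = list())
  for (nm in names(scored)) {
    sc <- scored[[nm]]
    cl <- sc$clinical
    aucs <- vapply(horizons, function(h)
      tryCatch(time_dependent_roc(sc$scores, cl$os_days, cl$event, h)$auc,
               error = function(e) NA_real_), numeric(1))
    names(aucs) <- paste0("auc_", horizons, "d")
    cut <- if (cutoff_policy == "per_cohort" && nm != names(scored)[1L]) {
      youden_cutoff(time_dependent_roc(sc$scores, cl$os_days, cl$event,
                                       cutoff_horizon))$cutoff
    } else train_cut$cutoff
    strat <- stratify(sc$scores, cut)
    lr <- if (nlevels(droplevels(strat$risk_group)) == 2)
      logrank_test(cl$os_days, cl$event, strat$risk_group) else NULL
    km <- lapply(split(seq_len(nrow(cl)), strat$risk_group), function(ix) {
      if (!length(ix)) return(NULL)
      fit <- suppressWarnings(km_estimate(cl$os_days[ix], cl$event[ix]))
      med <- if (length(fit$time) && any(fit$surv <= 0.5))
        min(fit$time[fit$surv <= 0.5]) else NA_real_
      list(n = length(ix), events = sum(cl$event[ix]), median_days = med)
    })
    cox <- tryCatch(
      clinical_cox(strat, cl, covariates = intersect(covariates, names(cl))),
      error = function(e) NULL)
    assoc <- tryCatch(suppressWarnings(association_suite(strat, cl)),
                      error = function(e) NULL)
    tmb_res <- NULL
    if (!is.null(cohorts[[nm]]$mutations)) {
      tm <- tmb(cohorts[[nm]]$mutations[strat$sample_id],
                exome_megabases = exome_megabases)
      hi <- strat$risk_group == "high"
      tmb_res <- list(
        wilcoxon = if (any(hi) && any(!hi))
          suppressWarnings(wilcox.test(tm[hi], tm[!hi]))$p.value
        else NA_real_,
        spearman = correlation_test(strat$risk_score, tm,
                                    method = "spearman"),
        median_high = median(tm[hi]), median_low = median(tm[!hi]))
    }
    report$cohorts[[nm]] <- list(
      n = nrow(cl), auc = aucs, cutoff = cut,
      n_high = sum(strat$risk_group == "high"),
      n_low = sum(strat$risk_group == "low"),
      logrank = if (!is.null(lr)) list(statistic = lr$statistic,
                                       p = lr$p.value) else NULL,
      km = km,
      cox = if (!is.null(cox)) list(
        univariate = cox_table(cox$univariate),
        multivariate = cox_table(cox$multivariate),
        independent = cox$independent) else NULL,
      associations = assoc,
      tmb = tmb_res,
      scores = strat)
  }
  report
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized keys (all optional unless a subcommand needs them):
#' `expression`, `clinical`, `mutations`, `genes` (newline-delimited gene
#' list), `signature`, `out`, `validation` (array of objects with `name`,
#' `expression`, `clinical`, `mutations`), `simulate` (arguments for
#' [simulation_config()], `planted_pairs` as an array of objects),
#' `mad_threshold` (0.5), `mad_constant` (1), `prevalence_low` (0.2),
#' `prevalence_high` (0.8), `screen_alpha` (0.05), `lasso_repetitions`
#' (1000), `lasso_folds` (10), `lasso_threshold` (0.5), `roc_horizons`
#' (365/730/1095), `cutoff_horizon` (1095), `cutoff_policy`
#' (`train_transfer`), `time_unit` (`days`), `seed` (1).
#'
#' @param path JSON file.
#' @return config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    pairsig_input_error(sprintf("config file not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(mad_threshold = 0.5, mad_constant = 1,
                   prevalence_low = 0.2, prevalence_high = 0.8,
                   screen_alpha = 0.05, lasso_repetitions = 1000,
                   lasso_folds = 10, lasso_threshold = 0.5,
                   roc_horizons = c(365, 730, 1095), cutoff_horizon = 1095,
                   cutoff_policy = "train_transfer", time_unit = "days",
                   seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!(cfg$prevalence_low >= 0 && cfg$prevalence_low < cfg$prevalence_high &&
        cfg$prevalence_high <= 1))
    pairsig_input_error("prevalence bounds out of range")
  if (any(cfg$roc_horizons <= 0) || cfg$cutoff_horizon <= 0)
    pairsig_input_error("ROC horizons must be positive")
  if (!cfg$cutoff_policy %in% c("train_transfer", "per_cohort"))
    pairsig_input_error("unknown cutoff policy")
  cfg
}

# days conversion for clinical tables recorded in other units
to_days <- function(x, unit) {
  switch(unit, days = x, months = x * 30.44, years = x * 365.25,
         pairsig_input_error(sprintf("unknown time unit '%s'", unit)))
}

load_cohort_files <- function(expression, clinical, mutations = NULL,
                              time_unit = "days") {
  cl <- read_clinical(clinical)
  cl$os_days <- to_days(cl$os_days, time_unit)
  list(expression = read_expression(expression), clinical = cl,
       mutations = if (!is.null(mutations) && nzchar(mutations))
         read_mutations(mutations) else NULL)
}

config_cohorts <- function(cfg) {
  cohorts <- list(training = load_cohort_files(cfg$expression, cfg$clinical,
                                               cfg$mutations, cfg$time_unit))
  if (!is.null(cfg$validation)) {
    val <- cfg$validation
    if (is.data.frame(val)) val <- split(val, seq_len(nrow(val)))
    for (v in val) {
      nm <- if (!is.null(v$name)) v$name else
        paste0("validation", length(cohorts))
      cohorts[[nm]] <- load_cohort_files(v$expression, v$clinical,
                                         v$mutations, cfg$time_unit)
    }
  }
  cohorts
}

#' Run the signature-construction pipeline from a configuration file
#'
#' @param config path to a JSON config (see [read_pipeline_config()]) or an
#'   already-parsed config list.
#' @return the [build_signature()] result, invisibly; the signature and a
#'   funnel log are written under `out` when configured.
#' @export
run_build <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (is.null(cfg$expression) || is.null(cfg$clinical))
    pairsig_input_error("build needs expression and clinical paths")
  cohorts <- config_cohorts(cfg)
  tr <- cohorts[[1L]]
  m <- match(colnames(tr$expression), tr$clinical$sample_id)
  if (anyNA(m))
    pairsig_input_error("expression and clinical sample ids disagree")
  cl <- tr$clinical[m, , drop = FALSE]
  genes <- if (!is.null(cfg$genes)) readLines(cfg$genes) else
    rownames(tr$expression)
  genes <- intersect(genes, rownames(tr$expression))
  res <- build_signature(tr$expression, cl$os_days, cl$event, genes = genes,
                         validation = lapply(cohorts[-1L],
                                             `[[`, "expression"),
                         mad_threshold = cfg$mad_threshold,
                         mad_constant = cfg$mad_constant,
                         prevalence_low = cfg$prevalence_low,
                         prevalence_high = cfg$prevalence_high,
                         screen_alpha = cfg$screen_alpha,
                         lasso_repetitions = cfg$lasso_repetitions,
                         lasso_folds = cfg$lasso_folds,
                         lasso_threshold = cfg$lasso_threshold,
                         seed = cfg$seed)
  if (!is.null(cfg$out)) {
    if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
    write_signature(res$signature, file.path(cfg$out, "signature.tsv"))
    jsonlite::write_json(as.list(res$funnel),
                         file.path(cfg$out, "build_funnel.json"),
                         auto_unbox = TRUE)
  }
  invisible(res)
}

#' Score cohorts with a signature and run the full evaluation
#'
#' @param config path to a JSON config or a parsed config list.
#' @param signature optional `signature_model`; defaults to the file named
#'   by the config's `signature` key, or to the trained signature under
#'   `out` from a previous [run_build()].
#' @return the [evaluate_signature()] report, invisibly; written as
#'   `evaluation_report.json` (plus per-cohort `scores_*.tsv`) under `out`
#'   when configured.
#' @export
run_score_evaluate <- function(config, signature = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (is.null(signature)) {
    sig_path <- cfg$signature
    if (is.null(sig_path) && !is.null(cfg$out) &&
        file.exists(file.path(cfg$out, "signature.tsv")))
      sig_path <- file.path(cfg$out, "signature.tsv")
    if (is.null(sig_path))
      pairsig_input_error("no signature supplied or configured")
    signature <- load_signature(sig_path)
  }
  cohorts <- config_cohorts(cfg)
  report <- evaluate_signature(signature, cohorts,
                               horizons = cfg$roc_horizons,
                               cutoff_horizon = cfg$cutoff_horizon,
                               cutoff_policy = cfg$cutoff_policy)
  if (!is.null(cfg$out)) {
    if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
    slim <- report
    for (nm in names(slim$cohorts)) {
      write_scores(slim$cohorts[[nm]]$scores,
                   file.path(cfg$out, paste0("scores_", nm, ".tsv")))
      slim$cohorts[[nm]]$scores <- NULL
    }
    jsonlite::write_json(slim, file.path(cfg$out, "evaluation_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         null = "null", force = TRUE)
  }
  invisible(report)
}

#' Simulate a cohort from a configuration file and export it
#'
#' @param config path to a JSON config or a parsed config list; the
#'   `simulate` block holds [simulation_config()] arguments.
#' @param out output directory (overrides the config's `out`).
#' @return the generated `synthetic_cohort`, invisibly.
#' @export
run_simulate <- function(config, out = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  sim <- cfg$simulate
  if (is.null(sim)) pairsig_input_error("config has no 'simulate' block")
  sim <- sim[!vapply(sim, is.null, logical(1))]
  if (is.null(sim$seed)) sim$seed <- cfg$seed
  cohort <- generate_cohort(do.call(simulation_config, sim))
  dest <- if (!is.null(out)) out else cfg$out
  if (!is.null(dest)) export_cohort(cohort, dest)
  invisible(cohort)
}
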