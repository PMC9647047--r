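#' Univariate and multivariate Cox models for the risk score
#'
#' Fits the risk score alone, then together with clinical covariates
#' (categorical covariates are encoded by reference-level treatment
#' contrasts). The score is flagged as an independent prognostic factor
#' when its multivariate Wald p-value is below 0.05.
#'
#' @param scores a `risk_scores` data.frame.
#' @param clinical clinical table (see [read_clinical()]); matched to
#'   `scores` by `sample_id`.
#' @param covariates clinical column names to adjust for (default age,
#'   gender, histology, stage); an empty vector reduces the multivariate
#'   model to the univariate one.
#' @return list with `univariate` and `multivariate` [cox_fit()] objects
#'   and logical `independent`.
#' @export
clinical_cox <- function(scores, clinical,
                         covariates = c("age_years", "gender", "histology",
                                        "stage")) {
  m <- match(scores$sample_id, clinical$sample_id)
  if (anyNA(m))
    pairsig_input_error("samples in scores missing from clinical table")
  cl <- clinical[m, , drop = FALSE]
  miss <- setdiff(covariates, names(cl))
  if (length(miss))
    pairsig_input_error(paste("clinical covariate(s) not found:",
                              paste(miss, collapse = ", ")))
  uni <- cox_fit(matrix(scores$risk_score, ncol = 1,
                        dimnames = list(NULL, "risk_score")),
                 cl$os_days, cl$event)
  if (!length(covariates)) {
    return(list(univariate = uni, multivariate = uni,
                independent = uni$p[["risk_score"]] < 0.05))
  }
  df <- data.frame(risk_score = scores$risk_score, cl[covariates],
                   stringsAsFactors = TRUE)
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  X <- stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    pairsig_input_error("collinear covariate encoding in multivariate model")
  multi <- cox_fit(X, cl$os_days, cl$event)
  list(univariate = uni, multivariate = multi,
       independent = isTRUE(multi$p[["risk_score"]] < 0.05))
}

# binary clinicopathologic splits used for rank-sum comparisons
default_splits <- list(
  stage   = function(v) ifelse(grepl("^(I|II)$", v), "I-II",
                        ifelse(grepl("^(III|IV)$", v), "III-IV", NA)),
  t_stage = function(v) ifelse(grepl("^T[12]$", v), "T1-2",
                        ifelse(grepl("^T[34]$", v), "T3-4", NA)),
  n_stage = function(v) ifelse(grepl("^N[01]$", v), "N0-1",
                        ifelse(grepl("^N[23]$", v), "N2-3", NA)),
  m_stage = function(v) ifelse(v == "M0", "M0",
                        ifelse(v == "M1", "M1", NA))
)

#' Clinicopathologic association tests for a stratified risk score
#'
#' For each categorical variable, a Pearson chi-square test (no continuity
#' correction) of the risk-group x category contingency table. For each
#' binary clinicopathologic split (stage I-II vs III-IV, T1-2 vs T3-4,
#' N0-1 vs N2-3, M0 vs M1), a two-sided Wilcoxon rank-sum comparison of the
#' risk-score distributions (exact for small tie-free samples, otherwise the
#' tie-corrected normal approximation). Variables whose contingency table
#' degenerates (a single observed category or group) are skipped with a
#' warning.
#'
#' @param scores a stratified `risk_scores` data.frame (see [stratify()]).
#' @param clinical clinical table matched by `sample_id`.
#' @param categorical clinical columns to chi-square against the risk group.
#' @return data.frame with columns `variable`, `test`, `statistic`, `p`,
#'   `effect`.
#' @export
association_suite <- function(scores, clinical,
                              categorical = c("gender", "stage", "t_stage",
                                              "n_stage", "m_stage",
                                              "histology")) {
  if (is.null(scores$risk_group))
    pairsig_input_error("scores must be stratified before association tests")
  m <- match(scores$sample_id, clinical$sample_id)
  if (anyNA(m))
    pairsig_input_error("samples in scores missing from clinical table")
  cl <- clinical[m, , drop = FALSE]
  res <- list()
  for (v in intersect(categorical, names(cl))) {
    ok <- !is.na(cl[[v]])
    tab <- table(scores$risk_group[ok], cl[[v]][ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      warning(sprintf("skipping chi-square for '%s': degenerate table", v),
              call. = FALSE)
      next
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res[[length(res) + 1L]] <- data.frame(
      variable = v, test = "chi-square",
      statistic = unname(ct$statistic), p = ct$p.value, effect = NA_real_)
  }
  for (v in intersect(names(default_splits), names(cl))) {
    grp <- default_splits[[v]](as.character(cl[[v]]))
    ok <- !is.na(grp)
    if (length(unique(grp[ok])) < 2) {
      warning(sprintf("skipping rank-sum for '%s': one-sided split", v),
              call. = FALSE)
      next
    }
    lv <- sort(unique(grp[ok]))
    x <- scores$risk_score[ok][grp[ok] == lv[2L]]  # advanced stage
    y <- scores$risk_score[ok][grp[ok] == lv[1L]]
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    res[[length(res) + 1L]] <- data.frame(
      variable = paste0(v, ":", lv[2L], "_vs_", lv[1L]), test = "wilcoxon",
      statistic = unname(wt$statistic), p = wt$p.value,
      effect = median(x) - median(y))
  }
  do.call(rbind, res)
}

#' Correlation between a risk score and a continuous marker
#'
#' Pearson (p by t approximation) or Spearman (p by the large-sample
#' approximation, tie-corrected) correlation. Zero-variance input is
#' flagged rather than an error: the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame row: `variable`, `test`, `statistic` (the coefficient),
#'   `p`, `effect` (the coefficient again, for uniformity).
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    pairsig_input_error("correlation needs equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance input: correlation undefined", call. = FALSE)
    return(data.frame(variable = method, test = method,
                      statistic = NA_real_, p = NA_real_, effect = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  data.frame(variable = method, test = method,
             statistic = unname(ct$estimate), p = ct$p.value,
             effect = unname(ct$estimate))
}

#' Tumor mutational burden: mutations per megabase
#'
#' @param mutation_counts named nonnegative per-sample mutation counts.
#' @param exome_megabases sequenced exome size in megabases (default 38).
#' @return named numeric vector of TMB values (mutations/Mb).
#' @export
tmb <- function(mutation_counts, exome_megabases = 38.0) {
  if (any(mutation_counts < 0))
    pairsig_input_error("negative mutation count")
  if (exome_megabases <= 0)
    pairsig_input_error("exome size must be positive")
  mutation_counts / exome_megabases
}
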