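#' Construct a signature model
#'
#' A signature is an ordered list of oriented gene pairs with Cox regression
#' coefficients: the risk score of a sample is
#' `sum_i beta_i * 1[expr(gene_a_i) > expr(gene_b_i)]`.
#'
#' @param gene_a,gene_b character vectors of pair members (indicator is 1
#'   when gene_a is expressed above gene_b).
#' @param beta finite nonzero coefficients (log hazard ratios).
#' @param cutoff optional training-derived risk cutoff.
#' @param provenance free-text label recording where the model came from.
#' @return data.frame of class `signature_model` with columns `pair_id`,
#'   `gene_a`, `gene_b`, `beta`; attributes `cutoff` and `provenance`.
#' @export
signature_model <- function(gene_a, gene_b, beta, cutoff = NULL,
                            provenance = "user") {
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(beta))
    pairsig_input_error("gene_a, gene_b and beta must have equal length")
  if (any(gene_a == gene_b))
    pairsig_input_error("a pair cannot relate a gene to itself")
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || any(beta == 0))
    pairsig_input_error("coefficients must be finite and nonzero")
  pair_id <- paste(gene_a, gene_b, sep = "|")
  if (anyDuplicated(pair_id))
    pairsig_input_error("duplicate pairs in signature")
  sig <- data.frame(pair_id = pair_id, gene_a = as.character(gene_a),
                    gene_b = as.character(gene_b), beta = beta,
                    stringsAsFactors = FALSE)
  attr(sig, "cutoff") <- cutoff
  attr(sig, "provenance") <- provenance
  class(sig) <- c("signature_model", "data.frame")
  sig
}

#' Load a signature from file or from the packaged fixture
#'
#' `source = "table2"` loads the packaged 23-pair B cell-related prognostic
#' signature for non-small cell lung cancer (28 distinct genes), with the
#' published multivariate Cox coefficients. Otherwise `source` is a path to
#' a tab-separated file with columns `pair_id`, `gene_a`, `gene_b`,
#' `coefficient`.
#'
#' @param source `"table2"` or a file path.
#' @return a `signature_model` in file order.
#' @export
load_signature <- function(source = "table2") {
  path <- if (identical(source, "table2")) {
    system.file("extdata", "table2_signature.tsv", package = "pairsig",
                mustWork = TRUE)
  } else source
  if (!file.exists(path))
    pairsig_input_error(sprintf("signature file not found: %s", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pair_id", "gene_a", "gene_b", "coefficient")
  if (!all(need %in% names(tab)))
    pairsig_input_error(paste("signature file needs columns:",
                              paste(need, collapse = ", ")))
  if (anyNA(suppressWarnings(as.numeric(tab$coefficient))))
    pairsig_input_error("non-numeric or missing coefficient in signature")
  signature_model(tab$gene_a, tab$gene_b, as.numeric(tab$coefficient),
                  provenance = if (identical(source, "table2"))
                    "packaged: published NSCLC 23-pair signature" else source)
}

#' Write a signature model as TSV
#'
#' Coefficients are serialized with full precision (`%.17g`) so the file
#' round-trips bit-exactly through [load_signature()].
#'
#' @param sig a `signature_model`.
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  out <- data.frame(pair_id = sig$pair_id, gene_a = sig$gene_a,
                    gene_b = sig$gene_b,
                    coefficient = sprintf("%.17g", sig$beta))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute weighted gene-pair risk scores
#'
#' Per sample, each signature pair contributes its coefficient when gene_a
#' is expressed above gene_b (the indicator rule of [build_pair_matrix()]);
#' the risk score is the coefficient-weighted sum of indicators.
#'
#' @param expr expression matrix containing every signature gene.
#' @param sig a `signature_model`.
#' @return data.frame of class `risk_scores` with columns `sample_id`,
#'   `risk_score`.
#' @export
compute_risk_scores <- function(expr, sig) {
  genes <- union(sig$gene_a, sig$gene_b)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent))
    pairsig_input_error(paste("signature genes absent from expression matrix:",
                              paste(absent, collapse = ", ")))
  ind <- (expr[sig$gene_a, , drop = FALSE] >
            expr[sig$gene_b, , drop = FALSE]) * 1
  scores <- drop(crossprod(ind, sig$beta))
  out <- data.frame(sample_id = colnames(expr), risk_score = scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Assign high/low risk groups at a cutoff
#'
#' Scores strictly above the cutoff are labelled `high`; scores at or below
#' it are `low` (the cutoff itself — typically the Youden-optimal threshold,
#' which is an attained score value — goes to the low-risk group).
#'
#' @param scores a `risk_scores` data.frame.
#' @param cutoff finite risk cutoff.
#' @return `scores` with a `risk_group` factor column (levels low, high).
#' @export
stratify <- function(scores, cutoff) {
  if (!is.finite(cutoff)) pairsig_input_error("cutoff must be finite")
  scores$risk_group <- factor(ifelse(scores$risk_score > cutoff,
                                     "high", "low"),
                              levels = c("low", "high"))
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Write risk scores (and groups, if assigned) as TSV
#' @param scores a `risk_scores` data.frame.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  out$risk_score <- sprintf("%.12g", out$risk_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
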