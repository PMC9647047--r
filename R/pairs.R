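#' Variability screen by median absolute deviation
#'
#' Keeps genes whose across-sample median absolute deviation strictly exceeds
#' `threshold`. By default the raw MAD, `median(|x - median(x)|)`, is used
#' with no consistency constant; set `constant = 1.4826` for the
#' normal-consistent estimator.
#'
#' @param expr expression matrix (genes x samples).
#' @param threshold nonnegative cut; genes with MAD > threshold are kept.
#' @param constant multiplier applied to the raw MAD (default 1, i.e. none).
#' @return character vector of retained gene ids, input order preserved.
#' @export
mad_filter <- function(expr, threshold = 0.5, constant = 1) {
  if (ncol(expr) < 2)
    pairsig_input_error("MAD filter needs at least 2 samples")
  if (threshold < 0) pairsig_input_error("MAD threshold must be >= 0")
  m <- apply(expr, 1L, function(x) mad(x, constant = constant))
  rownames(expr)[m > threshold]
}

#' Restrict a gene list to genes measured in every cohort
#'
#' @param gene_list character vector of candidate genes.
#' @param cohorts a single expression matrix or a list of them.
#' @return genes present in every cohort, original order preserved; an empty
#'   result raises a warning (downstream pairing will then fail loudly).
#' @export
intersect_available_genes <- function(gene_list, cohorts) {
  if (is.matrix(cohorts)) cohorts <- list(cohorts)
  if (!length(cohorts)) pairsig_input_error("need at least one cohort")
  keep <- gene_list
  for (co in cohorts) keep <- keep[keep %in% rownames(co)]
  if (!length(keep))
    warning("no gene is available in every cohort", call. = FALSE)
  keep
}

#' Encode all gene pairs of a sample set as a 0-or-1 matrix
#'
#' Enumerates every unordered pair of `genes` exactly once; within a pair the
#' gene listed earlier in `genes` is gene A, and the indicator for a sample
#' is 1 when expression(A) > expression(B), otherwise 0 (ties score 0).
#' With n genes the result has n(n-1)/2 pair rows.
#'
#' @param expr expression matrix containing all of `genes`.
#' @param genes character vector (length >= 2) defining pair membership and
#'   orientation.
#' @return a `pair_matrix`: list with `pairs` (data.frame pair_id, gene_a,
#'   gene_b) and `indicators` (0/1 matrix, pairs x samples).
#' @export
build_pair_matrix <- function(expr, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    pairsig_input_error(paste("genes absent from expression matrix:",
                              paste(head(missing, 5), collapse = ", ")))
  if (length(genes) < 2)
    pairsig_input_error("pairing needs at least 2 genes")
  idx <- combn(length(genes), 2L)
  a <- genes[idx[1L, ]]
  b <- genes[idx[2L, ]]
  ind <- (expr[a, , drop = FALSE] > expr[b, , drop = FALSE]) * 1L
  rownames(ind) <- paste(a, b, sep = "|")
  pm <- list(pairs = data.frame(pair_id = rownames(ind), gene_a = a,
                                gene_b = b, stringsAsFactors = FALSE),
             indicators = ind)
  class(pm) <- "pair_matrix"
  pm
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples\n",
              nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' Number of pairs and samples in a pair matrix
#' @param x a `pair_matrix`.
#' @export
dim.pair_matrix <- function(x) dim(x$indicators)

# internal: row subset preserving structure
subset_pairs <- function(pm, keep) {
  pm$pairs <- pm$pairs[keep, , drop = FALSE]
  pm$indicators <- pm$indicators[keep, , drop = FALSE]
  rownames(pm$pairs) <- NULL
  pm
}

#' Prevalence filter on pair indicators
#'
#' Excludes pairs whose indicator is 1 in fewer than `low` or more than
#' `high` of samples: such pairs carry little variation and no contrast
#' between patients. Boundaries are inclusive: a pair with prevalence
#' exactly `low` or `high` is kept.
#'
#' @param pm a `pair_matrix`.
#' @param low,high prevalence bounds, `0 <= low < high <= 1`.
#' @return filtered `pair_matrix`, pair order preserved.
#' @export
prevalence_filter <- function(pm, low = 0.2, high = 0.8) {
  if (!inherits(pm, "pair_matrix") || nrow(pm$indicators) == 0)
    pairsig_input_error("empty pair matrix")
  if (!(low >= 0 && low < high && high <= 1))
    pairsig_input_error("need 0 <= low < high <= 1")
  f <- rowMeans(pm$indicators)
  subset_pairs(pm, f >= low & f <= high)
}

#' Write a pair matrix as TSV (pair_id + one 0/1 column per sample)
#' @param pm a `pair_matrix`.
#' @param path output path.
#' @export
write_pair_matrix <- function(pm, path) {
  out <- data.frame(pair_id = pm$pairs$pair_id, pm$indicators,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
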