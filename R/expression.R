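#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix, genes in rows and samples
#' in columns, with unique non-empty row and column names. Values are assumed
#' to be on a monotone within-sample scale (e.g. log2 abundance); the pair
#' encoding only ever compares two genes within one sample, so the absolute
#' scale is irrelevant.
#'
#' Genes carrying any missing value are dropped with a warning: the pair
#' indicator is undefined for a missing comparison, and downstream filters
#' assume complete rows.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids,sample_ids optional character vectors overriding
#'   `dimnames(values)`.
#' @return a validated numeric matrix with `gene_ids` as rownames and
#'   `sample_ids` as colnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    pairsig_input_error("expression values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    pairsig_input_error("expression matrix needs gene and sample identifiers")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids))
    pairsig_input_error("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(sample_ids))
    pairsig_input_error("duplicate sample identifiers in expression matrix")
  dimnames(values) <- list(gene_ids, sample_ids)
  bad <- !complete.cases(values) | rowSums(!is.finite(values)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d gene(s) with missing or non-finite values: %s",
                    sum(bad), paste(head(gene_ids[bad], 5), collapse = ", ")),
            call. = FALSE)
    values <- values[!bad, , drop = FALSE]
  }
  values
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row starting with `gene_id` followed by sample ids, and
#' one row per gene.
#'
#' @param path file path.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    pairsig_input_error(sprintf("expression file not found: %s", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    pairsig_input_error("expression file needs a gene_id column plus samples")
  genes <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  expression_matrix(values, gene_ids = genes, sample_ids = colnames(tab)[-1L])
}

#' Write an expression matrix as a tab-separated file
#'
#' Values are serialized with 12 significant digits so that a write/read
#' round trip reproduces the matrix to that precision.
#'
#' @param expr expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- cbind(gene_id = rownames(expr),
               as.data.frame(apply(expr, 2, function(v) sprintf("%.12g", v))))
  colnames(out) <- c("gene_id", colnames(expr))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `sample_id`, `os_days`, `event` and any number
#' of clinicopathologic covariates (age_years, gender, stage, t_stage,
#' n_stage, m_stage, histology, ...).
#'
#' @param path file path.
#' @return data.frame with character sample ids.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    pairsig_input_error(sprintf("clinical file not found: %s", path))
  cl <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "os_days", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    pairsig_input_error(paste("clinical table missing column(s):",
                              paste(miss, collapse = ", ")))
  cl$sample_id <- as.character(cl$sample_id)
  if (any(cl$os_days < 0)) pairsig_input_error("negative survival times")
  if (!all(cl$event %in% c(0, 1)))
    pairsig_input_error("event indicator must be 0/1")
  cl
}

#' Read a per-sample mutation count table
#'
#' Tab-separated with columns `sample_id` and `mutation_count`.
#'
#' @param path file path.
#' @return named integer vector of counts, names = sample ids.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path))
    pairsig_input_error(sprintf("mutation file not found: %s", path))
  mu <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "mutation_count") %in% names(mu)))
    pairsig_input_error("mutation table needs sample_id and mutation_count")
  setNames(as.numeric(mu$mutation_count), as.character(mu$sample_id))
}
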