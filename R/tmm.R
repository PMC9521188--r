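#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample scaling factors for a count
#' matrix: the reference sample is picked by the upper-quartile rule, M/A
#' log-ratios are trimmed (30% on M, 5% on A, two-sided) and combined with
#' precision weights, and the factors are centred so their product is 1.
#' Computation is delegated to edgeR's TMM implementation.
#'
#' @param counts Count tibble: `gene_id` plus one non-negative integer column
#'   per sample.
#' @return Tibble: `sample_id`, `lib_size` (column sum), `norm_factor`.
#' @examples
#' d <- time_course_design(n_genes = 50)
#' sim <- simulate_counts(d, planted_truth(d, seed = 3))
#' normalize_tmm(sim$counts)
#' @export
normalize_tmm <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  zero <- colSums(m) == 0
  if (any(zero)) {
    abort(sprintf("sample '%s' has all-zero counts", colnames(m)[which(zero)[1]]))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM")
  tibble(sample_id = colnames(m),
         lib_size = unname(colSums(m)),
         norm_factor = unname(f))
}

# Count tibble (gene_id + sample columns) -> integer matrix with rownames.
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  if (anyDuplicated(counts$gene_id)) abort("duplicate gene_id in count table")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$gene_id
  m
}
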