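#' Z-scale expression trajectories
#'
#' Row-wise standardization of per-gene time profiles: `(x - mean) / sd`
#' with the sample standard deviation (n - 1 denominator). Rows with zero
#' variance carry no trajectory shape; they are excluded and listed in the
#' `excluded` attribute.
#'
#' @param profiles Tibble with `gene_id` and one numeric column per time
#'   point (conventionally `t_0`, `t_0.5`, ...), or a numeric matrix with
#'   gene rownames.
#' @return Tibble of the same shape restricted to scalable rows, each row
#'   with mean 0 and sd 1; attribute `excluded` holds the zero-variance gene
#'   ids.
#' @examples
#' p <- tibble::tibble(gene_id = c("a", "b"),
#'                     t_0 = c(1, 2), t_1 = c(2, 2), t_3 = c(3, 2))
#' z <- zscale(p)
#' attr(z, "excluded")  # "b" is constant
#' @export
zscale <- function(profiles) {
  if (is.matrix(profiles)) {
    profiles <- dplyr::bind_cols(
      tibble(gene_id = rownames(profiles) %||% as.character(seq_len(nrow(profiles)))),
      as_tibble(as.data.frame(profiles)))
  }
  value_cols <- setdiff(names(profiles), "gene_id")
  if (length(value_cols) < 2) abort("need at least two time points to z-scale")
  m <- as.matrix(profiles[, value_cols])
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-finite profile value for gene '%s'",
                  profiles$gene_id[bad[1, 1]]))
  }
  sds <- row_sds(m)
  keep <- sds > 0
  z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) / sds[keep]
  out <- dplyr::bind_cols(tibble(gene_id = profiles$gene_id[keep]),
                          as_tibble(as.data.frame(z)))
  attr(out, "excluded") <- profiles$gene_id[!keep]
  out
}

#' Replicate-averaged expression profiles from counts
#'
#' Builds the per-gene time profiles that feed [zscale()]: normalized
#' expression `log2(CPM + 1)` (CPM on TMM-effective library sizes) averaged
#' over the replicates of each time point.
#'
#' @inheritParams estimate_dispersions
#' @param genes Optional gene ids to keep (e.g. the DEG union).
#' @return Tibble: `gene_id` plus one `t_*` column per time point.
#' @export
expression_profiles <- function(counts, samples, factors = NULL, genes = NULL) {
  m <- counts_matrix(counts)
  samples <- align_samples(samples, colnames(m))
  if (is.null(factors)) factors <- normalize_tmm(counts)
  eff <- effective_libsize(factors, colnames(m))
  logcpm <- log2(sweep(m, 2, eff / 1e6, `/`) + 1)
  tps <- sort(unique(samples$timepoint_h))
  prof <- vapply(tps, function(tp) {
    rowMeans(logcpm[, samples$timepoint_h == tp, drop = FALSE])
  }, numeric(nrow(m)))
  colnames(prof) <- timepoint_cols(tps)
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)),
                          as_tibble(as.data.frame(prof)))
  if (!is.null(genes)) out <- filter(out, .data$gene_id %in% genes)
  out
}
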