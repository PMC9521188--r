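#' Filter contrasts to differentially expressed genes
#'
#' Applies the classical triple filter: a gene is upregulated at time t when
#' `log2FC > log2(fc_threshold)`, `FDR < fdr_max` and `p < p_max` (strictly
#' more than an `fc_threshold`-fold change), and downregulated with
#' `log2FC < -log2(fc_threshold)`. Untested genes (`NA` statistics) are never
#' DEGs. The p and FDR cuts are applied jointly, exactly as stated, even
#' though the FDR cut usually implies the p cut.
#'
#' @param contrasts Contrast tibble with `gene_id`, `timepoint_h`, `log2FC`,
#'   `p`, `FDR` (e.g. [test_all_contrasts()] or [read_stats_table()]).
#' @param fc_threshold Fold-change threshold (strict). Default 2.
#' @param fdr_max FDR ceiling (strict). Default 0.01.
#' @param p_max Raw-p ceiling (strict). Default 0.01.
#' @return DEG tibble: `gene_id`, `timepoint_h`, `direction` (`"up"`/
#'   `"down"`), plus the filter thresholds as attributes.
#' @examples
#' ct <- tibble::tibble(gene_id = c("a", "b"), timepoint_h = 1,
#'                      log2FC = c(1.2, 2), p = c(0.001, 0.02),
#'                      FDR = c(0.005, 0.005))
#' filter_degs(ct)  # only gene "a" passes (gene "b" fails p < 0.01)
#' @export
filter_degs <- function(contrasts, fc_threshold = 2, fdr_max = 0.01,
                        p_max = 0.01) {
  need <- c("gene_id", "timepoint_h", "log2FC", "p", "FDR")
  missing <- setdiff(need, names(contrasts))
  if (length(missing)) {
    abort(sprintf("contrast table is missing column '%s'", missing[1]))
  }
  lfc_cut <- log2(fc_threshold)
  degs <- contrasts |>
    filter(!is.na(.data$log2FC), !is.na(.data$p), !is.na(.data$FDR),
           .data$FDR < fdr_max, .data$p < p_max,
           abs(.data$log2FC) > lfc_cut) |>
    mutate(direction = ifelse(.data$log2FC > 0, "up", "down")) |>
    select("gene_id", "timepoint_h", "direction") |>
    arrange(.data$timepoint_h, .data$direction, .data$gene_id)
  attr(degs, "fc_threshold") <- fc_threshold
  attr(degs, "fdr_max") <- fdr_max
  attr(degs, "p_max") <- p_max
  degs
}

#' Per-time-point DEG counts and the deduplicated union
#'
#' Summarizes a DEG table into the familiar per-time-point up/down/total
#' counts; a gene significant at several time points (or in both directions)
#' counts once in the union.
#'
#' @param degs DEG tibble from [filter_degs()].
#' @param timepoints_h Optional time points to report (zero rows filled in).
#' @return Tibble: `timepoint_h`, `up`, `down`, `total`; the union size is in
#'   attribute `union_size` (also returned by [deg_union()]).
#' @export
deg_counts <- function(degs, timepoints_h = NULL) {
  tab <- degs |>
    count(.data$timepoint_h, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("up", "down")) if (!col %in% names(tab)) tab[[col]] <- 0L
  if (!is.null(timepoints_h)) {
    tab <- tibble(timepoint_h = setdiff(timepoints_h, 0)) |>
      left_join(tab, by = "timepoint_h") |>
      mutate(across(c("up", "down"), ~ tidyr::replace_na(.x, 0L)))
  }
  tab <- tab |>
    mutate(total = .data$up + .data$down) |>
    select("timepoint_h", "up", "down", "total") |>
    arrange(.data$timepoint_h)
  attr(tab, "union_size") <- deg_union(degs)
  tab
}

#' Size of the deduplicated DEG union
#'
#' @param degs DEG tibble from [filter_degs()].
#' @return Integer: number of distinct genes appearing at any time point in
#'   either direction.
#' @export
deg_union <- function(degs) length(unique(degs$gene_id))
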