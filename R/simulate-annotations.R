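#' Simulate a gene-to-term annotation map with planted enrichments
#'
#' Background membership is uniform: every (gene, term) pair is annotated
#' independently with probability `terms_per_gene / n_terms`, so each gene
#' carries `terms_per_gene` terms in expectation. For each trajectory
#' archetype, `enriched_terms_per_archetype` designated terms are assigned to
#' that archetype's member genes at `fold_enrichment` times the background
#' rate (capped at 1). `fold_enrichment = 1` reduces exactly to the
#' background model, so downstream enrichment p-values are null-uniform.
#'
#' @param truth A [planted_truth()] (supplies genes, archetypes and the seed).
#' @param n_terms Number of annotation terms. Default 200.
#' @param terms_per_gene Expected terms per gene under the background.
#'   Default 10. `0` yields an empty map.
#' @param enriched_terms_per_archetype Designated terms per archetype.
#'   Default 2.
#' @param fold_enrichment Rate multiplier for designated (archetype, term)
#'   pairs; must be >= 1. Default 8.
#' @return List: `annotations` (tibble `gene_id`, `term_id`), `enriched`
#'   (tibble `archetype`, `term_id` of the planted associations), `manifest`.
#' @export
simulate_annotations <- function(truth,
                                 n_terms = 200,
                                 terms_per_gene = 10,
                                 enriched_terms_per_archetype = 2,
                                 fold_enrichment = 8) {
  stopifnot(inherits(truth, "pti_truth"))
  if (fold_enrichment < 1) abort("fold_enrichment must be >= 1")
  n_arch <- nrow(truth$delta)
  if (enriched_terms_per_archetype * n_arch > n_terms) {
    abort("more enriched terms requested than n_terms available")
  }
  if (terms_per_gene > n_terms) abort("terms_per_gene cannot exceed n_terms")
  genes <- truth$genes
  term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
  base_rate <- terms_per_gene / n_terms

  with_seed(derive_seed(truth$seed, "annotations"), {
    enriched <- if (enriched_terms_per_archetype > 0 && n_arch > 0) {
      picks <- sample(term_ids, enriched_terms_per_archetype * n_arch)
      tibble(archetype = rep(seq_len(n_arch), each = enriched_terms_per_archetype),
             term_id = picks)
    } else {
      tibble(archetype = integer(), term_id = character())
    }
    if (terms_per_gene == 0) {
      ann <- tibble(gene_id = character(), term_id = character())
    } else {
      # rate matrix genes x terms: background, lifted for planted pairs
      rate <- matrix(base_rate, nrow(genes), n_terms,
                     dimnames = list(genes$gene_id, term_ids))
      if (fold_enrichment > 1 && nrow(enriched) > 0) {
        for (i in seq_len(nrow(enriched))) {
          members <- genes$archetype == enriched$archetype[i]
          rate[members, enriched$term_id[i]] <-
            min(1, base_rate * fold_enrichment)
        }
      }
      hit <- matrix(runif(length(rate)) < rate, nrow(rate))
      idx <- which(hit, arr.ind = TRUE)
      ann <- tibble(gene_id = genes$gene_id[idx[, 1]],
                    term_id = term_ids[idx[, 2]]) |>
        arrange(.data$gene_id, .data$term_id)
    }
    manifest <- truth_manifest(truth,
                               extra = list(enriched_terms = enriched,
                                            n_terms = n_terms,
                                            terms_per_gene = terms_per_gene,
                                            fold_enrichment = fold_enrichment))
    list(annotations = ann, enriched = enriched, manifest = manifest)
  })
}
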