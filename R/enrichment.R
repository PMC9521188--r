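#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes in a draw of `n`
#' from a universe of `N` genes of which `K` carry the annotation:
#' `p = sum_{x = k}^{min(n, K)} C(K, x) C(N - K, n - x) / C(N, n)`.
#' Evaluated through `stats::phyper` (log-space-stable); arguments are
#' validated against the feasibility bounds
#' `max(0, n + K - N) <= k <= min(n, K)`.
#'
#' @param k Observed overlap count.
#' @param n Cluster (draw) size.
#' @param K Annotation (category) size.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1]. Vectorized.
#' @examples
#' hypergeom_upper_tail(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  with(args, {
    check_int <- function(x, nm) {
      if (any(x < 0) || any(x != round(x))) {
        abort(sprintf("argument '%s' must be a non-negative integer", nm))
      }
    }
    check_int(k, "k"); check_int(n, "n"); check_int(K, "K"); check_int(N, "N")
    if (any(n > N)) abort("argument 'n' exceeds the universe size N")
    if (any(K > N)) abort("argument 'K' exceeds the universe size N")
    if (any(k > pmin(n, K))) abort("argument 'k' exceeds min(n, K)")
    if (any(k < pmax(0, n + K - N))) abort("argument 'k' is below max(0, n + K - N)")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, rep_len, length.out = len)
}

#' Cluster-wise over-representation of annotation categories
#'
#' One upper-tail hypergeometric test per (cluster, category) pair: is the
#' category over-represented among the cluster's genes relative to the
#' universe? Genes outside the declared universe are dropped from both the
#' clusters and the categories (with a message). Benjamini-Hochberg
#' adjustment is applied across all tests within each category class.
#'
#' @param assignment Cluster assignment tibble (`gene_id`, `cluster`), e.g.
#'   `fit$assignment` from [kmeans_cluster()].
#' @param annotations Annotation tibble: `gene_id`, `term_id`, optionally
#'   `class` (e.g. `"GO"`, `"TF-family"`, `"motif"`) and `label`.
#' @param universe Character vector of gene ids forming the background;
#'   default all genes in `annotations` (genome-wide). A common alternative
#'   is the DEG union.
#' @param class Value for the `class` column when `annotations` lacks one.
#' @return A `pti_enrichment` tibble: `cluster`, `term_id`, `class`, `k`
#'   (overlap), `n` (cluster size in universe), `K` (category size in
#'   universe), `N` (universe size), `p`, `q` (BH within class).
#' @examples
#' ann <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
#'                       term_id = c("T1", "T1", "T1", "T2"))
#' cl <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
#'                      cluster = c(1, 1, 1, 2))
#' cluster_enrichment(cl, ann)
#' @export
cluster_enrichment <- function(assignment, annotations, universe = NULL,
                               class = "GO") {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)),
            all(c("gene_id", "cluster") %in% names(assignment)))
  if (!"class" %in% names(annotations)) annotations$class <- class
  if (is.null(universe)) universe <- unique(annotations$gene_id)
  universe <- unique(universe)
  if (length(universe) == 0) abort("the gene universe is empty")
  N <- length(universe)

  dropped <- sum(!unique(annotations$gene_id) %in% universe)
  if (dropped > 0) {
    message(sprintf("%d annotated gene(s) outside the universe dropped", dropped))
  }
  ann <- filter(annotations, .data$gene_id %in% universe)
  asg <- filter(assignment, .data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$cluster)

  cluster_sizes <- count(asg, .data$cluster, name = "n")
  cat_sizes <- ann |> distinct(.data$term_id, .data$class, .data$gene_id) |>
    count(.data$term_id, .data$class, name = "K")

  overlaps <- asg |>
    inner_join(distinct(ann, .data$gene_id, .data$term_id, .data$class),
               by = "gene_id", relationship = "many-to-many") |>
    count(.data$cluster, .data$term_id, .data$class, name = "k")

  cells <- tidyr::expand_grid(cluster = cluster_sizes$cluster,
                              term_id = unique(cat_sizes$term_id)) |>
    left_join(cat_sizes, by = "term_id") |>
    left_join(cluster_sizes, by = "cluster") |>
    left_join(overlaps, by = c("cluster", "term_id", "class")) |>
    mutate(k = tidyr::replace_na(.data$k, 0L), N = N,
           p = hypergeom_upper_tail(.data$k, .data$n, .data$K, N)) |>
    group_by(.data$class) |>
    mutate(q = adjust_bh(.data$p)) |>
    ungroup() |>
    select("cluster", "term_id", "class", "k", "n", "K", "N", "p", "q") |>
    arrange(.data$class, .data$cluster, .data$term_id)
  class(cells) <- c("pti_enrichment", class(cells))
  cells
}

#' Heatmap-ready -log10(p) matrix
#'
#' Arranges cluster-by-category enrichment p-values into the matrix behind
#' the familiar enrichment heatmaps: darker (larger -log10 p) means stronger
#' over-representation. Missing (cluster, category) pairs are 0.
#'
#' @param cells Enrichment table from [cluster_enrichment()].
#' @param clusters Row order; default sorted unique clusters in `cells`.
#' @param categories Column order; default sorted unique categories.
#' @param value Which p to transform: `"p"` (raw, default — as enrichment
#'   heatmap figures conventionally display) or `"q"` (BH-adjusted).
#' @return Numeric matrix, rows = categories, columns = clusters, of
#'   `-log10(p)` values (>= 0).
#' @export
heatmap_matrix <- function(cells, clusters = NULL, categories = NULL,
                           value = c("p", "q")) {
  value <- match.arg(value)
  clusters <- clusters %||% sort(unique(cells$cluster))
  categories <- categories %||% sort(unique(cells$term_id))
  m <- matrix(0, length(categories), length(clusters),
              dimnames = list(categories, as.character(clusters)))
  keep <- cells$term_id %in% categories & cells$cluster %in% clusters
  sub <- cells[keep, ]
  m[cbind(match(sub$term_id, categories),
          match(sub$cluster, clusters))] <- -log10(sub[[value]])
  m
}

#' @rdname cluster_enrichment
#' @param object A `pti_enrichment` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pti_enrichment <- function(object, ...) {
  df <- mutate(as_tibble(object), neglog10_p = -log10(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$term_id,
                                   fill = .data$neglog10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 name = expression(-log[10] * p)) +
    ggplot2::labs(x = "cluster", y = NULL) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::theme_minimal()
}
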