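#' Cluster z-scaled trajectories with k-means
#'
#' Euclidean k-means with careful seeding: each restart draws initial
#' centers with probability proportional to squared distance from the
#' centers already chosen (k-means++), runs the standard k-means iterations,
#' and the solution with the smallest within-cluster sum of squares over
#' `n_restarts` restarts is kept. Restarts that converge with an empty
#' cluster are discarded and replaced. Clusters are then relabeled
#' deterministically — downregulated clusters first, ordered by trough time,
#' then upregulated clusters by peak time — so labels are comparable across
#' runs (the conventional 1..k ordering of time-course cluster figures).
#'
#' A cluster is "down" when its centroid's minimum deviates from 0 more than
#' its maximum; ties are labeled "up".
#'
#' @param traj Z-scaled trajectory tibble from [zscale()] (or
#'   [simulate_trajectories()]).
#' @param k Number of clusters (1 <= k <= number of genes).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param n_restarts Number of seeded restarts. Default 25.
#' @param iter_max Maximum k-means iterations per restart. Default 100.
#' @return A `pti_kmeans` object: `assignment` tibble (`gene_id`, `cluster`,
#'   `direction`), `centroids` (k x timepoints matrix), `W_k`
#'   (within-cluster sum of squares), `totss`, `summary` tibble (cluster,
#'   direction, peak/trough time, size), `z` (the input matrix), `k`,
#'   `seed`.
#' @examples
#' sim <- simulate_trajectories(200, seed = 4)
#' fit <- kmeans_cluster(sim$trajectories[, -2], k = 10, seed = 4)
#' glance(fit)
#' @export
kmeans_cluster <- function(traj, k, seed = 1L, n_restarts = 25, iter_max = 100) {
  z <- traj_matrix(traj)
  n <- nrow(z)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort(sprintf("k = %d exceeds the number of genes (%d)", k, n))
  timepoints <- colnames(z)
  best <- NULL
  with_seed(derive_seed(seed, "kmeans"), {
    done <- 0; attempts <- 0
    while (done < n_restarts && attempts < 5 * n_restarts + 10) {
      attempts <- attempts + 1
      init <- kmeanspp_init(z, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(z, centers = init, iter.max = iter_max)),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0)) next  # empty cluster: replace restart
      done <- done + 1
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) abort("k-means failed to produce a valid solution")
  relabeled <- relabel_clusters(best$centers, best$cluster)
  centroids <- relabeled$centroids
  colnames(centroids) <- timepoints
  assignment <- tibble(gene_id = traj$gene_id,
                       cluster = relabeled$labels,
                       direction = relabeled$summary$direction[relabeled$labels])
  structure(
    list(assignment = assignment,
         centroids = centroids,
         W_k = best$tot.withinss,
         totss = best$totss,
         summary = relabeled$summary,
         z = z, k = k, seed = seed),
    class = "pti_kmeans"
  )
}

traj_matrix <- function(traj) {
  stopifnot(is.data.frame(traj), "gene_id" %in% names(traj))
  cols <- setdiff(names(traj), c("gene_id", "archetype", "cluster", "direction"))
  m <- as.matrix(traj[, cols])
  rownames(m) <- traj$gene_id
  m
}

# k-means++ seeding: first center uniform, then proportional to D^2.
kmeanspp_init <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  idx <- sample.int(n, 1)
  centers[1, ] <- z[idx, ]
  if (k == 1) return(centers)
  d2 <- rowSums((z - matrix(centers[1, ], n, ncol(z), byrow = TRUE))^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- z[idx, ]
    d2 <- pmin(d2, rowSums((z - matrix(centers[j, ], n, ncol(z), byrow = TRUE))^2))
  }
  centers
}

# Deterministic relabeling by (direction, extremum time): down clusters first
# ordered by trough time, then up clusters by peak time; ties by size then
# original label. Direction is judged relative to the centroid's baseline
# (first time point) value, not to 0: a z-scaled sustained-repression profile
# sits high at baseline and below the row mean afterwards, so its largest
# deviation from 0 is the positive baseline — baseline-relative excursions
# classify such shapes correctly. Tie -> up.
relabel_clusters <- function(centers, labels) {
  k <- nrow(centers)
  sizes <- tabulate(labels, nbins = k)
  base <- centers[, 1]
  direction <- unname(ifelse(base - apply(centers, 1, min) >
                               apply(centers, 1, max) - base,
                             "down", "up"))
  ext_time <- vapply(seq_len(k), function(j) {
    if (direction[j] == "down") which.min(centers[j, ]) else which.max(centers[j, ])
  }, integer(1))
  ord <- order(direction != "down", ext_time, -sizes, seq_len(k))
  new_of_old <- match(seq_len(k), ord)
  summary <- tibble(
    cluster = seq_len(k),
    direction = direction[ord],
    extremum_timepoint = ext_time[ord],
    size = sizes[ord]
  )
  list(labels = new_of_old[labels],
       centroids = centers[ord, , drop = FALSE],
       summary = summary)
}

#' Summarize clusters of a trajectory k-means fit
#'
#' Per-cluster mean z-trajectory, direction, peak (or trough) time point and
#' size.
#'
#' @param fit A `pti_kmeans` from [kmeans_cluster()].
#' @param timepoints_h Optional numeric time points to report instead of
#'   column indices.
#' @return Tibble: `cluster`, `direction`, `peak_time_h`, `size`, plus one
#'   centroid column per time point.
#' @export
summarize_clusters <- function(fit, timepoints_h = NULL) {
  stopifnot(inherits(fit, "pti_kmeans"))
  tp <- timepoints_h %||% parse_timepoints(colnames(fit$centroids))
  out <- fit$summary |>
    mutate(peak_time_h = tp[.data$extremum_timepoint]) |>
    select("cluster", "direction", "peak_time_h", "size")
  dplyr::bind_cols(out, as_tibble(as.data.frame(fit$centroids)))
}

parse_timepoints <- function(cols) {
  tp <- suppressWarnings(as.numeric(sub("^t_", "", cols)))
  if (anyNA(tp)) seq_along(cols) else tp
}

#' Select marker genes from clusters
#'
#' Within each requested cluster, genes whose trajectory correlates with the
#' cluster centroid at or above `cor_floor` are ranked by that correlation
#' (ties broken by the gene's maximal absolute log2 fold change across time
#' points) and the top `n_per_cluster` are returned. A cluster where no gene
#' reaches the floor falls back to pure correlation ranking and is flagged.
#'
#' @param fit A `pti_kmeans`.
#' @param contrasts Contrast tibble covering the clustered genes (for the
#'   fold-change tie-break).
#' @param n_per_cluster Markers per cluster. Default 2.
#' @param clusters Clusters to draw from; default all upregulated clusters.
#' @param cor_floor Minimum Pearson correlation with the centroid.
#'   Default 0.8.
#' @return Tibble: `cluster`, `gene_id`, `correlation`, `max_abs_log2FC`,
#'   `rank`, `fallback`.
#' @export
select_markers <- function(fit, contrasts, n_per_cluster = 2,
                           clusters = NULL, cor_floor = 0.8) {
  stopifnot(inherits(fit, "pti_kmeans"))
  if (is.null(clusters)) {
    clusters <- fit$summary$cluster[fit$summary$direction == "up"]
  }
  maxfc <- contrasts |>
    filter(!is.na(.data$log2FC)) |>
    group_by(.data$gene_id) |>
    summarise(max_abs_log2FC = max(abs(.data$log2FC)), .groups = "drop")
  purrr::map_dfr(clusters, function(cl) {
    idx <- which(fit$assignment$cluster == cl)
    if (length(idx) == 0) return(NULL)
    genes <- fit$assignment$gene_id[idx]
    cen <- fit$centroids[cl, ]
    cors <- apply(fit$z[idx, , drop = FALSE], 1, stats::cor, y = cen)
    tab <- tibble(cluster = cl, gene_id = genes, correlation = unname(cors)) |>
      left_join(maxfc, by = "gene_id") |>
      mutate(max_abs_log2FC = dplyr::coalesce(.data$max_abs_log2FC, 0))
    eligible <- tab |> filter(.data$correlation >= cor_floor)
    fallback <- nrow(eligible) == 0
    pool <- if (fallback) tab else eligible
    pool |>
      arrange(dplyr::desc(.data$correlation), dplyr::desc(.data$max_abs_log2FC),
              .data$gene_id) |>
      head(n_per_cluster) |>
      mutate(rank = dplyr::row_number(), fallback = fallback)
  })
}

#' @export
print.pti_kmeans <- function(x, ...) {
  cat(sprintf("<pti_kmeans> k = %d, %d genes, W_k = %.3f\n",
              x$k, nrow(x$assignment), x$W_k))
  print(x$summary)
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x,object A `pti_kmeans`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pti_kmeans <- function(x, ...) summarize_clusters(x)

#' @rdname kmeans_cluster
#' @exportS3Method generics::glance
glance.pti_kmeans <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignment), W_k = x$W_k,
         totss = x$totss, betweenss = x$totss - x$W_k,
         prop_explained = 1 - x$W_k / x$totss)
}

#' @rdname kmeans_cluster
#' @exportS3Method ggplot2::autoplot
autoplot.pti_kmeans <- function(object, ...) {
  tp <- parse_timepoints(colnames(object$centroids))
  cen <- as.data.frame(object$centroids)
  cen$cluster <- seq_len(nrow(cen))
  long <- tidyr::pivot_longer(cen, -"cluster", names_to = "timepoint",
                              values_to = "z")
  long$timepoint_h <- tp[match(long$timepoint, colnames(object$centroids))]
  long$direction <- object$summary$direction[long$cluster]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint_h, y = .data$z,
                                     colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time after treatment (h)", y = "centroid z-score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
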