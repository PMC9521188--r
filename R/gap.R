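#' Gap statistic for choosing the number of clusters
#'
#' For each candidate k, compares the log within-cluster dispersion of the
#' data, `log W_k`, to its expectation under a reference null of no cluster
#' structure: B datasets drawn uniformly over the per-feature ranges of the
#' data, clustered the same way. `gap(k) = E*[log W_k] - log W_k`, with
#' reference standard error `s_k = sd_B(log W*_k) * sqrt(1 + 1/B)`. The
#' selected k is the smallest k with `gap(k) >= gap(k+1) - s_{k+1}` (the
#' one-standard-error rule); if no k satisfies it, the largest candidate is
#' returned.
#'
#' @param traj Z-scaled trajectory tibble (see [zscale()]).
#' @param k_range Candidate cluster numbers. Default `1:12`.
#' @param B Number of reference datasets (>= 10). Default 50.
#' @param seed Integer seed.
#' @param n_restarts Restarts for clustering the data. Default 25.
#' @param n_restarts_ref Restarts for each reference dataset (fewer, since
#'   only the dispersion is needed). Default 5.
#' @return A `pti_gap` object: `curve` tibble (`k`, `log_W`, `E_log_W`,
#'   `gap`, `s`), `selected_k`, `B`.
#' @examples
#' sim <- simulate_trajectories(150, seed = 2)
#' g <- gap_statistic(sim$trajectories[, -2], k_range = 1:4, B = 10, seed = 2)
#' g$curve
#' @export
gap_statistic <- function(traj, k_range = 1:12, B = 50, seed = 1L,
                          n_restarts = 25, n_restarts_ref = 5) {
  if (B < 10) abort("B must be >= 10")
  z <- traj_matrix(traj)
  n <- nrow(z)
  if (any(k_range < 1) || any(k_range >= n)) {
    abort("k_range must lie within [1, n_genes)")
  }
  rng <- apply(z, 2, range)
  if (all(rng[1, ] == rng[2, ])) abort("degenerate data: all points identical")
  k_range <- sort(unique(k_range))

  log_W <- vapply(k_range, function(k) {
    log(kmeans_cluster(traj, k, seed = seed + k, n_restarts = n_restarts)$W_k)
  }, numeric(1))

  ref_log_W <- with_seed(derive_seed(seed, "gap-reference"), {
    vapply(seq_len(B), function(b) {
      ref <- vapply(seq_len(ncol(z)), function(j) {
        runif(n, rng[1, j], rng[2, j])
      }, numeric(n))
      ref_tbl <- dplyr::bind_cols(tibble(gene_id = as.character(seq_len(n))),
                                  as_tibble(as.data.frame(ref)))
      vapply(k_range, function(k) {
        log(kmeans_cluster(ref_tbl, k, seed = seed + 1000L * b + k,
                           n_restarts = n_restarts_ref)$W_k)
      }, numeric(1))
    }, numeric(length(k_range)))
  })
  ref_log_W <- matrix(ref_log_W, nrow = length(k_range))
  E_log_W <- rowMeans(ref_log_W)
  s <- apply(ref_log_W, 1, sd) * sqrt(1 + 1 / B)
  gap <- E_log_W - log_W

  selected <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1)) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) { selected <- k_range[i]; break }
  }
  structure(
    list(curve = tibble(k = k_range, log_W = log_W, E_log_W = E_log_W,
                        gap = gap, s = s),
         selected_k = selected, B = B, seed = seed),
    class = "pti_gap"
  )
}

#' @export
print.pti_gap <- function(x, ...) {
  cat(sprintf("<pti_gap> selected k = %d (B = %d references)\n",
              x$selected_k, x$B))
  print(x$curve)
  invisible(x)
}

#' @rdname gap_statistic
#' @param x,object A `pti_gap`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pti_gap <- function(x, ...) x$curve

#' @rdname gap_statistic
#' @exportS3Method generics::glance
glance.pti_gap <- function(x, ...) {
  tibble(selected_k = x$selected_k, B = x$B,
         max_gap_k = x$curve$k[which.max(x$curve$gap)])
}

#' @rdname gap_statistic
#' @exportS3Method ggplot2::autoplot
autoplot.pti_gap <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$s,
                                          ymax = .data$gap + .data$s)) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic") +
    ggplot2::theme_minimal()
}
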