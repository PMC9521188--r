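#' Simulate a negative-binomial time-course count matrix
#'
#' Draws gene-level counts for every sample in the design from a negative
#' binomial with mean `mu_g * 2^delta[a(g), t] * s_j` and variance
#' `mean + phi_g * mean^2`, where `s_j` is a per-sample library-size factor
#' drawn log-uniformly from `size_factor_range` (so between-sample
#' normalization is non-trivial) and `delta` is the planted archetype
#' trajectory of gene g (null genes are flat). Fully deterministic for a
#' fixed truth seed.
#'
#' @param design A [time_course_design()].
#' @param truth A [planted_truth()] built on the same design.
#' @param size_factor_range Range of the log-uniform library-size factors.
#'   Default `c(0.7, 1.4)`.
#' @return A list with
#'   * `counts`: tibble, `gene_id` plus one integer column per sample;
#'   * `samples`: the design's sample sheet with the drawn `size_factor`;
#'   * `manifest`: a [truth_manifest()] recording every planted value.
#' @examples
#' d <- time_course_design(n_genes = 20)
#' sim <- simulate_counts(d, planted_truth(d, seed = 7))
#' sim$counts
#' @export
simulate_counts <- function(design, truth, size_factor_range = c(0.7, 1.4)) {
  stopifnot(inherits(design, "pti_design"), inherits(truth, "pti_truth"))
  if (nrow(truth$genes) != design$n_genes) {
    abort("design and truth disagree on the number of genes")
  }
  bad <- which(truth$genes$mu <= 0 | truth$genes$phi <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive mu or phi for gene index %d", bad[1]))
  }
  samples <- design$samples
  n <- design$n_genes
  counts <- with_seed(derive_seed(truth$seed, "counts"), {
    s_j <- exp(runif(nrow(samples), log(size_factor_range[1]),
                     log(size_factor_range[2])))
    samples$size_factor <- s_j
    a <- truth$genes$archetype
    t_idx <- match(samples$timepoint_h, design$timepoints_h)
    # per-gene per-sample mean: flat for null genes, 2^delta modulated otherwise
    m <- matrix(truth$genes$mu, n, nrow(samples))
    resp <- a > 0
    if (any(resp)) {
      m[resp, ] <- m[resp, ] * 2^truth$delta[a[resp], t_idx, drop = FALSE]
    }
    m <- sweep(m, 2, s_j, `*`)
    cnt <- matrix(rnbinom(length(m), mu = m, size = 1 / truth$genes$phi),
                  n, nrow(samples))
    colnames(cnt) <- samples$sample_id
    cnt
  })
  # with_seed returns the matrix; recompute size factors deterministically for
  # the sample sheet (same stream, first draws)
  s_j <- with_seed(derive_seed(truth$seed, "counts"), {
    exp(runif(nrow(samples), log(size_factor_range[1]), log(size_factor_range[2])))
  })
  samples$size_factor <- s_j
  counts_tbl <- bind_cols_counts(truth$genes$gene_id, counts)
  manifest <- truth_manifest(truth, design,
                             extra = list(size_factors =
                                            setNames(s_j, samples$sample_id)))
  list(counts = counts_tbl, samples = samples, manifest = manifest)
}

bind_cols_counts <- function(gene_id, m) {
  storage.mode(m) <- "integer"
  out <- as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble(gene_id = gene_id), out)
  out
}

#' Simulate z-scaled expression trajectories with planted archetypes
#'
#' Direct trajectory-level generator used to benchmark the clustering stage
#' in isolation: each gene's profile is its archetype's z-scaled trajectory
#' plus i.i.d. Gaussian noise (in z-units), then re-standardized row-wise.
#'
#' @param n_genes Number of trajectories.
#' @param archetypes Log2-offset matrix as in [default_archetypes()]; rows are
#'   z-scaled internally.
#' @param noise_sd Gaussian noise standard deviation in z-units. Default 0.3.
#' @param seed Integer seed.
#' @return A list with `trajectories` (tibble: `gene_id`, `archetype`, one
#'   `t_*` column per timepoint, rows z-scaled) and `labels` (integer vector).
#' @export
simulate_trajectories <- function(n_genes,
                                  archetypes = default_archetypes(),
                                  noise_sd = 0.3,
                                  seed = 1L) {
  k <- nrow(archetypes)
  z_arch <- t(apply(archetypes, 1, function(r) (r - mean(r)) / sd(r)))
  with_seed(derive_seed(seed, "trajectories"), {
    labels <- rep_len(seq_len(k), n_genes)[sample.int(n_genes)]
    z <- z_arch[labels, , drop = FALSE] +
      matrix(rnorm(n_genes * ncol(z_arch), sd = noise_sd), n_genes)
    z <- (z - rowMeans(z)) / row_sds(z)
    colnames(z) <- colnames(archetypes)
    traj <- dplyr::bind_cols(
      tibble(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
             archetype = labels),
      as_tibble(as.data.frame(z))
    )
    list(trajectories = traj, labels = labels)
  })
}

#' Assemble a truth manifest
#'
#' A serializable record of everything planted by the generators — gene to
#' archetype assignments, NB parameters, archetype trajectories, motif odds,
#' planted motif occurrences, enriched annotation terms and the seed —
#' sufficient to score parameter and cluster recovery without re-simulation.
#'
#' @param truth A [planted_truth()].
#' @param design The matching [time_course_design()] (optional).
#' @param extra Named list of additional components (planted motif positions,
#'   enriched terms, size factors, ...).
#' @return A `pti_manifest` list.
#' @export
truth_manifest <- function(truth, design = NULL, extra = list()) {
  out <- c(list(
    seed = truth$seed,
    genes = truth$genes,
    delta = truth$delta,
    motif_odds = truth$motif_odds,
    timepoints_h = design$timepoints_h %||% NULL
  ), extra)
  structure(out, class = "pti_manifest")
}

#' Write a truth manifest to JSON
#'
#' @param manifest A `pti_manifest`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor", force = TRUE)
  invisible(path)
}
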