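#' Describe a time-course experimental design
#'
#' Captures the sampling layout of a baseline-anchored time-course RNA-seq
#' experiment: leaf tissue harvested at a series of time points after
#' elicitor treatment, with biological replicates at each point. The first
#' time point is the untreated 0 h baseline every later point is contrasted
#' against.
#'
#' @param timepoints_h Strictly increasing numeric vector of sampling times in
#'   hours; the first entry must be 0 (the baseline). Default
#'   `c(0, 0.5, 1, 3, 6, 12)`.
#' @param replicates Biological replicates per time point (>= 2). Default 3.
#' @param n_genes Number of genes to simulate. Default 2000.
#' @param library_size_target Optional expected total counts per sample. When
#'   supplied, baseline means are rescaled so the expected column sum at the
#'   baseline matches it; `NULL` (default) leaves gene means as given.
#' @return A `pti_design` list with the validated fields and a `samples`
#'   tibble (`sample_id`, `timepoint_h`, `replicate`).
#' @examples
#' d <- time_course_design(n_genes = 50)
#' d$samples
#' @export
time_course_design <- function(timepoints_h = c(0, 0.5, 1, 3, 6, 12),
                               replicates = 3,
                               n_genes = 2000,
                               library_size_target = NULL) {
  if (length(timepoints_h) < 2 || any(diff(timepoints_h) <= 0)) {
    abort("timepoints_h must be strictly increasing with at least two points")
  }
  if (timepoints_h[1] != 0) abort("the first timepoint must be the 0 h baseline")
  if (any(timepoints_h < 0)) abort("timepoints_h must be non-negative")
  if (replicates < 2) abort("replicates must be >= 2")
  if (n_genes < 1) abort("n_genes must be positive")
  samples <- tidyr::expand_grid(timepoint_h = timepoints_h,
                                replicate = seq_len(replicates)) |>
    mutate(sample_id = sprintf("T%s_r%d", .data$timepoint_h, .data$replicate)) |>
    select("sample_id", "timepoint_h", "replicate")
  structure(
    list(timepoints_h = as.numeric(timepoints_h),
         replicates = as.integer(replicates),
         n_genes = as.integer(n_genes),
         library_size_target = library_size_target,
         samples = samples),
    class = "pti_design"
  )
}

#' @export
print.pti_design <- function(x, ...) {
  cat(sprintf("<pti_design> %d genes, %d timepoints (%s h), %d replicates\n",
              x$n_genes, length(x$timepoints_h),
              paste(x$timepoints_h, collapse = ", "), x$replicates))
  invisible(x)
}

#' Default planted trajectory archetypes
#'
#' Ten log2 fold-change trajectories over `timepoints_h`, anchored at 0 at the
#' baseline. Archetypes 1-4 are downregulated (a rapid sustained drop; a
#' transient drop bottoming at 3 h that recovers by 12 h; a gradual decline
#' bottoming at 12 h; a sharp early drop at 1 h with partial recovery) and
#' archetypes 5-10 are upregulated with peaks at 0.5, 1, 3, 6 h, a sustained
#' 6-and-12 h plateau, and 12 h respectively — the trajectory shapes typically
#' resolved by k-means clustering of elicitor-response time courses. The
#' shapes were chosen once so that their z-scaled profiles are mutually well
#' separated (minimum pairwise Euclidean distance about 1.6 z-units).
#'
#' @param timepoints_h Time grid; only the default 6-point grid has built-in
#'   shapes, other grids must supply their own archetype matrix.
#' @return A 10 x length(timepoints_h) matrix of log2 offsets, rows named
#'   `archetype_1` ... `archetype_10`.
#' @export
default_archetypes <- function(timepoints_h = c(0, 0.5, 1, 3, 6, 12)) {
  if (length(timepoints_h) != 6) {
    abort("built-in archetypes are defined on the 6-point grid; supply a custom matrix")
  }
  m <- rbind(
    c(0, -1.5, -3.0, -3.0, -3.0, -3.0),  # rapid sustained down
    c(0, -0.5, -2.0, -3.0, -2.0,  0.0),  # down at 3 h, recovered by 12 h
    c(0, -0.5, -1.0, -1.5, -2.5, -3.5),  # gradual decline, trough 12 h
    c(0, -2.0, -3.0, -2.0, -1.5, -1.0),  # sharp early down, partial recovery
    c(0,  3.0,  2.0,  0.5,  0.0,  0.0),  # peak 0.5 h
    c(0,  1.5,  3.0,  1.5,  0.5,  0.0),  # peak 1 h
    c(0,  0.5,  1.5,  3.0,  1.5,  0.5),  # peak 3 h
    c(0,  0.0,  0.0,  1.0,  3.0,  0.5),  # peak 6 h
    c(0,  0.0,  0.0,  2.0,  3.0,  3.0),  # plateau at 6 and 12 h
    c(0,  0.0,  0.0,  0.0,  0.5,  3.0)   # peak 12 h
  )
  dimnames(m) <- list(paste0("archetype_", 1:10), timepoint_cols(timepoints_h))
  m
}

validate_archetypes <- function(delta) {
  if (any(delta[, 1] != 0)) abort("archetype trajectories must be 0 at the baseline")
  n <- nrow(delta)
  n_down <- min(4L, n)
  for (a in seq_len(n)) {
    lo <- min(delta[a, ]); hi <- max(delta[a, ])
    if (a <= n_down && !(lo < 0 && hi <= 0)) {
      abort(sprintf("archetype %d must be downregulated (min < 0, max <= 0)", a))
    }
    if (a > n_down && !(hi > 0 && lo >= 0)) {
      abort(sprintf("archetype %d must be upregulated (max > 0, min >= 0)", a))
    }
  }
  invisible(delta)
}

#' Planted ground truth for a synthetic experiment
#'
#' Assigns each gene a baseline mean, a negative-binomial dispersion and a
#' trajectory archetype (0 = null gene with a flat profile, 1-10 = the planted
#' response archetypes), and fixes per-archetype motif planting odds. The
#' returned object is the single source of truth for [simulate_counts()],
#' [simulate_genome()] and [simulate_annotations()].
#'
#' Counts are NB with variance `mu + phi * mu^2` (dispersion `phi`).
#'
#' @param design A [time_course_design()].
#' @param archetypes Matrix of per-archetype log2 offsets (rows = archetypes,
#'   columns = timepoints); default [default_archetypes()].
#' @param prop_null Fraction of genes with no planted response. Default 0.5.
#' @param mu_meanlog,mu_sdlog Log-normal parameters of baseline means.
#'   Defaults log(100) and 1 — a realistic spread of expression levels.
#' @param phi_mean Mean NB dispersion; per-gene dispersions are Gamma-drawn
#'   around it (shape 4). Default 0.1.
#' @param motif_odds Optional archetype x motif matrix of planting odds `o`
#'   (0 = never plant, Inf = always); rows = archetypes 1..A, columns named by
#'   motif. `NULL` installs [default_motif_odds()].
#' @param seed Integer seed governing all draws.
#' @return A `pti_truth` list: `genes` tibble (`gene_id`, `archetype`, `mu`,
#'   `phi`), the archetype `delta` matrix, `motif_odds`, and `seed`.
#' @examples
#' tr <- planted_truth(time_course_design(n_genes = 100), seed = 1)
#' dplyr::count(tr$genes, archetype)
#' @export
planted_truth <- function(design,
                          archetypes = default_archetypes(design$timepoints_h),
                          prop_null = 0.5,
                          mu_meanlog = log(100), mu_sdlog = 1,
                          phi_mean = 0.1,
                          motif_odds = NULL,
                          seed = 1L) {
  stopifnot(inherits(design, "pti_design"))
  if (ncol(archetypes) != length(design$timepoints_h)) {
    abort("archetype matrix must have one column per timepoint")
  }
  validate_archetypes(archetypes)
  n <- design$n_genes
  n_arch <- nrow(archetypes)
  genes <- with_seed(derive_seed(seed, "truth"), {
    archetype <- rep(0L, n)
    n_resp <- round((1 - prop_null) * n)
    if (n_resp > 0) {
      idx <- sample.int(n, n_resp)
      archetype[idx] <- rep_len(seq_len(n_arch), n_resp)[sample.int(n_resp)]
    }
    tibble(
      gene_id = sprintf("gene_%05d", seq_len(n)),
      archetype = archetype,
      mu = stats::rlnorm(n, mu_meanlog, mu_sdlog),
      phi = stats::rgamma(n, shape = 4, rate = 4 / phi_mean)
    )
  })
  if (!is.null(design$library_size_target)) {
    genes$mu <- genes$mu * design$library_size_target / sum(genes$mu)
  }
  if (is.null(motif_odds)) motif_odds <- default_motif_odds(n_arch)
  structure(
    list(genes = genes, delta = archetypes, motif_odds = motif_odds,
         seed = as.integer(seed)),
    class = "pti_truth"
  )
}

#' @export
print.pti_truth <- function(x, ...) {
  cat(sprintf("<pti_truth> %d genes (%d null, %d planted across %d archetypes), seed %d\n",
              nrow(x$genes), sum(x$genes$archetype == 0),
              sum(x$genes$archetype > 0), nrow(x$delta), x$seed))
  invisible(x)
}

#' Default per-archetype motif planting odds
#'
#' A sparse archetype x motif odds matrix emulating the cluster-dependent
#' promoter composition seen in elicitor-response data: W-box in the early
#' upregulated archetypes (WRKY-driven induction), G-box/ABRE-like in the
#' mid-response archetypes, GCC-box/DRE in the late ones, CG-1 and
#' TGA-element in the downregulated archetypes. Odds `o` translate to a
#' planting probability `o / (1 + o)` per promoter.
#'
#' @param n_archetypes Number of archetypes (rows). Default 10.
#' @return Numeric matrix, rows `archetype_*`, columns motif names from
#'   [motif_dictionary()].
#' @export
default_motif_odds <- function(n_archetypes = 10) {
  motifs <- motif_dictionary()$name
  m <- matrix(0, n_archetypes, length(motifs),
              dimnames = list(paste0("archetype_", seq_len(n_archetypes)), motifs))
  set_odds <- function(a, motif, o) {
    if (a <= n_archetypes && motif %in% motifs) m[a, motif] <<- o
  }
  set_odds(5, "W-box", 9); set_odds(6, "W-box", 9)
  set_odds(7, "G-box", 9); set_odds(7, "ABRE-like", 4)
  set_odds(8, "GCC-box", 9); set_odds(8, "DRE/CRT", 4)
  set_odds(9, "Myc-related", 6)
  set_odds(10, "DRE-like", 6)
  set_odds(1, "CG-1", 6); set_odds(3, "CG-1", 6)
  set_odds(4, "TGA-element", 6); set_odds(2, "AtMyb3", 6)
  m
}
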