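# Internal helpers shared across modules.

# Deterministic per-stage seed derivation: one user seed governs all stochastic
# stages, but each stage draws from its own stream so stages are independently
# reproducible. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1000003 * h) %% .Machine$integer.max)
}

# Evaluate `expr` with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Sample standard deviation by row of a matrix (n - 1 denominator).
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

assert_probability <- function(p, what = "p") {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("%s values must lie in [0, 1]; offending index %d (value %g)",
                  what, which(bad)[1], p[which(bad)[1]]))
  }
  invisible(p)
}

# Stable timepoint column names for wide trajectory tibbles: t_0, t_0.5, ...
timepoint_cols <- function(timepoints_h) paste0("t_", timepoints_h)
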