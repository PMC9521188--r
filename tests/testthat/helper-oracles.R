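# Independent oracles and fixture builders shared across tests. Each oracle
# is coded from the published definition of the quantity it checks, not from
# the package implementation.

# --- Benjamini-Hochberg step-up, definitional ------------------------------
# adjusted_(i) = min_{j : p_(j) >= p_(i)} min(1, p_(j) * m / rank(j))
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# --- Upper-tail hypergeometric, brute-force pmf summation ------------------
hyper_oracle <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# --- TMM weighted trimmed mean, coded from the definition ------------------
# Reference column: upper-quartile rule (f75 closest to the mean f75).
# M = log2 relative abundance ratio, A = average log abundance, precision
# weights = inverse asymptotic variance of M; two-sided trim of 30% on M and
# 5% on A; factors centred to product 1.
tmm_oracle <- function(m) {
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)), function(j) {
    quantile(m[, j], 0.75) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    if (j == ref) return(1)
    obs <- m[, j]; rf <- m[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (is.na(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(m)), one, numeric(1))
  f / exp(mean(log(f)))
}

# --- Brute-force motif matching: enumerate words, compare substrings -------
scan_oracle <- function(seq, motif, strand_mode = "both") {
  words <- motif_words(motif)
  w <- motif$width
  seq <- toupper(seq)
  L <- nchar(seq)
  find_in <- function(s) {
    if (L < w) return(integer())
    subs <- substring(s, 1:(L - w + 1), w:L)
    which(subs %in% words)
  }
  fwd <- find_in(seq)
  res <- data.frame(position = fwd, strand = rep("+", length(fwd)))
  if (strand_mode == "both") {
    rc <- oracle_revcomp(seq)
    rev_hits <- find_in(rc)
    if (length(rev_hits)) {
      res <- rbind(res, data.frame(position = L - rev_hits - w + 2,
                                   strand = rep("-", length(rev_hits))))
    }
  }
  res[order(res$position, res$strand), , drop = FALSE]
}

# Independent reverse complement (Biostrings), used only by oracles.
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# --- Fixture builders ------------------------------------------------------
# A pti_truth with hand-set parameters (fixed mu/phi, explicit archetypes).
manual_truth <- function(n_genes, mu = 100, phi = 0.1,
                         archetype = rep(0L, n_genes),
                         delta = matrix(0, 1, 2), seed = 1L) {
  structure(
    list(genes = tibble::tibble(
           gene_id = sprintf("g%05d", seq_len(n_genes)),
           archetype = as.integer(archetype),
           mu = rep_len(mu, n_genes),
           phi = rep_len(phi, n_genes)),
         delta = delta,
         motif_odds = ptiseq::default_motif_odds(nrow(delta)),
         seed = as.integer(seed)),
    class = "pti_truth")
}

# Random DNA of length n under an independent RNG stream.
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Randomized-p transform for discrete upper-tail hypergeometric p-values:
# F(k-1 upper) + U * pmf(k) is exactly Uniform(0,1) under the null, which
# makes KS applicable despite discreteness.
randomized_hyper_p <- function(k, n, K, N, u) {
  phyper(k, K, N - K, n, lower.tail = FALSE) + u * dhyper(k, K, N - K, n)
}

# A 10-gene fixture on one 6-kb contig: mixed strands, one plus-strand gene
# close to the left contig edge (truncated window) and one minus-strand gene
# close to the right edge.
promoter_fixture <- function() {
  contig <- random_dna(6000, seed = 314)
  models <- tibble::tibble(
    gene_id = sprintf("fx%02d", 1:10),
    contig = "chrF",
    strand = c("+", "-", "+", "-", "+", "-", "+", "-", "+", "-"),
    cds_start = c(1501L, 200L, 400L, 900L, 2600L, 3100L, 3900L, 4300L,
                  5200L, 5650L),
    cds_end   = c(1800L, 450L, 650L, 1100L, 2800L, 3300L, 4100L, 4500L,
                  5400L, 5900L))
  list(genome = c(chrF = contig), contig = contig, models = models)
}
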