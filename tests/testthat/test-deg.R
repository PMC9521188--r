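# Differential-expression stage: TMM factors, the NB contrast test, BH
# adjustment and the triple DEG filter.

test_that("TMM factors are 1 for identical columns and compensate scaling", {
  m <- tibble::tibble(gene_id = paste0("g", 1:20),
                      s1 = rpois(20, 50) + 1L)
  m$s2 <- m$s1
  m$s3 <- m$s1
  f <- normalize_tmm(m)
  expect_equal(f$norm_factor, rep(1, 3))

  # sample B = 2 x sample A: all M-values are 0 after library-size division,
  # so both factors stay 1 and normalized expression is equal
  two <- tibble::tibble(gene_id = paste0("g", 1:20),
                        A = as.integer(rpois(20, 60) + 1L))
  two$B <- two$A * 2L
  f2 <- normalize_tmm(two)
  expect_equal(f2$norm_factor, rep(1, 2), tolerance = 1e-12)
  norm <- as.matrix(two[, -1]) %*% diag(1 / (f2$lib_size * f2$norm_factor))
  expect_equal(norm[, 1], norm[, 2], tolerance = 1e-12)

  expect_error(normalize_tmm(tibble::tibble(gene_id = "g1", a = 0L, b = 1L)),
               "all-zero")
})

test_that("TMM matches an independently coded weighted trimmed mean", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, {
      matrix(rnbinom(20 * 4, mu = runif(20, 20, 2000), size = 5), 20, 4,
             dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    })
    counts <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                               tibble::as_tibble(as.data.frame(m)))
    f <- normalize_tmm(counts)
    expect_equal(f$norm_factor, unname(tmm_oracle(m)), tolerance = 1e-10)
    expect_lt(abs(prod(f$norm_factor) - 1), 1e-12)
  }
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(adjust_bh(c(0.005, 0.011, 0.02, 0.8)),
               c(0.02, 0.022, 0.0267, 0.8), tolerance = 5e-3)
  expect_equal(adjust_bh(c(0.005, 0.011, 0.02, 0.8)),
               bh_oracle(c(0.005, 0.011, 0.02, 0.8)), tolerance = 1e-15)
  expect_identical(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(0.03, 5)), rep(0.03, 5), tolerance = 1e-15)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(404, {
    for (i in 1:50) {
      p <- runif(sample(1:500, 1))
      expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("BH output dominates raw p and preserves order", {
  withr::with_seed(7, {
    p <- runif(200)
    q <- adjust_bh(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  })
})

test_that("identical groups give log2FC 0 and p 1", {
  counts <- tibble::tibble(gene_id = paste0("g", 1:5),
                           a1 = c(10L, 40L, 5L, 100L, 7L))
  for (s in c("a2", "a3", "b1", "b2", "b3")) counts[[s]] <- counts$a1
  samples <- tibble::tibble(sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                            timepoint_h = rep(c(0, 1), each = 3),
                            replicate = rep(1:3, 2))
  ct <- test_contrast(counts, samples, timepoint_h = 1)
  expect_equal(ct$log2FC, rep(0, 5), tolerance = 1e-8)
  expect_equal(ct$p, rep(1, 5), tolerance = 1e-8)
})

test_that("low-count genes are left untested and errors are informative", {
  counts <- tibble::tibble(gene_id = c("lo", "hi"),
                           a1 = c(1L, 50L), a2 = c(0L, 60L), a3 = c(1L, 40L),
                           b1 = c(0L, 80L), b2 = c(2L, 90L), b3 = c(0L, 100L))
  samples <- tibble::tibble(sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                            timepoint_h = rep(c(0, 3), each = 3),
                            replicate = rep(1:3, 2))
  ct <- test_contrast(counts, samples, timepoint_h = 3)
  expect_true(is.na(ct$p[ct$gene_id == "lo"]))
  expect_false(is.na(ct$p[ct$gene_id == "hi"]))
  expect_error(test_contrast(counts, samples, timepoint_h = 99), "not a testable")

  one_rep <- samples[c(1, 4:6), ]
  expect_error(
    test_contrast(counts[, c("gene_id", "a1", "b1", "b2", "b3")], one_rep,
                  timepoint_h = 3),
    "two replicates")
})

test_that("the triple filter applies strict fold, FDR and p cuts", {
  ct <- tibble::tibble(
    gene_id = c("up_ok", "p_fail", "boundary", "down_ok", "fdr_fail", "na_gene"),
    timepoint_h = 1,
    log2FC = c(1.2, 2.0, 1.0, -3, 4, NA),
    p = c(0.001, 0.02, 0.001, 1e-6, 0.001, NA),
    FDR = c(0.005, 0.005, 0.005, 1e-4, 0.02, NA))
  degs <- filter_degs(ct)
  expect_setequal(degs$gene_id, c("up_ok", "down_ok"))
  expect_identical(degs$direction[degs$gene_id == "up_ok"], "up")
  expect_identical(degs$direction[degs$gene_id == "down_ok"], "down")
  expect_error(filter_degs(ct[, -5]), "FDR")
})

test_that("deg_counts sums directions and deduplicates the union", {
  degs <- tibble::tibble(gene_id = c("a", "a", "b", "c"),
                         timepoint_h = c(0.5, 1, 1, 1),
                         direction = c("up", "up", "down", "up"))
  tab <- deg_counts(degs, timepoints_h = c(0, 0.5, 1, 3))
  expect_identical(tab$total, tab$up + tab$down)
  expect_identical(tab$total[tab$timepoint_h == 3], 0L)
  expect_identical(attr(tab, "union_size"), 3L)
  expect_identical(deg_union(degs), 3L)
  empty <- deg_counts(degs[0, ], timepoints_h = c(0, 1))
  expect_identical(empty$total, 0L)
  expect_identical(attr(empty, "union_size"), 0L)
})

test_that("planted fold changes are recovered with the expected magnitude", {
  # 100 of 1000 genes carry a 4-fold increase at 3 h (a realistic DE
  # fraction: TMM's trimmed mean needs a mostly-null transcriptome)
  n <- 1000
  delta <- matrix(0, 5, 6)
  delta[1:4, 2] <- -1  # unused down archetypes (layout requirement)
  delta[5, 4] <- 2
  arch <- rep(c(0L, 5L), times = c(n - 100, 100))
  tr <- manual_truth(n, mu = 200, phi = 0.05, archetype = arch,
                     delta = delta, seed = 77)
  d <- time_course_design(n_genes = n)
  sim <- simulate_counts(d, tr)
  ct <- test_all_contrasts(sim$counts, sim$samples)
  at3 <- ct[ct$timepoint_h == 3, ]
  est <- median(at3$log2FC[arch == 5], na.rm = TRUE)
  expect_lt(abs(est - 2), 0.2)
  degs <- filter_degs(ct)
  hit <- unique(degs$gene_id)
  expect_gt(mean(tr$genes$gene_id[arch == 5] %in% hit), 0.8)
  expect_lt(mean(tr$genes$gene_id[arch == 0] %in% hit), 0.02)
})

test_that("false-discovery control holds on a balanced mixed simulation", {
  # 500 up + 500 down 4-fold at 3 h among 4000 nulls, full design: the
  # fraction of false discoveries among genes declared at FDR < 0.01 stays
  # within 1.5x the nominal level
  n <- 5000
  delta <- matrix(0, 5, 6)
  delta[1, 4] <- -2
  delta[2:4, 2] <- -0.0001
  delta[5, 4] <- 2
  arch <- c(rep(1L, 500), rep(5L, 500), rep(0L, 4000))
  tr <- manual_truth(n, mu = 100, phi = 0.1, archetype = arch,
                     delta = delta, seed = 502)
  d <- time_course_design(n_genes = n)
  sim <- simulate_counts(d, tr, size_factor_range = c(1, 1))
  ct <- test_contrast(sim$counts, sim$samples, timepoint_h = 3)
  ct$FDR <- adjust_bh(ct$p)
  declared <- ct$gene_id[!is.na(ct$FDR) & ct$FDR < 0.01]
  expect_gt(length(declared), 800)
  efdr <- mean(declared %in% tr$genes$gene_id[arch == 0])
  expect_lte(efdr, 1.5 * 0.01)
})
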