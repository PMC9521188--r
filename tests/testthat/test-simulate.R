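# Synthetic-data generators: seeded determinism, NB moment structure,
# planted-signal bookkeeping.

test_that("simulated counts are reproducible and reject bad parameters", {
  d <- time_course_design(n_genes = 30)
  tr <- planted_truth(d, seed = 99)
  a <- simulate_counts(d, tr)
  b <- simulate_counts(d, tr)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples$size_factor, b$samples$size_factor)

  tr_bad <- tr
  tr_bad$genes$mu[7] <- 0
  expect_error(simulate_counts(d, tr_bad), "gene index 7")
})

test_that("null flat genes reproduce their baseline mean", {
  # 1000 genes, all null, mu = 100, tiny dispersion: the grand sample mean
  # per gene should sit within 3 SE of 100
  n <- 1000
  tr <- manual_truth(n, mu = 100, phi = 1e-4, seed = 21,
                     delta = matrix(c(0, -1, -1, -1, -1, -1), 1, 6, byrow = TRUE))
  d <- time_course_design(n_genes = n)
  sim <- simulate_counts(d, tr, size_factor_range = c(1, 1))
  m <- as.matrix(sim$counts[, -1])
  gene_means <- rowMeans(m)
  se <- sqrt(100 / ncol(m))  # ~Poisson at phi -> 0
  expect_gt(mean(abs(gene_means - 100) < 3 * se), 0.99)
  expect_lt(abs(mean(gene_means) - 100), 3 * se / sqrt(n))
})

test_that("a planted log2 offset of 2 quadruples the time-point mean", {
  n <- 1000
  delta <- matrix(c(0, 0, 0, 2, 0, 0), 5, 6, byrow = TRUE)
  delta[1:4, ] <- -delta[1:4, ]  # rows 1-4 must be down archetypes
  tr <- manual_truth(n, mu = 100, phi = 0.1, archetype = rep(5L, n),
                     delta = delta, seed = 22)
  d <- time_course_design(n_genes = n)
  sim <- simulate_counts(d, tr, size_factor_range = c(1, 1))
  m <- as.matrix(sim$counts[, -1])
  at3 <- m[, sim$samples$timepoint_h == 3]
  at0 <- m[, sim$samples$timepoint_h == 0]
  ratio <- mean(at3) / mean(at0)
  # mean over 3000 draws of NB(400, phi=.1): 3 SE of the ratio ~ 0.07
  expect_lt(abs(ratio - 4), 0.15)
})

test_that("NB marginals match mean mu and variance mu + phi mu^2", {
  mu <- 80; phi <- 0.15
  d <- time_course_design(timepoints_h = c(0, 1), replicates = 500, n_genes = 4)
  tr <- manual_truth(4, mu = mu, phi = phi, seed = 31,
                     delta = matrix(0, 1, 2))
  sim <- simulate_counts(d, tr, size_factor_range = c(1, 1))
  m <- as.matrix(sim$counts[, -1])
  n <- ncol(m)
  sigma2 <- mu + phi * mu^2
  # exact NB fourth central moment via pmf summation (independent oracle)
  xs <- 0:qnbinom(1 - 1e-13, mu = mu, size = 1 / phi)
  pmf <- dnbinom(xs, mu = mu, size = 1 / phi)
  mu4 <- sum((xs - mu)^4 * pmf)
  se_mean <- sqrt(sigma2 / n)
  se_var <- sqrt((mu4 - (n - 3) / (n - 1) * sigma2^2) / n)
  for (g in 1:4) {
    expect_lt(abs(mean(m[g, ]) - mu), 3 * se_mean)
    expect_lt(abs(var(m[g, ]) - sigma2), 3 * se_var)
  }
})

test_that("simulated genome plants motifs recoverably on both strands", {
  d <- time_course_design(n_genes = 80)
  tr <- planted_truth(d, seed = 12, prop_null = 0)
  gen <- simulate_genome(tr)
  expect_identical(sort(unique(strsplit(substr(gen$genome[1], 1, 5000),
                                        "")[[1]])), c("A", "C", "G", "T"))
  proms <- extract_promoters(gen$models, gen$genome)
  expect_true(all(nchar(proms$sequence) == 1000))
  pl <- gen$manifest$planted
  expect_gt(nrow(pl), 0)
  # every planted occurrence is recovered by the scanner at its position
  hits <- motif_hits(proms, strand_mode = "both")
  found <- vapply(seq_len(nrow(pl)), function(i) {
    any(hits$gene_id == pl$gene_id[i] & hits$motif == pl$motif[i] &
          hits$position == pl$position[i])
  }, logical(1))
  expect_identical(mean(found), 1)
  # determinism
  gen2 <- simulate_genome(tr)
  expect_identical(gen$genome, gen2$genome)
  expect_identical(gen$manifest$planted, gen2$manifest$planted)
})

test_that("forced odds plant a W-box in every archetype-5 promoter", {
  d <- time_course_design(n_genes = 60)
  tr <- planted_truth(d, seed = 13, prop_null = 0.5)
  tr$motif_odds[] <- 0
  tr$motif_odds[5, "W-box"] <- Inf
  gen <- simulate_genome(tr)
  proms <- extract_promoters(gen$models, gen$genome)
  pres <- presence_table(proms, motif_dictionary()[motif_dictionary()$name == "W-box", ])
  a5 <- tr$genes$gene_id[tr$genes$archetype == 5]
  expect_true(all(pres$`W-box`[pres$gene_id %in% a5]))
})

test_that("zero odds leave motif presence at the background random rate", {
  d <- time_course_design(n_genes = 400)
  tr <- planted_truth(d, seed = 14)
  tr$motif_odds[] <- 0
  gen <- simulate_genome(tr)
  proms <- extract_promoters(gen$models, gen$genome)
  # Myc-related (CACATG) is not its own reverse complement, so the
  # two-strand closed-form rate applies: q = 1/4^6 per window per strand,
  # presence ~ 1 - (1 - q)^(2 (L - w + 1)), ignoring overlap correction
  myc <- motif_dictionary()[motif_dictionary()$name == "Myc-related", ]
  pres <- presence_table(proms, myc)
  q <- 1 / 4^6
  p_hit <- 1 - (1 - q)^(2 * (1000 - 6 + 1))
  obs <- mean(pres$`Myc-related`)
  ci <- 3 * sqrt(p_hit * (1 - p_hit) / nrow(pres))
  expect_lt(abs(obs - p_hit), ci + 0.01)
})

test_that("annotation simulator plants detectable terms and honors degenerate input", {
  d <- time_course_design(n_genes = 600)
  tr <- planted_truth(d, seed = 15, prop_null = 0.5)
  ann <- simulate_annotations(tr, n_terms = 100, terms_per_gene = 5,
                              enriched_terms_per_archetype = 1,
                              fold_enrichment = 8)
  expect_gt(nrow(ann$annotations), 0)
  expect_identical(nrow(ann$enriched), 10L)
  # empty map when terms_per_gene = 0
  ann0 <- simulate_annotations(tr, terms_per_gene = 0)
  expect_identical(nrow(ann0$annotations), 0L)
  # over-requesting enriched terms is rejected
  expect_error(simulate_annotations(tr, n_terms = 10,
                                    enriched_terms_per_archetype = 2),
               "more enriched terms")
})
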