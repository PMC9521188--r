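# Trajectory stage: z-scaling, k-means clustering, cluster summaries and
# marker selection.

test_that("zscale standardizes rows and flags constant profiles", {
  p <- tibble::tibble(gene_id = c("lin", "flat"),
                      t_0 = c(1, 2), t_0.5 = c(2, 2), t_1 = c(3, 2),
                      t_3 = c(4, 2), t_6 = c(5, 2), t_12 = c(6, 2))
  z <- zscale(p)
  expect_identical(z$gene_id, "lin")
  expect_identical(attr(z, "excluded"), "flat")
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1.3363, -0.8018, -0.2673, 0.2673, 0.8018, 1.3363),
               tolerance = 1e-4)
  # idempotence on already standardized rows
  z2 <- zscale(z)
  expect_equal(as.matrix(z[, -1]), as.matrix(z2[, -1]), tolerance = 1e-12)
  # rows satisfy the invariants exactly
  m <- as.matrix(z[, -1])
  expect_lt(abs(rowMeans(m)), 1e-10)
  expect_lt(abs(apply(m, 1, sd) - 1), 1e-10)

  bad <- p
  bad$t_3[1] <- NA
  expect_error(zscale(bad), "lin")
})

test_that("k-means separates trivially separable data and handles k = 1", {
  traj <- tibble::tibble(gene_id = paste0("g", 1:6),
                         t_0 = c(0, 0, 0, 10, 10, 10),
                         t_1 = c(0, 0, 0, 10, 10, 10))
  fit <- kmeans_cluster(traj, k = 2, seed = 1, n_restarts = 5)
  expect_identical(sort(fit$summary$size), c(3L, 3L))
  expect_equal(fit$W_k, 0)
  expect_identical(length(unique(fit$assignment$cluster[1:3])), 1L)

  one <- kmeans_cluster(traj, k = 1, seed = 1, n_restarts = 2)
  expect_equal(one$W_k, one$totss)
  expect_equal(unname(one$centroids[1, ]), c(5, 5))
  expect_error(kmeans_cluster(traj, k = 7, seed = 1), "exceeds")
})

test_that("total sum of squares decomposes into within plus between", {
  sim <- simulate_trajectories(300, seed = 8)
  fit <- kmeans_cluster(sim$trajectories[, -2], k = 7, seed = 8)
  z <- fit$z
  tss <- sum(sweep(z, 2, colMeans(z))^2)
  wss <- sum(vapply(seq_len(nrow(z)), function(i) {
    sum((z[i, ] - fit$centroids[fit$assignment$cluster[i], ])^2)
  }, numeric(1)))
  expect_equal(fit$W_k, wss, tolerance = 1e-8)
  bss <- sum(fit$summary$size *
               rowSums(sweep(fit$centroids, 2, colMeans(z))^2))
  expect_equal(tss, fit$W_k + bss, tolerance = 1e-6)
})

test_that("more restarts never worsen the k-means objective", {
  sim <- simulate_trajectories(250, seed = 17)
  w1 <- kmeans_cluster(sim$trajectories[, -2], k = 10, seed = 5,
                       n_restarts = 1)$W_k
  w25 <- kmeans_cluster(sim$trajectories[, -2], k = 10, seed = 5,
                        n_restarts = 25)$W_k
  expect_lte(w25, w1 + 1e-12)
})

test_that("clusters are relabeled down-first by extremum time with directions", {
  sim <- simulate_trajectories(400, seed = 23, noise_sd = 0.2)
  fit <- kmeans_cluster(sim$trajectories[, -2], k = 10, seed = 23)
  sumy <- summarize_clusters(fit)
  expect_identical(sumy$direction, c(rep("down", 4), rep("up", 6)))
  expect_identical(sum(sumy$size), 400L)
  # extremum times non-decreasing within each direction block
  expect_true(!is.unsorted(sumy$peak_time_h[sumy$direction == "down"]))
  expect_true(!is.unsorted(sumy$peak_time_h[sumy$direction == "up"]))
  # up-cluster peaks follow the planted peaks 0.5, 1, 3, 6, 6, 12
  expect_equal(sumy$peak_time_h[sumy$direction == "up"],
               c(0.5, 1, 3, 6, 6, 12))
})

test_that("direction calls follow baseline-relative excursion with tie -> up", {
  centers <- rbind(c(-0.2, 0.1, 1.5, 0.4, -0.5, -0.6),   # up, peak 1 h
                   c(1.79, 0.6, -0.6, -0.6, -0.6, -0.6), # sustained down
                   c(0, 0, 0, 0, 0, 0))                  # tie -> up
  colnames(centers) <- paste0("t_", c(0, 0.5, 1, 3, 6, 12))
  rel <- ptiseq:::relabel_clusters(centers, c(1L, 2L, 3L, 1L))
  s <- rel$summary
  expect_identical(s$direction[s$cluster == rel$labels[1]], "up")
  expect_identical(s$extremum_timepoint[s$cluster == rel$labels[1]], 3L)
  expect_identical(s$direction[s$cluster == rel$labels[2]], "down")
  expect_identical(s$direction[s$cluster == rel$labels[3]], "up")
})

test_that("markers are picked by centroid correlation with fold-change tie-break", {
  sim <- simulate_trajectories(300, seed = 31)
  fit <- kmeans_cluster(sim$trajectories[, -2], k = 10, seed = 31)
  ct <- tibble::tibble(gene_id = rep(sim$trajectories$gene_id, 2),
                       timepoint_h = rep(c(1, 3), each = 300),
                       log2FC = withr::with_seed(1, runif(600, 0, 5)),
                       p = 0.001, FDR = 0.005)
  mk <- select_markers(fit, ct, n_per_cluster = 2)
  up_clusters <- fit$summary$cluster[fit$summary$direction == "up"]
  expect_setequal(unique(mk$cluster), up_clusters)
  expect_true(all(mk$correlation >= 0.8 | mk$fallback))
  # markers track their centroid shape
  expect_gt(min(mk$correlation), 0.9)
  # the two-gene ordering: higher correlation first
  for (cl in unique(mk$cluster)) {
    sub <- mk[mk$cluster == cl, ]
    expect_true(!is.unsorted(rev(sub$correlation)))
  }

  # single-gene cluster returns its gene regardless of rank
  tiny <- tibble::tibble(gene_id = c("a", "b", "c"),
                         t_0 = c(0, 0.1, 5), t_1 = c(1, 1.1, -5),
                         t_3 = c(2, 2.1, 0))
  fit2 <- kmeans_cluster(tiny, k = 2, seed = 2, n_restarts = 3)
  lone <- fit2$summary$cluster[fit2$summary$size == 1]
  mk2 <- select_markers(fit2, ct, n_per_cluster = 2, clusters = lone)
  expect_identical(nrow(mk2), 1L)
})
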