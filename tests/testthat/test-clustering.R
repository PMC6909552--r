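test_that("pearson_distance honors affine invariance and hand values", {
  x <- rbind(a = c(1, 2, 3), b = 2 * c(1, 2, 3) + 5, c = -c(1, 2, 3),
             d = c(1, 3, 2))
  colnames(x) <- paste0("s", 1:3)
  d <- as.matrix(pearson_distance(x))
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_equal(d["a", "d"], 0.5, tolerance = 1e-12)  # r = 0.5 by hand
  expect_equal(diag(d), stats::setNames(rep(0, 4), rownames(x)))
})

test_that("pearson_distance matches a two-pass correlation oracle to 1e-12", {
  m <- random_expr(20, 8, 7)
  d <- as.matrix(pearson_distance(m))
  for (i in 1:19) for (j in (i + 1):20) {
    expect_equal(d[i, j], 1 - oracle_pearson(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("pearson_distance rejects constant profiles by name", {
  m <- rbind(flat = rep(3, 4), ok = 1:4)
  colnames(m) <- paste0("s", 1:4)
  expect_error(pearson_distance(m), "flat")
})

test_that("distance on TPM and on z-scores coincide", {
  m <- random_expr(15, 6, 9)
  expect_equal(as.numeric(pearson_distance(m)),
               as.numeric(pearson_distance(zscore_rows(m))),
               tolerance = 1e-9)
})

test_that("complete-linkage clustering matches a naive O(n^3) oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:12, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.01, 2)
    D <- D + t(D)
    dimnames(D) <- list(paste0("g", 1:n), paste0("g", 1:n))
    for (k in c(1, 2, max(2, n %/% 2), n)) {
      ours <- hierarchical_clusters(stats::as.dist(D), k = k)
      oracle <- oracle_agglomerate(D, k)
      expect_equal(adjusted_rand_index(ours, oracle), 1)
    }
  }
})

test_that("planted well-separated groups are recovered exactly", {
  set.seed(2)
  t <- seq(0, 2 * pi, length.out = 10)
  a <- t(replicate(6, sin(t) + stats::rnorm(10, 0, 0.01)))
  b <- t(replicate(6, cos(2 * t) + stats::rnorm(10, 0, 0.01)))
  m <- rbind(a, b) + 5
  dimnames(m) <- list(paste0("g", 1:12), paste0("s", 1:10))
  cl <- hierarchical_clusters(pearson_distance(m), k = 2)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 6)), 1)
})

test_that("degenerate cuts behave: singletons at k = n, one lump at k = 1", {
  m <- random_expr(9, 5, 3)
  d <- pearson_distance(m)
  expect_equal(sort(unique(hierarchical_clusters(d, k = 9))), 1:9)
  expect_equal(unname(hierarchical_clusters(d, k = 1)), rep(1, 9))
  expect_error(hierarchical_clusters(d, k = 10), "between 1 and")
})

test_that("zscore_rows matches hand values and normalizes exactly", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 10, 40))
  colnames(m) <- paste0("s", 1:3)
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(z["b", ]), c(-10, -10, 20) / sqrt(300),
               tolerance = 1e-9)
  big <- random_expr(30, 12, 5)
  zz <- zscore_rows(big)
  expect_lt(max(abs(rowMeans(zz))), 1e-9)
  expect_lt(max(abs(apply(zz, 1, stats::sd) - 1)), 1e-9)
  expect_error(zscore_rows(rbind(flat = rep(2, 3))), "flat")
})

test_that("centroids average members and replicates per timepoint", {
  md <- data.frame(sample_id = paste0("s", 1:4), cultivar = "cv",
                   tree_replicate = c("T1", "T2", "T1", "T2"),
                   date = as.Date(c("2015-07-01", "2015-07-01",
                                    "2015-08-01", "2015-08-01")))
  z <- rbind(g1 = c(1, 3, -2, -2), g2 = c(-1, -3, 2, 2),
             g3 = c(0, 2, -1, -1))
  colnames(z) <- md$sample_id
  cent <- cluster_centroids(z, c(g1 = 1, g2 = 1, g3 = 2), md)
  expect_equal(unname(cent["1", ]), c(0, 0))       # z and -z cancel
  expect_equal(unname(cent["2", ]), c(1, -1))      # single-gene cluster
  expect_error(cluster_centroids(z, c(g1 = 1, gX = 2), md), "gX")
})

test_that("peak ordering sorts by argmax with the larger-cluster tie rule", {
  cent <- rbind(`1` = c(0, 0, 0, 0, 1), `2` = c(1, 0, 0, 0, 0),
                `3` = c(0, 0, 1, 0, 0))
  expect_equal(order_clusters_by_peak(cent), c(2, 3, 1))
  ordered <- rbind(`1` = c(1, 0, 0), `2` = c(0, 1, 0), `3` = c(0, 0, 1))
  expect_equal(order_clusters_by_peak(ordered), 1:3)
  tied <- rbind(`1` = c(0, 1, 0.2), `2` = c(0, 1, 0.1))
  expect_equal(order_clusters_by_peak(tied, sizes = c(`1` = 3, `2` = 10)),
               c(2, 1))
  relab <- relabel_clusters(c(gA = 1, gB = 2), peak_order = c(2, 1))
  expect_equal(relab, c(gA = 2, gB = 1))
})

test_that("centroid correlations are +/-1 for exact and mirrored members", {
  md <- simple_metadata(paste0("s", 1:4),
                        c("2015-07-01", "2015-08-01", "2015-09-01",
                          "2015-10-01"))
  z <- rbind(g1 = c(-1.2, 0.3, 0.4, 0.5), g2 = c(1.2, -0.3, -0.4, -0.5),
             g3 = c(-0.6, 0.15, 0.2, 0.25))
  colnames(z) <- md$sample_id
  assignment <- c(g1 = 1, g2 = 2, g3 = 1)
  cent <- cluster_centroids(z, assignment, md)
  r <- centroid_correlations(z, cent, assignment, md)
  expect_equal(unname(r[c("g1", "g3")]), c(1, 1), tolerance = 1e-9)
  r2 <- centroid_correlations(z, -cent, assignment, md)
  expect_equal(unname(r2["g1"]), -1, tolerance = 1e-9)
})

test_that("relabeled centroid peak times are non-decreasing in label", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 6))
  tpm <- compute_tpm(sim$counts, sim$gene_lengths)
  cm <- cluster_expression(tpm, sim$metadata, rownames(tpm), k = 6,
                           reference_cultivar = "Garnet")
  peaks <- apply(cm$centroids, 1, which.max)
  expect_true(all(diff(peaks) >= 0))
})
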