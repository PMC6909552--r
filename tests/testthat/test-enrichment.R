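test_that("hypergeometric upper tail matches exhaustive enumeration on known cases", {
  # N=10, K=4, n=5, k=4: C(4,4)*C(6,1)/C(10,5) = 6/252
  universe <- paste0("g", 1:10)
  ann <- data.frame(gene_id = paste0("g", 1:4), set_id = "S")
  res <- hypergeom_overrep(paste0("g", c(1:4, 10)), ann, universe)
  expect_equal(res$pvalue, 6 / 252, tolerance = 1e-12)
  expect_equal(res[, c("k", "n", "K", "N")],
               data.frame(k = 4L, n = 5L, K = 4L, N = 10L),
               ignore_attr = TRUE)

  # k = 0: upper tail includes all mass
  res0 <- hypergeom_overrep(paste0("g", 8:10), ann["gene_id" != "", ][0, ],
                            universe)
  expect_equal(nrow(res0), 0)
  res0b <- hypergeom_overrep(paste0("g", 9:10),
                             data.frame(gene_id = "g1", set_id = "S"),
                             universe)
  expect_equal(res0b$pvalue, 1)

  # K = N: every universe gene annotated -> p = 1
  all_ann <- data.frame(gene_id = universe, set_id = "S")
  resK <- hypergeom_overrep(paste0("g", 1:3), all_ann, universe)
  expect_equal(resK$pvalue, 1)
})

test_that("hypergeometric p agrees with subset enumeration for modest universes", {
  for (N in c(5, 8, 11)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(n, K)) {
          expect_equal(budphase:::hyper_upper_tail(k, K, n, N),
                       oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH step-up reproduces the hand example and edge cases", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment matches the reference step-up on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- stats::runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("go_fisher equals the 2x2 tail and filters/ranks as specified", {
  # table [[3,1],[1,5]]: N=10, K=4, n=4, k=3 -> P(X>=3) = 25/210
  universe <- paste0("g", 1:10)
  ann <- data.frame(gene_id = paste0("g", 1:4), set_id = "GO:1")
  res <- go_fisher(paste0("g", c(1, 2, 3, 10)), ann, universe, p_cut = 1)
  expect_equal(res$pvalue, 25 / 210, tolerance = 1e-12)

  # a term annotating no cluster gene is never selected at p_cut 0.005
  ann2 <- rbind(ann, data.frame(gene_id = "g9", set_id = "GO:2"))
  strict <- go_fisher(paste0("g", c(1, 2, 3, 10)), ann2, universe,
                      p_cut = 0.005)
  expect_false("GO:2" %in% strict$set_id)

  # top_n truncation keeps the smallest p-values
  many <- data.frame(gene_id = rep(paste0("g", 1:4), 12),
                     set_id = rep(sprintf("GO:%02d", 1:12), each = 4))
  top <- go_fisher(paste0("g", 1:4), many, universe, p_cut = 1, top_n = 3)
  expect_equal(nrow(top), 3)
})

test_that("the Fisher and hypergeometric code paths agree to 1e-12", {
  set.seed(12)
  universe <- paste0("g", 1:40)
  ann <- data.frame(gene_id = sample(universe, 60, replace = TRUE),
                    set_id = sample(c("A", "B", "C"), 60, replace = TRUE))
  cluster <- sample(universe, 12)
  hyp <- hypergeom_overrep(cluster, ann, universe)
  fis <- go_fisher(cluster, ann, universe, p_cut = 1.1, top_n = 100)
  shared <- intersect(hyp$set_id, fis$set_id)
  expect_equal(hyp$pvalue[match(shared, hyp$set_id)],
               fis$pvalue[match(shared, fis$set_id)], tolerance = 1e-12)
})

test_that("planted enrichment is detected and label permutation destroys it", {
  cfg <- sim_config(n_genes = 2000, seed = 21)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  assignment <- sim$truth$gene_cluster
  universe <- names(assignment)
  planted <- ann$planted[ann$planted$kind == "tf" & ann$planted$cluster == 5, ]
  cluster5 <- names(assignment)[assignment == 5]
  res <- hypergeom_overrep(cluster5, ann$tf, universe)
  expect_lt(res$padj[res$set_id == planted$set_id], 0.05)
  expect_equal(res$set_id[1], planted$set_id)   # planted set ranks first

  set.seed(7)
  perm_p <- replicate(50, {
    shuffled <- stats::setNames(sample(assignment), names(assignment))
    cl5 <- names(shuffled)[shuffled == 5]
    r <- hypergeom_overrep(cl5, ann$tf, universe, adjust = FALSE)
    r$pvalue[r$set_id == planted$set_id]
  })
  expect_gt(stats::median(perm_p), 0.1)
})

test_that("fold-1 annotations yield uniform enrichment p-values", {
  cfg <- sim_config(n_genes = 2000, seed = 31, enrichment_fold = 1)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  res <- enrich_clusters(sim$truth$gene_cluster, ann$go)
  # randomized p-values remove the discreteness of the hypergeometric null
  set.seed(1)
  p_next <- budphase:::hyper_upper_tail(res$k + 1, res$K, res$n, res$N)
  p_rand <- p_next + stats::runif(nrow(res)) * (res$pvalue - p_next)
  ks <- stats::ks.test(p_rand, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate enrichment inputs error or saturate", {
  expect_error(hypergeom_overrep(character(0),
                                 data.frame(gene_id = "g", set_id = "S"),
                                 c("g")), "empty cluster")
  expect_error(hypergeom_overrep("g", data.frame(gene_id = "g", set_id = "S"),
                                 character(0)), "empty universe")
  expect_error(hypergeom_overrep("x", data.frame(gene_id = "g", set_id = "S"),
                                 "g"), "outside the universe")
})
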