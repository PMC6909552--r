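test_that("simulation is fully reproducible under a seed", {
  cfg <- sim_config(n_genes = 200, seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr$cq_table, b$qpcr$cq_table)
  expect_identical(a$budbreak, b$budbreak)
  expect_identical(a$annotations$tf, b$annotations$tf)

  c2 <- simulate_dataset(sim_config(n_genes = 200, seed = 124))
  expect_false(identical(a$counts, c2$counts))
})

test_that("configuration is validated", {
  expect_error(sim_config(nonsense = 1), "unknown sim_config field")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(sim_config(n_genes = 5L, markers_per_cluster = 1L),
               "more planted markers than genes")
})

test_that("cluster sizes sum to n_genes and follow the given proportions", {
  cfg <- sim_config(n_genes = 777)
  sizes <- budphase:::cluster_sizes(cfg)
  expect_equal(sum(sizes), 777)
  expect_equal(order(sizes), order(cfg$cluster_proportions))
})

test_that("zero-noise members reproduce their centroid exactly", {
  cfg <- sim_config(n_genes = 150, seed = 5, profile_noise_sd = 0,
                    dispersion = 0)
  sim <- simulate_counts(cfg)
  tpm <- compute_tpm(sim$counts, sim$gene_lengths)
  cl1 <- names(sim$truth$gene_cluster)[sim$truth$gene_cluster == 5]
  keep <- cl1[apply(tpm[cl1, , drop = FALSE], 1, stats::sd) > 0]
  # members share one latent profile up to a gene-specific scale, so their
  # z-score profiles (hence the centroid) coincide exactly
  z <- zscore_rows(tpm[keep, , drop = FALSE])
  expect_lt(max(abs(sweep(z, 2, colMeans(z)))), 1e-9)
})

test_that("sample sheet matches the study design", {
  sim <- simulate_counts(sim_config(n_genes = 150, seed = 2))
  md <- sim$metadata
  expect_setequal(unique(md$cultivar), c("Cristobalina", "Garnet", "Regina"))
  # sampling stops at flowering: the early cultivar has fewer dates
  n_dates <- tapply(md$date, md$cultivar, function(d) length(unique(d)))
  expect_equal(as.vector(n_dates[c("Cristobalina", "Garnet", "Regina")]),
               c(10, 11, 11))
  expect_true(all(table(md$cultivar, md$date) %in% c(0, 3)))
  expect_true(all(md$stage %in% STAGE_LEVELS))
  # every cultivar passes through all five stages
  for (cv in unique(md$cultivar))
    expect_setequal(unique(md$stage[md$cultivar == cv]), STAGE_LEVELS)
})

test_that("planted annotation rates reflect the enrichment fold", {
  cfg <- sim_config(n_genes = 2000, seed = 9)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  planted <- ann$planted[ann$planted$kind == "motif", ][1, ]
  members <- names(sim$truth$gene_cluster)[
    sim$truth$gene_cluster == planted$cluster]
  in_rate <- mean(members %in%
                    ann$motif$gene_id[ann$motif$set_id == planted$set_id])
  bg_rate <- mean(setdiff(names(sim$truth$gene_cluster), members) %in%
                    ann$motif$gene_id[ann$motif$set_id == planted$set_id])
  expect_gt(in_rate, 3 * bg_rate)
})

test_that("bud-break curves cross 50% at the planted release dates, in order", {
  cfg <- sim_config(n_genes = 150, seed = 3)
  sim <- simulate_counts(cfg)
  clean <- simulate_budbreak(cfg, sim$truth, n_buds = NULL)
  ests <- vapply(split(clean, clean$cultivar), function(df)
    as.numeric(estimate_dormancy_release(df$date, df$percent_bbch53,
                                         interpolate = TRUE)$date),
    numeric(1))
  planted <- c(as.numeric(sim$truth$release_dates),
               as.numeric(cfg$qpcr_release_date))
  names(planted) <- c(names(sim$truth$release_dates), cfg$qpcr_cultivar)
  expect_lt(max(abs(ests[names(planted)] - planted)), 1.01)
  expect_equal(order(ests[c("Cristobalina", "Garnet", "Regina")]), 1:3)
})

test_that("noisy bud-break recovery stays within one fortnight almost surely", {
  cfg <- sim_config(n_genes = 150, seed = 8)
  sim <- simulate_counts(cfg)
  hits <- replicate(100, {
    bb <- simulate_budbreak(cfg, sim$truth,
                            n_buds = cfg$budbreak_n_buds)
    garnet <- bb[bb$cultivar == "Garnet", ]
    est <- estimate_dormancy_release(garnet$date, garnet$percent_bbch53,
                                     interpolate = TRUE)
    est$released &&
      abs(as.numeric(est$date - sim$truth$release_dates[["Garnet"]])) <= 14
  })
  expect_gte(mean(hits), 0.95)
})

test_that("reference genes recover flat normalized profiles", {
  cfg <- sim_config(n_genes = 150, seed = 11)
  sim <- simulate_counts(cfg)
  qp <- simulate_qpcr(cfg, sim$truth)
  agg <- stats::aggregate(cq ~ sample_id + gene_id, qp$cq_table, mean)
  curves <- qp$truth$curves
  for (g in cfg$reference_gene_ids) {
    rows <- agg[agg$gene_id == g, ]
    cr <- curves[curves$gene_id == g, ]
    qty <- 10^((rows$cq - cr$intercept) / cr$slope)
    expect_lt(stats::sd(qty) / mean(qty), 0.25)  # flat up to platform noise
  }
})

test_that("emitted files round-trip losslessly through the package readers", {
  dir <- tempfile("simdata")
  sim <- simulate_dataset(sim_config(n_genes = 150, seed = 17))
  write_dataset(sim, dir)
  counts <- read_expression_tsv(file.path(dir, "counts.tsv"))
  expect_equal(counts, sim$counts, ignore_attr = FALSE)
  lengths <- read_gene_lengths(file.path(dir, "lengths.tsv"))
  expect_equal(lengths, sim$gene_lengths)
  md <- read_metadata_tsv(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, sim$metadata$sample_id)
  expect_equal(md$stage, sim$metadata$stage)
  ann <- read_annotation_tsv(file.path(dir, "annotations_go.tsv"))
  expect_equal(ann, sim$annotations$go, ignore_attr = TRUE)
  bb <- read_budbreak_csv(file.path(dir, "budbreak.csv"))
  expect_equal(bb$percent_bbch53, sim$budbreak$percent_bbch53,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
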