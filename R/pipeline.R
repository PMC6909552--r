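#' Assemble a validated pipeline configuration
#'
#' Nested parameter blocks for every stage, with defaults matching the
#' standard analysis: k = 10 clusters, DEG alpha = 0.05, GO p cutoff 0.005,
#' bud-break threshold 50%, 500 train/test splits with 5-fold internal CV.
#' Unknown keys, at either level, are rejected. `overrides` may be a nested
#' list or a YAML file path with the same structure.
#'
#' @param overrides nested list (or YAML path) overriding defaults.
#' @param seed overrides the simulation seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), seed = NULL) {
  cfg <- list(
    simulation = sim_config(),
    filters = list(min_mean_count = 3, max_zero_fraction = 0.75,
                   min_cv = 0.3, cv_on = "tpm"),
    de = list(dormant_stages = c("endodormancy", "dormancy_release"),
              alpha = 0.05),
    clustering = list(k = 10, linkage = "complete",
                      reference_cultivar = "Garnet",
                      gene_set = "filtered"),
    markers = list(clusters = c(1, 4, 5, 7, 8, 9, 10), min_mean_tpm = 10,
                   max_family_size = 5),
    enrichment = list(p_cut = 0.005, top_n = 10),
    model = list(n_splits = 500, test_fraction = 0.3, n_folds = 5,
                 log2 = TRUE),
    phenology = list(threshold = 50, interpolate = TRUE)
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop("unknown pipeline_config block(s): ", paste(unknown, collapse = ", "))
  for (block in names(overrides)) {
    if (block == "simulation") {
      cfg$simulation <- do.call(sim_config, overrides$simulation)
      next
    }
    bad <- setdiff(names(overrides[[block]]), names(cfg[[block]]))
    if (length(bad) > 0)
      stop("unknown key(s) in block '", block, "': ",
           paste(bad, collapse = ", "))
    cfg[[block]][names(overrides[[block]])] <- overrides[[block]]
  }
  if (!is.null(seed)) cfg$simulation$seed <- as.integer(seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full dormancy-staging pipeline on a synthetic dataset
#'
#' Executes, in order: simulation, TPM + gene filtering, the stand-in DE
#' caller, Pearson-distance clustering of the DEGs on the reference
#' cultivar, chronological relabeling, marker selection, TF-target
#' enrichment, stage-model training and repeated train/test evaluation,
#' RT-qPCR quantification and cross-platform stage prediction for the
#' held-out cultivar, and dormancy-release estimation from the bud-break
#' series. When `out_dir` is given, artifacts and a machine-readable run
#' manifest (seed, parameter hash, stage record counts) are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts and manifest.
#' @return list with every stage's result plus a `summary` block (ARI
#'   against the planted clusters, markers recovered, mean weighted F1,
#'   cross-platform accuracy, chronology consistency, release-date errors).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  log_stage <- function(...) message("[budphase] ", ...)

  log_stage("simulate: ", config$simulation$n_genes, " genes")
  sim <- simulate_dataset(config$simulation)

  log_stage("preprocess: TPM + filters")
  tpm <- compute_tpm(sim$counts, sim$gene_lengths)
  report <- filter_genes(sim$counts, tpm,
                         min_mean_count = config$filters$min_mean_count,
                         max_zero_fraction = config$filters$max_zero_fraction,
                         min_cv = config$filters$min_cv,
                         cv_on = config$filters$cv_on)
  kept <- report$surviving_gene_ids

  ref_cv <- config$clustering$reference_cultivar
  ref_samples <- sim$metadata$sample_id[sim$metadata$cultivar == ref_cv]
  log_stage("differential expression (stand-in) on ", ref_cv)
  degs <- call_degs(tpm[kept, ref_samples, drop = FALSE],
                    sim$metadata[sim$metadata$cultivar == ref_cv, ],
                    dormant_stages = config$de$dormant_stages,
                    alpha = config$de$alpha)
  deg_ids <- degs$gene_id[degs$is_deg]

  # "filtered" clusters every filter survivor; "degs" restricts to the
  # stand-in DE calls (the two-group contrast has limited power for
  # profiles symmetric across the dormant/non-dormant split)
  cluster_genes <- switch(config$clustering$gene_set,
                          filtered = kept, degs = deg_ids,
                          stop("clustering$gene_set must be 'filtered' or 'degs'"))
  log_stage("clustering ", length(cluster_genes), " genes (",
            config$clustering$gene_set, "), k = ", config$clustering$k)
  clust <- cluster_expression(tpm, sim$metadata, cluster_genes,
                              k = config$clustering$k,
                              linkage = config$clustering$linkage,
                              reference_cultivar = ref_cv)

  log_stage("marker selection")
  # degenerate (near-empty) clusters carry no usable profile; drop them from
  # the panel like tiny clusters are excluded from marker selection
  sizes <- table(clust$assignment)
  panel_clusters <- intersect(config$markers$clusters,
                              as.integer(names(sizes)[sizes >= 5]))
  if (length(panel_clusters) < length(config$markers$clusters))
    warning("dropping panel cluster(s) with < 5 genes: ",
            paste(setdiff(config$markers$clusters, panel_clusters),
                  collapse = ", "))
  panel <- select_markers(clust$correlations, clust$assignment, tpm,
                          family_table = sim$truth$family_table,
                          clusters = panel_clusters,
                          min_mean_tpm = config$markers$min_mean_tpm,
                          max_family_size = config$markers$max_family_size)

  log_stage("enrichment (TF targets)")
  enrichment <- enrich_clusters(clust$assignment, sim$annotations$tf)

  log_stage("stage model: train + ", config$model$n_splits, " splits")
  model <- train_stage_model(tpm, sim$metadata, panel$gene_id,
                             reference_date = config$simulation$reference_date,
                             log2 = config$model$log2,
                             n_folds = config$model$n_folds)
  evaluation <- evaluate_splits(model$training_scores, model$training_labels,
                                n_splits = config$model$n_splits,
                                test_fraction = config$model$test_fraction,
                                seed = config$simulation$seed,
                                n_folds = config$model$n_folds)

  log_stage("qPCR quantification + cross-platform prediction")
  qpcr <- qpcr_relative_expression(sim$qpcr$cq_table, sim$qpcr$standards,
                                   config$simulation$reference_gene_ids)
  # the qPCR assays target one gene per planted marker cluster; pair each
  # detected panel cluster with the planted cluster it shares most genes
  # with, so assays line up with the model's features even if cluster
  # labels shift (e.g. after a merge elsewhere in the tree)
  qp_panel <- sim$qpcr$truth$panel
  cont <- table(clust$assignment,
                sim$truth$gene_cluster[names(clust$assignment)])
  majority <- colnames(cont)[max.col(cont, ties.method = "first")]
  names(majority) <- rownames(cont)
  assay_ids <- vapply(panel$cluster, function(cl) {
    planted_cl <- majority[as.character(cl)]
    qp_panel$gene_id[qp_panel$cluster == as.integer(planted_cl)][1]
  }, character(1))
  qpcr_mat <- qpcr$matrix[assay_ids, , drop = FALSE]
  rownames(qpcr_mat) <- panel$gene_id
  prediction <- tryCatch(
    crossplatform_predict(model, qpcr_mat, sim$qpcr$metadata),
    error = function(e) e)

  log_stage("phenology: release-date estimation")
  release <- lapply(split(sim$budbreak, sim$budbreak$cultivar), function(df)
    estimate_dormancy_release(df$date, df$percent_bbch53,
                              threshold = config$phenology$threshold,
                              interpolate = config$phenology$interpolate))

  planted <- sim$truth$gene_cluster[names(clust$assignment)]
  ari <- adjusted_rand_index(clust$assignment, planted)
  planted_markers <- sim$truth$markers$gene_id[
    sim$truth$markers$cluster %in% config$markers$clusters]
  markers_recovered <- sum(panel$gene_id %in% planted_markers)
  release_error <- vapply(names(release), function(cv) {
    true_date <- if (cv == config$simulation$qpcr_cultivar)
      config$simulation$qpcr_release_date else sim$truth$release_dates[[cv]]
    if (!release[[cv]]$released) return(NA_real_)
    abs(as.numeric(release[[cv]]$date - true_date))
  }, numeric(1))
  qpcr_accuracy <- if (inherits(prediction, "error")) NA_real_ else
    mean(as.character(prediction$labels) == sim$qpcr$truth$stage)
  summary <- list(
    n_genes = config$simulation$n_genes,
    n_filtered = length(kept),
    n_degs = length(deg_ids),
    planted_cluster_ari = ari,
    markers_recovered = markers_recovered,
    n_marker_clusters = length(config$markers$clusters),
    mean_weighted_f1 = evaluation$mean,
    qpcr_accuracy = qpcr_accuracy,
    qpcr_chronology = if (inherits(prediction, "error")) NA_real_ else
      prediction$chronology_consistency,
    release_error_days = release_error)

  result <- list(config = config, sim = sim, tpm = tpm,
                 filter_report = report, degs = degs, clusters = clust,
                 panel = panel, enrichment = enrichment, model = model,
                 evaluation = evaluation, qpcr = qpcr,
                 prediction = prediction, release = release,
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(sim, file.path(out_dir, "data"))
    utils::write.table(
      data.frame(gene_id = names(clust$assignment),
                 cluster = unname(clust$assignment)),
      file.path(out_dir, "cluster_assignments.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(degs, file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(panel),
                       file.path(out_dir, "marker_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_stage_model(model, file.path(out_dir, "stage_model.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("budphase")),
      seed = config$simulation$seed,
      parameter_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                           collapse = ""))),
      stages = list(genes_in = config$simulation$n_genes,
                    genes_filtered = length(kept),
                    degs = length(deg_ids),
                    clusters = config$clustering$k,
                    markers = nrow(panel),
                    samples = nrow(sim$metadata)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
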