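#' Default simulation configuration for a synthetic dormancy time course
#'
#' Describes the synthetic study: three cultivars with contrasting dormancy
#' release dates sampled at 11 dates (July to March) on 3 replicate trees;
#' 2000 genes in 10 temporal clusters whose sizes are proportional to a
#' typical DEG clustering of this design; smooth unimodal (Gaussian bump)
#' latent profiles peaking in chronological order, time-shifted per cultivar
#' after endodormancy onset by each cultivar's release-date offset;
#' negative-binomial read counts; planted marker genes, planted annotation
#' enrichments, and an independent qPCR-platform cultivar.
#'
#' @param ... overrides for any default field; unknown names are an error.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 2000L,
    n_clusters = 10L,
    # relative cluster sizes, rescaled to n_genes
    cluster_proportions = c(1549, 70, 113, 884, 156, 989, 648, 612, 924, 739),
    cultivars = data.frame(
      cultivar = c("Cristobalina", "Garnet", "Regina"),
      release_date = as.Date(c("2015-12-09", "2016-01-29", "2016-02-26")),
      flowering_date = as.Date(c("2016-03-20", "2016-04-05", "2016-04-15")),
      stringsAsFactors = FALSE),
    reference_cultivar = "Garnet",
    # candidate sampling dates; each cultivar is sampled only until its
    # flowering date (so early cultivars have fewer dates)
    dates = as.Date(c("2015-07-15", "2015-08-20", "2015-09-15", "2015-10-10",
                      "2015-10-25", "2015-11-10", "2015-12-10", "2016-01-10",
                      "2016-01-29", "2016-02-26", "2016-04-01")),
    replicates = 3L,
    endodormancy_onset = as.Date("2015-10-01"),
    reference_date = as.Date("2015-10-10"),
    # cluster expression peaks sit inside their stage (organogenesis,
    # paradormancy, endo-, release, ecodormancy midpoints on the reference
    # cultivar's calendar), in chronological order
    cluster_peak_dates = as.Date(c("2015-07-15", "2015-08-10", "2015-09-01",
                                   "2015-09-20", "2015-11-05", "2015-12-05",
                                   "2016-01-05", "2016-01-29", "2016-02-20",
                                   "2016-03-10")),
    profile_sigma_days = 30,
    # growth-resumption genes stay induced once activated: the last cluster
    # plateaus after its rise instead of decaying
    sustained_clusters = 10L,
    amplitude = 3,
    profile_noise_sd = 0.1,
    marker_noise_factor = 0.25,
    dispersion = 0.01,
    library_size_range = c(8e5, 1.2e6),
    length_range = c(500L, 5000L),
    markers_per_cluster = 1L,
    marker_clusters = c(1, 4, 5, 7, 8, 9, 10),
    annotation_background_rate = 0.1,
    enrichment_fold = 5,
    n_sets = c(tf = 25L, motif = 30L, go = 40L),
    qpcr_cultivar = "Fertard",
    qpcr_release_date = as.Date("2016-02-26"),
    qpcr_flowering_date = as.Date("2016-04-15"),
    qpcr_multiplicative_sd = 0.2,
    cq_sd = 0.2,
    qpcr_technical_replicates = 3L,
    reference_gene_ids = c("RPII", "EF1"),
    budbreak_n_buds = 30L,
    budbreak_scale_days = 6
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (f in c("dates", "cluster_peak_dates", "endodormancy_onset",
              "reference_date", "qpcr_release_date", "qpcr_flowering_date"))
    cfg[[f]] <- as.Date(cfg[[f]])
  cfg$cultivars$release_date <- as.Date(cfg$cultivars$release_date)
  cfg$cultivars$flowering_date <- as.Date(cfg$cultivars$flowering_date)
  if (abs(sum(cluster_sizes(cfg)) - cfg$n_genes) > 0)
    stop("internal error: cluster sizes do not sum to n_genes")
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (cfg$markers_per_cluster * cfg$n_clusters > cfg$n_genes)
    stop("more planted markers than genes")
  if (any(cluster_sizes(cfg) < cfg$markers_per_cluster))
    stop("infeasible config: a cluster has fewer genes than planted markers",
         " (increase n_genes or rebalance cluster_proportions)")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Integer cluster sizes summing exactly to n_genes (largest-remainder).
cluster_sizes <- function(config) {
  prop <- config$cluster_proportions
  if (length(prop) != config$n_clusters)
    stop("cluster_proportions must have n_clusters entries")
  raw <- prop / sum(prop) * config$n_genes
  sizes <- floor(raw)
  rem <- config$n_genes - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

# Cluster peak dates on the reference-cultivar timeline, chronological.
cluster_peaks <- function(config) {
  peaks <- as.Date(config$cluster_peak_dates)
  if (length(peaks) != config$n_clusters)
    peaks <- as.Date(seq(min(as.numeric(peaks)), max(as.numeric(peaks)),
                         length.out = config$n_clusters),
                     origin = "1970-01-01")
  peaks
}

# Per-cultivar stage calendars from the configured release/flowering dates.
config_calendars <- function(config) {
  cals <- lapply(seq_len(nrow(config$cultivars)), function(i)
    stage_calendar(config$cultivars$cultivar[i],
                   config$cultivars$release_date[i],
                   config$cultivars$flowering_date[i],
                   endodormancy_onset = config$endodormancy_onset))
  names(cals) <- config$cultivars$cultivar
  cals
}

# Post-onset shift (days) of each cultivar relative to the reference.
cultivar_shifts <- function(config) {
  ref <- config$cultivars$release_date[
    config$cultivars$cultivar == config$reference_cultivar]
  stats::setNames(as.numeric(config$cultivars$release_date - ref),
                  config$cultivars$cultivar)
}

# Gaussian-bump latent profile value at dates t for peak p. Sustained
# profiles hold their maximum after the peak (rise-and-plateau).
bump_profile <- function(t, peak, sigma, sustained = FALSE) {
  x <- as.numeric(t) - as.numeric(peak)
  f <- exp(-0.5 * (x / sigma)^2)
  if (sustained) f[x > 0] <- 1
  f
}

# Latent profile of one cluster at effective dates t_eff.
cluster_profile_value <- function(t_eff, cluster, config, peaks) {
  bump_profile(t_eff, peaks[cluster], config$profile_sigma_days,
               sustained = cluster %in% config$sustained_clusters)
}

# Effective (dormancy-clock) date mapping a cultivar's calendar time onto
# the reference cultivar's timeline. Before endodormancy onset the clocks
# agree; through endodormancy each cultivar's clock runs proportionally so
# that its own release date maps onto the reference release date (early
# cultivars accumulate their chilling requirement faster); after release,
# time advances in days-since-release on both clocks.
effective_dates <- function(dates, release, release_ref, onset) {
  t <- as.numeric(dates)
  onset <- as.numeric(onset)
  release <- as.numeric(release)
  release_ref <- as.numeric(release_ref)
  ifelse(t <= onset, t,
         ifelse(t <= release,
                onset + (t - onset) * (release_ref - onset) / (release - onset),
                release_ref + (t - release)))
}

#' Simulate a read-count matrix with planted temporal clusters
#'
#' Every gene belongs to one of `n_clusters` clusters with a smooth unimodal
#' latent z-profile peaking at the cluster's characteristic date; cultivars
#' other than the reference are time-shifted after endodormancy onset by
#' their release-date offset. Counts are drawn negative-binomially around
#' TPM-scaled latent means with per-sample library sizes. One low-noise,
#' well-expressed marker gene is planted per cluster.
#'
#' @param config a [sim_config()].
#' @return list: `counts` (genes x samples), `gene_lengths`, `metadata`
#'   (with true stage labels), `truth` (gene -> cluster, marker ids, family
#'   table, calendars, peaks, release dates).
#' @export
simulate_counts <- function(config = sim_config()) {
  set.seed(config$seed)
  n_genes <- config$n_genes
  sizes <- cluster_sizes(config)
  peaks <- cluster_peaks(config)
  shifts <- cultivar_shifts(config)
  calendars <- config_calendars(config)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  gene_cluster <- stats::setNames(rep(seq_len(config$n_clusters), sizes),
                                  gene_ids)
  gene_lengths <- stats::setNames(
    sample(seq(config$length_range[1], config$length_range[2]), n_genes,
           replace = TRUE), gene_ids)
  base <- stats::setNames(stats::rlnorm(n_genes, log(10), 1), gene_ids)
  noise_sd <- stats::setNames(rep(config$profile_noise_sd, n_genes), gene_ids)

  # planted markers: first markers_per_cluster genes of each cluster, given
  # high baseline expression and reduced profile noise
  markers <- do.call(rbind, lapply(seq_len(config$n_clusters), function(cl) {
    ids <- gene_ids[gene_cluster == cl][seq_len(config$markers_per_cluster)]
    data.frame(cluster = cl, gene_id = ids, stringsAsFactors = FALSE)
  }))
  base[markers$gene_id] <- stats::rlnorm(nrow(markers), log(40), 0.3)
  noise_sd[markers$gene_id] <- config$profile_noise_sd * config$marker_noise_factor

  # gene families: markers are singletons; a quarter of the other genes sit
  # in large (size > 5) families
  others <- setdiff(gene_ids, markers$gene_id)
  shuffled <- sample(others)
  fam_rows <- list(); fam_id <- 0L; i <- 1
  while (i <= length(shuffled)) {
    fam_id <- fam_id + 1L
    size <- sample(c(1L, 2L, 3L, 8L, 12L), 1,
                   prob = c(0.45, 0.2, 0.15, 0.12, 0.08))
    members <- shuffled[i:min(i + size - 1, length(shuffled))]
    fam_rows[[fam_id]] <- data.frame(
      gene_id = members, family_id = sprintf("FAM%04d", fam_id),
      family_size = length(members), stringsAsFactors = FALSE)
    i <- i + size
  }
  family_table <- rbind(
    do.call(rbind, fam_rows),
    data.frame(gene_id = markers$gene_id,
               family_id = sprintf("FAM_M%02d", seq_len(nrow(markers))),
               family_size = 1L, stringsAsFactors = FALSE))

  # sample sheet; sampling stops at each cultivar's flowering date
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      date = config$dates,
                      cultivar = config$cultivars$cultivar,
                      stringsAsFactors = FALSE)
  flowering <- stats::setNames(config$cultivars$flowering_date,
                               config$cultivars$cultivar)
  grid <- grid[grid$date <= flowering[grid$cultivar], , drop = FALSE]
  metadata <- data.frame(
    sample_id = sprintf("%s_%s_T%d", grid$cultivar, format(grid$date),
                        grid$replicate),
    cultivar = grid$cultivar,
    tree_replicate = paste0("T", grid$replicate),
    date = grid$date,
    stringsAsFactors = FALSE)
  metadata$stage <- vapply(seq_len(nrow(metadata)), function(i)
    assign_stage_labels(metadata$date[i], calendars[[metadata$cultivar[i]]]),
    character(1))

  # latent log2 expression and NB counts
  n_samples <- nrow(metadata)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(gene_ids, metadata$sample_id))
  lib_sizes <- stats::runif(n_samples, config$library_size_range[1],
                            config$library_size_range[2])
  release_ref <- config$cultivars$release_date[
    config$cultivars$cultivar == config$reference_cultivar]
  releases <- stats::setNames(config$cultivars$release_date,
                              config$cultivars$cultivar)
  cluster_profile <- matrix(NA_real_, config$n_clusters, n_samples)
  for (j in seq_len(n_samples)) {
    t_eff <- effective_dates(metadata$date[j],
                             releases[metadata$cultivar[j]], release_ref,
                             config$endodormancy_onset)
    cluster_profile[, j] <- vapply(seq_len(config$n_clusters), function(cl)
      cluster_profile_value(t_eff, cl, config, peaks), numeric(1))
  }
  eps <- matrix(stats::rnorm(n_genes * n_samples, 0, 1), n_genes) * noise_sd
  log2q <- log2(base) + config$amplitude * (cluster_profile[gene_cluster, ] + eps)
  q <- 2^log2q
  w <- q * gene_lengths
  frac <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(frac, 2, lib_sizes, "*")
  # dispersion 0 means noiseless observation (expected counts), so latent
  # structure is reproduced exactly; any positive dispersion gives NB draws
  counts[] <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    mu
  }

  truth <- list(
    gene_cluster = gene_cluster,
    markers = markers,
    family_table = family_table,
    stage = stats::setNames(metadata$stage, metadata$sample_id),
    release_dates = stats::setNames(config$cultivars$release_date,
                                    config$cultivars$cultivar),
    calendars = calendars,
    peaks = peaks,
    shifts = shifts)
  list(counts = counts, gene_lengths = gene_lengths, metadata = metadata,
       truth = truth)
}

#' Simulate annotation tables with planted per-cluster enrichments
#'
#' Genes are annotated to each set at a uniform background rate; for each
#' planted (cluster, set) pair the in-cluster annotation rate is
#' `enrichment_fold` times the background (capped at 1). One set is planted
#' per cluster for each annotation kind.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return list with data frames `tf`, `motif`, `go` (columns `gene_id`,
#'   `set_id`) and `planted` (kind, cluster, set_id).
#' @export
simulate_annotations <- function(config, truth) {
  if (config$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  set.seed(config$seed + 1L)
  genes <- names(truth$gene_cluster)
  bg <- config$annotation_background_rate
  planted_rate <- min(1, config$enrichment_fold * bg)
  kinds <- names(config$n_sets)
  planted_all <- list()
  tables <- lapply(kinds, function(kind) {
    n_sets <- config$n_sets[[kind]]
    set_ids <- switch(kind,
      tf = sprintf("TF%03d", seq_len(n_sets)),
      motif = sprintf("MP%05d", seq_len(n_sets)),
      go = sprintf("GO:%07d", seq_len(n_sets)))
    planted <- data.frame(kind = kind,
                          cluster = seq_len(config$n_clusters),
                          set_id = set_ids[seq_len(config$n_clusters)],
                          stringsAsFactors = FALSE)
    planted_all[[kind]] <<- planted
    rows <- lapply(seq_len(n_sets), function(s) {
      rate <- rep(bg, length(genes))
      hit <- planted$cluster[planted$set_id == set_ids[s]]
      if (length(hit) == 1)
        rate[truth$gene_cluster == hit] <- planted_rate
      member <- stats::runif(length(genes)) < rate
      if (!any(member)) return(NULL)
      data.frame(gene_id = genes[member], set_id = set_ids[s],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(tables) <- kinds
  tables$planted <- do.call(rbind, planted_all)
  rownames(tables$planted) <- NULL
  tables
}

#' Simulate RT-qPCR Cq tables and dilution standards for a held-out cultivar
#'
#' Generates marker-gene latent profiles for an independent cultivar with
#' its own calendar and post-onset shift, applies multiplicative
#' (platform/pipetting) noise, converts quantities to Cq through planted
#' per-gene standard curves with Cq measurement noise, and emits a matching
#' dilution series per gene. Reference genes are generated flat.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return list: `cq_table`, `standards`, `metadata` (with true stages),
#'   `truth` (planted curves, quantities, stage labels).
#' @export
simulate_qpcr <- function(config, truth) {
  set.seed(config$seed + 2L)
  panel <- truth$markers
  marker_ids <- panel$gene_id
  all_genes <- c(marker_ids, config$reference_gene_ids)
  calendar <- stage_calendar(config$qpcr_cultivar, config$qpcr_release_date,
                             config$qpcr_flowering_date,
                             endodormancy_onset = config$endodormancy_onset)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      date = config$dates, stringsAsFactors = FALSE)
  grid <- grid[grid$date <= config$qpcr_flowering_date, , drop = FALSE]
  metadata <- data.frame(
    sample_id = sprintf("%s_%s_T%d", config$qpcr_cultivar, format(grid$date),
                        grid$replicate),
    cultivar = config$qpcr_cultivar,
    tree_replicate = paste0("T", grid$replicate),
    date = grid$date, stringsAsFactors = FALSE)
  metadata$stage <- assign_stage_labels(metadata$date, calendar)

  peaks <- truth$peaks
  release_ref <- config$cultivars$release_date[
    config$cultivars$cultivar == config$reference_cultivar]
  t_eff <- effective_dates(metadata$date, config$qpcr_release_date,
                           release_ref, config$endodormancy_onset)
  quantities <- matrix(NA_real_, length(all_genes), nrow(metadata),
                       dimnames = list(all_genes, metadata$sample_id))
  for (i in seq_along(marker_ids)) {
    f <- cluster_profile_value(t_eff, panel$cluster[i], config, peaks)
    quantities[marker_ids[i], ] <- 10 * 2^(config$amplitude * f)
  }
  for (g in config$reference_gene_ids) quantities[g, ] <- 50
  noise <- matrix(exp(stats::rnorm(length(quantities), 0,
                                   config$qpcr_multiplicative_sd)),
                  nrow(quantities))
  observed <- quantities * noise

  curves <- data.frame(
    gene_id = all_genes,
    slope = stats::runif(length(all_genes), -3.6, -3.1),
    intercept = stats::runif(length(all_genes), 22, 26),
    stringsAsFactors = FALSE)

  n_tech <- max(1L, config$qpcr_technical_replicates)
  cq_table <- do.call(rbind, lapply(seq_along(all_genes), function(i) {
    g <- all_genes[i]
    true_cq <- curves$intercept[i] + curves$slope[i] * log10(observed[g, ])
    do.call(rbind, lapply(seq_len(n_tech), function(r)
      data.frame(sample_id = colnames(observed), gene_id = g,
                 cq = true_cq + stats::rnorm(length(true_cq), 0, config$cq_sd),
                 stringsAsFactors = FALSE)))
  }))
  rownames(cq_table) <- NULL

  dilutions <- c(100, 10, 1, 0.1, 0.01)
  standards <- do.call(rbind, lapply(seq_along(all_genes), function(i) {
    cq <- curves$intercept[i] + curves$slope[i] * log10(dilutions) +
      stats::rnorm(length(dilutions), 0, config$cq_sd)
    data.frame(gene_id = all_genes[i], dilution_quantity = dilutions, cq = cq,
               stringsAsFactors = FALSE)
  }))
  rownames(standards) <- NULL

  list(cq_table = cq_table, standards = standards, metadata = metadata,
       truth = list(curves = curves, quantities = quantities,
                    stage = stats::setNames(metadata$stage,
                                            metadata$sample_id),
                    calendar = calendar, panel = panel))
}

#' Simulate fortnightly forcing-test bud-break series
#'
#' Logistic bud-break curves in time with the 50% crossing at each
#' cultivar's planted release date, sampled fortnightly from 1 November,
#' with binomial observation noise over `budbreak_n_buds` assayed buds
#' (exact percentages when `n_buds = NULL`).
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @param n_buds number of buds assayed per observation; `NULL` for
#'   noiseless curves. Defaults to `config$budbreak_n_buds`.
#' @return data frame `cultivar`, `date`, `percent_bbch53`.
#' @export
simulate_budbreak <- function(config, truth, n_buds = config$budbreak_n_buds) {
  set.seed(config$seed + 3L)
  releases <- c(truth$release_dates,
                stats::setNames(config$qpcr_release_date, config$qpcr_cultivar))
  out <- lapply(names(releases), function(cv) {
    dates <- seq(as.Date("2015-11-01"), as.Date("2016-04-30"), by = 14)
    p <- 100 / (1 + exp(-(as.numeric(dates) - as.numeric(releases[[cv]])) /
                          config$budbreak_scale_days))
    pct <- if (is.null(n_buds)) p
           else stats::rbinom(length(p), n_buds, p / 100) / n_buds * 100
    data.frame(cultivar = cv, date = dates, percent_bbch53 = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_counts()], [simulate_annotations()], [simulate_qpcr()]
#' and [simulate_budbreak()] under one configuration and seed.
#'
#' @param config a [sim_config()].
#' @return list of class `bud_simulation` with elements `config`, `counts`,
#'   `gene_lengths`, `metadata`, `truth`, `annotations`, `qpcr`,
#'   `budbreak`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  base <- simulate_counts(config)
  ann <- simulate_annotations(config, base$truth)
  qpcr <- simulate_qpcr(config, base$truth)
  budbreak <- simulate_budbreak(config, base$truth)
  structure(list(config = config, counts = base$counts,
                 gene_lengths = base$gene_lengths, metadata = base$metadata,
                 truth = base$truth, annotations = ann, qpcr = qpcr,
                 budbreak = budbreak),
            class = "bud_simulation")
}
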