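#' Pearson correlation distance between gene expression profiles
#'
#' `d(i, j) = 1 - r(i, j)` where r is the Pearson correlation of the two
#' genes' profiles across samples; d lies in \[0, 2\], is 0 on the diagonal
#' and symmetric. Scale- and offset-invariant, so TPM and z-score profiles
#' give identical distances.
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @return a `stats::dist` object over genes.
#' @export
pearson_distance <- function(expr) {
  check_expression_matrix(expr, "expression matrix", nonneg = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s), filter first: ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  d <- 1 - stats::cor(t(expr))
  d[d < 0] <- 0   # guard against -1e-17 round-off
  stats::as.dist(d)
}

#' Cut an agglomerative clustering of a distance matrix into k groups
#'
#' Hierarchical (agglomerative) clustering of the distance matrix with the
#' given linkage, with the tree cut into exactly `k` groups. Labels follow
#' the order of first appearance in the input; use
#' [order_clusters_by_peak()] to relabel chronologically.
#'
#' @param dist a `stats::dist` object (e.g. from [pearson_distance()]).
#' @param k number of clusters (default 10).
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return named integer vector: gene -> cluster label in 1..k.
#' @export
hierarchical_clusters <- function(dist, k = 10,
                                  linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (!inherits(dist, "dist")) stop("dist must be a stats::dist object")
  n <- attr(dist, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of genes (", n, ")")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(dist, method = method)
  stats::cutree(tree, k = k)
}

#' Row-wise z-score standardization
#'
#' For each gene, `z = (x - mean) / sd` across samples, so every row has
#' mean 0 and standard deviation 1. The sample sd (n - 1 denominator) is
#' used by default.
#'
#' @param expr numeric matrix, genes x samples.
#' @param denominator `"sample"` (n - 1, default) or `"population"` (n).
#' @return matrix of z-scores with the same dimnames.
#' @export
zscore_rows <- function(expr, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  if (denominator == "population")
    s <- s * sqrt((ncol(expr) - 1) / ncol(expr))
  if (any(!is.finite(s)) || any(s == 0))
    stop("constant row(s) cannot be z-scored: ",
         paste(utils::head(rownames(expr)[s == 0], 5), collapse = ", "))
  (expr - m) / s
}

# Map each sample to its timepoint key, chronologically ordered.
timepoint_keys <- function(metadata, timepoint = c("date", "cultivar_date")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "date") {
    key <- as.character(metadata$date)
    levels <- as.character(sort(unique(metadata$date)))
  } else {
    key <- paste(metadata$cultivar, metadata$date, sep = "@")
    u <- unique(data.frame(cultivar = metadata$cultivar,
                           date = metadata$date, key = key))
    u <- u[order(u$cultivar, u$date), ]
    levels <- u$key
  }
  factor(key, levels = levels)
}

#' Mean z-score profile of each cluster over timepoints
#'
#' The centroid of cluster c at timepoint t is the mean z-score over all
#' member genes and all replicate samples (across cultivars when several are
#' supplied) harvested at t. Columns are in chronological order.
#'
#' @param z z-score matrix from [zscore_rows()], genes x samples.
#' @param assignment named integer vector, gene -> cluster.
#' @param metadata sample metadata covering `colnames(z)`.
#' @param timepoint `"date"` (default: average replicates and cultivars per
#'   date) or `"cultivar_date"`.
#' @return matrix, clusters x timepoints, rownames the cluster labels.
#' @export
cluster_centroids <- function(z, assignment, metadata,
                              timepoint = c("date", "cultivar_date")) {
  timepoint <- match.arg(timepoint)
  metadata <- check_metadata(metadata, colnames(z))
  miss <- setdiff(names(assignment), rownames(z))
  if (length(miss) > 0)
    stop("clustered gene(s) absent from z matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  keys <- timepoint_keys(metadata, timepoint)
  clusters <- sort(unique(assignment))
  out <- matrix(NA_real_, length(clusters), nlevels(keys),
                dimnames = list(clusters, levels(keys)))
  for (i in seq_along(clusters)) {
    members <- names(assignment)[assignment == clusters[i]]
    if (length(members) == 0) stop("cluster ", clusters[i], " has no members")
    sub <- z[members, , drop = FALSE]
    for (lv in levels(keys))
      out[i, lv] <- mean(sub[, keys == lv, drop = FALSE])
  }
  out
}

#' Chronological relabeling of clusters by expression peak
#'
#' Orders clusters by the timepoint at which their centroid profile peaks
#' (earliest first); ties are broken by putting the larger cluster first,
#' then by the original label. Returns the permutation: `peak_order[i]` is
#' the original label of the cluster that becomes label i.
#'
#' @param centroids matrix from [cluster_centroids()] on a chronologically
#'   sorted timepoint axis.
#' @param sizes optional named vector of cluster sizes (for tie-breaking).
#' @return integer vector of original labels in new-label order.
#' @export
order_clusters_by_peak <- function(centroids, sizes = NULL) {
  peaks <- apply(centroids, 1, which.max)
  labels <- rownames(centroids)
  if (is.null(sizes)) sizes <- stats::setNames(rep(0, length(labels)), labels)
  sz <- sizes[labels]
  ord <- order(peaks, -sz, labels)
  out <- as.integer(labels[ord])
  if (anyNA(out)) out <- labels[ord]
  out
}

#' Apply a chronological relabeling to a cluster assignment
#'
#' @param assignment named integer vector, gene -> original cluster label.
#' @param peak_order permutation from [order_clusters_by_peak()].
#' @return named integer vector with labels 1..k in peak chronology.
#' @export
relabel_clusters <- function(assignment, peak_order) {
  new_label <- stats::setNames(seq_along(peak_order), as.character(peak_order))
  out <- new_label[as.character(assignment)]
  names(out) <- names(assignment)
  out
}

#' Pearson correlation of each gene with its own cluster centroid
#'
#' For each gene, the correlation between its z-score profile (over samples)
#' and the centroid value of its cluster at the timepoint of each sample,
#' i.e. along the same sample axis the centroids were computed on.
#'
#' @inheritParams cluster_centroids
#' @param centroids matrix from [cluster_centroids()].
#' @return named numeric vector of correlations in \[-1, 1\].
#' @export
centroid_correlations <- function(z, centroids, assignment, metadata,
                                  timepoint = c("date", "cultivar_date")) {
  timepoint <- match.arg(timepoint)
  metadata <- check_metadata(metadata, colnames(z))
  keys <- timepoint_keys(metadata, timepoint)
  genes <- names(assignment)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    cl <- as.character(assignment[[g]])
    if (!cl %in% rownames(centroids))
      stop("no centroid for cluster ", cl, " (gene ", g, ")")
    profile <- centroids[cl, as.character(keys)]
    if (stats::sd(profile) == 0)
      stop("constant centroid for cluster ", cl)
    out[g] <- stats::cor(z[g, ], profile)
  }
  out
}

#' Cluster DEG expression profiles end to end
#'
#' Convenience wrapper: Pearson distance on the reference cultivar's TPM
#' profiles, agglomerative clustering cut at k, z-scores, centroids over all
#' supplied cultivars, chronological relabeling, and per-gene centroid
#' correlations.
#'
#' @param tpm TPM matrix (all cultivars), genes x samples.
#' @param metadata sample metadata.
#' @param genes gene ids to cluster (e.g. DEGs).
#' @param k number of clusters (default 10).
#' @param linkage linkage method (default `"complete"`).
#' @param reference_cultivar cultivar whose profiles define the distance
#'   matrix; `NULL` uses all samples.
#' @param correlation_timepoint timepoint axis for the gene-to-centroid
#'   correlations: `"cultivar_date"` (default; the centroid follows each
#'   cultivar's own temporal shift) or `"date"`.
#' @return list of class `cluster_model`: `k`, `linkage`, `assignment`
#'   (chronologically relabeled), `centroids` (date axis), `peak_order`,
#'   `correlations`, `sizes`.
#' @export
cluster_expression <- function(tpm, metadata, genes, k = 10,
                               linkage = "complete",
                               reference_cultivar = NULL,
                               correlation_timepoint = c("cultivar_date",
                                                         "date")) {
  correlation_timepoint <- match.arg(correlation_timepoint)
  metadata <- check_metadata(metadata, colnames(tpm))
  genes <- intersect(genes, rownames(tpm))
  if (length(genes) < k) stop("fewer genes (", length(genes), ") than clusters")
  ref_samples <- if (is.null(reference_cultivar)) metadata$sample_id
                 else metadata$sample_id[metadata$cultivar == reference_cultivar]
  if (length(ref_samples) < 2)
    stop("reference cultivar has fewer than 2 samples")
  x <- tpm[genes, ref_samples, drop = FALSE]
  keep <- apply(x, 1, stats::sd) > 0
  x <- x[keep, , drop = FALSE]
  d <- pearson_distance(x)
  assignment <- hierarchical_clusters(d, k = k, linkage = linkage)
  z <- zscore_rows(tpm[rownames(x), , drop = FALSE])
  centroids <- cluster_centroids(z, assignment, metadata)
  sizes <- table(assignment)
  peak_order <- order_clusters_by_peak(centroids, sizes)
  assignment <- relabel_clusters(assignment, peak_order)
  centroids <- cluster_centroids(z, assignment, metadata)
  corr_centroids <- if (correlation_timepoint == "date") centroids
    else cluster_centroids(z, assignment, metadata,
                           timepoint = correlation_timepoint)
  corrs <- centroid_correlations(z, corr_centroids, assignment, metadata,
                                 timepoint = correlation_timepoint)
  structure(list(k = k, linkage = linkage, assignment = assignment,
                 centroids = centroids, peak_order = peak_order,
                 correlations = corrs, sizes = table(assignment)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Expression cluster model: k =", x$k, ", linkage =", x$linkage, "\n")
  print(x$sizes)
  invisible(x)
}
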