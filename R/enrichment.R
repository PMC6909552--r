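#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric p-value P(X >= k), X ~ Hyper(N, K, n).
hyper_upper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of annotation sets in a gene cluster
#'
#' For each annotation set (TF target list, promoter motif, GO term, ...),
#' tests whether the cluster carries more annotated genes than expected from
#' the universe, with the exact upper-tail hypergeometric probability
#' `P(X >= k)` for k annotated genes among n cluster genes, K annotated in
#' the universe of N. Duplicate (gene, set) records are collapsed to
#' gene-level presence before testing.
#'
#' @param cluster_genes gene ids in the cluster (must lie in `universe`).
#' @param annotation data frame with columns `gene_id` and `set_id`.
#' @param universe gene ids forming the testing universe (e.g. all DEGs).
#' @param adjust apply BH adjustment over the sets tested here (default
#'   TRUE; one family per call, i.e. per cluster x annotation kind).
#' @return data frame `set_id`, `k`, `n`, `K`, `N`, `pvalue`, `padj`,
#'   sorted by ascending p then set id.
#' @export
hypergeom_overrep <- function(cluster_genes, annotation, universe,
                              adjust = TRUE) {
  universe <- unique(universe)
  cluster_genes <- unique(cluster_genes)
  if (length(universe) == 0) stop("empty universe")
  if (length(cluster_genes) == 0) stop("empty cluster")
  out <- setdiff(cluster_genes, universe)
  if (length(out) > 0)
    stop("cluster gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "set_id")])
  if (nrow(ann) == 0)
    return(data.frame(set_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(cluster_genes)
  K_tab <- table(ann$set_id)
  in_cluster <- ann[ann$gene_id %in% cluster_genes, ]
  k_tab <- table(factor(in_cluster$set_id, levels = names(K_tab)))
  res <- data.frame(set_id = names(K_tab),
                    k = as.integer(k_tab),
                    n = n,
                    K = as.integer(K_tab),
                    N = N, stringsAsFactors = FALSE)
  res$pvalue <- hyper_upper_tail(res$k, res$K, res$n, res$N)
  res$padj <- if (adjust) bh_adjust(res$pvalue) else NA_real_
  res[order(res$pvalue, res$set_id), , drop = FALSE]
}

#' Classic-Fisher GO term enrichment for a gene cluster
#'
#' One-sided Fisher exact test on the 2x2 membership table (in cluster /
#' annotated), which coincides with the hypergeometric upper tail. Terms are
#' filtered at `p_cut` on the raw p-value and the `top_n` terms with the
#' lowest p are returned (ties broken by term id). No ontology-graph
#' propagation is performed: annotations are taken as the flat gene-to-term
#' table supplied.
#'
#' @inheritParams hypergeom_overrep
#' @param p_cut raw p-value cutoff (default 0.005).
#' @param top_n number of top terms to keep (default 10).
#' @return data frame like [hypergeom_overrep()] (without `padj`), at most
#'   `top_n` rows, p < `p_cut`.
#' @export
go_fisher <- function(cluster_genes, annotation, universe,
                      p_cut = 0.005, top_n = 10) {
  universe <- unique(universe)
  cluster_genes <- unique(cluster_genes)
  if (length(universe) == 0) stop("empty universe")
  if (length(cluster_genes) == 0) stop("empty cluster")
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "set_id")])
  N <- length(universe)
  n <- length(cluster_genes)
  sets <- sort(unique(ann$set_id))
  rows <- lapply(sets, function(s) {
    annotated <- ann$gene_id[ann$set_id == s]
    K <- length(annotated)
    k <- length(intersect(annotated, cluster_genes))
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set_id = s, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(set_id = character(), k = integer(),
                                      n = integer(), K = integer(),
                                      N = integer(), pvalue = numeric()))
  res <- res[res$pvalue < p_cut, , drop = FALSE]
  res <- res[order(res$pvalue, res$set_id), , drop = FALSE]
  utils::head(res, top_n)
}

#' Per-cluster over-representation across a whole clustering
#'
#' Runs [hypergeom_overrep()] for every cluster of an assignment against a
#' common universe, BH-adjusting within each cluster (one correction family
#' per cluster, matching per-cluster reporting).
#'
#' @param assignment named integer vector, gene -> cluster.
#' @param annotation data frame `gene_id`, `set_id`.
#' @param universe testing universe; defaults to all assigned genes (the
#'   DEG set).
#' @return data frame with a leading `cluster` column.
#' @export
enrich_clusters <- function(assignment, annotation, universe = NULL) {
  if (is.null(universe)) universe <- names(assignment)
  clusters <- sort(unique(assignment))
  rows <- lapply(clusters, function(cl) {
    res <- hypergeom_overrep(names(assignment)[assignment == cl],
                             annotation, universe)
    if (nrow(res) == 0) return(NULL)
    cbind(cluster = cl, res)
  })
  do.call(rbind, rows)
}
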