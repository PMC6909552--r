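#' Select a minimal marker-gene panel, one gene per chosen cluster
#'
#' Within each requested cluster, genes are first screened for eligibility:
#' mean TPM at least `min_mean_tpm` (markers must be easy to assay), gene
#' family size at most `max_family_size` (avoiding redundancy among close
#' paralogs), and absence from a user exclusion list (e.g. genes without
#' workable primers). The eligible gene whose profile correlates best with
#' the cluster centroid is selected; ties are broken by higher mean TPM,
#' then lexicographic gene id.
#'
#' @param correlations named vector of per-gene centroid correlations, e.g.
#'   from [cluster_expression()].
#' @param assignment named integer vector, gene -> cluster label.
#' @param tpm TPM matrix used for the mean-expression screen.
#' @param family_table optional data frame `gene_id`, `family_id`,
#'   `family_size`; genes not listed are treated as singletons.
#' @param clusters cluster labels to draw markers from (default 1, 4, 5, 7,
#'   8, 9, 10 — clusters that are neither tiny nor redundant with another
#'   profile are the useful ones; the choice remains the caller's).
#' @param min_mean_tpm minimum mean TPM for eligibility (default 10).
#' @param max_family_size maximum gene family size (default 5).
#' @param exclude gene ids to exclude outright.
#' @return a `marker_panel` data frame: `cluster`, `gene_id`, `r`,
#'   `mean_tpm`, sorted by cluster label, with the selection criteria stored
#'   in `attr(, "criteria")`.
#' @export
select_markers <- function(correlations, assignment, tpm,
                           family_table = NULL,
                           clusters = c(1, 4, 5, 7, 8, 9, 10),
                           min_mean_tpm = 10, max_family_size = 5,
                           exclude = character()) {
  check_expression_matrix(tpm, "TPM matrix")
  genes <- names(assignment)
  if (is.null(genes) || is.null(names(correlations)))
    stop("assignment and correlations must be named by gene id")
  mean_tpm <- rowMeans(tpm)
  fam_size <- stats::setNames(rep(1L, length(genes)), genes)
  if (!is.null(family_table)) {
    idx <- match(genes, family_table$gene_id)
    fam_size[!is.na(idx)] <- family_table$family_size[idx[!is.na(idx)]]
  }
  rows <- lapply(sort(clusters), function(cl) {
    members <- genes[assignment == cl]
    if (length(members) == 0)
      stop("cluster ", cl, " has no genes")
    ok_expr <- mean_tpm[members] >= min_mean_tpm
    ok_fam <- fam_size[members] <= max_family_size
    ok_excl <- !members %in% exclude
    eligible <- members[ok_expr & ok_fam & ok_excl]
    if (length(eligible) == 0) {
      binding <- c(
        if (!any(ok_expr)) sprintf("mean TPM < %g for all genes", min_mean_tpm),
        if (!any(ok_fam)) sprintf("family size > %d for all genes", max_family_size),
        if (!any(ok_excl)) "all genes excluded",
        sprintf("%d member(s), none passing the joint screen", length(members)))
      stop("cluster ", cl, " has no eligible marker gene (",
           paste(binding, collapse = "; "), ")")
    }
    r <- correlations[eligible]
    ord <- order(-r, -mean_tpm[eligible], eligible)
    best <- eligible[ord[1]]
    data.frame(cluster = cl, gene_id = best, r = unname(r[ord[1]]),
               mean_tpm = unname(mean_tpm[best]), stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  attr(panel, "criteria") <- list(clusters = sort(clusters),
                                  min_mean_tpm = min_mean_tpm,
                                  max_family_size = max_family_size,
                                  n_excluded = length(exclude))
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", nrow(x), "genes, one per cluster\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
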