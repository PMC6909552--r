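#' Compute transcripts per million (TPM)
#'
#' Length-normalizes raw read counts within each sample so that every sample
#' column sums to one million: for gene i and sample j,
#' `TPM_ij = (c_ij / L_i) / sum_g(c_gj / L_g) * 1e6`, with lengths L in bp.
#'
#' @param counts numeric matrix of raw read counts, genes x samples, with
#'   gene row names and sample column names.
#' @param gene_lengths numeric vector of gene lengths (bp), named by gene id
#'   or aligned to `rownames(counts)`.
#' @return numeric matrix of TPM values, same dimnames as `counts`.
#' @examples
#' counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' compute_tpm(counts, c(g1 = 1000, g2 = 2000))
#' @export
compute_tpm <- function(counts, gene_lengths) {
  check_expression_matrix(counts, "count matrix")
  if (!is.null(names(gene_lengths))) {
    miss <- setdiff(rownames(counts), names(gene_lengths))
    if (length(miss) > 0)
      stop("missing gene length for: ", paste(utils::head(miss, 5), collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
  } else if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must be named or match nrow(counts)")
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("all gene lengths must be positive")
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero))
    stop("sample(s) with zero total expression: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Filter genes on expression level, prevalence and variability
#'
#' Applies, sequentially, the three standard time-course filters: remove
#' lowly expressed genes (mean raw count below `min_mean_count`), genes not
#' expressed in most samples (zero counts in more than `max_zero_fraction`
#' of samples), and genes with little change between samples (coefficient of
#' variation below `min_cv`). A gene survives iff mean count >=
#' `min_mean_count`, zero fraction <= `max_zero_fraction` and CV >= `min_cv`.
#'
#' The CV (sd/mean) is computed on TPM by default, i.e. on the expression
#' unit the downstream clustering uses; set `cv_on = "counts"` to use raw
#' counts instead.
#'
#' @param counts raw count matrix, genes x samples.
#' @param tpm matching TPM matrix (required unless `cv_on = "counts"`).
#' @param min_mean_count minimum mean raw count (default 3).
#' @param max_zero_fraction maximum tolerated fraction of zero counts
#'   (default 0.75).
#' @param min_cv minimum coefficient of variation (default 0.3).
#' @param cv_on `"tpm"` (default) or `"counts"`: unit on which the CV filter
#'   is evaluated.
#' @return an object of class `filter_report`: a list with `n_input`,
#'   `n_low_expression_removed`, `n_mostly_zero_removed`, `n_low_cv_removed`
#'   and `surviving_gene_ids`.
#' @export
filter_genes <- function(counts, tpm = NULL, min_mean_count = 3,
                         max_zero_fraction = 0.75, min_cv = 0.3,
                         cv_on = c("tpm", "counts")) {
  cv_on <- match.arg(cv_on)
  check_expression_matrix(counts, "count matrix")
  if (cv_on == "tpm") {
    if (is.null(tpm)) stop("tpm matrix required when cv_on = \"tpm\"")
    check_expression_matrix(tpm, "TPM matrix")
    if (!identical(dimnames(counts), dimnames(tpm)))
      stop("counts and tpm must share gene and sample ids in the same order")
  }
  n_input <- nrow(counts)

  mean_count <- rowMeans(counts)
  keep1 <- mean_count >= min_mean_count
  n_low <- sum(!keep1)

  zero_frac <- rowMeans(counts[keep1, , drop = FALSE] == 0)
  keep2 <- zero_frac <= max_zero_fraction
  n_zero <- sum(!keep2)

  expr <- if (cv_on == "tpm") tpm else counts
  expr <- expr[rownames(counts)[keep1][keep2], , drop = FALSE]
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, 0)
  keep3 <- cv >= min_cv
  n_cv <- sum(!keep3)

  report <- list(
    n_input = n_input,
    n_low_expression_removed = n_low,
    n_mostly_zero_removed = n_zero,
    n_low_cv_removed = n_cv,
    surviving_gene_ids = rownames(expr)[keep3],
    parameters = list(min_mean_count = min_mean_count,
                      max_zero_fraction = max_zero_fraction,
                      min_cv = min_cv, cv_on = cv_on)
  )
  class(report) <- "filter_report"
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Gene filter report\n")
  cat("  input genes:            ", x$n_input, "\n")
  cat("  low expression removed: ", x$n_low_expression_removed, "\n")
  cat("  mostly zero removed:    ", x$n_mostly_zero_removed, "\n")
  cat("  low CV removed:         ", x$n_low_cv_removed, "\n")
  cat("  surviving genes:        ", length(x$surviving_gene_ids), "\n")
  invisible(x)
}

#' Stand-in differential expression caller (Welch t on log2 TPM)
#'
#' Splits samples into dormant vs non-dormant groups by stage label and
#' tests each gene with a two-sided Welch t-test on log2(TPM + 1), adjusting
#' p-values by Benjamini-Hochberg. This is a deliberately simple stand-in
#' for a count-model DE method; an externally computed DEG table (e.g. from
#' a dedicated DE package) can be supplied to downstream steps instead via
#' [read_deg_table()].
#'
#' @param tpm TPM matrix, genes x samples.
#' @param metadata data frame with `sample_id` and `stage` columns covering
#'   every sample.
#' @param dormant_stages stage labels forming the dormant group (default
#'   endodormancy + dormancy release).
#' @param alpha adjusted-p threshold for the `is_deg` flag (default 0.05).
#' @return data frame with `gene_id`, `log2fc` (dormant minus non-dormant
#'   mean of log2(TPM+1)), `pvalue`, `padj`, `is_deg`.
#' @export
call_degs <- function(tpm, metadata,
                      dormant_stages = c("endodormancy", "dormancy_release"),
                      alpha = 0.05) {
  check_expression_matrix(tpm, "TPM matrix")
  metadata <- check_metadata(metadata, colnames(tpm))
  if (!"stage" %in% names(metadata) || anyNA(metadata$stage))
    stop("every sample needs a stage label to call DEGs")
  dormant <- metadata$stage %in% dormant_stages
  if (sum(dormant) < 2 || sum(!dormant) < 2)
    stop("each group needs at least 2 samples (dormant: ", sum(dormant),
         ", non-dormant: ", sum(!dormant), ")")
  x <- log2(tpm + 1)
  a <- x[, dormant, drop = FALSE]
  b <- x[, !dormant, drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(x)), function(i) {
    va <- stats::var(a[i, ]); vb <- stats::var(b[i, ])
    if (va == 0 && vb == 0) return(if (lfc[i] == 0) 1 else 0)
    stats::t.test(a[i, ], b[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  padj <- bh_adjust(p)
  data.frame(gene_id = rownames(tpm), log2fc = unname(lfc), pvalue = p,
             padj = padj, is_deg = padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
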