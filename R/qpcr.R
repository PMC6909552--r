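#' Fit an RT-qPCR relative standard curve from a dilution series
#'
#' Ordinary least squares of Cq on log10(quantity) over a cDNA dilution
#' series. A valid assay has a negative slope (about -3.32 for perfect
#' doubling chemistry); amplification efficiency is
#' `10^(-1/slope) - 1`.
#'
#' @param quantities dilution quantities (arbitrary units, > 0), at least 3
#'   distinct values.
#' @param cq measured quantification cycles.
#' @return object of class `standard_curve`: `slope`, `intercept` (Cq at
#'   quantity 1), `efficiency`, `r_squared`.
#' @export
fit_standard_curve <- function(quantities, cq) {
  if (length(quantities) != length(cq)) stop("quantities/cq length mismatch")
  if (any(!is.finite(quantities)) || any(quantities <= 0))
    stop("dilution quantities must be positive")
  if (length(unique(quantities)) < 3) stop("need at least 3 distinct dilutions")
  if (any(!is.finite(cq))) stop("Cq values must be finite")
  fit <- stats::lm(cq ~ log10(quantities))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("non-negative standard-curve slope (", signif(slope, 3),
         "): invalid assay")
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1, r_squared = r2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Cq = %.3f %+.3f log10(Q); efficiency %.1f%%, R^2 %.4f\n",
              x$intercept, x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Convert Cq values to relative quantities with a standard curve
#'
#' `quantity = 10^((cq - intercept) / slope)`; monotonically decreasing in
#' Cq for a valid (negative-slope) curve.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param cq numeric Cq values.
#' @return relative quantities (arbitrary units).
#' @export
quantify_cq <- function(curve, cq) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (any(!is.finite(cq))) stop("Cq values must be finite")
  10^((cq - curve$intercept) / curve$slope)
}

#' Normalize gene quantities by the mean of reference genes per sample
#'
#' Divides every gene's quantity in a sample by the average quantity of the
#' reference genes (constitutively expressed controls such as RPII and EF1)
#' in that sample. The arithmetic mean is the default; the geometric mean
#' is available.
#'
#' @param quantities data frame with `sample_id`, `gene_id`, `quantity`
#'   (> 0).
#' @param reference_genes reference gene ids, all quantified in every
#'   sample.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return data frame `sample_id`, `gene_id`, `quantity`,
#'   `normalized_value`, reference genes excluded.
#' @export
normalize_by_reference <- function(quantities, reference_genes,
                                   mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  req <- c("sample_id", "gene_id", "quantity")
  if (!all(req %in% names(quantities)))
    stop("quantities must have columns sample_id, gene_id, quantity")
  if (any(quantities$quantity <= 0)) stop("quantities must be positive")
  samples <- unique(quantities$sample_id)
  ref_mean <- vapply(samples, function(s) {
    q <- quantities$quantity[quantities$sample_id == s &
                               quantities$gene_id %in% reference_genes]
    found <- quantities$gene_id[quantities$sample_id == s &
                                  quantities$gene_id %in% reference_genes]
    miss <- setdiff(reference_genes, found)
    if (length(miss) > 0)
      stop("reference gene(s) ", paste(miss, collapse = ", "),
           " not quantified in sample ", s)
    if (mean_type == "arithmetic") mean(q) else exp(mean(log(q)))
  }, numeric(1))
  out <- quantities[!quantities$gene_id %in% reference_genes, , drop = FALSE]
  out$normalized_value <- out$quantity / ref_mean[match(out$sample_id, samples)]
  rownames(out) <- NULL
  out
}

#' Full RT-qPCR quantification: standard curves, quantities, normalization
#'
#' Averages technical replicate Cq values per (sample, gene), fits a
#' standard curve per gene from its dilution series, converts Cq to
#' relative quantities, and normalizes target genes by the reference genes.
#'
#' @param cq_table data frame `sample_id`, `gene_id`, `cq` (technical
#'   replicates as repeated rows).
#' @param standards data frame `gene_id`, `dilution_quantity`, `cq`.
#' @param reference_genes reference gene ids.
#' @param mean_type reference averaging, `"arithmetic"` or `"geometric"`.
#' @return list: `curves` (per gene), `table` (long data frame with
#'   `normalized_value`), `matrix` (genes x samples of normalized values).
#' @export
qpcr_relative_expression <- function(cq_table, standards, reference_genes,
                                     mean_type = "arithmetic") {
  req <- c("sample_id", "gene_id", "cq")
  if (!all(req %in% names(cq_table)))
    stop("cq_table must have columns sample_id, gene_id, cq")
  agg <- stats::aggregate(cq ~ sample_id + gene_id, data = cq_table, FUN = mean)
  genes <- unique(agg$gene_id)
  curves <- lapply(stats::setNames(genes, genes), function(g) {
    std <- standards[standards$gene_id == g, , drop = FALSE]
    if (nrow(std) == 0) stop("no dilution standards for gene ", g)
    fit_standard_curve(std$dilution_quantity, std$cq)
  })
  agg$quantity <- vapply(seq_len(nrow(agg)), function(i)
    quantify_cq(curves[[agg$gene_id[i]]], agg$cq[i]), numeric(1))
  norm <- normalize_by_reference(agg[, c("sample_id", "gene_id", "quantity")],
                                 reference_genes, mean_type = mean_type)
  target_genes <- setdiff(genes, reference_genes)
  samples <- unique(agg$sample_id)
  mat <- matrix(NA_real_, length(target_genes), length(samples),
                dimnames = list(target_genes, samples))
  for (i in seq_len(nrow(norm)))
    mat[norm$gene_id[i], norm$sample_id[i]] <- norm$normalized_value[i]
  list(curves = curves, table = norm, matrix = mat)
}
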