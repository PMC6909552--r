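# Plain-text readers/writers for the pipeline's tabular formats. All files
# are UTF-8, tab- or comma-separated, '.' decimal, with a header row.

#' Read an expression matrix from TSV (first column `gene_id`)
#'
#' @param path TSV file, columns: `gene_id` then one column per sample.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV (first column `gene_id`)
#'
#' @param x numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene lengths from a two-column TSV (`gene_id`, `length_bp`)
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$length_bp, df$gene_id)
}

#' Write gene lengths to TSV
#' @param lengths named numeric vector.
#' @param path output path.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(data.frame(gene_id = names(lengths),
                                length_bp = unname(lengths)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expected header: `sample_id`, `cultivar`, `tree_replicate` (or `tree`),
#' `date` (ISO 8601), optional `stage`.
#' @param path TSV path.
#' @return data frame with parsed dates.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("tree" %in% names(df) && !"tree_replicate" %in% names(df))
    names(df)[names(df) == "tree"] <- "tree_replicate"
  check_metadata(df)
}

#' Write sample metadata to TSV
#' @param metadata data frame.
#' @param path output path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene/set annotation table (`gene_id`, `set_id`) from TSV
#' @param path TSV path.
#' @return data frame with `gene_id`, `set_id`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "set_id") %in% names(df)))
    stop("annotation TSV needs gene_id and set_id columns")
  df
}

#' Read a DEG table (`gene_id`, `log2fc`, `pvalue`, `padj`, `is_deg`)
#' @param path TSV path.
#' @return data frame.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "padj")
  if (!all(need %in% names(df)))
    stop("DEG TSV needs at least gene_id and padj columns")
  if (!"is_deg" %in% names(df)) df$is_deg <- df$padj < 0.05
  df
}

#' Write a complete synthetic dataset to plain-text files
#'
#' Emits `counts.tsv`, `lengths.tsv`, `metadata.tsv`,
#' `annotations_{tf,motif,go}.tsv`, `qpcr_cq.csv`, `standards.csv`,
#' `qpcr_metadata.tsv`, `budbreak.csv` and `truth.json` into a directory.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "bud_simulation")) stop("sim must be a bud_simulation")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_gene_lengths(sim$gene_lengths, file.path(dir, "lengths.tsv"))
  write_metadata_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  for (kind in c("tf", "motif", "go"))
    utils::write.table(sim$annotations[[kind]],
                       file.path(dir, sprintf("annotations_%s.tsv", kind)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$qpcr$cq_table, file.path(dir, "qpcr_cq.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$qpcr$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE, quote = FALSE)
  write_metadata_tsv(sim$qpcr$metadata, file.path(dir, "qpcr_metadata.tsv"))
  utils::write.csv(sim$budbreak, file.path(dir, "budbreak.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    gene_cluster = as.list(sim$truth$gene_cluster),
    markers = sim$truth$markers,
    stage = as.list(sim$truth$stage),
    release_dates = as.list(format(sim$truth$release_dates)),
    planted_enrichment = sim$annotations$planted)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a forcing-test bud-break series from CSV
#'
#' Expected header: `cultivar`, `date`, `percent_bbch53`.
#' @param path CSV path.
#' @return data frame with parsed dates.
#' @export
read_budbreak_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "date", "percent_bbch53")
  if (!all(need %in% names(df)))
    stop("bud-break CSV needs columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}
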