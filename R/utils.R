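#' Coerce stage labels to an ordered factor
#'
#' @param x character or factor of stage labels.
#' @return factor with levels [STAGE_LEVELS].
#' @export
stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), STAGE_LEVELS)
  if (length(bad) > 0)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = STAGE_LEVELS)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the pair-counting contingency table. 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Shared matrix checks: finite, unique dimnames, optionally non-negative.
check_expression_matrix <- function(x, what = "expression matrix",
                                    nonneg = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (nrow(x) == 0 || ncol(x) == 0) stop(what, " is empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stop(what, " has duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop(what, " has duplicate sample ids")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  if (nonneg && any(x < 0)) stop(what, " contains negative values")
  invisible(x)
}

check_metadata <- function(metadata, sample_ids = NULL) {
  req <- c("sample_id", "cultivar", "date")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("metadata has duplicate sample ids")
  metadata$date <- as.Date(metadata$date)
  if (anyNA(metadata$date)) stop("metadata dates must parse as ISO 8601")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, metadata$sample_id)
    if (length(miss) > 0)
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  }
  if ("stage" %in% names(metadata)) {
    present <- !is.na(metadata$stage) & metadata$stage != ""
    metadata$stage[!present] <- NA
    metadata$stage <- as.character(metadata$stage)
    bad <- setdiff(unique(metadata$stage[present]), STAGE_LEVELS)
    if (length(bad) > 0)
      stop("unknown stage label(s) in metadata: ", paste(bad, collapse = ", "))
  }
  metadata
}
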