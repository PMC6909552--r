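#' Normalize a marker panel by each cultivar's October reference sample
#'
#' Divides every expression value by the mean expression of the same gene in
#' the reference-date samples (replicates averaged) of the same cultivar.
#' October marks the beginning of endodormancy and is sampled in every
#' cultivar, which makes it a natural common reference; reference samples map
#' to 1 for every gene, and the resulting ratios are unit-free, so RNA-seq
#' TPM and RT-qPCR relative quantities become directly comparable.
#'
#' @param expr numeric matrix, marker genes x samples (TPM or relative
#'   qPCR quantities).
#' @param metadata sample metadata covering `colnames(expr)`.
#' @param reference_date a `Date` (or string) naming the reference sampling
#'   date, or a vector named by cultivar when reference dates differ.
#' @param log2 return log2 ratios instead of plain ratios (default FALSE).
#' @return matrix of the same shape, ratios to the cultivar reference.
#' @export
october_normalize <- function(expr, metadata, reference_date, log2 = FALSE) {
  check_expression_matrix(expr, "panel matrix")
  metadata <- check_metadata(metadata, colnames(expr))
  out <- expr
  for (cv in unique(metadata$cultivar)) {
    ref_date <- if (!is.null(names(reference_date))) {
      if (!cv %in% names(reference_date))
        stop("no reference date for cultivar ", cv)
      as.Date(reference_date[[cv]])
    } else as.Date(reference_date)
    cv_samples <- metadata$sample_id[metadata$cultivar == cv]
    ref_samples <- metadata$sample_id[metadata$cultivar == cv &
                                        metadata$date == ref_date]
    if (length(ref_samples) == 0)
      stop("cultivar ", cv, " has no sample at reference date ", ref_date)
    ref <- rowMeans(expr[, ref_samples, drop = FALSE])
    bad <- ref <= 0
    if (any(bad))
      stop("zero reference expression for gene ",
           rownames(expr)[which(bad)[1]], " in cultivar ", cv)
    out[, cv_samples] <- expr[, cv_samples, drop = FALSE] / ref
  }
  if (log2) base::log2(out) else out
}

#' Fit a two-component PCA of samples in marker space
#'
#' Mean-centers the columns (no scaling) and takes the top two right
#' singular vectors. Sign convention: within each component the loading
#' entry of largest magnitude is made positive, so the decomposition is
#' deterministic.
#'
#' @param X numeric matrix, samples x features (markers).
#' @return object of class `stage_pca`: `feature_ids`, `center`, `loadings`
#'   (features x 2, orthonormal), `explained_variance_fraction`, `scores`
#'   (training scores, samples x 2).
#' @export
fit_pca <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (ncol(X) < 2) stop("need at least 2 features")
  if (!all(is.finite(X))) stop("X contains non-finite values")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  if (max(sv$d) <= 0)
    stop("centered data has rank 0 (all samples identical); PCA undefined")
  # rank-1 data (samples on a line) is allowed: the second component spans
  # the null space with zero explained variance
  loadings <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- c("PC1", "PC2")
  scores <- Xc %*% loadings
  explained <- (sv$d^2 / sum(sv$d^2))[1:2]
  structure(list(feature_ids = colnames(X), center = center,
                 loadings = loadings,
                 explained_variance_fraction = explained,
                 scores = scores),
            class = "stage_pca")
}

#' Project samples onto a fitted PCA plane
#'
#' @param pca a `stage_pca` from [fit_pca()].
#' @param X samples x features matrix whose columns include
#'   `pca$feature_ids`.
#' @return samples x 2 score matrix.
#' @export
project_pca <- function(pca, X) {
  if (!inherits(pca, "stage_pca")) stop("pca must be a stage_pca")
  miss <- setdiff(pca$feature_ids, colnames(X))
  if (length(miss) > 0)
    stop("missing marker feature(s): ", paste(miss, collapse = ", "))
  X <- X[, pca$feature_ids, drop = FALSE]
  if (!all(is.finite(X))) stop("X contains non-finite values")
  sweep(X, 2, pca$center) %*% pca$loadings
}

# --- penalized multinomial logistic regression (softmax), Newton solver ---

softmax_rows <- function(eta) {
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  e / rowSums(e)
}

# Objective: sum NLL + lambda/2 * ||B||_F^2 over all entries (incl. intercept).
multinom_nll <- function(B, X, Y, lambda) {
  eta <- X %*% B
  m <- apply(eta, 1, max)
  lse <- m + log(rowSums(exp(eta - m)))
  -sum(rowSums(Y * eta) - lse) + lambda / 2 * sum(B^2)
}

multinom_grad <- function(B, X, Y, lambda) {
  P <- softmax_rows(X %*% B)
  t(X) %*% (P - Y) + lambda * B
}

# Damped Newton on the vectorized coefficient matrix. The penalized NLL is
# strictly convex (lambda > 0), so this converges to the unique optimum.
fit_softmax_newton <- function(X, Y, lambda, tol = 1e-8, max_iter = 200) {
  p <- ncol(X); C <- ncol(Y)
  B <- matrix(0, p, C)
  for (iter in seq_len(max_iter)) {
    P <- softmax_rows(X %*% B)
    G <- t(X) %*% (P - Y) + lambda * B
    if (sqrt(sum(G^2)) < tol) break
    # Hessian of the vectorized problem: blocks H[(a,b)] = X' W_ab X,
    # W_ab = diag(p_a (1{a=b} - p_b)); plus lambda I.
    H <- matrix(0, p * C, p * C)
    for (a in seq_len(C)) for (b in seq_len(C)) {
      w <- P[, a] * ((a == b) - P[, b])
      H[((a - 1) * p + 1):(a * p), ((b - 1) * p + 1):(b * p)] <-
        t(X * w) %*% X
    }
    diag(H) <- diag(H) + lambda
    step <- tryCatch(solve(H, as.vector(G)),
                     error = function(e) as.vector(G) / max(diag(H)))
    f0 <- multinom_nll(B, X, Y, lambda)
    t_step <- 1
    repeat {
      B_new <- B - t_step * matrix(step, p, C)
      if (multinom_nll(B_new, X, Y, lambda) <= f0 || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    B <- B - t_step * matrix(step, p, C)
  }
  B
}

# Deterministic stratified fold ids: round-robin within class, input order.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- ((seq_along(idx) - 1) %% n_folds) + 1
  }
  fold
}

#' Fit the five-stage multinomial logistic regression on PCA scores
#'
#' Softmax regression of stage on the two PCA coordinates plus an intercept,
#' minimizing the L2-penalized multinomial negative log-likelihood with a
#' damped Newton solver (gradient-norm tolerance `tol`). The ridge penalty
#' applies to all coefficients, which keeps the full class parameterization
#' strictly convex. The penalty is chosen from `reg_grid` by stratified
#' `n_folds`-fold cross-validated accuracy; ties go to the stronger
#' regularization.
#'
#' @param scores samples x 2 matrix of PCA coordinates.
#' @param labels stage labels (character or factor), one per sample.
#' @param n_folds CV folds (default 5); shrunk with a warning when the
#'   rarest class has fewer members.
#' @param reg_grid candidate penalty strengths (default 10 log-spaced values
#'   spanning 1e-4 to 1e4).
#' @param tol Newton gradient-norm tolerance (default 1e-8).
#' @param classes class levels; defaults to the stage order in
#'   [STAGE_LEVELS] restricted to labels present.
#' @return object of class `stage_model`: `classes`, `coefficients`
#'   ((intercept + 2 coords) x classes), `lambda`, `cv_accuracy`,
#'   `n_samples`, `n_folds`, and a `pca` slot (NULL here; filled by
#'   [train_stage_model()]).
#' @export
fit_multinomial_lr <- function(scores, labels, n_folds = 5,
                               reg_grid = 10^seq(-4, 4, length.out = 10),
                               tol = 1e-8, classes = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels)) stop("scores/labels length mismatch")
  if (is.null(classes)) {
    classes <- if (all(labels %in% STAGE_LEVELS))
      STAGE_LEVELS[STAGE_LEVELS %in% labels] else sort(unique(labels))
  }
  if (length(unique(labels)) < 2) stop("need at least 2 classes to fit")
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning("rarest class has ", min_class, " samples; reducing CV folds")
    n_folds <- max(2, min_class)
  }
  X <- cbind(`(Intercept)` = 1, scores)
  Y <- outer(labels, classes, "==") * 1
  fold <- stratified_folds(labels, n_folds)
  cv_acc <- vapply(reg_grid, function(lambda) {
    correct <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < length(classes)) next
      B <- fit_softmax_newton(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                              lambda, tol = tol)
      pred <- classes[max.col(X[!tr, , drop = FALSE] %*% B,
                              ties.method = "first")]
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / length(labels)
  }, numeric(1))
  best <- max(cv_acc)
  lambda <- max(reg_grid[cv_acc >= best - 1e-12])   # ties -> stronger penalty
  B <- fit_softmax_newton(X, Y, lambda, tol = tol)
  dimnames(B) <- list(c("(Intercept)", "PC1", "PC2"), classes)
  structure(list(classes = classes, coefficients = B, lambda = lambda,
                 cv_accuracy = stats::setNames(cv_acc, signif(reg_grid, 3)),
                 n_samples = nrow(scores), n_folds = n_folds, pca = NULL),
            class = "stage_model")
}

#' Predict bud stages from PCA scores
#'
#' Softmax probabilities and argmax class; exact probability ties resolve to
#' the earlier class in developmental order.
#'
#' @param model a `stage_model`.
#' @param scores samples x 2 matrix of PCA coordinates.
#' @return list with `labels` (factor in class order) and `probabilities`
#'   (samples x classes, rows summing to 1).
#' @export
predict_stage <- function(model, scores) {
  if (!inherits(model, "stage_model")) stop("model must be a stage_model")
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores contain non-finite values")
  X <- cbind(1, scores)
  P <- softmax_rows(X %*% model$coefficients)
  colnames(P) <- model$classes
  idx <- max.col(P, ties.method = "first")
  list(labels = factor(model$classes[idx], levels = model$classes),
       probabilities = P)
}

#' Class-support-weighted F1 score
#'
#' Per-class F1 = 2PR/(P+R) (0 where precision + recall = 0), averaged with
#' weights proportional to each class's support in `y_true`.
#'
#' @param y_true,y_pred label vectors of equal positive length.
#' @return numeric scalar in \[0, 1\].
#' @export
weighted_f1 <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  f1 <- vapply(unique(y_true), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    prec_den <- sum(y_pred == cl)
    rec_den <- sum(y_true == cl)
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- tp / rec_den
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- table(y_true)[unique(y_true)]
  sum(f1 * as.numeric(support)) / length(y_true)
}

#' Repeated stratified train/test evaluation of the stage classifier
#'
#' For each split: a stratified random train/test partition, a full
#' [fit_multinomial_lr()] (with its internal CV) on the training part, and
#' the weighted F1 on the held-out part. Splits leaving a class absent from
#' the training set are redrawn (and counted).
#'
#' @param scores samples x 2 PCA score matrix.
#' @param labels stage labels.
#' @param n_splits number of train/test combinations (default 500).
#' @param test_fraction held-out fraction per class (default 0.3).
#' @param seed RNG seed for reproducibility.
#' @param ... passed to [fit_multinomial_lr()].
#' @return object of class `evaluation_report`: `f1` (per split), `mean`,
#'   `sd`, `n_splits`, `n_resampled`, `confusion` (aggregated).
#' @export
evaluate_splits <- function(scores, labels, n_splits = 500,
                            test_fraction = 0.3, seed = 1, ...) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- if (all(labels %in% STAGE_LEVELS))
    STAGE_LEVELS[STAGE_LEVELS %in% labels] else sort(unique(labels))
  set.seed(seed)
  f1 <- numeric(n_splits)
  n_resampled <- 0L
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (s in seq_len(n_splits)) {
    repeat {
      test_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        n_test <- max(1, round(length(idx) * test_fraction))
        if (n_test >= length(idx)) n_test <- length(idx) - 1
        sample(idx, n_test)
      }))
      train_idx <- setdiff(seq_along(labels), test_idx)
      if (length(unique(labels[train_idx])) == length(classes)) break
      n_resampled <- n_resampled + 1L
    }
    model <- fit_multinomial_lr(scores[train_idx, , drop = FALSE],
                                labels[train_idx], classes = classes, ...)
    pred <- predict_stage(model, scores[test_idx, , drop = FALSE])$labels
    f1[s] <- weighted_f1(labels[test_idx], pred)
    confusion <- confusion + table(factor(labels[test_idx], levels = classes),
                                   factor(pred, levels = classes))
  }
  structure(list(f1 = f1, mean = mean(f1), sd = stats::sd(f1),
                 n_splits = n_splits, n_resampled = n_resampled,
                 confusion = confusion),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Stage model evaluation over %d splits: mean weighted F1 = %.4f (sd %.4f)\n",
              x$n_splits, x$mean, x$sd))
  invisible(x)
}

#' Train the full bud-stage classifier from a marker-panel expression matrix
#'
#' October-normalizes the marker panel per cultivar, fits the 2-D PCA of
#' samples in marker space, and fits the cross-validated multinomial
#' logistic regression of stage on the two coordinates. The returned model
#' carries the PCA, so qPCR-platform data can be projected into the same
#' plane by [crossplatform_predict()].
#'
#' @param expr marker genes x samples expression matrix (TPM).
#' @param metadata sample metadata with stages for every sample.
#' @param markers marker gene ids (rows of `expr` to use).
#' @param reference_date October reference date passed to
#'   [october_normalize()].
#' @param log2 use log2 ratios (default FALSE).
#' @param ... passed to [fit_multinomial_lr()].
#' @return a `stage_model` with `pca`, `reference_date`, `log2`,
#'   `training_scores` and `training_labels` filled in.
#' @export
train_stage_model <- function(expr, metadata, markers, reference_date,
                              log2 = FALSE, ...) {
  metadata <- check_metadata(metadata, colnames(expr))
  if (!"stage" %in% names(metadata) || anyNA(metadata$stage))
    stop("every training sample needs a stage label")
  miss <- setdiff(markers, rownames(expr))
  if (length(miss) > 0)
    stop("missing marker(s) in expression matrix: ",
         paste(miss, collapse = ", "))
  panel <- expr[markers, , drop = FALSE]
  norm <- october_normalize(panel, metadata, reference_date, log2 = log2)
  pca <- fit_pca(t(norm))
  scores <- pca$scores
  model <- fit_multinomial_lr(scores, metadata$stage, ...)
  model$pca <- pca
  model$reference_date <- reference_date
  model$log2 <- log2
  model$training_scores <- scores
  model$training_labels <- metadata$stage
  model
}

#' @export
print.stage_model <- function(x, ...) {
  cat("Multinomial bud-stage model (", length(x$classes), " classes, lambda = ",
      signif(x$lambda, 3), ")\n", sep = "")
  print(signif(x$coefficients, 3))
  invisible(x)
}

#' Predict bud stages for qPCR-platform samples with an RNA-seq model
#'
#' October-normalizes the qPCR relative expression of the marker genes with
#' the qPCR cultivar's own reference sample, projects the samples into the
#' PCA plane fitted on RNA-seq data, and applies the multinomial model.
#' Also reports, per cultivar, the fraction of chronologically consecutive
#' sample pairs whose predicted stage is non-decreasing in developmental
#' order (a chronology-consistency check).
#'
#' @param model a `stage_model` from [train_stage_model()].
#' @param rel_expr marker genes x samples matrix of reference-normalized
#'   qPCR quantities (see [qpcr_relative_expression()]).
#' @param metadata metadata for the qPCR samples.
#' @param reference_date reference date for the qPCR cultivar(s); defaults
#'   to the model's training reference date.
#' @return list: `labels`, `probabilities`, `scores`,
#'   `chronology_consistency` (fraction in \[0, 1\]).
#' @export
crossplatform_predict <- function(model, rel_expr, metadata,
                                  reference_date = NULL) {
  if (!inherits(model, "stage_model") || is.null(model$pca))
    stop("model must be a trained stage_model carrying its PCA")
  metadata <- check_metadata(metadata, colnames(rel_expr))
  miss <- setdiff(model$pca$feature_ids, rownames(rel_expr))
  if (length(miss) > 0)
    stop("qPCR data lack marker gene(s): ", paste(miss, collapse = ", "))
  if (is.null(reference_date)) reference_date <- model$reference_date
  norm <- october_normalize(rel_expr[model$pca$feature_ids, , drop = FALSE],
                            metadata, reference_date,
                            log2 = isTRUE(model$log2))
  scores <- project_pca(model$pca, t(norm))
  pred <- predict_stage(model, scores)
  stage_idx <- match(as.character(pred$labels), STAGE_LEVELS)
  consistent <- 0L; pairs <- 0L
  for (cv in unique(metadata$cultivar)) {
    idx <- which(metadata$cultivar == cv)
    idx <- idx[order(metadata$date[idx])]
    if (length(idx) < 2) next
    steps <- diff(stage_idx[idx])
    consistent <- consistent + sum(steps >= 0)
    pairs <- pairs + length(steps)
  }
  list(labels = pred$labels, probabilities = pred$probabilities,
       scores = scores,
       chronology_consistency = if (pairs > 0) consistent / pairs else NA_real_)
}

#' Serialize a stage model to JSON
#'
#' Writes feature ids, centering vector, loadings, classes, coefficients
#' and regularization so a model can be stored and reloaded losslessly.
#'
#' @param model a `stage_model` with its PCA.
#' @param path output file path.
#' @export
write_stage_model <- function(model, path) {
  coef_list <- lapply(model$classes, function(cl)
    as.list(stats::setNames(model$coefficients[, cl],
                            rownames(model$coefficients))))
  names(coef_list) <- model$classes
  obj <- list(classes = model$classes,
              coefficients = coef_list,
              lambda = model$lambda,
              reference_date = as.character(model$reference_date),
              log2 = isTRUE(model$log2),
              pca = list(feature_ids = model$pca$feature_ids,
                         center = model$pca$center,
                         loadings = model$pca$loadings,
                         explained_variance_fraction =
                           model$pca$explained_variance_fraction))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a stage model written by [write_stage_model()]
#'
#' @param path JSON file path.
#' @return a `stage_model`.
#' @export
read_stage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- sapply(obj$classes, function(cl) unlist(obj$coefficients[[cl]]))
  rownames(B) <- c("(Intercept)", "PC1", "PC2")
  loadings <- as.matrix(obj$pca$loadings)
  center <- unlist(obj$pca$center)
  names(center) <- obj$pca$feature_ids
  dimnames(loadings) <- list(obj$pca$feature_ids, c("PC1", "PC2"))
  pca <- structure(list(feature_ids = obj$pca$feature_ids, center = center,
                        loadings = loadings,
                        explained_variance_fraction =
                          unlist(obj$pca$explained_variance_fraction),
                        scores = NULL),
                   class = "stage_pca")
  rd <- obj$reference_date
  rd_dates <- as.Date(unlist(rd))
  if (!is.null(names(rd))) names(rd_dates) <- names(rd)
  structure(list(classes = obj$classes, coefficients = B,
                 lambda = obj$lambda, pca = pca,
                 reference_date = rd_dates,
                 log2 = isTRUE(obj$log2)),
            class = "stage_model")
}
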