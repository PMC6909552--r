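test_that("October normalization maps references to 1 and scales linearly", {
  md <- simple_metadata(paste0("s", 1:3),
                        c("2015-10-10", "2015-12-01", "2016-02-01"))
  expr <- rbind(g1 = c(4, 10, 6), g2 = c(2, 2, 8))
  colnames(expr) <- md$sample_id
  norm <- october_normalize(expr, md, as.Date("2015-10-10"))
  expect_equal(unname(norm[, "s1"]), c(1, 1))
  expect_equal(norm["g1", "s2"], 2.5)
  doubled <- expr; doubled[, "s2"] <- 2 * doubled[, "s2"]
  norm2 <- october_normalize(doubled, md, as.Date("2015-10-10"))
  expect_equal(norm2[, "s2"], 2 * norm[, "s2"])

  zero <- expr; zero["g2", "s1"] <- 0
  expect_error(october_normalize(zero, md, as.Date("2015-10-10")), "g2")
  expect_error(october_normalize(expr, md, as.Date("2015-10-11")),
               "no sample at reference date")
})

test_that("October normalization uses each cultivar's own reference", {
  md <- rbind(simple_metadata(c("a1", "a2"), c("2015-10-10", "2015-12-01"),
                              cultivar = "A"),
              simple_metadata(c("b1", "b2"), c("2015-10-25", "2015-12-01"),
                              cultivar = "B"))
  expr <- matrix(c(2, 8, 5, 10), 1, 4,
                 dimnames = list("g", c("a1", "a2", "b1", "b2")))
  norm <- october_normalize(expr, md,
                            c(A = "2015-10-10", B = "2015-10-25"))
  expect_equal(unname(norm[1, ]), c(1, 4, 1, 2))
})

test_that("fit_pca matches prcomp up to the sign convention", {
  set.seed(8)
  X <- matrix(stats::rnorm(60), 12, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  pca <- fit_pca(X)
  ref <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    s <- sign(sum(pca$loadings[, j] * ref$rotation[, j]))
    expect_equal(pca$loadings[, j], s * ref$rotation[, j],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(pca$scores[, j], s * ref$x[, j], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(pca$explained_variance_fraction,
               (ref$sdev^2 / sum(ref$sdev^2))[1:2], tolerance = 1e-9)
  # orthonormal loadings, deterministic sign
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:2)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("PCA degenerate and structured inputs behave as specified", {
  line <- cbind(m1 = 1:10, m2 = 2 * (1:10) + 3)
  pca <- fit_pca(line + 0)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-9)
  expect_error(fit_pca(cbind(m1 = rep(1, 5), m2 = rep(2, 5))), "rank")

  X <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  pca2 <- fit_pca(X)
  expect_equal(as.numeric(project_pca(pca2, rbind(pca2$center))), c(0, 0),
               tolerance = 1e-9)
  expect_equal(project_pca(pca2, X), pca2$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(project_pca(pca2, X[, 1:2]), "missing marker")
})

test_that("multinomial fit separates a separable toy problem", {
  set.seed(3)
  scores <- rbind(cbind(stats::rnorm(20, -3, 0.2), stats::rnorm(20, 0, 0.2)),
                  cbind(stats::rnorm(20, 3, 0.2), stats::rnorm(20, 0, 0.2)))
  labels <- rep(c("endodormancy", "ecodormancy"), each = 20)
  m <- fit_multinomial_lr(scores, labels)
  pred <- predict_stage(m, scores)
  expect_equal(mean(as.character(pred$labels) == labels), 1)
  expect_equal(rowSums(pred$probabilities), rep(1, 40), tolerance = 1e-9)
})

test_that("label-permuted data yield chance-level CV accuracy", {
  set.seed(14)
  scores <- matrix(stats::rnorm(120), 60, 2)
  labels <- sample(rep(c("organogenesis", "endodormancy", "ecodormancy"), 20))
  m <- fit_multinomial_lr(scores, labels)
  expect_lt(abs(max(m$cv_accuracy) - 1 / 3), 0.15)
})

test_that("the fitted optimum beats random coefficients and has tiny gradient", {
  set.seed(4)
  toy <- staged_scores(8, sd = 0.5)
  m <- fit_multinomial_lr(toy$scores, toy$labels)
  X <- cbind(1, toy$scores)
  Y <- outer(toy$labels, m$classes, "==") * 1
  g <- budphase:::multinom_grad(m$coefficients, X, Y, m$lambda)
  expect_lt(sqrt(sum(g^2)), 1e-6)
  f_opt <- budphase:::multinom_nll(m$coefficients, X, Y, m$lambda)
  for (i in 1:100) {
    B <- matrix(stats::rnorm(length(m$coefficients), 0, 2),
                nrow(m$coefficients))
    expect_gte(budphase:::multinom_nll(B, X, Y, m$lambda), f_opt)
  }
})

test_that("prediction breaks exact ties by developmental order", {
  m <- structure(list(classes = c("organogenesis", "ecodormancy"),
                      coefficients = matrix(0, 3, 2),
                      lambda = 1, pca = NULL), class = "stage_model")
  pred <- predict_stage(m, matrix(c(0.3, -0.2), 1, 2))
  expect_equal(as.character(pred$labels), "organogenesis")
  expect_equal(unname(pred$probabilities[1, ]), c(0.5, 0.5))
  expect_error(predict_stage(m, matrix(c(NA, 1), 1, 2)), "non-finite")
})

test_that("weighted F1 reproduces hand values and equals accuracy when balanced", {
  expect_equal(weighted_f1(c("A", "B"), c("A", "B")), 1)
  expect_equal(weighted_f1(c("A", "A", "B"), c("A", "B", "B")), 2 / 3,
               tolerance = 1e-12)
  expect_equal(weighted_f1(c("A", "B"), c("B", "A")), 0)
  expect_error(weighted_f1(character(0), character(0)), "empty")
  # balanced classes with symmetric cross-flips: weighted F1 equals accuracy
  y <- rep(c("A", "B"), each = 20)
  p <- y; p[3] <- "B"; p[25] <- "A"
  expect_equal(weighted_f1(y, p), mean(y == p), tolerance = 1e-12)
})

test_that("repeated splits are reproducible and detect shuffled labels", {
  toy <- staged_scores(10, sd = 0.15)
  r1 <- evaluate_splits(toy$scores, toy$labels, n_splits = 8, seed = 42)
  r2 <- evaluate_splits(toy$scores, toy$labels, n_splits = 8, seed = 42)
  expect_identical(r1$f1, r2$f1)
  expect_equal(r1$mean, 1, tolerance = 1e-12)

  set.seed(13)
  shuffled <- sample(toy$labels)
  r3 <- evaluate_splits(toy$scores, shuffled, n_splits = 8, seed = 42)
  expect_lt(r3$mean, 0.45)
})

test_that("stage models serialize to JSON and reload losslessly", {
  toy <- staged_scores(6, sd = 0.2)
  X <- cbind(toy$scores, toy$scores[, 1] - toy$scores[, 2],
             toy$scores[, 1] * 0.5)
  colnames(X) <- paste0("m", 1:4)
  md <- simple_metadata(sprintf("s%02d", seq_len(nrow(X))),
                        rep("2015-10-10", nrow(X)), stage = toy$labels)
  expr <- t(X) + 10
  colnames(expr) <- md$sample_id
  model <- train_stage_model(expr, md, paste0("m", 1:4),
                             reference_date = as.Date("2015-10-10"))
  path <- tempfile(fileext = ".json")
  write_stage_model(model, path)
  back <- read_stage_model(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(back$pca$loadings, model$pca$loadings, tolerance = 1e-12)
  expect_equal(back$pca$center, model$pca$center, tolerance = 1e-12)
  newX <- matrix(stats::rnorm(8), 2, 4, dimnames = list(NULL, paste0("m", 1:4)))
  expect_equal(predict_stage(back, project_pca(back$pca, newX))$probabilities,
               predict_stage(model, project_pca(model$pca, newX))$probabilities,
               tolerance = 1e-9)
})
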