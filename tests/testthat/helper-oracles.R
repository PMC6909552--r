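# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Two-pass Pearson correlation between two vectors (textbook formula).
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive-enumeration hypergeometric upper tail: probability that a
# uniformly random n-subset of 1..N contains at least k of the K annotated
# elements, by enumerating all C(N, n) subsets.
oracle_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)   # annotated elements are 1..K
  mean(hits >= k)
}

# Naive O(n^3) agglomerative clustering on a distance matrix, cut at k.
oracle_agglomerate <- function(D, k, linkage = "complete") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  link_fun <- switch(linkage, complete = max, average = mean)
  while (length(clusters) > k) {
    best_d <- Inf; best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- link_fun(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Random expression-like matrix with dimnames.
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, 3, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Small metadata frame: one cultivar, one sample per date.
simple_metadata <- function(sample_ids, dates, cultivar = "cv1",
                            stage = NULL) {
  md <- data.frame(sample_id = sample_ids, cultivar = cultivar,
                   tree_replicate = "T1", date = as.Date(dates),
                   stringsAsFactors = FALSE)
  if (!is.null(stage)) md$stage <- stage
  md
}

# Well-separated 2-D scores for 5 stages (Gaussian blobs on a ring).
staged_scores <- function(n_per_class = 12, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- cbind(cos(seq(0, 4, length.out = 5)),
                   sin(seq(0, 4, length.out = 5))) * 3
  scores <- do.call(rbind, lapply(1:5, function(i)
    cbind(stats::rnorm(n_per_class, centers[i, 1], sd),
          stats::rnorm(n_per_class, centers[i, 2], sd))))
  list(scores = scores, labels = rep(STAGE_LEVELS, each = n_per_class))
}
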