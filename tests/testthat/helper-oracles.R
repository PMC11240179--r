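# Independent brute-force oracles used to validate the fast implementations.
# These deliberately avoid the package's own search code: plain R distance
# enumeration and sorting.

# Exhaustive kNN: squared Euclidean, ties broken towards the lower train
# index, query never its own neighbour.
knn_oracle <- function(X, train_idx, query_idx, k) {
  out <- matrix(0L, length(query_idx), k)
  for (qi in seq_along(query_idx)) {
    q <- query_idx[qi]
    d2 <- colSums((t(X[train_idx, , drop = FALSE]) - X[q, ])^2)
    d2[train_idx == q] <- Inf
    out[qi, ] <- train_idx[order(d2, train_idx)][seq_len(k)]
  }
  out
}

# Majority vote with the documented tie-break (nearest neighbour's label
# among the tied labels).
majority_oracle <- function(nb_labels) {
  counts <- table(nb_labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) top else nb_labels[nb_labels %in% top][1]
}

# Per-entry evaluation of the log-scaled TF-IDF formula on a dense count
# matrix, followed by row l2 normalization.
tfidf_oracle <- function(C) {
  n <- nrow(C)
  X <- matrix(0, n, ncol(C))
  df <- colSums(C > 0)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(C))) {
      if (C[i, j] > 0) {
        X[i, j] <- (1 + log(C[i, j])) * (1 + log((1 + n) / (1 + df[j])))
      }
    }
  }
  for (i in seq_len(n)) {
    nrm <- sqrt(sum(X[i, ]^2))
    if (nrm > 0) X[i, ] <- X[i, ] / nrm
  }
  X
}

# 99% binomial bound for an empirical proportion, inflated slightly because
# kNN-based test points share training neighbours (positive correlation).
binom99_tol <- function(p, m, inflate = 1.3) {
  2.576 * sqrt(p * (1 - p) / m) * inflate
}

# Labelled Gaussian mixture via the package generator, unpacked to plain
# matrix + labels for test convenience.
make_mixture <- function(n, n_topics, sep, dim, seed) {
  topics <- lapply(seq_len(n_topics), function(i) {
    synthetic_topic(sprintf("t%02d", i), vocabulary = "word")
  })
  cfg <- synthetic_config(n, topics = topics, cluster_separation = sep,
                          dim = dim, seed = seed)
  mix <- generate_vector_mixture(cfg)
  list(X = as.matrix(mix$vectors$X), labels = mix$labels,
       vectors = mix$vectors)
}
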