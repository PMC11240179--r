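test_that("exact kNN graph equals the exhaustive distance-sort oracle", {
  set.seed(41)
  X <- matrix(rnorm(50 * 5), 50, 5)
  g <- build_knn_graph(X, 7)
  expect_equal(g, knn_oracle(X, 1:50, 1:50, 7), ignore_attr = TRUE)
  # no point is its own neighbour
  expect_false(any(g == row(g)))
  expect_error(build_knn_graph(X, 50), "smaller")
})

test_that("cosine mode orders neighbours by angle", {
  set.seed(42)
  X <- matrix(rnorm(30 * 4), 30, 4)
  g <- build_knn_graph(X, 5, metric = "cosine")
  Xn <- X / sqrt(rowSums(X^2))
  expect_equal(g, knn_oracle(Xn, 1:30, 1:30, 5), ignore_attr = TRUE)
})

test_that("approximate kNN reaches 95% recall against exact search", {
  mix <- make_mixture(2000, 5, sep = 4, dim = 20, seed = 43)
  exact <- build_knn_graph(mix$X, 10)
  approx <- build_knn_graph(mix$X, 10, mode = "approximate", seed = 2)
  recall <- mean(vapply(seq_len(nrow(exact)), function(i)
    length(intersect(exact[i, ], approx[i, ])) / 10, numeric(1)))
  expect_gte(recall, 0.95)
})

test_that("uniform affinities satisfy the graph invariants", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(80 * 6), 80, 6)
    A <- uniform_affinities(build_knn_graph(X, 10))
    P <- A$P
    expect_lt(abs(sum(P) - 1), 1e-12)
    expect_lt(max(abs(P - Matrix::t(P))), 1e-15)
    expect_equal(sum(Matrix::diag(P)), 0)
    # each row keeps its own k neighbours plus any reverse neighbours, so
    # the support is at least k per row and at most 2nk overall (hub points
    # can exceed 2k individually)
    nnz_per_row <- Matrix::rowSums(P != 0)
    expect_true(all(nnz_per_row >= 10))
    expect_lte(sum(nnz_per_row), 2 * 80 * 10)
    expect_true(all(P@x >= 0))
  }
})

test_that("affinities match hand enumeration on collinear points", {
  # points at 0, 1, 3 on a line with k = 1: kNN(1)={2}, kNN(2)={1},
  # kNN(3)={2}; p12 = (1+1)/(2n) = 1/3, p23 = (0+1)/(2n) = 1/6
  X <- matrix(c(0, 1, 3), ncol = 1)
  A <- uniform_affinities(build_knn_graph(X, 1))
  P <- as.matrix(A$P)
  expect_equal(P[1, 2], 1 / 3)
  expect_equal(P[2, 1], 1 / 3)
  expect_equal(P[2, 3], 1 / 6)
  expect_equal(P[3, 2], 1 / 6)
  expect_equal(P[1, 3], 0)
  expect_equal(sum(P), 1)
})

test_that("mutual neighbour pairs get (1/k + 1/k) / (2n)", {
  # two close points plus a far cluster: the pair are mutual neighbours
  set.seed(44)
  far <- matrix(rnorm(16 * 2), 16, 2) + 100
  X <- rbind(c(0, 0), c(0.1, 0), far)
  k <- 3
  A <- uniform_affinities(build_knn_graph(X, k))
  n <- nrow(X)
  expect_equal(as.matrix(A$P)[1, 2], (1 / k + 1 / k) / (2 * n))
})

test_that("t-SNE is deterministic and recovers cluster structure", {
  mix <- make_mixture(600, 3, sep = 8, dim = 20, seed = 45)
  P <- uniform_affinities(build_knn_graph(mix$X, 10))
  emb1 <- tsne_embed(P, mix$X, repulsion = "exact")
  emb2 <- tsne_embed(P, mix$X, repulsion = "exact")
  expect_identical(emb1$Y, emb2$Y)
  expect_equal(dim(emb1$Y), c(600, 2))
  expect_true(all(is.finite(emb1$Y)))

  acc2d <- knn_label_accuracy(emb1$Y, mix$labels, k = 10, test_size = 200,
                              seed = 6)$value
  expect_gte(acc2d, 95)

  # optimization sanity: KL falls during the post-exaggeration phase
  kl <- emb1$kl
  expect_lt(kl[length(kl)], kl[251])
  expect_length(kl, emb1$schedule$total_iters + 1)
})

test_that("the KL trace is invariant to rigid rotation of the inputs", {
  # affinities depend only on pairwise distances, so a rotated input yields
  # the same graph; with a common initialization the optimization path and
  # KL trace coincide
  set.seed(46)
  X <- make_mixture(300, 3, sep = 6, dim = 10, seed = 47)$X
  R <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  g1 <- build_knn_graph(X, 10)
  g2 <- build_knn_graph(X %*% R, 10)
  expect_identical(g1, g2)
  sched <- tsne_schedule(300, total_iters = 300, anneal_iters = 100)
  init <- pca_init(X)
  e1 <- tsne_embed(uniform_affinities(g1), init, sched,
                   repulsion = "exact")
  e2 <- tsne_embed(uniform_affinities(g2), init, sched,
                   repulsion = "exact")
  expect_lt(max(abs(e1$kl - e2$kl)), 1e-6)
})

test_that("Barnes-Hut repulsion tracks the exact optimizer", {
  mix <- make_mixture(800, 4, sep = 6, dim = 15, seed = 48)
  P <- uniform_affinities(build_knn_graph(mix$X, 10))
  sched <- tsne_schedule(800, total_iters = 750, anneal_iters = 250)
  exact <- tsne_embed(P, mix$X, sched, repulsion = "exact")
  bh <- tsne_embed(P, mix$X, sched, repulsion = "bh", theta = 0.5)
  # evaluate both final embeddings under the exact objective
  eval_kl <- function(Y) {
    tsne_embed(P, Y, tsne_schedule(800, total_iters = 0, anneal_iters = 0),
               repulsion = "exact")$kl[1]
  }
  kl_e <- eval_kl(exact$Y)
  kl_b <- eval_kl(bh$Y)
  expect_lt(abs(kl_b - kl_e) / kl_e, 0.05)
})

test_that("malformed affinity inputs are rejected", {
  mix <- make_mixture(50, 2, sep = 5, dim = 5, seed = 49)
  A <- uniform_affinities(build_knn_graph(mix$X, 5))
  bad <- A
  bad$P <- bad$P * 2          # mass 2, not 1
  expect_error(tsne_embed(bad, mix$X), "sum to 1")
  asym <- A
  asym$P[1, 2] <- asym$P[1, 2] + 0.01
  expect_error(tsne_embed(asym, mix$X), "symmetric")
})

test_that("PCA init is small-scale and sign-canonical", {
  set.seed(50)
  X <- matrix(rnorm(400), 100, 4)
  Y <- pca_init(X)
  expect_equal(dim(Y), c(100, 2))
  expect_equal(sd(Y[, 1]), 1e-4, tolerance = 1e-12)
  expect_gt(Y[which.max(abs(Y[, 1])), 1], 0)
})

test_that("orientation alignment equals the 4-sign-pair oracle", {
  set.seed(51)
  mk <- function(Y) list(ids = as.character(seq_len(nrow(Y))), Y = Y)
  Y <- matrix(rnorm(200), 100, 2)
  ref <- mk(Y)
  emb <- structure(mk(Y), class = "embedding2d")

  same <- align_orientation(emb, ref)
  expect_equal(attr(same, "flip"), c(1, 1))

  flipped <- structure(mk(cbind(-Y[, 1], Y[, 2])), class = "embedding2d")
  fixed <- align_orientation(flipped, ref)
  expect_equal(attr(fixed, "flip"), c(-1, 1))
  expect_equal(fixed$Y, Y)

  for (i in 1:5) {
    A <- matrix(rnorm(80), 40, 2)
    B <- matrix(rnorm(80), 40, 2)
    res <- align_orientation(structure(mk(A), class = "embedding2d"),
                             mk(B))
    scores <- sapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                     function(s) cor(s[1] * A[, 1], B[, 1]) +
                       cor(s[2] * A[, 2], B[, 2]))
    expect_equal(cor(res$Y[, 1], B[, 1]) + cor(res$Y[, 2], B[, 2]),
                 max(scores))
  }

  expect_error(align_orientation(structure(mk(A[1, , drop = FALSE]),
                                           class = "embedding2d"),
                                 mk(B[1, , drop = FALSE])),
               "shared ids")
})
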