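#' Build a k-nearest-neighbour graph
#'
#' Exact mode compares every pair by brute force (squared Euclidean, or
#' cosine via row normalization) with distance ties broken towards the
#' lower index; a point is never its own neighbour. Approximate mode runs
#' NN-descent from a seeded random start, the standard approach at corpus
#' scale; it should be validated against exact mode on a sample (the suite
#' requires >= 95% recall).
#'
#' @param vectors a [vector_set()] or numeric matrix (rows = points).
#' @param k number of neighbours, `1 <= k <= n - 1`.
#' @param mode `"exact"` or `"approximate"`.
#' @param metric distance metric; defaults to the vector set's tag.
#' @param seed seed for the approximate mode's random initialization.
#' @return integer matrix, row i holding the indices of the k nearest
#'   neighbours of point i in increasing distance order.
#' @export
build_knn_graph <- function(vectors, k, mode = c("exact", "approximate"),
                            metric = NULL, seed = 1) {
  mode <- match.arg(mode)
  X <- if (inherits(vectors, "vector_set")) {
    metric <- metric %||% vectors$metric
    as_dense_matrix(vectors$X)
  } else {
    metric <- metric %||% "euclidean"
    as_dense_matrix(vectors)
  }
  n <- nrow(X)
  if (k >= n) stop("`k` must be smaller than the number of points",
                   call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (metric == "cosine") {
    rn <- sqrt(rowSums(X^2))
    rn[rn == 0] <- 1
    X <- X / rn   # squared Euclidean on the sphere orders like cosine
  }
  Xt <- t(X)
  if (mode == "exact") {
    knn_brute_cpp(Xt, Xt, as.integer(k), seq_len(n) - 1L)
  } else {
    init <- with_seed(seed, matrix(sample.int(n, n * k, replace = TRUE),
                                   n, k))
    nn_descent_cpp(Xt, init, max_iters = 20L)
  }
}

#' Uniform affinities on a kNN graph
#'
#' Replaces perplexity-calibrated Gaussian affinities with uniform weights
#' on the kNN graph: directed weights `w[j|i] = 1/k` for j among the k
#' nearest neighbours of i, symmetrized as
#' `p[i,j] = (w[j|i] + w[i|j]) / (2n)`. The result is symmetric, has zero
#' diagonal, total mass 1, and between k and 2k nonzeros per row.
#'
#' @param knn integer matrix from [build_knn_graph()].
#' @param k neighbours per point; defaults to `ncol(knn)`.
#' @return object of class `affinity_graph`: list with sparse symmetric `P`
#'   and `k`.
#' @export
uniform_affinities <- function(knn, k = ncol(knn)) {
  n <- nrow(knn)
  stopifnot(k >= 1, k <= ncol(knn))
  knn <- knn[, seq_len(k), drop = FALSE]
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(knn),
                            x = 1 / k, dims = c(n, n))
  P <- (W + Matrix::t(W)) / (2 * n)
  structure(list(P = methods::as(P, "CsparseMatrix"), k = k),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> n=%d, k=%d, nnz=%d, total mass %.6f\n",
              nrow(x$P), x$k, length(x$P@x), sum(x$P@x)))
  invisible(x)
}

#' Optimizer schedule for [tsne_embed()]
#'
#' The early-exaggeration factor anneals linearly from `rho_start` down to 1
#' over the first `anneal_iters` iterations (instead of an abrupt switch)
#' and stays at 1 for the remaining iterations. The learning rate defaults
#' to n/12 and momentum switches from 0.5 to 0.8 after the exaggeration
#' phase, the standard optimizer settings.
#'
#' @param n number of points (sets the default learning rate n/12).
#' @param total_iters total gradient-descent iterations (default 2250).
#' @param anneal_iters length of the annealed exaggeration phase (250).
#' @param rho_start initial exaggeration factor (12).
#' @param learning_rate step size; default `n / 12`.
#' @param momentum_early,momentum_late momentum per phase.
#' @param seed recorded seed (the optimizer itself is deterministic; the
#'   seed covers the PCA initialization contract).
#' @return object of class `tsne_schedule`.
#' @export
tsne_schedule <- function(n, total_iters = 2250, anneal_iters = 250,
                          rho_start = 12, learning_rate = n / 12,
                          momentum_early = 0.5, momentum_late = 0.8,
                          seed = 1) {
  stopifnot(total_iters >= anneal_iters, rho_start >= 1)
  rho <- c(seq(rho_start, 1, length.out = anneal_iters),
           rep(1, total_iters - anneal_iters))
  momentum <- c(rep(momentum_early, anneal_iters),
                rep(momentum_late, total_iters - anneal_iters))
  structure(
    list(exaggeration = rho, momentum = momentum,
         learning_rate = learning_rate, total_iters = total_iters,
         anneal_iters = anneal_iters, rho_start = rho_start,
         seed = as.integer(seed)),
    class = "tsne_schedule"
  )
}

#' PCA initialization for t-SNE
#'
#' Projects onto the first two principal components, canonicalizes each
#' component's sign (largest-magnitude score positive) and rescales so the
#' first coordinate has standard deviation `scale_sd` (1e-4 by default),
#' the usual convention for stability during early exaggeration.
#'
#' @param X numeric matrix or [vector_set()].
#' @param scale_sd target s.d. of the first embedding coordinate.
#' @return n x 2 matrix.
#' @export
pca_init <- function(X, scale_sd = 1e-4) {
  if (inherits(X, "vector_set")) X <- as_dense_matrix(X$X)
  pc <- prcomp(X, rank. = 2, center = TRUE, scale. = FALSE)
  S <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    m <- which.max(abs(S[, j]))
    if (S[m, j] < 0) S[, j] <- -S[, j]
  }
  S * (scale_sd / sd(S[, 1]))
}

#' Embed an affinity graph in 2D with t-SNE
#'
#' Gradient descent on the Kullback-Leibler divergence between the fixed
#' affinities and a Student-t kernel over 2D distances, with the attractive
#' term multiplied by the annealed exaggeration factor. Deterministic given
#' the initialization; `repulsion = "exact"` evaluates the O(n^2) repulsive
#' term exactly (the reference at desk scale), `"bh"` uses a Barnes-Hut
#' quadtree approximation for larger n.
#'
#' @param P an `affinity_graph` from [uniform_affinities()].
#' @param init either a [vector_set()] / matrix of high-dimensional vectors
#'   (PCA-initialized internally) or an n x 2 matrix of starting
#'   coordinates.
#' @param schedule a [tsne_schedule()]; default built from n.
#' @param repulsion `"exact"` or `"bh"`.
#' @param theta Barnes-Hut accuracy parameter (used when
#'   `repulsion = "bh"`).
#' @param ids optional point ids.
#' @return object of class `embedding2d`: list with `ids`, `Y` (n x 2),
#'   `kl` (KL divergence at the start of every iteration plus one final
#'   entry) and the `schedule`.
#' @export
tsne_embed <- function(P, init, schedule = NULL,
                       repulsion = c("exact", "bh"), theta = 0.5,
                       ids = NULL) {
  repulsion <- match.arg(repulsion)
  stopifnot(inherits(P, "affinity_graph"))
  M <- P$P
  n <- nrow(M)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (!Matrix::isSymmetric(M, tol = 1e-10)) {
    stop("affinity matrix must be symmetric", call. = FALSE)
  }
  if (abs(sum(M@x) - 1) > 1e-8) {
    stop("affinity matrix must sum to 1", call. = FALSE)
  }
  if (inherits(init, "vector_set")) {
    ids <- ids %||% init$ids
    init <- as_dense_matrix(init$X)
  }
  init <- as_dense_matrix(init)
  Y0 <- if (ncol(init) == 2 && nrow(init) == n) init else pca_init(init)
  if (nrow(Y0) != n) stop("init size does not match affinity graph",
                          call. = FALSE)
  schedule <- schedule %||% tsne_schedule(n)
  Tm <- methods::as(M, "TsparseMatrix")
  res <- tsne_run_cpp(Tm@i, Tm@j, Tm@x, Y0,
                      schedule$exaggeration, schedule$learning_rate,
                      schedule$momentum,
                      if (repulsion == "exact") -1 else theta)
  structure(
    list(ids = ids %||% as.character(seq_len(n)), Y = res$Y,
         kl = as.numeric(res$kl), schedule = schedule),
    class = "embedding2d"
  )
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> n=%d, %d iterations, final KL %.4f\n",
              nrow(x$Y), x$schedule$total_iters, x$kl[length(x$kl)]))
  invisible(x)
}

#' Align the axis orientation of an embedding to a reference
#'
#' The t-SNE objective is invariant to axis sign flips, so embeddings of
#' the same corpus can come out mirrored. This picks, from the four
#' (+/-x, +/-y) sign pairs, the one maximizing the sum of per-axis Pearson
#' correlations with a reference embedding over the shared ids, and applies
#' it.
#'
#' @param embedding,reference `embedding2d` objects (or lists with `ids`
#'   and n x 2 `Y`).
#' @return `embedding` with flipped axes; the chosen signs are in attribute
#'   `"flip"`.
#' @export
align_orientation <- function(embedding, reference) {
  ids <- intersect(embedding$ids, reference$ids)
  if (length(ids) < 2) stop("need at least 2 shared ids", call. = FALSE)
  A <- embedding$Y[match(ids, embedding$ids), , drop = FALSE]
  B <- reference$Y[match(ids, reference$ids), , drop = FALSE]
  best <- c(1, 1)
  best_score <- -Inf
  for (sx in c(1, -1)) {
    for (sy in c(1, -1)) {
      score <- cor(sx * A[, 1], B[, 1]) + cor(sy * A[, 2], B[, 2])
      if (!is.na(score) && score > best_score) {
        best_score <- score
        best <- c(sx, sy)
      }
    }
  }
  embedding$Y <- sweep(embedding$Y, 2, best, `*`)
  attr(embedding, "flip") <- best
  embedding
}
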