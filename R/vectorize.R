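#' Document vector sets
#'
#' A `vector_set` holds an n x d numeric representation of n documents
#' together with their ids, the distance metric the representation is meant
#' to be searched under, and a provenance tag.
#'
#' @param ids character vector of document ids (one per row).
#' @param X numeric matrix or `Matrix` sparse matrix, documents in rows.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param provenance free-form tag, e.g. `"tfidf"`, `"svd"`, `"backend"`.
#' @return an object of class `vector_set`.
#' @export
vector_set <- function(ids, X,
                       metric = c("euclidean", "cosine"),
                       provenance = "unknown") {
  metric <- match.arg(metric)
  if (!(is.matrix(X) || inherits(X, "Matrix"))) {
    stop("`X` must be a matrix", call. = FALSE)
  }
  if (length(ids) != nrow(X)) {
    stop("`ids` must have one entry per row of `X`", call. = FALSE)
  }
  vals <- if (inherits(X, "sparseMatrix")) X@x else X
  if (length(vals) && any(!is.finite(vals))) {
    stop("`X` must contain only finite values", call. = FALSE)
  }
  structure(list(ids = as.character(ids), X = X, metric = metric,
                 provenance = provenance),
            class = "vector_set")
}

#' @export
print.vector_set <- function(x, ...) {
  cat(sprintf("<vector_set> %d x %d (%s, metric=%s, provenance=%s)\n",
              nrow(x$X), ncol(x$X),
              if (inherits(x$X, "sparseMatrix")) "sparse" else "dense",
              x$metric, x$provenance))
  invisible(x)
}

#' @export
dim.vector_set <- function(x) dim(x$X)

#' Tokenize abstracts and build a document-term count matrix
#'
#' Tokens are lowercased matches of `token_pattern` (default: runs of two or
#' more word characters, so single letters and punctuation are dropped). The
#' vocabulary is sorted, and terms appearing in fewer than `min_doc_count`
#' documents are removed.
#'
#' @param texts character vector of abstracts.
#' @param token_pattern regular expression matched with `perl = TRUE`.
#' @param min_doc_count minimum document frequency for a term to be kept.
#' @return object of class `doc_term_counts`: list with `C` (sparse
#'   `dgCMatrix` of counts, documents in rows), `vocabulary`, and `n`.
#' @export
tokenize_and_vocab <- function(texts, token_pattern = "\\w{2,}",
                               min_doc_count = 1) {
  if (length(texts) == 0) stop("empty corpus", call. = FALSE)
  toks <- regmatches(tolower(texts),
                     gregexpr(token_pattern, tolower(texts), perl = TRUE))
  lens <- lengths(toks)
  if (sum(lens) == 0) {
    stop("no tokens found in corpus", call. = FALSE)
  }
  all_tokens <- unlist(toks, use.names = FALSE)
  vocab <- sort(unique(all_tokens))
  j <- match(all_tokens, vocab)
  i <- rep.int(seq_along(texts), lens)
  C <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(texts), length(vocab)),
                            dimnames = list(NULL, vocab))
  C <- methods::as(C, "CsparseMatrix")  # duplicates summed -> counts
  if (min_doc_count > 1) {
    df <- Matrix::colSums(C > 0)
    keep <- df >= min_doc_count
    C <- C[, keep, drop = FALSE]
    vocab <- vocab[keep]
  }
  structure(list(C = C, vocabulary = vocab, n = length(texts)),
            class = "doc_term_counts")
}

#' Log-scaled TF-IDF with row l2 normalization
#'
#' Computes, for every nonzero count `C[i, j]`,
#' \deqn{X_{ij} = (1 + \ln C_{ij}) \cdot
#'       \left(1 + \ln \frac{1 + n}{1 + \mathrm{df}_j}\right)}
#' where `n` is the number of documents and `df_j` the number of documents
#' containing term `j`; zero counts stay exactly zero, so the sparsity
#' pattern of the counts is preserved. Each nonzero row is then scaled to
#' unit l2 norm (all-zero rows are left as zero).
#'
#' @param counts a [tokenize_and_vocab()] result.
#' @param ids optional document ids; defaults to row numbers.
#' @return a [vector_set()] with provenance `"tfidf"`.
#' @export
tfidf_matrix <- function(counts, ids = NULL) {
  stopifnot(inherits(counts, "doc_term_counts"))
  C <- methods::as(counts$C, "CsparseMatrix")
  n <- counts$n
  df <- Matrix::colSums(C > 0)
  idf <- 1 + log((1 + n) / (1 + df))
  X <- C
  # dgCMatrix: @x runs down columns; map each nonzero to its column's idf
  col_of <- rep.int(seq_len(ncol(C)), diff(C@p))
  X@x <- (1 + log(C@x)) * idf[col_of]
  rn <- sqrt(Matrix::rowSums(X^2))
  rn[rn == 0] <- 1
  X <- Matrix::Diagonal(x = 1 / rn) %*% X
  X <- methods::as(X, "CsparseMatrix")
  vector_set(ids = ids %||% as.character(seq_len(n)), X = X,
             metric = "euclidean", provenance = "tfidf")
}

#' Truncated SVD reduction of a vector set
#'
#' Projects onto the top-`d` right singular subspace and returns the scores
#' `U %*% diag(S)`. Component signs are canonicalized so that the
#' largest-magnitude loading of each component is positive. With
#' `row_normalize = TRUE` the reduced rows are scaled to unit l2 norm,
#' which makes Euclidean neighbour search equivalent to cosine similarity
#' on the reduced space.
#'
#' @param vectors a [vector_set()].
#' @param d target dimensionality, at most `min(n, ncol)`.
#' @param row_normalize scale reduced rows to unit norm.
#' @return a [vector_set()] with provenance `"svd"`.
#' @export
reduce_svd <- function(vectors, d, row_normalize = FALSE) {
  stopifnot(inherits(vectors, "vector_set"))
  X <- as_dense_matrix(vectors$X)
  if (d > min(dim(X))) {
    stop("`d` must be at most min(n, ncol(X))", call. = FALSE)
  }
  sv <- svd(X, nu = d, nv = d)
  U <- sv$u
  V <- sv$v
  for (j in seq_len(d)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  S <- U %*% diag(sv$d[seq_len(d)], d)
  metric <- "euclidean"
  if (row_normalize) {
    rn <- sqrt(rowSums(S^2))
    rn[rn == 0] <- 1
    S <- S / rn
  }
  out <- vector_set(vectors$ids, S, metric = metric, provenance = "svd")
  attr(out, "singular_values") <- sv$d[seq_len(d)]
  attr(out, "loadings") <- V
  out
}

#' Center or whiten a vector set
#'
#' `"centered"` subtracts column means. `"whitened"` additionally rotates
#' into the eigenbasis of the sample covariance and rescales each direction
#' to unit variance (PCA whitening); near-zero eigenvalues are floored at
#' `eps` times the leading eigenvalue to keep the transform stable on
#' rank-deficient input.
#'
#' @param vectors a [vector_set()].
#' @param mode one of `"raw"`, `"centered"`, `"whitened"`.
#' @param eps relative eigenvalue floor used when whitening.
#' @return a [vector_set()].
#' @export
transform_vectors <- function(vectors, mode = c("raw", "centered",
                                                "whitened"),
                              eps = 1e-10) {
  stopifnot(inherits(vectors, "vector_set"))
  mode <- match.arg(mode)
  if (mode == "raw") return(vectors)
  X <- as_dense_matrix(vectors$X)
  Xc <- sweep(X, 2, colMeans(X))
  if (mode == "centered") {
    return(vector_set(vectors$ids, Xc, metric = vectors$metric,
                      provenance = vectors$provenance))
  }
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, eps * max(eig$values))
  W <- Xc %*% eig$vectors %*% diag(1 / sqrt(vals), length(vals))
  vector_set(vectors$ids, W, metric = vectors$metric,
             provenance = vectors$provenance)
}

#' Adapter contract for external text-embedding backends
#'
#' Transformer representations enter the pipeline only through this
#' interface: a backend is a function `f(texts, pooling)` returning one
#' numeric row per text, where `pooling` selects the token-pooling strategy
#' (`"cls"` for the initial classifier token, `"sep"` for the trailing
#' separator token, `"mean"` for averaging over tokens). No model ships
#' with this package.
#'
#' @param fun function taking `(texts, pooling)` and returning a numeric
#'   matrix with `length(texts)` rows.
#' @param name backend name recorded as provenance.
#' @return object of class `vector_backend`.
#' @export
vector_backend <- function(fun, name = "backend") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, name = name), class = "vector_backend")
}

#' @rdname vector_backend
#' @param backend a `vector_backend`.
#' @param texts character vector to embed.
#' @param pooling one of `"cls"`, `"sep"`, `"mean"`.
#' @param ids optional document ids.
#' @export
embed_texts <- function(backend, texts, pooling = c("sep", "cls", "mean"),
                        ids = NULL) {
  stopifnot(inherits(backend, "vector_backend"))
  pooling <- match.arg(pooling)
  X <- backend$fun(texts, pooling)
  if (!is.matrix(X) || nrow(X) != length(texts)) {
    stop("backend must return one row per text", call. = FALSE)
  }
  vector_set(ids %||% as.character(seq_along(texts)), X,
             metric = "euclidean", provenance = "backend")
}
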