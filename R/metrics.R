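#' Metric report container
#'
#' Every corpus statistic returns one of these: the metric name, its value
#' (percent for accuracies/recall/isolatedness, years for RMSE), the k
#' used, sample sizes, the sampling seed, and optionally the per-point
#' values behind the mean.
#'
#' @keywords internal
metric_report <- function(metric, value, k = NA_integer_, n_test = NA,
                          n_train = NA, seed = NA, per_point = NULL) {
  structure(
    list(metric = metric, value = value, k = k, n_test = n_test,
         n_train = n_train, seed = seed, per_point = per_point),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  unit <- if (grepl("rmse", x$metric)) "years" else "%"
  cat(sprintf("<metric_report> %s: %.3f %s (k=%s, n_test=%s, n_train=%s)\n",
              x$metric, x$value, unit, x$k, x$n_test, x$n_train))
  invisible(x)
}

# Resolve a vector_set or matrix to a dense matrix, points in rows.
metric_matrix <- function(vectors) {
  if (inherits(vectors, "vector_set")) as_dense_matrix(vectors$X)
  else as_dense_matrix(vectors)
}

# kNN of query rows among train rows; self_of[q] gives the train index the
# query corresponds to (excluded), or NA.
knn_among <- function(X, train_idx, query_idx, k, self_excluded = TRUE) {
  Xt <- t(X[train_idx, , drop = FALSE])
  Xq <- t(X[query_idx, , drop = FALSE])
  self_pos <- if (self_excluded) match(query_idx, train_idx) else
    rep(NA_integer_, length(query_idx))
  self_pos[is.na(self_pos)] <- 0L
  nn <- knn_brute_cpp(Xt, Xq, as.integer(k), self_pos - 1L)
  matrix(train_idx[nn], nrow = nrow(nn))
}

#' kNN label classification accuracy
#'
#' Each test point is predicted with the majority label among its k nearest
#' labelled training points; majority ties are broken by the label of the
#' nearest neighbour carrying a tied label. The test set is drawn from the
#' labelled points, and neighbours are searched among labelled non-test
#' points only.
#'
#' @param vectors [vector_set()] or matrix.
#' @param labels character vector, `NA` = unlabeled.
#' @param k neighbours (default 10).
#' @param test_size number of test points sampled from labelled points.
#' @param seed sampling seed.
#' @param test_idx optional explicit test indices (overrides sampling).
#' @return a `metric_report` with accuracy in percent.
#' @export
knn_label_accuracy <- function(vectors, labels, k = 10, test_size = NULL,
                               seed = 1, test_idx = NULL) {
  X <- metric_matrix(vectors)
  labeled <- which(!is.na(labels))
  if (length(unique(labels[labeled])) < 2) {
    stop("need at least 2 distinct labels", call. = FALSE)
  }
  if (is.null(test_idx)) {
    test_size <- test_size %||% min(1000L, floor(length(labeled) / 5))
    if (test_size > length(labeled)) {
      stop("`test_size` exceeds the number of labelled points",
           call. = FALSE)
    }
    test_idx <- with_seed(seed, sample(labeled, test_size))
  }
  train_idx <- setdiff(labeled, test_idx)
  nn <- knn_among(X, train_idx, test_idx, k)
  correct <- vapply(seq_along(test_idx), function(q) {
    nb_labels <- labels[nn[q, ]]
    majority_label(nb_labels) == labels[test_idx[q]]
  }, logical(1))
  metric_report("knn_accuracy", 100 * mean(correct), k = k,
                n_test = length(test_idx), n_train = length(train_idx),
                seed = seed, per_point = correct)
}

# Majority vote over neighbour labels (nearest first); ties go to the
# nearest neighbour whose label is among the tied ones.
majority_label <- function(nb_labels) {
  counts <- table(nb_labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  nb_labels[nb_labels %in% top][1]
}

#' Chance-level accuracy by stratified guessing
#'
#' Predicts each test point by sampling from the empirical label
#' distribution of the training labels (the stratified dummy-classifier
#' baseline); in expectation this equals the sum of squared label
#' proportions.
#'
#' @inheritParams knn_label_accuracy
#' @return a `metric_report` with accuracy in percent.
#' @export
chance_level_accuracy <- function(labels, test_size = NULL, seed = 1,
                                  test_idx = NULL) {
  labeled <- which(!is.na(labels))
  if (length(labeled) < 1) stop("need at least one label", call. = FALSE)
  seeds <- child_seeds(seed, 2)
  if (is.null(test_idx)) {
    test_size <- test_size %||% min(1000L, floor(length(labeled) / 5))
    test_idx <- with_seed(seeds[1], sample(labeled, test_size))
  }
  train_labels <- labels[setdiff(labeled, test_idx)]
  if (length(train_labels) == 0) train_labels <- labels[test_idx]
  pred <- with_seed(seeds[2],
                    sample(train_labels, length(test_idx), replace = TRUE))
  correct <- pred == labels[test_idx]
  metric_report("chance_accuracy", 100 * mean(correct),
                n_test = length(test_idx), n_train = length(train_labels),
                seed = seed, per_point = correct)
}

#' kNN publication-year prediction RMSE
#'
#' Predicts each test paper's publication year as the mean year of its k
#' nearest training papers (`mode = "knn"`), or of k uniformly drawn
#' training papers (`mode = "chance"`), and reports the root mean-squared
#' error in years.
#'
#' @inheritParams knn_label_accuracy
#' @param years numeric vector of publication years (no missing values).
#' @param mode `"knn"` or `"chance"`.
#' @return a `metric_report` with RMSE in years.
#' @export
knn_year_rmse <- function(vectors, years, k = 10, test_size = NULL,
                          seed = 1, mode = c("knn", "chance"),
                          test_idx = NULL) {
  mode <- match.arg(mode)
  X <- metric_matrix(vectors)
  n <- nrow(X)
  if (anyNA(years) || length(years) != n) {
    stop("`years` must be complete, one per point", call. = FALSE)
  }
  seeds <- child_seeds(seed, 2)
  if (is.null(test_idx)) {
    test_size <- test_size %||% min(1000L, floor(n / 5))
    test_idx <- with_seed(seeds[1], sample.int(n, test_size))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  pred <- if (mode == "knn") {
    nn <- knn_among(X, train_idx, test_idx, k)
    rowMeans(matrix(years[nn], nrow = nrow(nn)))
  } else {
    with_seed(seeds[2], vapply(seq_along(test_idx), function(q)
      mean(years[sample(train_idx, k, replace = FALSE)]), numeric(1)))
  }
  err <- pred - years[test_idx]
  metric_report(paste0("year_rmse_", mode), sqrt(mean(err^2)), k = k,
                n_test = length(test_idx), n_train = length(train_idx),
                seed = seed, per_point = err)
}

#' kNN recall of an embedding
#'
#' For each sampled point, the overlap between its k nearest neighbours in
#' the high-dimensional space and in the low-dimensional embedding, divided
#' by k and averaged; reported in percent. 100% means the embedding
#' preserves every local neighbourhood.
#'
#' @param highD,lowD [vector_set()]s (or matrices) over the same ids in the
#'   same order.
#' @param k neighbours.
#' @param subset_size number of points sampled for the average.
#' @param seed sampling seed.
#' @param subset_idx optional explicit point indices.
#' @return a `metric_report` with recall in percent.
#' @export
knn_recall <- function(highD, lowD, k = 10, subset_size = NULL, seed = 1,
                       subset_idx = NULL) {
  if (inherits(highD, "vector_set") && inherits(lowD, "vector_set") &&
      !identical(highD$ids, lowD$ids)) {
    stop("`highD` and `lowD` must share the same ids", call. = FALSE)
  }
  Xh <- metric_matrix(highD)
  Xl <- if (inherits(lowD, "embedding2d")) lowD$Y else metric_matrix(lowD)
  n <- nrow(Xh)
  if (nrow(Xl) != n) stop("point counts differ", call. = FALSE)
  if (is.null(subset_idx)) {
    subset_size <- min(subset_size %||% n, n)
    subset_idx <- with_seed(seed, sample.int(n, subset_size))
  }
  all_idx <- seq_len(n)
  nn_h <- knn_among(Xh, all_idx, subset_idx, k)
  nn_l <- knn_among(Xl, all_idx, subset_idx, k)
  overlap <- vapply(seq_along(subset_idx), function(q)
    length(intersect(nn_h[q, ], nn_l[q, ])) / k, numeric(1))
  metric_report("knn_recall", 100 * mean(overlap), k = k,
                n_test = length(subset_idx), n_train = n, seed = seed,
                per_point = overlap)
}

#' Isolatedness of a sub-corpus
#'
#' The mean, over sampled corpus members, of the fraction of their k
#' nearest neighbours (searched over the entire dataset, excluding the
#' query itself) that also belong to the corpus; in percent. 100% marks a
#' fully detached literature.
#'
#' @param vectors [vector_set()] or matrix over the whole dataset.
#' @param mask logical membership vector (e.g. a [select_subcorpus()]
#'   mask).
#' @param k neighbours.
#' @param subset_size members sampled (capped at the corpus size;
#'   default 5000).
#' @param seed sampling seed.
#' @param subset_idx optional explicit member indices.
#' @return a `metric_report` with isolatedness in percent.
#' @export
isolatedness <- function(vectors, mask, k = 10, subset_size = 5000,
                         seed = 1, subset_idx = NULL) {
  X <- metric_matrix(vectors)
  members <- which(as.logical(mask))
  if (length(members) < k + 1) {
    stop("corpus must have at least k + 1 members", call. = FALSE)
  }
  if (is.null(subset_idx)) {
    m <- min(subset_size, length(members))
    subset_idx <- with_seed(seed, sample(members, m))
  }
  nn <- knn_among(X, seq_len(nrow(X)), subset_idx, k)
  frac <- rowMeans(matrix(as.logical(mask)[nn], nrow = nrow(nn)))
  metric_report("isolatedness", 100 * mean(frac), k = k,
                n_test = length(subset_idx), n_train = nrow(X),
                seed = seed, per_point = frac)
}

#' Yearly kNN overlap of a source corpus with a target label
#'
#' For each calendar year, samples up to `per_year_cap` source-corpus
#' papers published that year and computes, per paper, the fraction of its
#' k nearest neighbours (over the whole dataset) carrying the target label;
#' returns the yearly means. Smoothing is left to [fit_trend()].
#'
#' @param vectors [vector_set()] or matrix over the whole dataset.
#' @param source_mask logical; papers whose neighbourhoods are examined.
#' @param target_mask logical; papers counting towards the overlap.
#' @param years publication year per paper.
#' @param k neighbours.
#' @param per_year_cap maximum papers sampled per year (default 500).
#' @param seed sampling seed.
#' @return data.frame with `year`, `value` (mean overlap fraction) and
#'   `n_sampled`.
#' @export
knn_overlap_series <- function(vectors, source_mask, target_mask, years,
                               k = 10, per_year_cap = 500, seed = 1) {
  X <- metric_matrix(vectors)
  src <- which(as.logical(source_mask))
  if (length(src) == 0) stop("source corpus is empty", call. = FALSE)
  tgt <- as.logical(target_mask)
  yrs <- sort(unique(years[src]))
  seeds <- child_seeds(seed, length(yrs))
  rows <- lapply(seq_along(yrs), function(t) {
    pool <- src[years[src] == yrs[t]]
    take <- if (length(pool) > per_year_cap) {
      with_seed(seeds[t], sample(pool, per_year_cap))
    } else pool
    nn <- knn_among(X, seq_len(nrow(X)), take, k)
    frac <- rowMeans(matrix(tgt[nn], nrow = nrow(nn)))
    data.frame(year = yrs[t], value = mean(frac), n_sampled = length(take))
  })
  do.call(rbind, rows)
}

#' Fraction of flagged points inside a 2D region
#'
#' Counts the points of an embedding inside an axis-aligned box or a
#' polygon (boundary inclusive) and how many of them are flagged, e.g.
#' retracted papers inside a suspicious region of the map.
#'
#' @param embedding `embedding2d` or n x 2 coordinate matrix.
#' @param flags logical vector, one per point.
#' @param region either `c(xmin, xmax, ymin, ymax)` or a polygon as an
#'   m x 2 vertex matrix.
#' @return list with `count_flagged`, `count_total`, `fraction`.
#' @export
region_flag_fraction <- function(embedding, flags, region) {
  Y <- if (inherits(embedding, "embedding2d")) embedding$Y else
    as_dense_matrix(embedding)
  flags <- as.logical(flags)
  stopifnot(length(flags) == nrow(Y))
  inside <- if (is.matrix(region)) {
    point_in_polygon(Y[, 1], Y[, 2], region)
  } else {
    stopifnot(length(region) == 4)
    Y[, 1] >= region[1] & Y[, 1] <= region[2] &
      Y[, 2] >= region[3] & Y[, 2] <= region[4]
  }
  total <- sum(inside)
  if (total == 0) stop("region contains no points", call. = FALSE)
  flagged <- sum(inside & flags)
  list(count_flagged = flagged, count_total = total,
       fraction = flagged / total)
}

# Even-odd ray casting with an explicit on-edge check (edges count as
# inside).
point_in_polygon <- function(px, py, poly) {
  m <- nrow(poly)
  xs <- poly[, 1]
  ys <- poly[, 2]
  nxt <- c(2:m, 1)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    for (e in seq_len(m)) {
      x1 <- xs[e]; y1 <- ys[e]; x2 <- xs[nxt[e]]; y2 <- ys[nxt[e]]
      # on-edge check
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
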