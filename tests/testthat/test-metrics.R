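test_that("kNN label accuracy equals the brute-force classifier oracle", {
  mix <- make_mixture(200, 4, sep = 2, dim = 8, seed = 61)
  test_idx <- seq(1, 200, by = 4)
  rep_acc <- knn_label_accuracy(mix$X, mix$labels, k = 10,
                                test_idx = test_idx)
  train_idx <- setdiff(seq_len(200), test_idx)
  nn <- knn_oracle(mix$X, train_idx, test_idx, 10)
  pred <- vapply(seq_along(test_idx), function(q)
    majority_oracle(mix$labels[nn[q, ]]), character(1))
  oracle_acc <- 100 * mean(pred == mix$labels[test_idx])
  expect_equal(rep_acc$value, oracle_acc, tolerance = 0)
  expect_equal(rep_acc$n_test, length(test_idx))
})

test_that("accuracy hits its perfect-separation and chance limits", {
  mix <- make_mixture(800, 4, sep = 10, dim = 20, seed = 62)
  acc <- knn_label_accuracy(mix$X, mix$labels, k = 10, test_size = 300,
                            seed = 3)$value
  expect_equal(acc, 100)

  mix0 <- make_mixture(2000, 4, sep = 0, dim = 10, seed = 63)
  acc0 <- knn_label_accuracy(mix0$X, mix0$labels, k = 10,
                             test_size = 1000, seed = 3)$value
  chance <- chance_level_accuracy(mix0$labels, test_size = 1000,
                                  seed = 3)$value
  expect_lt(abs(acc0 - 25), 100 * binom99_tol(0.25, 1000))
  expect_lt(abs(chance - 25), 100 * binom99_tol(0.25, 1000))
})

test_that("chance accuracy follows the stratified-guessing closed form", {
  expect_equal(chance_level_accuracy(rep("only", 50), test_size = 20,
                                     seed = 1)$value, 100)
  set.seed(64)
  labels <- sample(c("a", "b"), 4000, replace = TRUE)
  ch <- chance_level_accuracy(labels, test_size = 2000, seed = 2)$value
  expect_lt(abs(ch - 50), 100 * binom99_tol(0.5, 2000))

  p <- c(0.6, 0.3, 0.1)
  labels <- sample(c("x", "y", "z"), 6000, replace = TRUE, prob = p)
  ch <- chance_level_accuracy(labels, test_size = 3000, seed = 2)$value
  expect_lt(abs(ch - 100 * sum(p^2)),
            100 * binom99_tol(sum(p^2), 3000))
})

test_that("year RMSE equals its oracle and degenerate limits", {
  mix <- make_mixture(300, 3, sep = 2, dim = 6, seed = 65)
  set.seed(66)
  years <- sample(1990:2020, 300, replace = TRUE)
  test_idx <- seq(2, 300, by = 3)
  rep_rmse <- knn_year_rmse(mix$X, years, k = 10, test_idx = test_idx)
  train_idx <- setdiff(seq_len(300), test_idx)
  nn <- knn_oracle(mix$X, train_idx, test_idx, 10)
  pred <- rowMeans(matrix(years[nn], nrow = nrow(nn)))
  oracle <- sqrt(mean((pred - years[test_idx])^2))
  expect_equal(rep_rmse$value, oracle, tolerance = 0)

  const <- knn_year_rmse(mix$X, rep(2000, 300), k = 10,
                         test_idx = test_idx)
  expect_equal(const$value, 0)
})

test_that("kNN recall equals the set-overlap oracle and its limits", {
  set.seed(67)
  X <- matrix(rnorm(100 * 10), 100, 10)
  Y <- matrix(rnorm(100 * 2), 100, 2)
  idx <- 1:100
  rec <- knn_recall(X, Y, k = 10, subset_idx = idx)
  nn_h <- knn_oracle(X, idx, idx, 10)
  nn_l <- knn_oracle(Y, idx, idx, 10)
  oracle <- 100 * mean(vapply(idx, function(q)
    length(intersect(nn_h[q, ], nn_l[q, ])) / 10, numeric(1)))
  expect_equal(rec$value, oracle, tolerance = 0)

  expect_equal(knn_recall(X, X, k = 10, subset_idx = idx)$value, 100)
})

test_that("isolatedness equals brute-force neighbour counting", {
  mix <- make_mixture(400, 4, sep = 3, dim = 8, seed = 68)
  mask <- mix$labels == mix$labels[1]
  members <- which(mask)
  rep_iso <- isolatedness(mix$X, mask, k = 10, subset_idx = members)
  nn <- knn_oracle(mix$X, 1:400, members, 10)
  oracle <- 100 * mean(rowMeans(matrix(mask[nn], nrow = nrow(nn))))
  expect_equal(rep_iso$value, oracle, tolerance = 0)

  # whole-corpus mask is trivially 100%
  expect_equal(isolatedness(mix$X, rep(TRUE, 400), k = 10,
                            seed = 1)$value, 100)
  expect_error(isolatedness(mix$X, c(rep(TRUE, 5), rep(FALSE, 395)),
                            k = 10), "k \\+ 1")
})

test_that("isolatedness is monotone in cluster separation", {
  vals <- vapply(c(0.5, 3, 8), function(s) {
    mix <- make_mixture(900, 3, sep = s, dim = 10, seed = 69)
    mask <- mix$labels == "t01"
    isolatedness(mix$X, mask, k = 10, seed = 4)$value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("full-corpus statistics are permutation invariant", {
  mix <- make_mixture(150, 3, sep = 4, dim = 6, seed = 70)
  mask <- mix$labels == "t01"
  iso <- isolatedness(mix$X, mask, k = 5, subset_idx = which(mask))
  perm <- sample(150)
  iso_p <- isolatedness(mix$X[perm, ], mask[perm], k = 5,
                        subset_idx = which(mask[perm]))
  expect_equal(iso$value, iso_p$value)
})

test_that("overlap series samples per year and detects drift", {
  # target absent everywhere -> all-zero series
  mix <- make_mixture(300, 3, sep = 4, dim = 6, seed = 71)
  years <- rep(2000:2009, each = 30)
  src <- mix$labels == "t01"
  none <- knn_overlap_series(mix$X, src, rep(FALSE, 300), years, k = 5)
  expect_true(all(none$value == 0))

  # per-year cap: a year with more source papers than the cap samples
  # exactly cap papers
  capped <- knn_overlap_series(mix$X, rep(TRUE, 300), src, years,
                               k = 5, per_year_cap = 12, seed = 5)
  expect_true(all(capped$n_sampled == 12))

  # constructed monotone drift: source points approach the target cluster
  # over the years, so overlap should rise with year
  set.seed(72)
  n_per <- 40
  yrs <- 2000:2011
  target <- matrix(rnorm(200 * 2), 200, 2)
  drift <- do.call(rbind, lapply(seq_along(yrs), function(t) {
    offset <- 12 - t                      # walks towards the target
    matrix(rnorm(n_per * 2), n_per, 2) + offset
  }))
  X <- rbind(target, drift)
  years_all <- c(rep(1999, 200), rep(yrs, each = n_per))
  src_mask <- c(rep(FALSE, 200), rep(TRUE, length(yrs) * n_per))
  tgt_mask <- !src_mask
  ser <- knn_overlap_series(X, src_mask, tgt_mask, years_all, k = 10,
                            seed = 6)
  ser <- ser[ser$year >= 2000, ]
  expect_gt(cor(ser$year, ser$value, method = "spearman"), 0)
})

test_that("region flag fractions count boundary-inclusive membership", {
  Y <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  flags <- rep(FALSE, 100)
  flags[Y[, 1] <= 2] <- TRUE
  box <- c(1, 2, 1, 10)             # 20 points, all flagged
  res <- region_flag_fraction(Y, flags, box)
  expect_equal(res$count_total, 20)
  expect_equal(res$count_flagged, 20)
  expect_equal(res$fraction, 1)

  poly <- cbind(c(0.5, 5.5, 5.5, 0.5), c(0.5, 0.5, 5.5, 5.5))
  res2 <- region_flag_fraction(Y, flags, poly)
  expect_equal(res2$count_total, 25)
  expect_equal(res2$count_flagged, 10)
  expect_equal(res2$fraction, 10 / 25)

  # boundary points are inside
  res3 <- region_flag_fraction(matrix(c(1, 1), 1), TRUE, c(1, 2, 1, 2))
  expect_equal(res3$count_total, 1)

  expect_error(region_flag_fraction(Y, flags, c(100, 101, 100, 101)),
               "no points")

  # random flags at rate q over a large region approach q
  set.seed(73)
  flags_q <- runif(100) < 0.3
  res4 <- region_flag_fraction(Y, flags_q, c(0, 11, 0, 11))
  expect_lt(abs(res4$fraction - 0.3), binom99_tol(0.3, 100, inflate = 1))
})

test_that("all percentage metrics stay within [0, 100]", {
  mix <- make_mixture(200, 3, sep = 1, dim = 5, seed = 74)
  mask <- mix$labels == "t01"
  vals <- c(
    knn_label_accuracy(mix$X, mix$labels, k = 5, test_size = 50,
                       seed = 1)$value,
    chance_level_accuracy(mix$labels, test_size = 50, seed = 1)$value,
    knn_recall(mix$X, matrix(rnorm(400), 200, 2), k = 5,
               subset_size = 50, seed = 1)$value,
    isolatedness(mix$X, mask, k = 5, seed = 1)$value
  )
  expect_true(all(vals >= 0 & vals <= 100))
})
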