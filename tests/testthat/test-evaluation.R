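test_that("stratified splitting hits the floor total within one row per class", {
  fm <- default_features()
  parts <- train_test_split(fm, split_spec(0.8, seed = 4))
  expect_identical(nrow(parts$train), 406L)  # floor(0.8 * 508)
  expect_identical(nrow(parts$test), 102L)
  for (cl in 0:4) {
    n_cl <- sum(fm$label == cl)
    got <- sum(parts$train$label == cl)
    expect_lte(abs(got - 0.8 * n_cl), 1)
  }
  # determinism and disjointness
  again <- train_test_split(fm, split_spec(0.8, seed = 4))
  expect_identical(parts$train_idx, again$train_idx)
  expect_length(intersect(parts$train_idx, parts$test_idx), 0)

  other <- train_test_split(fm, split_spec(0.8, seed = 5))
  expect_false(identical(parts$train_idx, other$train_idx))
})

test_that("minimal two-row classes split one-and-one at fraction 0.5", {
  fm <- structure(data.frame(RMSH = stats::rnorm(10),
                             label = rep(0:4, each = 2)),
                  class = c("feature_matrix", "data.frame"))
  parts <- train_test_split(fm, split_spec(0.5))
  expect_identical(as.vector(table(parts$train$label)), rep(1L, 5))
  expect_identical(as.vector(table(parts$test$label)), rep(1L, 5))
  bad <- fm[-1, ]
  class(bad) <- class(fm)
  expect_error(train_test_split(bad, split_spec(0.5)), "at least 2 rows")
  expect_error(split_spec(1.2), "between 0 and 1")
})

test_that("the confusion grid equals a tally-by-loop oracle", {
  perfect <- confusion_matrix(0:4, 0:4, 5)
  expect_identical(unname(diag(perfect)), rep(1L, 5))
  expect_identical(sum(perfect), 5L)

  all_zero <- confusion_matrix(c(0, 1, 2, 3, 4), rep(0, 5), 5)
  expect_identical(unname(all_zero[, 1]), rep(1L, 5))
  expect_identical(sum(all_zero[, -1]), 0L)

  set.seed(40)
  truth <- sample(0:4, 100, replace = TRUE)
  pred <- sample(0:4, 100, replace = TRUE)
  grid <- confusion_matrix(truth, pred, 5)
  oracle <- matrix(0L, 5, 5)
  for (i in seq_along(truth)) {
    oracle[truth[i] + 1, pred[i] + 1] <- oracle[truth[i] + 1, pred[i] + 1] + 1L
  }
  expect_identical(unname(grid), oracle)
  expect_error(confusion_matrix(0:3, 0:4), "length mismatch")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 5), "out of range")
})

test_that("one-vs-rest reduction matches direct summation", {
  set.seed(41)
  truth <- sample(0:4, 200, replace = TRUE)
  pred <- sample(0:4, 200, replace = TRUE)
  grid <- confusion_matrix(truth, pred, 5)
  for (cl in 0:4) {
    counts <- binary_counts(grid, cl)
    expect_identical(counts$tp, sum(truth == cl & pred == cl))
    expect_identical(counts$fn, sum(truth == cl & pred != cl))
    expect_identical(counts$fp, sum(truth != cl & pred == cl))
    expect_identical(counts$tn, sum(truth != cl & pred != cl))
  }
  diagonal <- confusion_matrix(0:4, 0:4, 5)
  d <- binary_counts(diagonal, 2)
  expect_identical(c(d$fp, d$fn), c(0L, 0L))
  expect_error(binary_counts(grid, 9), "out of range")
})

test_that("derived metrics reproduce worked-example report rows", {
  # vertical-channel AMP feature row
  ampv <- derived_metrics(confusion_counts(1, 75.76, 0.103, 2.7607))
  expect_equal(ampv$sensitivity, 26.59, tolerance = 0.01 / 26.59)
  expect_equal(ampv$specificity, 99.86, tolerance = 0.01 / 99.86)
  expect_equal(ampv$precision, 90.66, tolerance = 0.01 / 90.66)
  # horizontal-channel covariance feature row
  covh <- derived_metrics(confusion_counts(1, 16.05, 2.5, 0.6645))
  expect_equal(covh$specificity, 86.52, tolerance = 0.01 / 86.52)
  expect_equal(covh$precision, 28.57, tolerance = 0.01 / 28.57)
})

test_that("derived metrics handle perfection and undefined denominators", {
  perfect <- derived_metrics(confusion_counts(10, 90, 0, 0))
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100, precision = 100))
  no_pos <- derived_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$precision))
  expect_false(is.na(no_pos$accuracy))
  expect_error(confusion_counts(-1, 1, 1, 1), "non-negative")
})

test_that("roc curves honour ranking structure", {
  truth <- c(0L, 0L, 1L, 1L)
  onehot <- cbind(`0` = c(1, 1, 0, 0), `1` = c(0, 0, 1, 1))
  r <- roc_curve(onehot, truth)
  expect_equal(r$auc, 1)
  expect_equal(unname(r$at_cutoff["sensitivity"]), 100)

  rev <- roc_curve(1 - onehot, truth)
  expect_equal(rev$auc, 0)

  const <- roc_curve(onehot * 0 + 0.3, truth)
  expect_equal(const$auc, 0.5)

  # reversing scores maps auc to 1 - auc
  set.seed(42)
  scores <- matrix(stats::runif(40), ncol = 2, dimnames = list(NULL, 0:1))
  t2 <- sample(0:1, 20, replace = TRUE)
  expect_equal(roc_curve(1 - scores, t2)$auc, 1 - roc_curve(scores, t2)$auc)
  expect_error(roc_curve(onehot, c(0L, 0L, 0L, 0L)), "positive")
})

test_that("roc auc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  truth <- sample(0:1, 50, replace = TRUE)
  score1 <- stats::runif(50)
  scores <- cbind(`1` = score1)  # single-class reduction is the binary roc
  mine <- roc_curve(scores, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, score1,
                                              levels = c(0, 1),
                                              direction = "<")))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-10)
})

test_that("jaccard index matches hand tallies and the accuracy identity", {
  expect_identical(jaccard_index(0:4, 0:4), 1)
  expect_identical(jaccard_index(c(0, 0, 1), c(1, 1, 0)), 0)
  truth <- c(0L, 0L, 1L, 1L); pred <- c(0L, 1L, 1L, 1L)
  # class 0: tp 1, fn 1, fp 0 -> 1/2; class 1: tp 2, fp 1 -> 2/3
  expect_equal(jaccard_index(truth, pred, "macro"), (1 / 2 + 2 / 3) / 2)
  expect_equal(jaccard_index(truth, pred, "micro"), 3 / 5)
  expect_error(jaccard_index(0:2, 0:3), "length mismatch")

  # micro-jaccard is a/(2 - a) for exact-match accuracy a
  set.seed(44)
  for (i in 1:25) {
    t5 <- sample(0:4, 60, replace = TRUE)
    p5 <- ifelse(stats::runif(60) < 0.6, t5, sample(0:4, 60, replace = TRUE))
    a <- mean(t5 == p5)
    expect_equal(jaccard_index(t5, p5), a / (2 - a))
  }
})

test_that("evaluate_all is deterministic and separable data scores highly", {
  b <- blob_features()
  fm <- structure(as.data.frame(b$x), names = c("f1", "f2"))
  fm$label <- b$labels
  class(fm) <- c("feature_matrix", "data.frame")
  r1 <- suppressWarnings(evaluate_all(fm, split_spec(0.8, seed = 4)))
  r2 <- suppressWarnings(evaluate_all(fm, split_spec(0.8, seed = 4)))
  expect_equal(r1$algorithms, r2$algorithms)
  for (alg in r1$algorithms) {
    expect_gte(alg$jaccard$test_micro, 0.9)
    expect_true(all(alg$per_class$sensitivity <= 100, na.rm = TRUE))
  }
})

test_that("accuracy lies between weighted extremes of sensitivity and specificity", {
  set.seed(45)
  for (i in 1:20) {
    truth <- sample(0:4, 80, replace = TRUE)
    pred <- sample(0:4, 80, replace = TRUE)
    grid <- confusion_matrix(truth, pred, 5)
    for (cl in 0:4) {
      cc <- binary_counts(grid, cl)
      m <- derived_metrics(cc)
      if (anyNA(m)) next
      lo <- min(m$sensitivity, m$specificity)
      hi <- max(m$sensitivity, m$specificity)
      expect_gte(m$accuracy, lo - 1e-9)
      expect_lte(m$accuracy, hi + 1e-9)
    }
  }
})
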