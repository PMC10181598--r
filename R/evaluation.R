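#' Train/test split specification
#'
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param seed Integer seed controlling the shuffle (default 4).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 4L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a feature matrix
#'
#' Shuffles within each class and allocates training rows per class by the
#' largest-remainder rule, so the total training size equals
#' `floor(train_fraction * n)` and each class's share is within one row of
#' its target. The same seed always yields the same partition.
#'
#' @param matrix A `feature_matrix` (or data.frame with a `label` column);
#'   every class needs at least 2 rows.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`, each a subset of
#'   `matrix` (class and attributes preserved), plus `train_idx` and
#'   `test_idx` row indices.
#' @export
train_test_split <- function(matrix, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- matrix$label
  if (is.null(labels)) stop("matrix must carry a label column", call. = FALSE)
  classes <- sort(unique(labels))
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(sizes < 2L)) {
    stop("every class needs at least 2 rows", call. = FALSE)
  }
  total_train <- floor(spec$train_fraction * length(labels))
  targets <- spec$train_fraction * sizes
  take <- floor(targets)
  take <- pmax(take, 1L)                       # never empty a class's train side
  take <- pmin(take, sizes - 1L)               # nor its test side
  short <- total_train - sum(take)
  if (short > 0) {
    # distribute remaining rows by largest fractional remainder
    rem <- targets - floor(targets)
    ord <- order(rem, decreasing = TRUE)
    for (j in ord) {
      if (short == 0) break
      if (take[j] < sizes[j] - 1L) { take[j] <- take[j] + 1L; short <- short - 1L }
    }
  }
  set.seed(spec$seed)
  train_idx <- integer(0)
  for (j in seq_along(classes)) {
    rows <- which(labels == classes[j])
    rows <- rows[sample.int(length(rows))]
    train_idx <- c(train_idx, rows[seq_len(take[j])])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  subset_keep <- function(idx) {
    out <- matrix[idx, , drop = FALSE]
    attributes(out)[c("window_width", "level", "mother")] <-
      attributes(matrix)[c("window_width", "level", "mother")]
    class(out) <- class(matrix)
    rownames(out) <- NULL
    out
  }
  list(train = subset_keep(train_idx), test = subset_keep(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Confusion matrix
#'
#' @param truth,predicted Equal-length integer label vectors.
#' @param n_classes Number of classes (grid is `n_classes x n_classes`,
#'   default 5).
#' @return Integer matrix `grid[t + 1, p + 1]` = count of samples with true
#'   class `t` predicted as `p`.
#' @export
confusion_matrix <- function(truth, predicted, n_classes = 5L) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(c(truth, predicted) < 0L) || any(c(truth, predicted) >= n_classes)) {
    stop("labels out of range 0..", n_classes - 1L, call. = FALSE)
  }
  lev <- 0:(n_classes - 1L)
  grid <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.integer(grid), n_classes, n_classes,
              dimnames = list(truth = lev, predicted = lev))
  m
}

#' One-vs-rest confusion counts
#'
#' Reduces a multiclass grid to the TP/TN/FP/FN quadruple of one class.
#'
#' @param grid A [confusion_matrix()] result.
#' @param class Class id (0-based).
#' @return A [confusion_counts()] object.
#' @export
binary_counts <- function(grid, class) {
  class <- as.integer(class)
  if (class < 0L || class >= nrow(grid)) stop("class out of range", call. = FALSE)
  i <- class + 1L
  tp <- grid[i, i]
  fn <- sum(grid[i, ]) - tp
  fp <- sum(grid[, i]) - tp
  tn <- sum(grid) - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' TP/TN/FP/FN quadruple
#'
#' Counts may be fractional (averaged report rows are accepted as worked
#' examples); all must be non-negative with a positive total.
#'
#' @param tp,tn,fp,fn Non-negative numbers.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || sum(v) <= 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and precision
#'
#' Derives the four report percentages from a TP/TN/FP/FN quadruple:
#' sensitivity `100 TP/(TP+FN)`, specificity `100 TN/(TN+FP)`, accuracy
#' `100 (TP+TN)/(TP+TN+FP+FN)` and precision `100 TP/(TP+FP)`. A metric
#' whose denominator is zero is undefined and reported as `NA` (never a
#' propagating `NaN`). Values are unrounded; round only for presentation.
#'
#' @param counts A [confusion_counts()] object.
#' @return A one-row `data.frame` with columns `sensitivity`,
#'   `specificity`, `accuracy`, `precision` (percent).
#' @export
derived_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(numer, denom) if (denom > 0) 100 * numer / denom else NA_real_
  with(counts, data.frame(
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    precision = safe(tp, tp + fp)
  ))
}

#' Micro-averaged one-vs-rest ROC curve
#'
#' Pools every (score, indicator) pair across classes — row `i`, class `c`
#' contributes score `scores[i, c]` with positive indicator
#' `truth[i] == c` — and sweeps the decision cutoff over all distinct
#' scores. Tied scores move as one block, so a constant score yields the
#' chance diagonal (AUC 0.5). Also reports sensitivity and specificity at
#' the fixed cutoff 0.5.
#'
#' @param scores Numeric matrix, one column per class (columns named by
#'   class id) of per-class scores.
#' @param truth Integer true labels, one per row.
#' @return An object of class `roc_curve`: `points` (data.frame with
#'   `cutoff`, `fpr`, `tpr`), `auc` (trapezoidal), and `at_cutoff`
#'   (sensitivity/specificity percentages at cutoff 0.5).
#' @export
roc_curve <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.integer(truth)
  if (nrow(scores) != length(truth)) stop("scores/labels mismatch", call. = FALSE)
  if (length(unique(truth)) < 2L) {
    stop("single-class truth: need at least one positive and one negative class",
         call. = FALSE)
  }
  classes <- as.integer(colnames(scores))
  pos <- as.vector(vapply(classes, function(cl) truth == cl,
                          logical(length(truth))))
  s <- as.vector(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; pos_ord <- pos[ord]
  tp <- cumsum(pos_ord); fp <- cumsum(!pos_ord)
  block_end <- c(which(diff(s_ord) != 0), length(s_ord))
  pts <- data.frame(cutoff = c(Inf, s_ord[block_end]),
                    fpr = c(0, fp[block_end] / n_neg),
                    tpr = c(0, tp[block_end] / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  hard <- s >= 0.5
  at_cutoff <- c(sensitivity = 100 * sum(hard & pos) / n_pos,
                 specificity = 100 * sum(!hard & !pos) / n_neg)
  structure(list(points = pts, auc = auc, at_cutoff = at_cutoff),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f; at cutoff 0.5: sens %.1f%%, spec %.1f%%\n",
              x$auc, x$at_cutoff["sensitivity"], x$at_cutoff["specificity"]))
  invisible(x)
}

#' Jaccard index of two label sequences
#'
#' Intersection-over-union agreement between predicted and true labels.
#' `micro` (default) pools the per-class counts,
#' `sum TP_c / sum (TP_c + FP_c + FN_c)`; `macro` averages the per-class
#' IoU `TP/(TP+FP+FN)` over the classes present in either sequence.
#'
#' @param truth,predicted Equal-length integer label vectors.
#' @param mode `"micro"` or `"macro"`.
#' @return A score in `[0, 1]`.
#' @export
jaccard_index <- function(truth, predicted, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  classes <- sort(unique(c(truth, predicted)))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    c(tp, tp + fp + fn)
  }, numeric(2))
  if (mode == "micro") {
    sum(per_class[1, ]) / sum(per_class[2, ])
  } else {
    iou <- per_class[1, ] / per_class[2, ]
    iou[per_class[2, ] == 0] <- 1  # class absent everywhere: perfect agreement
    mean(iou)
  }
}

#' Train and evaluate all three classifiers
#'
#' Splits the feature matrix, fits the KNN, SVM and decision-tree models on
#' the training side with the supplied hyperparameters, and reports per
#' algorithm: train and test Jaccard indices (micro and macro), the test
#' confusion grid, per-class metric rows and the micro-averaged ROC summary
#' (scores are KNN vote fractions, SVM decision values and tree leaf
#' proportions). Deterministic for a fixed split seed.
#'
#' @param matrix A labelled `feature_matrix`.
#' @param split A [split_spec()].
#' @param knn_k Neighbour count for KNN (default 4).
#' @param svm_c SVM cost (default 14.5).
#' @param kernel SVM [kernel_params()].
#' @param max_nodes Decision-tree node budget (default 10).
#' @return An object of class `eog_report`: list with `split_sizes`,
#'   `models` and per-algorithm results under `algorithms`.
#' @export
evaluate_all <- function(matrix, split = split_spec(), knn_k = 4L,
                         svm_c = 14.5, kernel = kernel_params(),
                         max_nodes = 10L) {
  parts <- train_test_split(matrix, split)
  train <- parts$train; test <- parts$test
  n_classes <- 5L
  models <- list(
    knn = knn_fit(train, k = knn_k),
    svm = svm_fit(train, C = svm_c, kernel = kernel),
    dt = dt_fit(train, max_nodes = max_nodes)
  )
  score_of <- function(name, model, data) {
    switch(name,
           knn = predict(model, data, type = "prob"),
           svm = predict(model, data, type = "decision"),
           dt = predict(model, data, type = "prob"))
  }
  algorithms <- lapply(names(models), function(name) {
    model <- models[[name]]
    pred_train <- predict(model, train)
    pred_test <- predict(model, test)
    grid <- confusion_matrix(test$label, pred_test, n_classes)
    per_class <- do.call(rbind, lapply(0:(n_classes - 1L), function(cl) {
      cbind(data.frame(class = cl), derived_metrics(binary_counts(grid, cl)))
    }))
    roc <- roc_curve(score_of(name, model, test), test$label)
    list(
      jaccard = list(
        train_micro = jaccard_index(train$label, pred_train),
        test_micro = jaccard_index(test$label, pred_test),
        train_macro = jaccard_index(train$label, pred_train, "macro"),
        test_macro = jaccard_index(test$label, pred_test, "macro")),
      accuracy = list(train = mean(pred_train == train$label),
                      test = mean(pred_test == test$label)),
      confusion = grid,
      per_class = per_class,
      roc = list(auc = roc$auc, at_cutoff = roc$at_cutoff)
    )
  })
  names(algorithms) <- names(models)
  structure(list(split_sizes = c(train = nrow(train), test = nrow(test)),
                 split = split, models = models, algorithms = algorithms),
            class = "eog_report")
}

#' @export
print.eog_report <- function(x, ...) {
  cat(sprintf("<eog_report> train %d / test %d windows\n",
              x$split_sizes["train"], x$split_sizes["test"]))
  for (name in names(x$algorithms)) {
    a <- x$algorithms[[name]]
    cat(sprintf("  %-3s  Jaccard train %.3f / test %.3f   AUC %.3f\n",
                name, a$jaccard$train_micro, a$jaccard$test_micro, a$roc$auc))
  }
  invisible(x)
}
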