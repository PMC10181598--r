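#' Euclidean distance between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(sum((y - x)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((as.numeric(y) - as.numeric(x))^2))
}

# z-score standardisation fitted on training data; constant columns keep
# scale 1 so they map to 0 rather than NaN.
fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

as_feature_input <- function(x) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$label
    x <- as.matrix(x[, setdiff(names(x), "label"), drop = FALSE])
    attr(x, "labels") <- labels
  } else {
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' Fit a k-nearest-neighbour classifier
#'
#' Stores the (optionally z-scored) training vectors; prediction assigns
#' the majority class among the `k` training points nearest in Euclidean
#' distance. Vote ties break towards the class with the nearer neighbour
#' within the `k`-set, then towards the lower class id; equal distances
#' rank in training order, so prediction is fully deterministic.
#'
#' @param x Numeric feature matrix (or a `feature_matrix`, whose `label`
#'   column then supplies `labels`).
#' @param labels Integer class labels, one per row of `x`.
#' @param k Neighbour count, `1 <= k <= nrow(x)` (default 4).
#' @param standardize z-score features using training statistics
#'   (default `TRUE`).
#' @return An object of class `eog_knn`.
#' @export
knn_fit <- function(x, labels = attr(x, "labels"), k = 4L, standardize = TRUE) {
  x <- as_feature_input(x)
  labels <- as.integer(labels)
  if (!nrow(x)) stop("empty training set", call. = FALSE)
  if (length(labels) != nrow(x)) stop("labels must match rows of x", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) stop("k must lie in 1..nrow(x)", call. = FALSE)
  std <- if (standardize) fit_standardizer(x) else NULL
  if (!is.null(std)) x <- apply_standardizer(x, std)
  structure(list(x = x, labels = labels, k = k, standardizer = std),
            class = "eog_knn")
}

#' @export
print.eog_knn <- function(x, ...) {
  cat(sprintf("<eog_knn> k = %d, %d training vectors, %d features\n",
              x$k, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Predict with a k-nearest-neighbour model
#'
#' @param object An `eog_knn` model.
#' @param newdata Feature matrix of query rows.
#' @param type `"class"` for hard labels, `"prob"` for the per-class vote
#'   fractions among the `k` neighbours.
#' @param ... Unused.
#' @return Integer labels, or a matrix of vote fractions with one column
#'   per class present in training.
#' @export
predict.eog_knn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_input(newdata)
  if (ncol(newdata) != ncol(object$x)) stop("dimension mismatch", call. = FALSE)
  if (!is.null(object$standardizer)) {
    newdata <- apply_standardizer(newdata, object$standardizer)
  }
  classes <- sort(unique(object$labels))
  probs <- matrix(0, nrow(newdata), length(classes),
                  dimnames = list(NULL, classes))
  pred <- integer(nrow(newdata))
  train_sq <- rowSums(object$x^2)
  for (i in seq_len(nrow(newdata))) {
    q <- newdata[i, ]
    d2 <- train_sq - 2 * drop(object$x %*% q) + sum(q^2)
    ord <- order(d2)  # stable: distance ties rank in training order
    nb <- ord[seq_len(object$k)]
    votes <- table(factor(object$labels[nb], levels = classes))
    probs[i, ] <- as.numeric(votes) / object$k
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) > 1L) {
      # nearer neighbour wins; then lower class id
      first_rank <- vapply(top, function(cl) {
        match(TRUE, object$labels[nb] == cl)
      }, integer(1))
      top <- top[first_rank == min(first_rank)]
    }
    pred[i] <- min(top)
  }
  if (type == "class") pred else probs
}
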