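#' Gini impurity of a class distribution
#'
#' @param class_proportions Non-negative proportions summing to 1
#'   (tolerance 1e-9).
#' @return `1 - sum(p_i^2)`.
#' @export
#' @examples
#' gini(1)                 # pure node -> 0
#' gini(c(0.5, 0.5))       # -> 0.5
#' gini(rep(0.2, 5))       # uniform over 5 classes -> 0.8
gini <- function(class_proportions) {
  p <- as.numeric(class_proportions)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  1 - sum(p^2)
}

# Best axis-parallel split of one node: exhaustive search over every
# feature and every midpoint between consecutive distinct sorted values,
# minimising the size-weighted child Gini. Ties break towards the lower
# feature index, then the lower threshold. Returns NULL when no split
# improves on the parent impurity.
best_split <- function(x, labels, classes) {
  n <- length(labels)
  counts <- table(factor(labels, levels = classes))
  parent <- gini(as.numeric(counts) / n)
  best <- NULL
  for (fj in seq_len(ncol(x))) {
    v <- x[, fj]
    ord <- order(v)
    vs <- v[ord]
    ls <- labels[ord]
    # cumulative class counts along the sorted order
    cum <- apply(vapply(classes, function(cl) cumsum(ls == cl),
                        numeric(n)), 2, identity)
    distinct <- which(diff(vs) > 0)
    for (cut in distinct) {
      nl <- cut; nr <- n - cut
      left <- cum[cut, ]; right <- as.numeric(counts) - left
      g <- (nl * (1 - sum((left / nl)^2)) +
              nr * (1 - sum((right / nr)^2))) / n
      if (g < parent - 1e-12 &&
          (is.null(best) || g < best$gini - 1e-12)) {
        best <- list(feature = fj, threshold = (vs[cut] + vs[cut + 1]) / 2,
                     gini = g, decrease = parent - g)
      }
    }
  }
  best
}

#' Fit a Gini decision tree with a node budget
#'
#' Grows a binary classification tree by recursive partitioning: each
#' split is the (feature, threshold) pair minimising the size-weighted
#' Gini impurity of the children, found by exhaustive midpoint search.
#' Growth is best-first (the candidate leaf whose best split decreases
#' impurity most is expanded next) and stops when the total node count
#' (internal + leaves) would exceed `max_nodes`, when every leaf is pure,
#' or when no split improves impurity. Leaves predict their majority
#' class, ties towards the lower class id.
#'
#' @param x Numeric feature matrix (or a `feature_matrix`).
#' @param labels Integer class labels.
#' @param max_nodes Node budget counting internal and leaf nodes
#'   (default 10).
#' @return An object of class `eog_tree` whose `nodes` data.frame lists
#'   one row per node (split feature/threshold for internal nodes, class
#'   and class proportions for leaves).
#' @export
dt_fit <- function(x, labels = attr(x, "labels"), max_nodes = 10L) {
  x <- as_feature_input(x)
  labels <- as.integer(labels)
  if (!nrow(x)) stop("empty training set", call. = FALSE)
  if (length(labels) != nrow(x)) stop("labels must match rows of x", call. = FALSE)
  if (any(!is.finite(x))) stop("feature values must be finite", call. = FALSE)
  max_nodes <- as.integer(max_nodes)
  classes <- sort(unique(labels))

  leaf_payload <- function(rows) {
    counts <- table(factor(labels[rows], levels = classes))
    props <- as.numeric(counts) / length(rows)
    list(class = classes[which.max(counts)], props = props)
  }

  # nodes: list of lists; id 1 is the root
  nodes <- list(list(id = 1L, rows = seq_len(nrow(x)), is_leaf = TRUE,
                     split = NULL, left = NA_integer_, right = NA_integer_,
                     payload = leaf_payload(seq_len(nrow(x)))))
  n_nodes <- 1L
  repeat {
    if (n_nodes + 2L > max_nodes) break
    # best candidate expansion across all current leaves
    cand_id <- NA_integer_; cand <- NULL
    for (nd in nodes) {
      if (!nd$is_leaf || length(unique(labels[nd$rows])) < 2L) next
      sp <- best_split(x[nd$rows, , drop = FALSE], labels[nd$rows], classes)
      if (is.null(sp)) next
      # weight by node size so the most impurity is removed globally
      sp$weighted <- sp$decrease * length(nd$rows)
      if (is.null(cand) || sp$weighted > cand$weighted) {
        cand <- sp; cand_id <- nd$id
      }
    }
    if (is.null(cand)) break
    nd <- nodes[[cand_id]]
    go_left <- x[nd$rows, cand$feature] <= cand$threshold
    left_rows <- nd$rows[go_left]; right_rows <- nd$rows[!go_left]
    lid <- n_nodes + 1L; rid <- n_nodes + 2L
    nodes[[cand_id]]$is_leaf <- FALSE
    nodes[[cand_id]]$split <- list(feature = cand$feature,
                                   threshold = cand$threshold)
    nodes[[cand_id]]$left <- lid
    nodes[[cand_id]]$right <- rid
    nodes[[lid]] <- list(id = lid, rows = left_rows, is_leaf = TRUE,
                         split = NULL, left = NA_integer_,
                         right = NA_integer_, payload = leaf_payload(left_rows))
    nodes[[rid]] <- list(id = rid, rows = right_rows, is_leaf = TRUE,
                         split = NULL, left = NA_integer_,
                         right = NA_integer_, payload = leaf_payload(right_rows))
    n_nodes <- n_nodes + 2L
  }
  for (i in seq_along(nodes)) nodes[[i]]$rows <- NULL
  structure(list(nodes = nodes, classes = classes, max_nodes = max_nodes,
                 n_nodes = n_nodes),
            class = "eog_tree")
}

#' @export
print.eog_tree <- function(x, ...) {
  n_leaves <- sum(vapply(x$nodes, function(nd) nd$is_leaf, logical(1)))
  cat(sprintf("<eog_tree> %d nodes (%d leaves), budget %d\n",
              x$n_nodes, n_leaves, x$max_nodes))
  invisible(x)
}

#' Predict with a decision tree
#'
#' @param object An `eog_tree` model.
#' @param newdata Feature matrix of query rows.
#' @param type `"class"` for hard labels, `"prob"` for leaf class
#'   proportions.
#' @param ... Unused.
#' @return Integer labels or a matrix of leaf proportions (one column per
#'   training class).
#' @export
predict.eog_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_input(newdata)
  n <- nrow(newdata)
  pred <- integer(n)
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_len(n)) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (nd$is_leaf) break
      id <- if (newdata[i, nd$split$feature] <= nd$split$threshold) {
        nd$left
      } else {
        nd$right
      }
    }
    pred[i] <- nd$payload$class
    probs[i, ] <- nd$payload$props
  }
  if (type == "class") pred else probs
}
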