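#' Polynomial kernel parameters
#'
#' The kernel is `K(a, b) = (gamma * <a, b> + r)^degree` with `gamma > 0`.
#'
#' @param gamma Positive scale; `NULL` (default) means `1 / n_features`,
#'   resolved at fit time.
#' @param r Offset (default 1).
#' @param degree Positive integer degree (default 3).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(gamma = NULL, r = 1, degree = 3L) {
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be positive", call. = FALSE)
  }
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be a positive integer", call. = FALSE)
  structure(list(gamma = gamma, r = r, degree = degree),
            class = "kernel_params")
}

#' Evaluate the polynomial kernel
#'
#' @param a,b Numeric vectors of equal length.
#' @param params A [kernel_params()] with `gamma` set.
#' @return `(gamma * <a, b> + r)^degree`.
#' @export
poly_kernel <- function(a, b, params = kernel_params(gamma = 1)) {
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  if (is.null(params$gamma)) stop("gamma must be set", call. = FALSE)
  (params$gamma * sum(as.numeric(a) * as.numeric(b)) + params$r)^params$degree
}

# Gram matrix of the polynomial kernel between row sets.
poly_kernel_matrix <- function(x, y, params) {
  (params$gamma * tcrossprod(x, y) + params$r)^params$degree
}

# Soft-margin binary SVM dual, solved by pairwise coordinate (SMO-style)
# updates on a precomputed Gram matrix. y in {-1, +1}. For each
# KKT-violating index the working partner is tried in decreasing
# |E_i - E_j| order until one admits progress (the single-candidate
# shortcut of the simplified algorithm can stall on a feasible but
# suboptimal point); sweeps repeat until a full pass makes no update or
# max_sweeps is reached.
smo_binary <- function(K, y, C, tol = 1e-4, max_sweeps = 60L) {
  n <- length(y)
  env <- new.env()
  env$alpha <- numeric(n)
  env$b <- 0
  env$f <- numeric(n)  # decision values K %*% (alpha * y) + b

  try_pair <- function(i, j) {
    Ei <- env$f[i] - y[i]; Ej <- env$f[j] - y[j]
    ai_old <- env$alpha[i]; aj_old <- env$alpha[j]
    if (y[i] != y[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    if (L >= H) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= -1e-12) return(FALSE)
    aj <- aj_old - y[j] * (Ei - Ej) / eta
    aj <- min(max(aj, L), H)
    if (abs(aj - aj_old) < 1e-10) return(FALSE)
    ai <- ai_old + y[i] * y[j] * (aj_old - aj)
    b1 <- env$b - Ei - y[i] * (ai - ai_old) * K[i, i] -
      y[j] * (aj - aj_old) * K[i, j]
    b2 <- env$b - Ej - y[i] * (ai - ai_old) * K[i, j] -
      y[j] * (aj - aj_old) * K[j, j]
    b_new <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
      (b1 + b2) / 2
    env$f <- env$f + y[i] * (ai - ai_old) * K[, i] +
      y[j] * (aj - aj_old) * K[, j] + (b_new - env$b)
    env$alpha[i] <- ai; env$alpha[j] <- aj; env$b <- b_new
    TRUE
  }

  examine <- function(idx) {
    changed <- 0L
    for (i in idx) {
      Ei <- env$f[i] - y[i]
      if (!((y[i] * Ei < -tol && env$alpha[i] < C) ||
            (y[i] * Ei > tol && env$alpha[i] > 0))) next
      cand <- order(abs(Ei - (env$f - y)), decreasing = TRUE)
      for (j in cand) {
        if (j == i) next
        if (try_pair(i, j)) { changed <- changed + 1L; break }
      }
    }
    changed
  }

  converged <- FALSE
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) break
    if (examine(seq_len(n)) == 0L) { converged <- TRUE; break }
    # optimise over the non-bound set until it is self-consistent
    repeat {
      sweeps <- sweeps + 1L
      if (sweeps > max_sweeps) break
      nb <- which(env$alpha > 1e-10 & env$alpha < C - 1e-10)
      if (!length(nb) || examine(nb) == 0L) break
    }
  }
  list(alpha = env$alpha, b = env$b, converged = converged)
}

#' Fit a one-vs-rest polynomial-kernel SVM
#'
#' Trains one soft-margin binary machine per class (that class against the
#' rest), each solved in the dual by SMO-style pairwise updates to the
#' stated tolerance. Prediction takes the class with the largest decision
#' value, ties towards the lower class id.
#'
#' @param x Numeric feature matrix (or a `feature_matrix`).
#' @param labels Integer class labels (at least two classes).
#' @param C Regularisation cost (> 0, default 14.5): larger values penalise
#'   margin violations harder.
#' @param kernel A [kernel_params()]; a `NULL` gamma resolves to
#'   `1 / n_features`.
#' @param standardize z-score features on training statistics (default `TRUE`).
#' @param tol KKT violation tolerance for the solver (default 1e-4).
#' @param max_sweeps Sweep budget per binary problem; exceeding it leaves a
#'   warning, never a silent failure.
#' @return An object of class `eog_svm`.
#' @export
svm_fit <- function(x, labels = attr(x, "labels"), C = 14.5,
                    kernel = kernel_params(), standardize = TRUE,
                    tol = 1e-4, max_sweeps = 60L) {
  x <- as_feature_input(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of x", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("C must be positive", call. = FALSE)
  if (is.null(kernel$gamma)) kernel$gamma <- 1 / ncol(x)
  std <- if (standardize) fit_standardizer(x) else NULL
  if (!is.null(std)) x <- apply_standardizer(x, std)
  K <- poly_kernel_matrix(x, x, kernel)
  machines <- lapply(classes, function(cl) {
    y <- ifelse(labels == cl, 1, -1)
    fit <- smo_binary(K, y, C, tol = tol)
    if (!fit$converged) {
      warning("SMO did not fully converge for class ", cl,
              " within the sweep budget", call. = FALSE)
    }
    sv <- which(fit$alpha > 1e-12)
    list(class = cl, alpha = fit$alpha[sv], y = y[sv], sv = sv, b = fit$b,
         converged = fit$converged)
  })
  structure(list(x = x, machines = machines, classes = classes, C = C,
                 kernel = kernel, standardizer = std, tol = tol),
            class = "eog_svm")
}

#' @export
print.eog_svm <- function(x, ...) {
  nsv <- vapply(x$machines, function(m) length(m$sv), integer(1))
  cat(sprintf("<eog_svm> one-vs-rest, C = %g, kernel (%g x + %g)^%d\n",
              x$C, x$kernel$gamma, x$kernel$r, x$kernel$degree))
  cat("  support vectors per class:", paste(nsv, collapse = ", "), "\n")
  invisible(x)
}

#' Predict with a one-vs-rest SVM
#'
#' @param object An `eog_svm` model.
#' @param newdata Feature matrix of query rows.
#' @param type `"class"` for hard labels, `"decision"` for the per-class
#'   decision values.
#' @param ... Unused.
#' @return Integer labels or a decision-value matrix (one column per class).
#' @export
predict.eog_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_input(newdata)
  if (ncol(newdata) != ncol(object$x)) stop("dimension mismatch", call. = FALSE)
  if (!is.null(object$standardizer)) {
    newdata <- apply_standardizer(newdata, object$standardizer)
  }
  dec <- vapply(object$machines, function(m) {
    Kq <- poly_kernel_matrix(newdata, object$x[m$sv, , drop = FALSE],
                             object$kernel)
    drop(Kq %*% (m$alpha * m$y)) + m$b
  }, numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata),
                dimnames = list(NULL, object$classes))
  if (type == "decision") return(dec)
  object$classes[apply(dec, 1, which.max)]  # which.max: ties -> lowest id
}

# Dual feasibility diagnostics for tests: box constraints and the equality
# constraint sum(alpha_i y_i) = 0 per binary machine.
svm_dual_gaps <- function(model) {
  vapply(model$machines, function(m) {
    c(box_low = min(0, min(m$alpha)),
      box_high = max(0, max(m$alpha - model$C)),
      equality = abs(sum(m$alpha * m$y)))
  }, numeric(3))
}
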