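#' Save a fitted classifier to a versioned JSON document
#'
#' All three model classes (`eog_knn`, `eog_svm`, `eog_tree`) serialise to
#' a plain JSON file holding their hyperparameters and fitted parameters,
#' so a trained model is inspectable and portable across sessions.
#'
#' @param model A fitted classifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1]
  if (!kind %in% c("eog_knn", "eog_svm", "eog_tree")) {
    stop("not a serialisable model: ", kind, call. = FALSE)
  }
  payload <- unclass(model)
  if (kind %in% c("eog_knn", "eog_svm")) {
    payload$x <- apply(payload$x, 1, identity, simplify = FALSE)  # row list
  }
  if (!is.null(payload$kernel)) payload$kernel <- unclass(payload$kernel)
  doc <- list(format = "eogwave-model", version = 1L, kind = kind,
              payload = payload)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

num <- function(v) as.numeric(unlist(v))
int <- function(v) as.integer(unlist(v))

#' Load a classifier saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The fitted model with its class restored.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "eogwave-model")) {
    stop("not an eogwave model file: ", path, call. = FALSE)
  }
  p <- doc$payload
  restore_std <- function(s) {
    if (is.null(s)) NULL else list(center = num(s$center), scale = num(s$scale))
  }
  restore_x <- function(rows) {
    do.call(rbind, lapply(rows, num))
  }
  out <- switch(doc$kind,
    eog_knn = list(x = restore_x(p$x), labels = int(p$labels), k = int(p$k),
                   standardizer = restore_std(p$standardizer)),
    eog_svm = list(
      x = restore_x(p$x),
      machines = lapply(p$machines, function(m) {
        list(class = int(m$class), alpha = num(m$alpha), y = num(m$y),
             sv = int(m$sv), b = num(m$b), converged = isTRUE(m$converged))
      }),
      classes = int(p$classes), C = num(p$C),
      kernel = structure(list(gamma = num(p$kernel$gamma),
                              r = num(p$kernel$r),
                              degree = int(p$kernel$degree)),
                         class = "kernel_params"),
      standardizer = restore_std(p$standardizer), tol = num(p$tol)),
    eog_tree = list(
      nodes = lapply(p$nodes, function(nd) {
        list(id = int(nd$id), is_leaf = isTRUE(nd$is_leaf),
             split = if (is.null(nd$split)) NULL else
               list(feature = int(nd$split$feature),
                    threshold = num(nd$split$threshold)),
             left = if (is.null(nd$left)) NA_integer_ else int(nd$left),
             right = if (is.null(nd$right)) NA_integer_ else int(nd$right),
             payload = list(class = int(nd$payload$class),
                            props = num(nd$payload$props)))
      }),
      classes = int(p$classes), max_nodes = int(p$max_nodes),
      n_nodes = int(p$n_nodes)),
    stop("unknown model kind: ", doc$kind, call. = FALSE)
  )
  structure(out, class = doc$kind)
}
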