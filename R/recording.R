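#' Class labels for the five eye movements
#'
#' Returns the mapping between movement names and integer class ids used
#' throughout the package: down = 0, blink = 1, up = 2, left = 3, right = 4.
#'
#' @return A named integer vector of length 5.
#' @export
#' @examples
#' eog_class_map()
eog_class_map <- function() {
  c(down = 0L, blink = 1L, up = 2L, left = 3L, right = 4L)
}

#' Construct a two-channel EOG recording
#'
#' An `eog_recording` holds the horizontal and vertical electrode voltages
#' (in volts, post-amplification), the sampling rate and, optionally, a
#' per-sample class label (integer 0-4, see [eog_class_map()]).
#'
#' @param horizontal Numeric vector, horizontal-channel voltage in volts.
#' @param vertical Numeric vector, vertical-channel voltage in volts; must
#'   have the same length as `horizontal`.
#' @param sampling_rate Sampling rate in Hz (single positive number).
#' @param labels Optional integer vector of per-sample class ids (0-4) the
#'   same length as the channels, or `NULL` for an unlabelled recording.
#' @return An object of class `eog_recording`.
#' @export
eog_recording <- function(horizontal, vertical, sampling_rate, labels = NULL) {
  horizontal <- as.numeric(horizontal)
  vertical <- as.numeric(vertical)
  if (length(horizontal) != length(vertical)) {
    stop("horizontal and vertical channels must have equal length", call. = FALSE)
  }
  if (anyNA(horizontal) || anyNA(vertical)) {
    stop("channel voltages must be numeric and non-missing", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(horizontal)) {
      stop("labels must match channel length", call. = FALSE)
    }
    bad <- labels[!is.na(labels)]
    if (length(bad) && (any(bad < 0L) || any(bad > 4L))) {
      stop("class ids must lie in 0..4", call. = FALSE)
    }
  }
  structure(
    list(horizontal = horizontal, vertical = vertical,
         sampling_rate = as.numeric(sampling_rate), labels = labels),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  n <- length(x$horizontal)
  cat(sprintf("<eog_recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sampling_rate, n / x$sampling_rate))
  rng <- range(c(x$horizontal, x$vertical))
  cat(sprintf("  voltage range: [%.4f, %.4f] V\n", rng[1], rng[2]))
  if (is.null(x$labels)) {
    cat("  unlabelled\n")
  } else {
    tab <- table(factor(x$labels, levels = 0:4))
    cat("  samples per class (0..4):", paste(tab, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a recording
#'
#' @param recording An [eog_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "eog_recording"))
  length(recording$horizontal)
}

#' Build a segment table
#'
#' A segment table assigns a movement class to a block of samples. Rows are
#' normalised to half-open, 0-based blocks `[start, end)`; overlapping rows
#' are rejected.
#'
#' @param class Integer class ids (0-4), one per row.
#' @param start 0-based first sample of each block (inclusive).
#' @param end 0-based end of each block (exclusive).
#' @return A `data.frame` of class `segment_table` with columns
#'   `class`, `start`, `end`.
#' @export
segment_table <- function(class = integer(), start = integer(), end = integer()) {
  class <- as.integer(class); start <- as.integer(start); end <- as.integer(end)
  if (length(class) != length(start) || length(class) != length(end)) {
    stop("class, start, end must have equal length", call. = FALSE)
  }
  if (length(class)) {
    if (any(class < 0L | class > 4L)) stop("class ids must lie in 0..4", call. = FALSE)
    if (any(start < 0L) || any(end <= start)) {
      stop("segments must satisfy 0 <= start < end", call. = FALSE)
    }
    ord <- order(start)
    if (any(utils::head(end[ord], -1) > utils::tail(start[ord], -1))) {
      stop("segments overlap after normalisation", call. = FALSE)
    }
  }
  structure(data.frame(class = class, start = start, end = end),
            class = c("segment_table", "data.frame"))
}

#' Default five-movement acquisition layout
#'
#' The default protocol records five 10-second movement periods in the order
#' down, up, blink, left, right, each spanning `samples_per_segment`
#' consecutive samples (6500 by default, 32,500 in total).
#'
#' @param samples_per_segment Samples per movement period.
#' @param segment_order Character vector of movement names (a permutation of
#'   the names of [eog_class_map()]).
#' @return A [segment_table()] covering `[0, 5 * samples_per_segment)`.
#' @export
default_segment_table <- function(samples_per_segment = 6500L,
                                  segment_order = c("down", "up", "blink",
                                                    "left", "right")) {
  samples_per_segment <- as.integer(samples_per_segment)
  if (samples_per_segment <= 0L) {
    stop("samples_per_segment must be positive", call. = FALSE)
  }
  map <- eog_class_map()
  if (!all(segment_order %in% names(map))) {
    stop("unknown movement name in segment_order", call. = FALSE)
  }
  k <- length(segment_order)
  segment_table(
    class = unname(map[segment_order]),
    start = samples_per_segment * (seq_len(k) - 1L),
    end = samples_per_segment * seq_len(k)
  )
}

#' Label a recording from a segment table
#'
#' Assigns per-sample class labels from the normalised half-open blocks of a
#' [segment_table()]. Samples not covered by any row are left `NA`; an empty
#' table returns the recording unlabelled.
#'
#' @param recording An [eog_recording()].
#' @param table A [segment_table()] whose rows lie within the recording.
#' @return The recording with its `labels` field replaced.
#' @export
apply_segment_table <- function(recording, table) {
  stopifnot(inherits(recording, "eog_recording"),
            inherits(table, "segment_table"))
  n <- n_samples(recording)
  if (nrow(table) == 0L) {
    recording$labels <- NULL
    return(recording)
  }
  if (any(table$end > n)) {
    stop("segment table extends beyond the recording", call. = FALSE)
  }
  labels <- rep(NA_integer_, n)
  for (i in seq_len(nrow(table))) {
    labels[(table$start[i] + 1L):table$end[i]] <- table$class[i]
  }
  recording$labels <- labels
  recording
}
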