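#' Partition a series into fixed-width windows
#'
#' Cuts a numeric series into non-overlapping consecutive windows of
#' `width` samples; a trailing remainder shorter than `width` is discarded
#' (a 2032-coefficient series gives exactly 508 four-sample windows).
#'
#' @param series Non-empty numeric vector.
#' @param width Window width (default 4).
#' @return A matrix with one window per row.
#' @export
make_windows <- function(series, width = 4L) {
  series <- as.numeric(series)
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  if (!length(series)) stop("series is empty", call. = FALSE)
  n_win <- length(series) %/% width
  if (n_win == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = width))
  }
  matrix(series[seq_len(n_win * width)], nrow = n_win, ncol = width, byrow = TRUE)
}

#' Feature names in report order
#'
#' The nine per-channel metrics, horizontal channel first (indices 0-8)
#' then vertical (indices 9-17).
#'
#' @return Character vector of 18 names.
#' @export
feature_names <- function() {
  metrics <- c("RMS", "AMP", "Variance", "Average", "Median",
               "Covariance", "Max", "Pspectrum", "Power")
  c(paste0(metrics, "H"), paste0(metrics, "V"))
}

# Unnormalised periodogram |FFT(x)|^2 / n over the non-negative
# frequencies (DC included).
periodogram_peak <- function(x, reducer = "max") {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  p <- p[seq_len(n %/% 2L + 1L)]
  if (reducer == "max") max(p) else sum(p)
}

#' Per-window feature vector
#'
#' Computes the nine metrics for each channel of one aligned window pair:
#' RMS (root mean square), AMP (peak-to-peak amplitude, max - min),
#' Variance (population, divide-by-n), Average, Median, Covariance
#' (population covariance of this channel's window with the other
#' channel's window, hence identical for both channels), Max, Pspectrum
#' (peak of the unnormalised periodogram) and Power (`sum(x^2) / n`).
#'
#' @param h_window,v_window Numeric vectors of equal width (>= 2):
#'   horizontal and vertical coefficient windows.
#' @param pspectrum_reducer `"max"` (default) or `"sum"`: how the window
#'   periodogram is reduced to the Pspectrum scalar.
#' @return Named numeric vector of length 18 ordered as [feature_names()].
#' @export
window_features <- function(h_window, v_window, pspectrum_reducer = c("max", "sum")) {
  pspectrum_reducer <- match.arg(pspectrum_reducer)
  h_window <- as.numeric(h_window)
  v_window <- as.numeric(v_window)
  w <- length(h_window)
  if (w != length(v_window)) stop("window widths differ", call. = FALSE)
  if (w < 2L) stop("window width must be >= 2", call. = FALSE)
  cov_hv <- mean((h_window - mean(h_window)) * (v_window - mean(v_window)))
  one_channel <- function(x) {
    mu <- mean(x)
    c(RMS = sqrt(mean(x^2)),
      AMP = max(x) - min(x),
      Variance = mean((x - mu)^2),
      Average = mu,
      Median = stats::median(x),
      Covariance = cov_hv,
      Max = max(x),
      Pspectrum = periodogram_peak(x, pspectrum_reducer),
      Power = sum(x^2) / length(x))
  }
  out <- c(one_channel(h_window), one_channel(v_window))
  names(out) <- feature_names()
  out
}

#' Windowed feature matrix of a labelled recording
#'
#' Runs both channels through the multilevel decomposition of the mother
#' wavelet, extracts the detail series at `level`, windows the two series
#' in lockstep and computes [window_features()] per window. Each window is
#' labelled by majority vote over the original samples it derives from
#' (window `w` spans original samples `[w * width * 2^level,
#' (w+1) * width * 2^level)`, clamped to the recording); vote ties break
#' towards the lower class id.
#'
#' @param recording A labelled [eog_recording()].
#' @param mother Mother wavelet ([wavelet_spec()] or name, default
#'   `"rbio3.1"`).
#' @param level Detail level carried forward (default 4).
#' @param width Window width in coefficients (default 4).
#' @param pspectrum_reducer Passed to [window_features()].
#' @return A `data.frame` of class `feature_matrix`: 18 feature columns
#'   named as [feature_names()] plus an integer `label` column; attributes
#'   `window_width`, `level` and `mother` record the construction.
#' @export
build_feature_matrix <- function(recording, mother = "rbio3.1", level = 4L,
                                 width = 4L,
                                 pspectrum_reducer = c("max", "sum")) {
  stopifnot(inherits(recording, "eog_recording"))
  pspectrum_reducer <- match.arg(pspectrum_reducer)
  if (is.null(recording$labels)) {
    stop("recording must be labelled", call. = FALSE)
  }
  mother <- as_wavelet_spec(mother)
  levels_needed <- max(5L, level)
  dh <- decompose(recording$horizontal, mother, levels_needed)
  dv <- decompose(recording$vertical, mother, levels_needed)
  h_win <- make_windows(smoothed_detail(dh, level), width)
  v_win <- make_windows(smoothed_detail(dv, level), width)
  n_win <- nrow(h_win)
  feats <- matrix(0, nrow = n_win, ncol = 18L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(n_win)) {
    feats[i, ] <- window_features(h_win[i, ], v_win[i, ], pspectrum_reducer)
  }
  n <- n_samples(recording)
  span <- width * 2^level
  labels <- integer(n_win)
  for (w in seq_len(n_win)) {
    lo <- (w - 1L) * span + 1L
    hi <- min(w * span, n)
    block <- recording$labels[lo:hi]
    block <- block[!is.na(block)]
    if (!length(block)) {
      labels[w] <- NA_integer_
    } else {
      tab <- table(block)
      best <- names(tab)[tab == max(tab)]
      labels[w] <- min(as.integer(best))
    }
  }
  out <- as.data.frame(feats)
  out$label <- labels
  structure(out, class = c("feature_matrix", "data.frame"),
            window_width = width, level = level, mother = mother$name)
}
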