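#' Shannon entropy of a coefficient series
#'
#' Scores the disorder of a wavelet coefficient series as the Shannon
#' entropy (base 2) of its normalised energy distribution
#' `p_i = c_i^2 / sum(c_j^2)`. Zero-energy coefficients contribute nothing
#' (`0 log 0 = 0`); an all-zero series has no defined distribution and is
#' rejected. The score is invariant to permuting the coefficients and to
#' rescaling them by any non-zero constant.
#'
#' @param coefficients Non-empty numeric vector, not all zero.
#' @return Entropy in bits (non-negative scalar).
#' @export
#' @examples
#' level_entropy(rep(1, 8))          # uniform over 8 -> 3 bits
#' level_entropy(c(5, 0, 0))         # degenerate -> 0 bits
level_entropy <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) || anyNA(coefficients)) {
    stop("coefficients must be non-empty and non-missing", call. = FALSE)
  }
  e <- coefficients^2
  total <- sum(e)
  if (total == 0) {
    stop("entropy undefined for an all-zero series", call. = FALSE)
  }
  p <- e[e > 0] / total
  -sum(p * log2(p))
}

#' Entropy scan over candidate wavelets
#'
#' Decomposes both channels of a recording to `levels` levels under every
#' candidate wavelet and scores each detail level by [level_entropy()],
#' producing the per-family, per-level entropy grid from which the mother
#' wavelet is selected.
#'
#' @param recording An [eog_recording()].
#' @param candidates Character vector of wavelet names (or list of
#'   [wavelet_spec()]s); at least one.
#' @param levels Decomposition depth (default 5).
#' @return A `data.frame` of class `entropy_table` with columns `channel`
#'   (`"horizontal"`/`"vertical"`), `wavelet`, `level` and `entropy` (bits).
#' @export
scan_families <- function(recording,
                          candidates = c("haar", "coif2", "sym4", "meyr",
                                         "bior3.1", "rbio3.1"),
                          levels = 5L) {
  stopifnot(inherits(recording, "eog_recording"))
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  specs <- lapply(candidates, as_wavelet_spec)
  rows <- list()
  for (ch in c("horizontal", "vertical")) {
    for (sp in specs) {
      dec <- decompose(recording[[ch]], sp, levels)
      for (lev in seq_len(levels)) {
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, wavelet = sp$name, level = lev,
          entropy = level_entropy(dec$details[[lev]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("entropy_table", "data.frame"))
}

#' Select the mother wavelet from an entropy table
#'
#' Picks the candidate minimising an aggregate of its entropy scores: by
#' default the sum over all levels and channels present in the table (the
#' least total disorder). Ties break towards the candidate appearing first
#' in the table.
#'
#' @param table An `entropy_table` from [scan_families()].
#' @param rule Aggregation rule: `"sum"` (default) or `"mean"`.
#' @return A [wavelet_spec()] for the winning candidate.
#' @export
select_mother <- function(table, rule = c("sum", "mean")) {
  rule <- match.arg(rule)
  if (!inherits(table, "data.frame") || !nrow(table)) {
    stop("entropy table is empty", call. = FALSE)
  }
  wavelets <- unique(table$wavelet)
  agg <- vapply(wavelets, function(w) {
    e <- table$entropy[table$wavelet == w]
    if (rule == "sum") sum(e) else mean(e)
  }, numeric(1))
  as_wavelet_spec(wavelets[which.min(agg)])
}
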