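# Shared fixtures, built in code.

# Tiny labelled recording: deterministic ramps, 40 samples per class.
tiny_recording <- function(n_per_class = 40L) {
  n <- 5L * n_per_class
  rec <- eog_recording(sin(seq_len(n) / 3), cos(seq_len(n) / 5),
                       sampling_rate = 100)
  apply_segment_table(rec, default_segment_table(n_per_class))
}

# Cached default synthetic recording and feature matrix (seed 4); these are
# deterministic, so computing them once per test run is safe and keeps the
# suite fast.
.fixture_cache <- new.env(parent = emptyenv())

default_recording <- function() {
  if (is.null(.fixture_cache$rec)) {
    .fixture_cache$rec <- generate_recording(synthetic_config())
  }
  .fixture_cache$rec
}

default_features <- function() {
  if (is.null(.fixture_cache$fm)) {
    .fixture_cache$fm <- build_feature_matrix(default_recording())
  }
  .fixture_cache$fm
}

# Small well-separated 5-class Gaussian feature set in 2-D.
blob_features <- function(n_per_class = 20L, sd = 0.3, seed = 1L) {
  set.seed(seed)
  centers <- cbind(c(0, 4, 0, 4, 2), c(0, 0, 4, 4, 2))
  x <- do.call(rbind, lapply(1:5, function(i) {
    cbind(stats::rnorm(n_per_class, centers[i, 1], sd),
          stats::rnorm(n_per_class, centers[i, 2], sd))
  }))
  list(x = x, labels = rep(0:4, each = n_per_class))
}
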