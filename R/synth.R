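#' Configuration for the synthetic EOG generator
#'
#' Describes a five-movement acquisition session: five 10-second periods
#' (down, up, blink, left, right) of `samples_per_segment` samples each,
#' hardware-bandpassed to `band_limits` and digitised with
#' `quantization_bits` bits over the voltage `envelope`.
#'
#' Each movement period is modelled as a train of saccade-and-return cycles:
#' the gaze steps to the deflected position (smoothed sigmoidal rise),
#' holds, and returns to rest. Deflection polarity and channel follow the
#' corneo-retinal dipole: rightward/upward gaze gives positive deflections
#' on the horizontal/vertical channel, leftward/downward negative; blinks
#' are large biphasic spikes dominating the vertical channel with small
#' horizontal crosstalk. On top of the deflection waveform each period
#' carries a sustained narrow-band muscle-tremor tone at `tremor_freq` Hz
#' whose RMS scales with the effort of the movement (`tremor_h`,
#' `tremor_v` per channel), plus Gaussian sensor noise band-limited to the
#' acquisition bandwidth.
#'
#' @param samples_per_segment Samples per movement period (default 6500).
#' @param segment_order Movement order (default down, up, blink, left, right).
#' @param sampling_rate Sampling rate in Hz. Default 650 Hz so that one
#'   6500-sample period spans the protocol's 10 seconds.
#' @param amplitude_map Named list (one entry per movement) of lists with
#'   fields `pulse` (peak deflection in volts, signed; for `blink` a
#'   two-element vector giving the positive and negative lobe), `tremor_h`
#'   and `tremor_v` (RMS of the muscle-tone component per channel, volts).
#' @param noise_sd RMS of the band-limited sensor noise (volts).
#' @param envelope Two-element voltage range the digitiser spans.
#' @param band_limits Acquisition bandwidth in Hz (low, high).
#' @param quantization_bits ADC resolution in bits (>= 1).
#' @param pulse_period_s,transition_s Saccade cycle length and sigmoid
#'   transition time constant, in seconds.
#' @param tremor_freq Frequency of the muscle-tremor tone in Hz
#'   (default 30.5, inside the acquisition band).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(samples_per_segment = 6500L,
                             segment_order = c("down", "up", "blink",
                                               "left", "right"),
                             sampling_rate = 650,
                             amplitude_map = default_amplitude_map(),
                             noise_sd = 0.003,
                             envelope = c(-0.3, 0.5),
                             band_limits = c(0.5, 50),
                             quantization_bits = 11L,
                             pulse_period_s = 1.25,
                             transition_s = 0.1,
                             tremor_freq = 30.5,
                             seed = 4L) {
  samples_per_segment <- as.integer(samples_per_segment)
  if (samples_per_segment <= 0L) {
    stop("samples_per_segment must be positive", call. = FALSE)
  }
  if (!all(segment_order %in% names(eog_class_map()))) {
    stop("unknown movement name in segment_order", call. = FALSE)
  }
  if (length(band_limits) != 2L || band_limits[2] <= band_limits[1]) {
    stop("band_limits must be an increasing (low, high) pair", call. = FALSE)
  }
  if (quantization_bits < 1L) stop("quantization_bits must be >= 1", call. = FALSE)
  if (length(envelope) != 2L || envelope[2] <= envelope[1]) {
    stop("envelope must be an increasing (low, high) pair", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  missing_mv <- setdiff(segment_order, names(amplitude_map))
  if (length(missing_mv)) {
    stop("amplitude_map lacks entries for: ",
         paste(missing_mv, collapse = ", "), call. = FALSE)
  }
  structure(
    list(samples_per_segment = samples_per_segment,
         segment_order = segment_order,
         sampling_rate = sampling_rate,
         amplitude_map = amplitude_map,
         noise_sd = noise_sd,
         envelope = envelope,
         band_limits = band_limits,
         quantization_bits = as.integer(quantization_bits),
         pulse_period_s = pulse_period_s,
         transition_s = transition_s,
         tremor_freq = tremor_freq,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default per-movement amplitudes
#'
#' Peak deflections follow the thresholds seen in typical recordings of
#' this protocol (right +0.24 V / left -0.22 V on the horizontal channel,
#' up +0.19 V / down -0.09 V on the vertical, blink +0.35/-0.15 V biphasic
#' on the vertical with a little horizontal crosstalk). Muscle-tremor RMS
#' scales with movement effort and differs per channel -- blinks
#' co-activate the orbicularis, so they carry the strongest horizontal
#' tremor of the vertical-channel movements -- giving every movement a
#' distinct two-channel signature while keeping the composite within the
#' digitiser envelope.
#'
#' @return Named list suitable for the `amplitude_map` argument of
#'   [synthetic_config()].
#' @export
default_amplitude_map <- function() {
  list(
    down  = list(pulse = -0.09,          tremor_h = 0.004, tremor_v = 0.026),
    up    = list(pulse = +0.19,          tremor_h = 0.004, tremor_v = 0.052),
    blink = list(pulse = c(0.35, -0.15), tremor_h = 0.013, tremor_v = 0.086),
    left  = list(pulse = -0.22,          tremor_h = 0.043, tremor_v = 0.006),
    right = list(pulse = +0.24,          tremor_h = 0.022, tremor_v = 0.006)
  )
}

# Band-limited Gaussian noise via FFT masking: exactly zero energy outside
# [band[1], band[2]] Hz, rescaled to the requested RMS.
band_limited_noise <- function(n, fs, band, sd) {
  if (sd <= 0 || n < 4L) return(numeric(n))
  x <- stats::rnorm(n)
  x <- fft_bandpass(x, fs, band)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sd / s)
}

# Zero all Fourier bins with frequency outside [band[1], band[2]] Hz
# (including DC), keeping conjugate symmetry.
fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f)  # folded (two-sided) frequency axis
  keep <- f >= band[1] & f <= band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Saccade-and-return cycle template on [0, 1): sigmoid rise at 10% of the
# cycle, sigmoid return at 55%, i.e. the gaze holds the deflected position
# for roughly 45% of the cycle.
saccade_cycle <- function(phase, tau) {
  stats::plogis((phase - 0.10) / tau) - stats::plogis((phase - 0.55) / tau)
}

# Biphasic blink spike train: difference of two Gaussians per cycle, the
# positive lobe leading.
blink_cycle <- function(phase, lobes, width = 0.06) {
  lobes[1] * exp(-0.5 * ((phase - 0.30) / width)^2) +
    lobes[2] * exp(-0.5 * ((phase - 0.48) / width)^2)
}

#' Generate a labelled synthetic EOG recording
#'
#' Renders the deterministic movement waveforms described in
#' [synthetic_config()], adds band-limited muscle tone and sensor noise,
#' applies the acquisition bandpass to the composite signal (the hardware
#' front end is AC-coupled, so no energy survives outside the configured
#' band) and digitises both channels over the voltage envelope.
#'
#' @param config A [synthetic_config()].
#' @return A labelled [eog_recording()] whose class layout follows the
#'   configured segment order.
#' @export
generate_recording <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  nseg <- config$samples_per_segment
  n <- nseg * length(config$segment_order)
  h <- numeric(n); v <- numeric(n)

  t_seg <- (0:(nseg - 1)) / fs
  cyc <- config$pulse_period_s
  phase <- (t_seg %% cyc) / cyc
  tau <- config$transition_s / cyc

  for (i in seq_along(config$segment_order)) {
    mv <- config$segment_order[i]
    amp <- config$amplitude_map[[mv]]
    idx <- ((i - 1L) * nseg + 1L):(i * nseg)
    if (mv == "blink") {
      pulse_v <- blink_cycle(phase, amp$pulse)
      pulse_h <- 0.05 * pulse_v
    } else {
      shape <- amp$pulse * saccade_cycle(phase, tau)
      if (mv %in% c("left", "right")) {
        pulse_h <- shape; pulse_v <- numeric(nseg)
      } else {
        pulse_v <- shape; pulse_h <- numeric(nseg)
      }
    }
    tone <- sqrt(2) * sin(2 * pi * config$tremor_freq * t_seg)
    h[idx] <- pulse_h + amp$tremor_h * tone
    v[idx] <- pulse_v + amp$tremor_v * tone
  }

  h <- h + band_limited_noise(n, fs, config$band_limits, config$noise_sd)
  v <- v + band_limited_noise(n, fs, config$band_limits, config$noise_sd)

  # acquisition front end: AC-coupled bandpass over the full session
  h <- fft_bandpass(h, fs, config$band_limits)
  v <- fft_bandpass(v, fs, config$band_limits)

  h <- quantize(h, config$envelope, config$quantization_bits)
  v <- quantize(v, config$envelope, config$quantization_bits)

  rec <- eog_recording(h, v, fs)
  apply_segment_table(rec, default_segment_table(nseg, config$segment_order))
}

# Uniform mid-tread quantiser: 2^bits steps across the envelope, with a
# reconstruction level at exactly 0 V so an all-zero signal is preserved;
# values are clamped to the envelope.
quantize <- function(x, envelope, bits) {
  step <- (envelope[2] - envelope[1]) / 2^bits
  q <- round(x / step)
  q <- pmin(pmax(q, ceiling(envelope[1] / step)), floor(envelope[2] / step))
  q * step
}

#' Blend class structure away to stress classifiers
#'
#' Interpolates every movement block towards the position-wise mean of all
#' blocks: `overlap = 0` returns the recording unchanged, `overlap = 1`
#' makes the five class blocks identical, so their amplitude distributions
#' are indistinguishable and downstream classification can do no better
#' than chance. Requires a labelled recording whose classes all occupy the
#' same number of samples (the default protocol layout).
#'
#' @param recording A labelled [eog_recording()].
#' @param overlap Blend fraction in `[0, 1]`.
#' @return The blended [eog_recording()].
#' @export
perturb_separability <- function(recording, overlap) {
  stopifnot(inherits(recording, "eog_recording"))
  if (!is.numeric(overlap) || length(overlap) != 1L ||
      is.na(overlap) || overlap < 0 || overlap > 1) {
    stop("overlap must be a single number in [0, 1]", call. = FALSE)
  }
  if (is.null(recording$labels)) stop("recording must be labelled", call. = FALSE)
  if (overlap == 0) return(recording)
  classes <- sort(unique(recording$labels))
  idx <- lapply(classes, function(cl) which(recording$labels == cl))
  sizes <- lengths(idx)
  if (length(unique(sizes)) != 1L) {
    stop("all classes must occupy equally many samples", call. = FALSE)
  }
  for (ch in c("horizontal", "vertical")) {
    m <- vapply(idx, function(ii) recording[[ch]][ii], numeric(sizes[1]))
    template <- rowMeans(m)
    for (j in seq_along(idx)) {
      recording[[ch]][idx[[j]]] <-
        (1 - overlap) * recording[[ch]][idx[[j]]] + overlap * template
    }
  }
  recording
}
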