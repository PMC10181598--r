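test_that("config validation rejects impossible protocols", {
  expect_error(synthetic_config(samples_per_segment = 0), "positive")
  expect_error(synthetic_config(band_limits = c(50, 0.5)), "increasing")
  expect_error(synthetic_config(quantization_bits = 0), ">= 1")
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
})

test_that("a silent configuration generates exactly zero", {
  amp0 <- lapply(default_amplitude_map(), function(a) {
    a$pulse <- a$pulse * 0; a$tremor_h <- 0; a$tremor_v <- 0; a
  })
  rec <- generate_recording(synthetic_config(noise_sd = 0,
                                             amplitude_map = amp0))
  expect_identical(rec$horizontal, numeric(32500))
  expect_identical(rec$vertical, numeric(32500))
})

test_that("identical seeds give bit-identical recordings", {
  a <- generate_recording(synthetic_config(seed = 4))
  b <- generate_recording(synthetic_config(seed = 4))
  expect_identical(a, b)
  c <- generate_recording(synthetic_config(seed = 5))
  expect_false(identical(a$horizontal, c$horizontal))
})

test_that("the default recording respects envelope and label layout", {
  rec <- default_recording()
  expect_identical(n_samples(rec), 32500L)
  expect_lte(max(rec$horizontal, rec$vertical), 0.5)
  expect_gte(min(rec$horizontal, rec$vertical), -0.3)
  expect_identical(as.vector(table(rec$labels)), rep(6500L, 5))
  # block order down, up, blink, left, right
  expect_identical(unique(rec$labels), c(0L, 2L, 1L, 3L, 4L))
})

test_that("movement polarity follows the corneo-retinal dipole", {
  rec <- default_recording()
  cfg <- synthetic_config()
  seg <- function(mv) which(rec$labels == eog_class_map()[[mv]])
  # deflection = channel level at the saccade plateau minus the rest level;
  # evaluated at cycle midpoints so the AC-coupled baseline drift cancels
  deflection <- function(x, idx) {
    t_seg <- (seq_along(idx) - 1) / cfg$sampling_rate
    phase <- (t_seg %% cfg$pulse_period_s) / cfg$pulse_period_s
    plateau <- abs(phase - 0.325) < 0.05
    rest <- abs(phase - 0.825) < 0.05
    mean(x[idx][plateau]) - mean(x[idx][rest])
  }
  h <- rec$horizontal; v <- rec$vertical
  expect_gt(deflection(h, seg("right")), 0.1)
  expect_lt(deflection(h, seg("left")), -0.1)
  expect_gt(deflection(v, seg("up")), 0.1)
  expect_lt(deflection(v, seg("down")), -0.04)
  # blink spikes dominate the vertical channel
  bl <- seg("blink")
  expect_gt(max(abs(v[bl])), 3 * max(abs(h[bl])))
})

test_that("generated channels are band-limited to the acquisition band", {
  rec <- default_recording()
  out_of_band_fraction <- function(x, fs, band) {
    n <- length(x)
    p <- Mod(stats::fft(x))^2
    f <- fs * (0:(n - 1)) / n
    f <- pmin(f, fs - f)
    sum(p[f < band[1] | f > band[2]]) / sum(p)
  }
  expect_lt(out_of_band_fraction(rec$horizontal, 650, c(0.5, 50)), 0.05)
  expect_lt(out_of_band_fraction(rec$vertical, 650, c(0.5, 50)), 0.05)
})

test_that("perturb_separability blends towards indistinguishable classes", {
  rec <- default_recording()
  expect_identical(perturb_separability(rec, 0), rec)
  expect_error(perturb_separability(rec, 1.5), "\\[0, 1\\]")
  expect_error(perturb_separability(rec, -0.1), "\\[0, 1\\]")

  full <- perturb_separability(rec, 1)
  # per-class mean absolute window amplitude is equalised
  classes <- 0:4
  for (ch in c("horizontal", "vertical")) {
    m <- vapply(classes, function(cl) mean(abs(full[[ch]][full$labels == cl])),
                numeric(1))
    expect_lt(max(m) - min(m), 1e-12)
  }

  # intermediate blend is deterministic and strictly between the extremes
  half1 <- perturb_separability(rec, 0.5)
  half2 <- perturb_separability(rec, 0.5)
  expect_identical(half1, half2)
  expect_false(identical(half1$horizontal, rec$horizontal))
  expect_false(identical(half1$horizontal, full$horizontal))
  # blending is linear: the 0.5 blend is the midpoint of the extremes
  expect_equal(half1$horizontal, (rec$horizontal + full$horizontal) / 2,
               tolerance = 1e-12)
})
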