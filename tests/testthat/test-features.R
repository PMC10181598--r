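test_that("window counts follow floor division with remainder dropped", {
  expect_identical(nrow(make_windows(numeric(2032), 4)), 508L)
  expect_identical(nrow(make_windows(numeric(4), 4)), 1L)
  expect_identical(nrow(make_windows(numeric(10), 4)), 2L)
  expect_error(make_windows(numeric(0)), "empty")
  expect_error(make_windows(1:8, 0), ">= 1")
  m <- make_windows(1:10, 4)
  expect_identical(m[2, ], as.numeric(5:8))
})

test_that("window features match hand arithmetic", {
  f <- window_features(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(f[["RMSH"]], sqrt(30 / 4))
  expect_equal(f[["PowerH"]], 7.5)
  expect_equal(f[["AMPH"]], 3)
  expect_equal(f[["AverageH"]], 2.5)
  expect_equal(f[["MedianH"]], 2.5)
  expect_equal(f[["MaxH"]], 4)
  expect_equal(f[["VarianceH"]], 1.25)  # population variance

  # constant window: RMS = |c|, Power = c^2, zero spread
  g <- window_features(rep(-2, 4), rep(1, 4))
  expect_equal(g[["RMSH"]], 2)
  expect_equal(g[["PowerH"]], 4)
  expect_equal(g[["AMPH"]], 0)
  expect_equal(g[["VarianceH"]], 0)

  expect_error(window_features(1:4, 1:3), "widths differ")
  expect_error(window_features(1, 1), ">= 2")
})

test_that("cross-channel covariance is symmetric and collapses to variance", {
  set.seed(5)
  h <- stats::rnorm(4); v <- stats::rnorm(4)
  f <- window_features(h, v)
  expect_identical(f[["CovarianceH"]], f[["CovarianceV"]])
  same <- window_features(h, h)
  expect_equal(same[["CovarianceH"]], same[["VarianceH"]])
})

test_that("population identities hold on random windows", {
  set.seed(6)
  for (i in 1:50) {
    h <- stats::rnorm(4); v <- stats::rnorm(4)
    f <- window_features(h, v)
    expect_lt(abs(f[["PowerH"]] - f[["RMSH"]]^2), 1e-10)
    expect_lt(abs(f[["VarianceH"]] - (f[["PowerH"]] - f[["AverageH"]]^2)), 1e-10)
    expect_gte(f[["AMPV"]], 0)
    expect_lte(f[["MedianV"]], f[["MaxV"]])
  }
})

test_that("periodogram peak reduces the window spectrum", {
  # constant window: all energy at DC, |sum|^2 / n = 16 c^2 / 4
  f <- window_features(rep(2, 4), rep(0, 4))
  expect_equal(f[["PspectrumH"]], 16)
  # alternating window: all energy at Nyquist
  g <- window_features(c(1, -1, 1, -1), rep(0, 4))
  expect_equal(g[["PspectrumH"]], 4)
  # sum reducer accumulates the one-sided spectrum instead
  s <- window_features(c(1, -1, 1, -1), rep(0, 4), pspectrum_reducer = "sum")
  expect_gte(s[["PspectrumH"]], g[["PspectrumH"]])
})

test_that("the default pipeline yields the 508 x 18 labelled matrix", {
  fm <- default_features()
  expect_identical(nrow(fm), 508L)
  expect_identical(colnames(fm), c(feature_names(), "label"))
  expect_true(all(fm$label %in% 0:4))
  expect_true(all(is.finite(as.matrix(fm[, 1:18]))))
  # first block of windows carries the first protocol class (down)
  expect_true(all(fm$label[1:101] == 0L))
  # all five classes are present with near-equal window counts
  expect_identical(sort(unique(fm$label)), 0:4)
  expect_true(all(abs(as.vector(table(fm$label)) - 101.6) <= 1))
})

test_that("an all-zero recording yields an all-zero finite matrix", {
  n <- 2560L
  rec <- eog_recording(numeric(n), numeric(n), 650)
  rec <- apply_segment_table(rec, default_segment_table(n / 5L))
  fm <- build_feature_matrix(rec)
  expect_true(all(as.matrix(fm[, 1:18]) == 0))
})

test_that("feature extraction requires labels and is deterministic", {
  rec <- default_recording()
  unlab <- rec; unlab$labels <- NULL
  expect_error(build_feature_matrix(unlab), "labelled")
  expect_identical(build_feature_matrix(rec), build_feature_matrix(rec))
})
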