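test_that("recording construction validates its invariants", {
  expect_error(eog_recording(1:3, 1:4, 100), "equal length")
  expect_error(eog_recording(1:3, 1:3, -1), "positive")
  expect_error(eog_recording(1:3, 1:3, 100, labels = c(0, 1, 9)), "0..4")
  rec <- eog_recording(1:4 / 10, 4:1 / 10, 650)
  expect_s3_class(rec, "eog_recording")
  expect_identical(n_samples(rec), 4L)
  expect_null(rec$labels)
})

test_that("default segment table follows the five-block protocol layout", {
  tab <- default_segment_table()
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$start, as.integer(6500 * 0:4))
  expect_identical(tab$end, as.integer(6500 * 1:5))
  # temporal order down, up, blink, left, right under the class map
  expect_identical(tab$class, c(0L, 2L, 1L, 3L, 4L))
})

test_that("segment labelling matches the protocol block structure", {
  n <- 32500L
  rec <- eog_recording(numeric(n), numeric(n), 650)
  rec <- apply_segment_table(rec, default_segment_table())
  # sample 0 is a downward movement (class 0), sample 26,050 a rightward one
  expect_identical(rec$labels[0 + 1L], 0L)
  expect_identical(rec$labels[26050 + 1L], 4L)
  expect_identical(as.vector(table(rec$labels)), rep(6500L, 5))

  # empty table removes labels; out-of-range table is rejected
  expect_null(apply_segment_table(rec, segment_table())$labels)
  expect_error(
    apply_segment_table(rec, segment_table(0L, 0L, n + 1L)),
    "beyond"
  )
  expect_error(segment_table(c(0L, 1L), c(0L, 50L), c(100L, 150L)), "overlap")
})

test_that("recordings round-trip through both formats", {
  rec <- tiny_recording()
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_recording(rec, path)
    back <- read_recording(path)
    expect_equal(back$horizontal, rec$horizontal, tolerance = 1e-12)
    expect_equal(back$vertical, rec$vertical, tolerance = 1e-12)
    expect_identical(back$labels, rec$labels)
    expect_equal(back$sampling_rate, rec$sampling_rate)
    expect_error(write_recording(rec, path), "overwrite")
  }
})

test_that("a hand-written four-sample csv loads", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("h_volts,v_volts,label",
               "0.1,-0.1,0", "0.2,-0.2,0", "0.3,-0.3,1", "0.4,-0.4,1"), path)
  rec <- read_recording(path)
  expect_identical(n_samples(rec), 4L)
  expect_identical(rec$labels, c(0L, 0L, 1L, 1L))
  expect_error(read_recording(withr::local_tempfile()), "no such file")
})

test_that("the synthetic recording survives the json container to 1e-9 V", {
  rec <- default_recording()
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_lt(max(abs(back$horizontal - rec$horizontal)), 1e-9)
  expect_lt(max(abs(back$vertical - rec$vertical)), 1e-9)
  expect_identical(back$labels, rec$labels)
})
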