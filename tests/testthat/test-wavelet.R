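test_that("wavelet specs parse and reject unknown names", {
  sp <- wavelet_spec("rbio", "3.1")
  expect_identical(sp$name, "rbio3.1")
  expect_identical(as_wavelet_spec("rbio3.1")$member, "3.1")
  expect_identical(as_wavelet_spec("haar")$family, "haar")
  expect_error(as_wavelet_spec("fk4"), "unknown wavelet")
  expect_error(wavelet_spec("rbio", "9.9"), "unknown wavelet")
})

test_that("coefficient counts follow ceil-halving under periodisation", {
  x <- sin(seq_len(32500) / 7)
  dec <- decompose(x, "rbio3.1", 5)
  expect_identical(lengths(dec$details),
                   c(16250L, 8125L, 4063L, 2032L, 1016L))
  expect_identical(length(dec$approximation), 1016L)
  expect_identical(length(smoothed_detail(dec, 4)), 2032L)
  expect_error(smoothed_detail(dec, 6), "level")
  expect_identical(smoothed_detail(dec, 2), dec$details[[2]])
})

test_that("every supported family reconstructs a random signal to 1e-8", {
  set.seed(42)
  x <- stats::rnorm(4096)
  for (w in supported_wavelets()) {
    dec <- decompose(x, w, 5)
    err <- max(abs(reconstruct(dec) - x))
    expect_lt(err, 1e-8, label = sprintf("reconstruction error for %s", w))
  }
})

test_that("odd-length signals reconstruct through the padded levels", {
  set.seed(7)
  x <- stats::rnorm(1013)  # odd at several levels
  for (w in c("haar", "sym4", "rbio3.1", "meyr")) {
    dec <- decompose(x, w, 5)
    expect_lt(max(abs(reconstruct(dec) - x)), 1e-8)
  }
})

test_that("constant signals produce vanishing detail coefficients", {
  x <- rep(3.7, 512)
  for (w in c("haar", "coif2", "sym4", "meyr", "bior3.1", "rbio3.1")) {
    dec <- decompose(x, w, 5)
    expect_lt(max(abs(unlist(dec$details))), 1e-10,
              label = sprintf("details for %s", w))
  }
})

test_that("decompose rejects signals shorter than 2^levels", {
  expect_error(decompose(1:16, "haar", 5), "too short")
})

test_that("entropy matches closed forms and rejects degenerate input", {
  expect_equal(level_entropy(rep(1, 8)), 3)                 # uniform over 8
  expect_equal(level_entropy(c(9, 0, 0, 0)), 0)             # single atom
  # energy shares (0.5, 0.25, 0.25): -sum p log2 p = 1.5 bits
  expect_equal(level_entropy(c(sqrt(2), 1, 1)), 1.5)
  expect_error(level_entropy(numeric(0)), "non-empty")
  expect_error(level_entropy(c(0, 0)), "all-zero")
})

test_that("entropy is permutation- and scale-invariant", {
  set.seed(11)
  for (i in 1:20) {
    c0 <- stats::rnorm(50)
    expect_equal(level_entropy(sample(c0)), level_entropy(c0))
    expect_equal(level_entropy(c0 * stats::runif(1, 0.1, 100)),
                 level_entropy(c0))
  }
})

test_that("the family scan emits one row per channel, candidate and level", {
  rec <- tiny_recording(64L)
  tab <- scan_families(rec, "haar")
  expect_identical(nrow(tab), 10L)  # 5 levels x 2 channels
  expect_true(all(tab$entropy >= 0))

  tab2 <- scan_families(rec, c("haar", "haar"))
  expect_identical(tab2$entropy[tab2$channel == "horizontal"][1:5],
                   tab2$entropy[tab2$channel == "horizontal"][6:10])

  twice <- scan_families(rec, c("haar", "rbio3.1"))
  again <- scan_families(rec, c("haar", "rbio3.1"))
  expect_identical(twice, again)
  expect_error(scan_families(rec, character(0)), "at least one")
})

test_that("select_mother agrees with exhaustive argmin", {
  rec <- tiny_recording(64L)
  cands <- c("haar", "sym4", "coif2", "rbio3.1", "bior3.1")
  tab <- scan_families(rec, cands)
  totals <- vapply(cands, function(w) sum(tab$entropy[tab$wavelet == w]),
                   numeric(1))
  expect_identical(select_mother(tab)$name, names(which.min(totals)))

  # constructed table with a known minimum
  fake <- structure(
    data.frame(channel = "horizontal",
               wavelet = rep(c("haar", "sym4"), each = 2),
               level = c(1, 2, 1, 2),
               entropy = c(1, 1, 0.4, 0.5)),
    class = c("entropy_table", "data.frame"))
  expect_identical(select_mother(fake)$name, "sym4")
  expect_error(select_mother(fake[0, ]), "empty")

  # single candidate: that candidate
  expect_identical(select_mother(scan_families(rec, "haar"))$name, "haar")

  # ties break towards the candidate appearing first
  tie <- fake
  tie$entropy <- c(0.4, 0.5, 0.4, 0.5)
  expect_identical(select_mother(tie)$name, "haar")
})

test_that("custom filter banks can be registered and used", {
  name <- register_wavelet("boxpair", c(1, 1) / sqrt(2), c(1, 1) / sqrt(2))
  expect_true(name %in% supported_wavelets())
  set.seed(3)
  x <- stats::rnorm(256)
  dec <- decompose(x, name, 3)
  ref <- decompose(x, "haar", 3)
  expect_equal(dec$details, ref$details, tolerance = 1e-12)
})
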