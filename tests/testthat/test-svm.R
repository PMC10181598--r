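test_that("polynomial kernel matches closed forms and is symmetric", {
  p <- kernel_params(gamma = 1, r = 1, degree = 2)
  expect_identical(poly_kernel(c(1, 0), c(1, 1), p), 4)
  lin <- kernel_params(gamma = 0.5, r = 0, degree = 1)
  expect_equal(poly_kernel(c(1, 2), c(3, 4), lin), 0.5 * 11)
  set.seed(2)
  for (i in 1:20) {
    a <- stats::rnorm(5); b <- stats::rnorm(5)
    expect_equal(poly_kernel(a, b, p), poly_kernel(b, a, p))
  }
  expect_error(poly_kernel(1:2, 1:3, p), "dimension mismatch")
  expect_error(kernel_params(gamma = -1), "positive")
  expect_error(kernel_params(degree = 0), "positive integer")
})

test_that("two well-separated points give a zero-error machine", {
  x <- matrix(c(-1, 0, 1, 0), 2, byrow = TRUE)
  y <- c(0L, 1L)
  m <- svm_fit(x, y, kernel = kernel_params(gamma = 1, r = 0, degree = 1),
               standardize = FALSE)
  expect_identical(predict(m, x), y)
  # both points support the margin in each binary machine
  expect_true(all(vapply(m$machines, function(mm) length(mm$sv), 1L) == 2L))
})

test_that("xor becomes separable under the degree-2 polynomial kernel", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  y <- c(0L, 0L, 1L, 1L)
  m <- svm_fit(x, y, C = 14.5, kernel = kernel_params(gamma = 1, r = 1,
                                                      degree = 2),
               standardize = FALSE)
  expect_identical(predict(m, x), y)
})

test_that("dual box and equality constraints hold at convergence", {
  b <- blob_features()
  m <- svm_fit(b$x, b$labels, C = 14.5)
  gaps <- eogwave:::svm_dual_gaps(m)
  expect_lt(max(abs(gaps["box_low", ])), 1e-6)
  expect_lt(max(abs(gaps["box_high", ])), 1e-6)
  expect_lt(max(abs(gaps["equality", ])), 1e-6)
  expect_identical(predict(m, b$x), b$labels)
})

test_that("conflicting duplicate labels cap training accuracy without crashing", {
  x <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), ncol = 2, byrow = TRUE)
  y <- c(0L, 1L, 0L, 0L)
  m <- suppressWarnings(svm_fit(x, y, standardize = FALSE))
  acc <- mean(predict(m, x) == y)
  expect_lte(acc, 0.75)  # at most 3 of the 4 constraints are satisfiable
})

test_that("degenerate training sets are rejected", {
  expect_error(svm_fit(matrix(1:4, 2), c(1L, 1L)), "two classes")
  expect_error(svm_fit(matrix(1:4, 2), c(0L, 1L), C = -2), "positive")
})

test_that("decision values justify the predicted class", {
  b <- blob_features()
  m <- svm_fit(b$x, b$labels)
  dec <- predict(m, b$x, type = "decision")
  expect_identical(ncol(dec), 5L)
  expect_identical(as.integer(colnames(dec)[apply(dec, 1, which.max)]),
                   predict(m, b$x))
})

test_that("predictions match an independent svm implementation on blobs", {
  skip_if_not_installed("e1071")
  b <- blob_features(n_per_class = 15)
  m <- svm_fit(b$x, b$labels, C = 14.5,
               kernel = kernel_params(gamma = 0.5, r = 1, degree = 3))
  ref <- e1071::svm(b$x, factor(b$labels), kernel = "polynomial",
                    degree = 3, gamma = 0.5, coef0 = 1, cost = 14.5,
                    scale = TRUE)
  set.seed(9)
  grid <- matrix(stats::rnorm(100 * 2, mean = 2, sd = 2), 100)
  agree <- mean(predict(m, grid) == as.integer(as.character(predict(ref, grid))))
  expect_gte(agree, 0.9)
})
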