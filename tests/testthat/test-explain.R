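test_that("a linear model recovers the closed-form Shapley values exactly", {
  set.seed(41)
  d <- 5L
  w <- rnorm(d)
  f <- function(X) as.numeric(X %*% w)
  X <- matrix(rnorm(3 * d), nrow = 3,
              dimnames = list(NULL, paste0("f", 1:d)))
  b <- matrix(rnorm(d), nrow = 1,
              dimnames = list(NULL, paste0("f", 1:d)))
  attr <- shapleyAttributions(f, X, b, nSamples = 3L, seed = 1L)
  # with a single background row every permutation yields w_i (x_i - b_i)
  expected <- sweep(X, 2, as.numeric(b)) * rep(w, each = 3)
  expect_equal(scoreMatrix(attr), expected, tolerance = 1e-10)
  expect_equal(attr@baseValue, f(b), tolerance = 1e-12)
})

test_that("sampled attributions match the exhaustive coalition oracle", {
  f <- function(X) X[, 1] * X[, 2] + X[, 3]^2
  x <- c(f1 = 1.2, f2 = -0.7, f3 = 0.5)
  b <- c(f1 = 0.1, f2 = 0.4, f3 = -0.2)
  exact <- shapleyExact(f, x, b)
  ests <- sapply(1:5, function(s) {
    a <- shapleyAttributions(
      f, matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
      matrix(b, nrow = 1, dimnames = list(NULL, names(x))),
      nSamples = 200L, seed = s)
    scoreMatrix(a)[1, ]
  })
  for (i in 1:3) {
    se <- stats::sd(ests[i, ]) / sqrt(5)
    expect_lt(abs(mean(ests[i, ]) - exact[i]), 3 * max(se, 1e-8))
  }
})

test_that("local accuracy holds exactly after the additive correction", {
  set.seed(42)
  f <- function(X) sin(X[, 1]) + X[, 2] * X[, 3]
  X <- matrix(rnorm(30 * 3), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  bg <- matrix(rnorm(10 * 3), ncol = 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  a <- shapleyAttributions(f, X, bg, nSamples = 10L, seed = 2L)
  dev <- abs(a@baseValue + rowSums(scoreMatrix(a)) - a@predictions)
  expect_lt(max(dev), 1e-10)
})

test_that("duplicated identical features share attribution in expectation", {
  f <- function(X) (X[, 1] + X[, 2])^2
  X <- matrix(c(1.3, 1.3, 0.2), nrow = 1,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  b <- matrix(c(-0.4, -0.4, 0.9), nrow = 1,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  a <- shapleyAttributions(f, X, b, nSamples = 2000L, seed = 3L)
  v <- scoreMatrix(a)[1, ]
  expect_lt(abs(v["f1"] - v["f2"]), 0.1)
})

test_that("feature ranking respects direction, ties and the k cap", {
  vals <- rbind(c(0.5, -0.9, 0.1), c(0.5, -0.9, 0.1))
  colnames(vals) <- c("up", "down", "small")
  a <- new("Attribution", values = vals, baseValue = 0,
           blocks = c("EXP", "CHEM", "EXP"), predictions = c(0, 0))
  expect_identical(rankFeatures(a, "positive", k = 1L)$feature, "up")
  expect_identical(rankFeatures(a, "absolute", k = 1L)$feature, "down")
  expect_identical(rankFeatures(a, "negative", k = 1L)$feature, "down")
  expect_equal(nrow(rankFeatures(a, "positive", k = 1000000L)), 3L)
  expect_identical(rankFeatures(a, "positive", k = 2L)$block,
                   c("EXP", "EXP"))
})

test_that("schema mismatches between X and background are rejected", {
  X <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "c")))
  expect_error(shapleyAttributions(function(M) rowSums(M), X, bg,
                                   nSamples = 1L), "schema")
})
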