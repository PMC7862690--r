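test_that("hand-computed four-gene cases give ES of 2 and -2", {
  expr <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  # set = top-ranked gene, alpha 0: P_hit jumps to 1, P_miss ramps 0..1
  expect_equal(ssgseaES(expr, "g1", alpha = 0), 2)
  expect_equal(ssgseaES(expr, "g4", alpha = 0), -2)
})

test_that("ES agrees with the brute-force reference on random profiles", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    expr <- stats::setNames(rnorm(n, 5, 2), sprintf("G%03d", sample(n)))
    k <- sample(1:(n - 1), 1)
    gs <- sample(names(expr), k)
    a <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgseaES(expr, gs, alpha = a),
                 ssgseaBrute(expr, gs, a), tolerance = 1e-10)
  }
})

test_that("reversing the ranking flips the score at alpha 0", {
  set.seed(7)
  expr <- stats::setNames(sample(seq(1, 9, 0.5), 12), letters[1:12])
  gs <- c("c", "h", "k")
  es <- ssgseaES(expr, gs, alpha = 0)
  # reverse ranks: strictly monotone decreasing transform of expression
  esRev <- ssgseaES(-expr, gs, alpha = 0)
  expect_equal(esRev, -es, tolerance = 1e-10)
})

test_that("NES is invariant to monotone expression transforms at alpha 0", {
  set.seed(8)
  expr <- matrix(rnorm(3 * 30, 5, 2), nrow = 3,
                 dimnames = list(paste0("c", 1:3), sprintf("G%02d", 1:30)))
  pc <- new("PathwayCollection",
            sets = list(P1 = sprintf("G%02d", 1:6),
                        P2 = sprintf("G%02d", 10:14)),
            descriptions = c(P1 = "", P2 = ""))
  a <- ssgseaMatrix(expr, pc, alpha = 0)
  b <- ssgseaMatrix(exp(expr), pc, alpha = 0)  # strictly monotone
  expect_equal(scoreMatrix(a), scoreMatrix(b), tolerance = 1e-10)
})

test_that("NES divides ES by mapped set size; degenerate sets handled", {
  expr <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  pc <- new("PathwayCollection",
            sets = list(TOP = "g1", PAIR = c("g1", "g4"),
                        NONE = c("zz1", "zz2")),
            descriptions = c(TOP = "", PAIR = "", NONE = ""))
  m <- matrix(expr, nrow = 1, dimnames = list("c1", names(expr)))
  suppressMessages(nes <- ssgseaMatrix(m, pc, alpha = 0))
  expect_equal(nes@scores[1, "TOP"], 2)  # ES 2 / size 1
  expect_equal(nes@scores[1, "PAIR"],
               ssgseaES(expr, c("g1", "g4"), alpha = 0) / 2)
  expect_equal(nes@scores[1, "NONE"], 0)

  expect_error(ssgseaES(expr, names(expr)), "whole profile")
  expect_warning(z <- ssgseaES(expr, "absent"), "intersect")
  expect_equal(z, 0)
})

test_that("identical cell profiles produce identical NES rows", {
  set.seed(9)
  v <- rnorm(25, 5, 2)
  expr <- rbind(c1 = v, c2 = v)
  colnames(expr) <- sprintf("G%02d", 1:25)
  pc <- new("PathwayCollection", sets = list(P = sprintf("G%02d", 3:9)),
            descriptions = c(P = ""))
  nes <- ssgseaMatrix(expr, pc)
  expect_identical(nes@scores["c1", ], nes@scores["c2", ])
})
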