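test_that("CNV gene sets exclude diploid genes and keep gains and losses", {
  cnv <- rbind(c1 = c(A = 0L, B = 2L, C = -1L),
               c2 = c(A = 0L, B = 0L, C = 0L),
               c3 = c(A = -2L, B = -1L, C = 1L))
  suppressMessages(sets <- cnvGeneSets(cnv))
  expect_setequal(sets$c1, c("B", "C"))
  expect_length(sets$c2, 0L)
  expect_setequal(sets$c3, c("A", "B", "C"))
  expect_error(cnvGeneSets(rbind(c1 = c(A = 3L))), "GISTIC")
})

# small synthetic blocks with controllable ids for assembly tests
dummyBlocks <- function(nPw = 4L, nBits = 8L,
                        drugs = c("d1", "d2"), cells = c("c1", "c2", "c3")) {
  pw <- sprintf("P%02d", seq_len(nPw))
  mk <- function(ids) matrix(rnorm(length(ids) * nPw), nrow = length(ids),
                             dimnames = list(ids, pw))
  list("CHEM" = matrix(rbinom(length(drugs) * nBits, 1, 0.3),
                       nrow = length(drugs),
                       dimnames = list(drugs, sprintf("b%02d", 1:nBits))),
       "DG-Net" = mk(drugs), "EXP" = mk(cells),
       "MUT-Net" = mk(cells), "CNV-Net" = mk(cells))
}

resp3 <- data.frame(drug = c("d1", "d1", "d2"),
                    cell = c("c1", "c2", "c3"),
                    response = c(0.5, -1, 2))

test_that("assembly concatenates blocks with broadcasting and tags", {
  set.seed(31)
  blocks <- dummyBlocks()
  fm <- assembleFeatures(blocks, resp3)
  expect_equal(ncol(scoreMatrix(fm)), 8L + 4L * 4L)
  expect_equal(nrow(scoreMatrix(fm)), 3L)
  expect_equal(sum(featureBlocks(fm) == "CHEM"), 8L)
  # drug rows broadcast: d1 CHEM identical across its two cells
  X <- scoreMatrix(fm)
  expect_identical(X[1, featureBlocks(fm) == "CHEM"],
                   X[2, featureBlocks(fm) == "CHEM"])
  # subset reproduces ablation widths
  expect_equal(ncol(scoreMatrix(assembleFeatures(blocks, resp3,
                                                 subset = "CHEM"))), 8L)
  expect_equal(ncol(scoreMatrix(
    assembleFeatures(blocks, resp3, subset = c("CHEM", "EXP")))), 12L)
})

test_that("pairs missing a block row are dropped; empty result errors", {
  set.seed(32)
  blocks <- dummyBlocks(drugs = "d1")  # d2 has no drug blocks
  expect_message(fm <- assembleFeatures(blocks, resp3), "dropped")
  expect_equal(nrow(scoreMatrix(fm)), 2L)
  expect_false("d2" %in% fm@drug)
  respNone <- data.frame(drug = "dX", cell = "cX", response = 1)
  expect_error(suppressMessages(assembleFeatures(blocks, respNone)),
               "no \\(drug, cell\\) pair")
})

test_that("assembly commutes with row permutations of the response table", {
  set.seed(33)
  blocks <- dummyBlocks()
  a <- assembleFeatures(blocks, resp3)
  b <- assembleFeatures(blocks, resp3[c(3, 1, 2), ])
  expect_identical(scoreMatrix(a)[order(rownames(scoreMatrix(a))), ],
                   scoreMatrix(b)[order(rownames(scoreMatrix(b))), ])
})

test_that("z-scoring fits population statistics and drops constants", {
  X <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(0, 1, -1))
  fm <- new("FeatureMatrix", data = X, blocks = rep("EXP", 3),
            drug = rep("d", 3), cell = paste0("c", 1:3),
            response = 1:3 / 2)
  zs <- zscoreFeatures(fm)
  expect_equal(unname(scoreMatrix(zs$features)[, "f1"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_identical(zs$stats@dropped, "f2")
  expect_false("f2" %in% colnames(scoreMatrix(zs$features)))
  # fitted stats reproduce mean 0 / sd 1 on the fitting rows
  Z <- scoreMatrix(zs$features)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1)),
            1e-10)
})

test_that("apply mode uses stored stats only, never the new rows", {
  set.seed(34)
  X <- matrix(rnorm(40), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  mk <- function(M) new("FeatureMatrix", data = M,
                        blocks = rep("EXP", ncol(M)),
                        drug = rep("d", nrow(M)),
                        cell = sprintf("c%d", seq_len(nrow(M))),
                        response = rnorm(nrow(M)))
  stats <- zscoreFeatures(mk(X))$stats
  # identity stats leave data unchanged
  id <- new("NormalizationStats",
            mean = stats::setNames(rep(0, 4), paste0("f", 1:4)),
            sd = stats::setNames(rep(1, 4), paste0("f", 1:4)),
            dropped = character())
  expect_equal(scoreMatrix(zscoreFeatures(mk(X), id)$features), X,
               tolerance = 1e-12)
  # the same row normalizes identically regardless of its batch companions
  row1 <- X[1, , drop = FALSE]
  batchA <- mk(rbind(row1, X[2:3, ]))
  batchB <- mk(rbind(row1, X[8:10, ] * 100))
  outA <- scoreMatrix(zscoreFeatures(batchA, stats)$features)[1, ]
  outB <- scoreMatrix(zscoreFeatures(batchB, stats)$features)[1, ]
  expect_identical(outA, outB)
})
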