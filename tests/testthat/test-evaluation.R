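test_that("repeated k-fold plans partition rows within each repeat", {
  drug <- rep(sprintf("d%02d", 1:10), each = 10)
  cell <- rep(sprintf("c%02d", 1:10), times = 10)
  plan <- makeSplits(drug, cell, "kfold", k = 10L, repeats = 5L,
                     seed = 9L)
  expect_length(plan@folds, 50L)
  for (r in 1:5) {
    folds <- Filter(function(f) f$rep == r, plan@folds)
    tests <- lapply(folds, `[[`, "test")
    expect_setequal(unlist(tests), seq_along(drug))    # cover all rows
    expect_equal(sum(lengths(tests)), length(drug))    # disjoint
    sizes <- lengths(tests)
    expect_lte(max(sizes) - min(sizes), 1L)            # balanced
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0L)
      expect_setequal(c(f$train, f$test), seq_along(drug))
    }
  }
  # deterministic given seed
  plan2 <- makeSplits(drug, cell, "kfold", k = 10L, repeats = 5L,
                      seed = 9L)
  expect_identical(plan@folds, plan2@folds)
  expect_error(makeSplits(drug[1:5], cell[1:5], "kfold", k = 10L),
               "exceeds")
})

test_that("LODO and LOCO folds are entity-disjoint, exhaustively", {
  drug <- rep(sprintf("d%02d", 1:6), each = 8)
  cell <- rep(sprintf("c%02d", 1:8), times = 6)
  for (mode in c("lodo", "loco")) {
    plan <- makeSplits(drug, cell, mode)
    ids <- if (mode == "lodo") drug else cell
    expect_length(plan@folds, length(unique(ids)))
    for (f in plan@folds) {
      expect_true(all(ids[f$test] == f$entity))
      expect_false(f$entity %in% ids[f$train])
      expect_setequal(c(f$train, f$test), seq_along(ids))
    }
  }
  expect_error(makeSplits(rep("d1", 4), paste0("c", 1:4), "lodo"),
               "distinct")
})

test_that("metrics match closed forms and satisfy RMSE >= MAE", {
  perfect <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect[c("MAE", "RMSE", "R2", "PCC")]),
               c(MAE = 0, RMSE = 0, R2 = 1, PCC = 1))
  m <- suppressWarnings(computeMetrics(c(0, 0), c(3, 4)))
  expect_equal(m$MAE, 3.5)
  expect_equal(m$RMSE, sqrt(12.5), tolerance = 1e-7)  # 3.5355
  expect_warning(mc <- computeMetrics(c(1, 2, 3), c(2, 2, 2)),
                 "zero-variance")
  expect_true(is.nan(mc$PCC))
  set.seed(11)
  for (i in 1:25) {
    yt <- rnorm(50); yp <- rnorm(50)
    mm <- computeMetrics(yt, yp)
    expect_gte(mm$RMSE, mm$MAE)
  }
  # equality iff all absolute errors are equal
  eq <- suppressWarnings(computeMetrics(c(0, 0), c(2, -2)))
  expect_equal(eq$RMSE, eq$MAE)
})

test_that("Laplace diagnostic accepts Laplace and rejects uniform residuals", {
  accept <- reject <- 0L
  for (s in 1:5) {
    set.seed(s)
    if (laplaceResidualTest(rlaplace(1000))$p.value > 0.05)
      accept <- accept + 1L
    if (laplaceResidualTest(runif(1000, -1, 1))$p.value < 0.01)
      reject <- reject + 1L
  }
  expect_gte(accept, 4L)
  expect_gte(reject, 4L)
  expect_error(laplaceResidualTest(rnorm(10)), "at least 30")
})

test_that("the cross-dataset floor is the disagreement on shared pairs", {
  a <- data.frame(drug = c("d1", "d2"), cell = c("c1", "c2"),
                  response = c(1, 2))
  same <- theoreticalFloor(a, a)
  expect_equal(c(same$MAE, same$RMSE), c(0, 0))
  b <- data.frame(drug = "d1", cell = "c1", response = 3)
  fl <- theoreticalFloor(a, b)
  expect_equal(c(fl$MAE, fl$RMSE, fl$n), c(2, 2, 1))
  disjoint <- data.frame(drug = "dX", cell = "cX", response = 0)
  expect_error(theoreticalFloor(a, disjoint), "shared")
})

test_that("the experiment driver scores every fold and pools predictions", {
  set.seed(12)
  n <- 60L
  X <- matrix(rnorm(n * 5), nrow = n,
              dimnames = list(NULL, paste0("f", 1:5)))
  fm <- new("FeatureMatrix", data = X, blocks = rep("EXP", 5),
            drug = rep(sprintf("d%d", 1:6), each = 10),
            cell = rep(sprintf("c%d", 1:10), times = 6),
            response = as.numeric(X %*% rep(0.5, 5)) + rnorm(n, 0, 0.1))
  plan <- makeSplits(fm@drug, fm@cell, "kfold", k = 3L, repeats = 2L,
                     seed = 4L)
  cfg <- fnnConfig(hidden = c(16L), dropout = 0, learningRate = 5e-3,
                   batchSize = 16L, maxEpochs = 60L, patience = 60L,
                   seed = 1L)
  res <- suppressWarnings(runExperiment(fm, plan, cfg))
  expect_equal(nrow(res$perFold), 6L)
  # each repeat's predictions cover every row exactly once
  expect_equal(nrow(res$predictions), 2L * n)
  expect_true(all(c("mean", "sd", "sdAcrossRepeats") %in%
                    colnames(res$aggregate)))
  # the model must beat the mean predictor on this easy signal
  p <- res$predictions
  expect_lt(sqrt(mean((p$yTrue - p$yPred)^2)), stats::sd(p$yTrue))
})
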