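#' Build cross-validation or leave-one-out split plans
#'
#' \code{kfold}: rows are shuffled and dealt into k folds of near-equal
#' size (within one row of each other), repeated \code{repeats} times with
#' different shuffles; every fold's test set partitions the rows within its
#' repeat. \code{lodo} / \code{loco}: one fold per distinct drug / cell,
#' whose test set is every row of that entity — so the held-out entity
#' never appears in its training rows.
#'
#' @param drug,cell character vectors identifying each row's pair.
#' @param mode "kfold", "lodo" or "loco".
#' @param k folds per repeat (kfold only).
#' @param repeats number of repeated shuffles (kfold only).
#' @param seed RNG seed; plans are deterministic given the seed.
#' @return a \linkS4class{SplitPlan}; each fold is a list with integer
#'   vectors \code{train}, \code{test} and (kfold) a \code{rep} index.
#' @export
makeSplits <- function(drug, cell, mode = c("kfold", "lodo", "loco"),
                       k = 10L, repeats = 5L, seed = 42L) {
  mode <- match.arg(mode)
  n <- length(drug)
  stopifnot(length(cell) == n, n >= 2L)
  folds <- list()
  if (mode == "kfold") {
    if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
    .withSeed(seed, {
      for (r in seq_len(repeats)) {
        assign <- sample(rep_len(seq_len(k), n))
        for (f in seq_len(k)) {
          test <- which(assign == f)
          folds[[length(folds) + 1L]] <-
            list(train = which(assign != f), test = test, rep = r)
        }
      }
    })
  } else {
    ids <- if (mode == "lodo") drug else cell
    ents <- sort(unique(ids))
    if (length(ents) < 2L)
      stop("need at least 2 distinct ", if (mode == "lodo") "drugs"
           else "cells")
    for (e in ents) {
      test <- which(ids == e)
      folds[[length(folds) + 1L]] <-
        list(train = which(ids != e), test = test, entity = e)
    }
  }
  new("SplitPlan", mode = mode, folds = folds, k = as.integer(k),
      repeats = as.integer(repeats), seed = as.integer(seed))
}

#' Regression metrics for one set of predictions
#'
#' @param yTrue,yPred numeric vectors of equal nonzero length.
#' @return data.frame with MAE, RMSE, R2 and PCC. PCC is NaN (with a
#'   warning) when either vector has zero variance; R2 is
#'   \eqn{1 - SS_{res}/SS_{tot}}.
#' @export
computeMetrics <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) > 0L)
  e <- yPred - yTrue
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  sst <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sst == 0) NaN else 1 - sum(e^2) / sst
  pcc <- if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0) {
    warning("zero-variance input; PCC undefined")
    NaN
  } else stats::cor(yTrue, yPred)
  data.frame(MAE = mae, RMSE = rmse, R2 = r2, PCC = pcc)
}

## Laplace distribution CDF
.plaplace <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' Laplace residual diagnostic
#'
#' Fits a Laplace distribution to the residuals (location = median,
#' scale = mean absolute deviation from the median, the maximum-likelihood
#' estimates) and tests the fit with a Kolmogorov-Smirnov statistic. A
#' large p-value is consistent with Laplacian errors — the regime where MAE
#' is the natural loss summary.
#'
#' @param residuals numeric vector of at least 30 residuals.
#' @return list with \code{location}, \code{scale}, \code{statistic} (KS D)
#'   and \code{p.value}.
#' @export
laplaceResidualTest <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 30L)
    stop("need at least 30 residuals, got ", length(residuals))
  m <- stats::median(residuals)
  b <- mean(abs(residuals - m))
  if (b == 0) stop("residuals are constant; Laplace scale undefined")
  ks <- suppressWarnings(
    stats::ks.test(residuals, function(q) .plaplace(q, m, b)))
  list(location = m, scale = b, statistic = unname(ks$statistic),
       p.value = ks$p.value)
}

#' Cross-dataset error floor between two response tables
#'
#' The MAE/RMSE between two datasets' measured responses on their shared
#' (drug, cell) pairs — the best any model trained on one dataset could
#' achieve on the other, since the measurements themselves disagree by this
#' much.
#'
#' @param responsesA,responsesB data.frames with columns drug, cell,
#'   response.
#' @return list with \code{MAE}, \code{RMSE} and \code{n} shared pairs.
#' @export
theoreticalFloor <- function(responsesA, responsesB) {
  m <- merge(responsesA, responsesB, by = c("drug", "cell"),
             suffixes = c(".a", ".b"))
  if (nrow(m) == 0L) stop("no shared (drug, cell) pairs")
  e <- m$response.a - m$response.b
  list(MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)), n = nrow(m))
}

#' Run a split plan end to end
#'
#' For every fold: train the network on the training rows (normalization
#' statistics are re-fit inside the fold by \code{\link{trainFNN}}, so test
#' rows never leak into them; the early-stopping validation split is carved
#' from within the training rows), predict the test rows, and score them.
#' For lodo/loco plans the per-fold metrics are per-entity metrics.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param plan a \linkS4class{SplitPlan} over the same rows.
#' @param config an \linkS4class{FNNConfig}; each fold is trained with
#'   \code{seed + fold index} so folds are independent but reproducible.
#' @return list with \code{perFold} (data.frame of metrics, one row per
#'   fold), \code{aggregate} (mean and sd of each metric), and
#'   \code{predictions} (data.frame: drug, cell, fold, yTrue, yPred).
#' @export
runExperiment <- function(features, plan, config = fnnConfig()) {
  stopifnot(is(features, "FeatureMatrix"), is(plan, "SplitPlan"))
  perFold <- NULL
  preds <- NULL
  for (fi in seq_along(plan@folds)) {
    fold <- plan@folds[[fi]]
    cfg <- config
    cfg@seed <- config@seed + fi
    model <- trainFNN(subsetRows(features, fold$train), cfg)
    testFm <- subsetRows(features, fold$test)
    yp <- predict(model, testFm)
    yt <- testFm@response
    mt <- suppressWarnings(computeMetrics(yt, yp))
    mt$fold <- fi
    if (!is.null(fold$rep)) mt$rep <- fold$rep
    if (!is.null(fold$entity)) mt$entity <- fold$entity
    perFold <- rbind(perFold, mt)
    preds <- rbind(preds, data.frame(
      drug = testFm@drug, cell = testFm@cell, fold = fi,
      yTrue = yt, yPred = yp))
  }
  num <- c("MAE", "RMSE", "R2", "PCC")
  agg <- data.frame(
    metric = num,
    mean = vapply(num, function(m) mean(perFold[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(num, function(m) stats::sd(perFold[[m]], na.rm = TRUE),
                numeric(1)))
  if (plan@mode == "kfold" && plan@repeats > 1L) {
    byRep <- stats::aggregate(perFold[num], by = list(rep = perFold$rep),
                              FUN = mean)
    agg$sdAcrossRepeats <- vapply(num, function(m)
      stats::sd(byRep[[m]]), numeric(1))
  }
  list(perFold = perFold, aggregate = agg, predictions = preds)
}
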