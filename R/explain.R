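## evaluate a model (FNNModel or plain function of a matrix) on a matrix
.modelFun <- function(model) {
  if (is.function(model)) return(model)
  if (is(model, "FNNModel")) return(function(X) predict(model, X))
  stop("model must be an FNNModel or a function(matrix) -> numeric")
}

#' Sampling-based Shapley attributions with background replacement
#'
#' Model-agnostic permutation Shapley: for each explained row, feature
#' permutations are drawn; features are switched one by one from a randomly
#' drawn background row's values to the explained row's values, and each
#' feature's attribution is the average marginal change in the model
#' output. "Feature removed" therefore means "replaced by background
#' values". The base value is the mean model output over the background
#' set. After sampling, the residual \eqn{f(x) - base - \sum_i \phi_i} is
#' spread equally over the features so that local accuracy (attributions
#' plus base value equal the prediction) holds exactly.
#'
#' Positive attributions mark features pushing the prediction up; under a
#' response stored as increase in -log(IC50), that reads as sensitizing.
#'
#' @param model an \linkS4class{FNNModel}, or any function mapping a
#'   numeric matrix to a numeric vector of predictions.
#' @param X numeric matrix (or \linkS4class{FeatureMatrix}) of rows to
#'   explain.
#' @param background numeric matrix (or \linkS4class{FeatureMatrix}) of
#'   reference rows; defaults in practice to ~100 training rows.
#' @param nSamples permutations per explained row.
#' @param seed RNG seed; estimates are reproducible given the seed.
#' @param blocks optional block tag per feature (taken from \code{X} when
#'   it is a \linkS4class{FeatureMatrix}).
#' @return an \linkS4class{Attribution}.
#' @export
shapleyAttributions <- function(model, X, background, nSamples = 20L,
                                seed = 42L, blocks = NULL) {
  f <- .modelFun(model)
  if (is(X, "FeatureMatrix")) {
    if (is.null(blocks)) blocks <- X@blocks
    X <- X@data
  }
  if (is(background, "FeatureMatrix")) background <- background@data
  stopifnot(nrow(background) > 0L, ncol(background) == ncol(X))
  if (!identical(colnames(background), colnames(X)))
    stop("feature schema mismatch between X and background")
  if (is.null(blocks)) blocks <- rep("", ncol(X))
  d <- ncol(X)
  n <- nrow(X)
  base <- mean(f(background))
  fx <- f(X)
  phi <- matrix(0, nrow = n, ncol = d,
                dimnames = list(rownames(X), colnames(X)))
  .withSeed(seed, {
    for (i in seq_len(n)) {
      x <- X[i, ]
      acc <- numeric(d)
      for (s in seq_len(nSamples)) {
        b <- background[sample.int(nrow(background), 1L), ]
        ord <- sample.int(d)
        ## walk the permutation: row j has the first j features (in ord)
        ## set to x, the rest to the background draw
        Z <- matrix(b, nrow = d + 1L, ncol = d, byrow = TRUE)
        for (j in seq_len(d)) Z[(j + 1L):(d + 1L), ord[j]] <- x[ord[j]]
        colnames(Z) <- colnames(X)
        out <- f(Z)
        acc[ord] <- acc[ord] + diff(out)
      }
      phi[i, ] <- acc / nSamples
    }
  })
  ## enforce local accuracy exactly: spread the sampling residual evenly
  resid <- fx - base - rowSums(phi)
  phi <- phi + resid / d
  new("Attribution", values = phi, baseValue = base, blocks = blocks,
      predictions = fx)
}

#' Rank features by Shapley attribution
#'
#' @param attribution an \linkS4class{Attribution}.
#' @param direction "positive" (largest mean signed value first),
#'   "negative" (most negative first) or "absolute" (largest magnitude
#'   first).
#' @param level "global" (mean across samples) or "perSample" (rank within
#'   one row, selected by \code{sample}).
#' @param k number of features to return; larger than the feature count
#'   returns all. Ties break by feature name.
#' @param sample row index when \code{level = "perSample"}.
#' @return data.frame with columns feature, block, score, rank.
#' @export
rankFeatures <- function(attribution, direction = c("positive", "negative",
                                                    "absolute"),
                         level = c("global", "perSample"), k = 20L,
                         sample = 1L) {
  direction <- match.arg(direction)
  level <- match.arg(level)
  stopifnot(k >= 1L)
  v <- if (level == "global") colMeans(attribution@values)
       else attribution@values[sample, ]
  feat <- colnames(attribution@values)
  if (is.null(feat)) feat <- sprintf("f%d", seq_along(v))
  score <- switch(direction, positive = v, negative = -v, absolute = abs(v))
  ord <- order(-score, feat, method = "radix")
  k <- min(k, length(v))
  sel <- ord[seq_len(k)]
  data.frame(feature = feat[sel], block = attribution@blocks[sel],
             score = v[sel], rank = seq_len(k), row.names = NULL)
}
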