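#' Construct a fully connected network configuration
#'
#' Defaults follow the DeepDSC-style architecture family: three hidden
#' layers [1024, 512, 256] with ReLU, light dropout, Adam optimization and
#' early stopping on a held-out validation split. All values are
#' configurable; smaller problems warrant smaller widths.
#'
#' @param hidden integer vector of hidden layer widths.
#' @param activation currently "relu".
#' @param dropout dropout rate on hidden activations, in [0, 1).
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param valFraction fraction of training rows held out for early
#'   stopping, in (0, 0.5].
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return an \linkS4class{FNNConfig}.
#' @export
fnnConfig <- function(hidden = c(1024L, 512L, 256L), activation = "relu",
                      dropout = 0.1, learningRate = 1e-4,
                      batchSize = 32L, maxEpochs = 800L, patience = 30L,
                      valFraction = 0.1, seed = 1L) {
  stopifnot(activation == "relu")
  new("FNNConfig", hidden = as.integer(hidden), activation = activation,
      dropout = dropout, learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), valFraction = valFraction,
      seed = as.integer(seed))
}

.initLayers <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    fanIn <- dims[l]
    list(W = matrix(stats::rnorm(fanIn * dims[l + 1L], 0,
                                 sqrt(2 / fanIn)),
                    nrow = fanIn),
         b = numeric(dims[l + 1L]))
  })
}

## forward pass; returns activations per layer (pre-output linear head)
.forward <- function(X, layers, dropout = 0, training = FALSE) {
  nL <- length(layers)
  acts <- vector("list", nL + 1L)
  masks <- vector("list", nL)
  acts[[1L]] <- X
  for (l in seq_len(nL)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    if (l < nL) {
      Z <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(Z)) >= dropout, nrow = nrow(Z)) /
          (1 - dropout)
        Z <- Z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1L]] <- Z
  }
  list(acts = acts, masks = masks)
}

#' Train the fully connected network regressor
#'
#' Minimizes mean-squared error with Adam on minibatches. A validation
#' split of \code{valFraction} of the rows is carved out before training;
#' after every epoch the validation loss is evaluated without dropout, the
#' best-validation weights are kept, and training stops once
#' \code{patience} epochs pass without improvement. Fully reproducible
#' given the config seed.
#'
#' By default the feature columns are z-scored internally (statistics fit
#' on the supplied rows only and stored in the model, so prediction on new
#' data reuses them); pass \code{normalize = FALSE} when the caller has
#' already normalized.
#'
#' @param features a \linkS4class{FeatureMatrix} (>= 20 rows).
#' @param config an \linkS4class{FNNConfig}.
#' @param normalize fit-and-store z-score statistics internally.
#' @return an \linkS4class{FNNModel}.
#' @export
trainFNN <- function(features, config = fnnConfig(), normalize = TRUE) {
  stopifnot(is(features, "FeatureMatrix"), is(config, "FNNConfig"))
  if (nrow(features@data) < 20L)
    stop("need at least 20 training rows")
  stats <- NULL
  if (normalize) {
    zs <- zscoreFeatures(features)
    features <- zs$features
    stats <- zs$stats
  }
  X <- features@data
  y <- features@response
  n <- nrow(X)
  d <- ncol(X)
  dims <- c(d, config@hidden, 1L)
  .withSeed(config@seed, {
    layers <- .initLayers(dims)
    mState <- lapply(layers, function(l)
      list(W = 0 * l$W, b = 0 * l$b))
    vState <- lapply(layers, function(l)
      list(W = 0 * l$W, b = 0 * l$b))
    nVal <- max(1L, round(n * config@valFraction))
    perm <- sample.int(n)
    valIdx <- perm[seq_len(nVal)]
    trIdx <- perm[-seq_len(nVal)]
    Xtr <- X[trIdx, , drop = FALSE]; ytr <- y[trIdx]
    Xval <- X[valIdx, , drop = FALSE]; yval <- y[valIdx]
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    hist <- data.frame(epoch = integer(), train = numeric(),
                       val = numeric())
    sinceBest <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(length(trIdx))
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      epochLoss <- 0
      for (bt in batches) {
        Xb <- Xtr[bt, , drop = FALSE]
        yb <- ytr[bt]
        fw <- .forward(Xb, layers, config@dropout, training = TRUE)
        pred <- fw$acts[[length(layers) + 1L]][, 1L]
        err <- pred - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("NaN/Inf training loss at epoch ", epoch,
               "; lower the learning rate")
        epochLoss <- epochLoss + loss * length(bt)
        delta <- matrix(2 * err / length(bt), ncol = 1L)
        step <- step + 1L
        for (l in rev(seq_along(layers))) {
          A <- fw$acts[[l]]
          gW <- crossprod(A, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(layers[[l]]$W)
            back <- back * (fw$acts[[l]] > 0)
            if (!is.null(fw$masks[[l - 1L]]))
              back <- back * fw$masks[[l - 1L]]
            delta <- back
          }
          mState[[l]]$W <- b1 * mState[[l]]$W + (1 - b1) * gW
          mState[[l]]$b <- b1 * mState[[l]]$b + (1 - b1) * gb
          vState[[l]]$W <- b2 * vState[[l]]$W + (1 - b2) * gW^2
          vState[[l]]$b <- b2 * vState[[l]]$b + (1 - b2) * gb^2
          corr <- config@learningRate *
            sqrt(1 - b2^step) / (1 - b1^step)
          layers[[l]]$W <- layers[[l]]$W -
            corr * mState[[l]]$W / (sqrt(vState[[l]]$W) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            corr * mState[[l]]$b / (sqrt(vState[[l]]$b) + eps)
        }
      }
      valPred <- .forward(Xval, layers)$acts[[length(layers) + 1L]][, 1L]
      valLoss <- mean((valPred - yval)^2)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train = epochLoss / length(trIdx),
                                     val = valLoss))
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, layers = layers, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config@patience) break
      }
    }
    new("FNNModel", weights = best$layers, config = config, stats = stats,
        schema = colnames(X), blocks = features@blocks, history = hist)
  })
}

#' Number of trainable parameters of a model
#' @param model an \linkS4class{FNNModel}.
#' @return integer count of weights plus biases.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@weights, function(l) length(l$W) + length(l$b),
             numeric(1)))
}

#' Predict responses for new drug-cell pairs
#'
#' Applies the model's stored normalization statistics (when present) and
#' runs the forward pass without dropout. The feature schema must match the
#' training schema exactly.
#'
#' @param object an \linkS4class{FNNModel}.
#' @param newdata a \linkS4class{FeatureMatrix} or numeric matrix with the
#'   training columns.
#' @return numeric vector of predictions, one per row, in row order.
#' @export
setMethod("predict", "FNNModel", function(object, newdata) {
  X <- if (is(newdata, "FeatureMatrix")) {
    if (!is.null(object@stats))
      zscoreFeatures(newdata, object@stats)$features@data
    else newdata@data
  } else {
    if (!is.null(object@stats) &&
        all(names(object@stats@mean) %in% colnames(newdata)))
      sweep(sweep(newdata[, names(object@stats@mean), drop = FALSE], 2,
                  object@stats@mean), 2, object@stats@sd, "/")
    else newdata
  }
  if (nrow(X) == 0L) return(numeric(0))
  missing <- setdiff(object@schema, colnames(X))
  extra <- setdiff(colnames(X), object@schema)
  if (length(missing) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(utils::head(missing, 5), collapse = ", "),
         "], extra: [", paste(utils::head(extra, 5), collapse = ", "), "]")
  X <- X[, object@schema, drop = FALSE]
  p <- .forward(X, object@weights)$acts[[length(object@weights) + 1L]][, 1L]
  as.numeric(p)
})
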