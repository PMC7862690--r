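# Independent oracles and shared fixtures for the suite. Oracles are written
# from the definitions, not from the package's code paths.

# Direct linear-solve oracle for random walk with restart:
# p = c (I - (1-c) W)^{-1} e, W column-normalized, dangling columns -> e.
rwrOracle <- function(network, seeds, restartProb) {
  nodes <- networkNodes(network)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(network)
  for (r in seq_len(nrow(e))) {
    A[e$from[r], e$to[r]] <- e$weight[r]
    A[e$to[r], e$from[r]] <- e$weight[r]
  }
  eVec <- numeric(n)
  eVec[match(intersect(seeds, nodes), nodes)] <-
    1 / length(intersect(seeds, nodes))
  W <- A
  for (j in seq_len(n)) {
    s <- sum(A[, j])
    W[, j] <- if (s > 0) A[, j] / s else eVec
  }
  p <- solve(diag(n) - (1 - restartProb) * W, restartProb * eVec)
  stats::setNames(as.numeric(p), nodes)
}

# Brute-force ssGSEA reference: explicit O(N * |S|) running sum, one rank
# position at a time.
ssgseaBrute <- function(expr, geneSet, alpha) {
  ord <- order(-expr, names(expr), method = "radix")
  g <- names(expr)[ord]
  v <- expr[ord]
  inSet <- g %in% geneSet
  nHit <- sum(inSet)
  nMiss <- length(g) - nHit
  denomHit <- 0
  for (i in seq_along(g)) if (inSet[i]) denomHit <- denomHit + abs(v[i])^alpha
  es <- 0; ph <- 0; pm <- 0
  for (i in seq_along(g)) {
    if (inSet[i]) ph <- ph + abs(v[i])^alpha / denomHit
    else pm <- pm + 1 / nMiss
    es <- es + (ph - pm)
  }
  unname(es)
}

# random connected-ish weighted graph for RWR property tests
randomTestNetwork <- function(nNodes, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(nNodes))
  # spanning chain plus random extras keeps at least one component structure
  from <- nodes[-nNodes]
  to <- nodes[-1]
  nExtra <- max(1L, round(nNodes * 0.8))
  ef <- sample(nodes, nExtra, replace = TRUE)
  et <- sample(nodes, nExtra, replace = TRUE)
  keep <- ef != et
  ppiNetwork(c(from, ef[keep]), c(to, et[keep]),
             runif(nNodes - 1L + sum(keep), 0.1, 1),
             extraNodes = nodes)
}

# Laplace quantile sampler for the residual-diagnostic tests
rlaplace <- function(n, location = 0, scale = 1) {
  u <- runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

# Exhaustive-coalition Shapley oracle with a single background row:
# f(S) evaluates x on S and the background elsewhere.
shapleyExact <- function(f, x, b) {
  d <- length(x)
  idx <- seq_len(d)
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  for (i in idx) {
    others <- setdiff(idx, i)
    for (r in seq_len(nrow(subsets))) {
      S <- unlist(subsets[r, ])
      if (S[i]) next
      sz <- sum(S)
      w <- factorial(sz) * factorial(d - sz - 1) / factorial(d)
      zS <- ifelse(S, x, b)
      zSi <- zS; zSi[i] <- x[i]
      phi[i] <- phi[i] + w * (f(rbind(zSi)) - f(rbind(zS)))
    }
  }
  phi
}

# memoised full-scale fixture + features shared by the heavier tests
.acceptanceCache <- new.env(parent = emptyenv())

acceptanceFixture <- function() {
  if (is.null(.acceptanceCache$fix))
    .acceptanceCache$fix <- generateFixture(fixtureConfig(seed = 101L))
  .acceptanceCache$fix
}

acceptanceFeatures <- function() {
  if (is.null(.acceptanceCache$fm)) {
    fix <- acceptanceFixture()
    blocks <- suppressWarnings(suppressMessages(
      featurizeAll(fix, nPerm = 1000L, seed = 202L)))
    .acceptanceCache$blocks <- blocks
    .acceptanceCache$fm <- suppressMessages(
      assembleFeatures(blocks, fix$responses))
  }
  .acceptanceCache$fm
}

# desk-scale training configuration used by the experiment-level tests
experimentConfig <- function(seed = 3L, maxEpochs = 150L, patience = 15L,
                             hidden = c(128L, 64L)) {
  fnnConfig(hidden = hidden, learningRate = 1e-3, batchSize = 64L,
            maxEpochs = maxEpochs, patience = patience, seed = seed)
}
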