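#' @importFrom Matrix sparseMatrix colSums Diagonal
NULL

## weighted adjacency of a PPINetwork as a sparse symmetric matrix,
## columns ordered by network nodes
.adjacency <- function(network) {
  nodes <- network@nodes
  e <- network@edges
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = c(e$weight, e$weight),
                       dims = c(length(nodes), length(nodes)),
                       dimnames = list(nodes, nodes))
}

#' Random walk with restart over a weighted PPI network
#'
#' Computes the stationary distribution of
#' \deqn{p = (1 - c) W p + c e}
#' where \eqn{W} is the column-normalized weighted adjacency matrix, \eqn{e}
#' is uniform over the seed genes that map onto the network, and \eqn{c} is
#' the restart probability. The stationary probability of a node measures
#' its closeness to the seed set. Columns of isolated (degree-zero) nodes
#' are redistributed onto the restart vector so that probability mass is
#' conserved.
#'
#' For networks below \code{exactBelow} nodes the fixed point is obtained by
#' a direct linear solve of \eqn{(I - (1-c)\tilde W)p = c e}; otherwise by
#' power iteration until the L1 change drops below \code{tol}.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seeds character vector of restart genes; seeds absent from the
#'   network are dropped (reported via a message).
#' @param restartProb restart probability \eqn{c} in (0, 1].
#' @param tol L1 convergence tolerance of the power iteration.
#' @param maxIter iteration cap.
#' @param exactBelow use the direct solve when the network has fewer nodes.
#' @return a \linkS4class{NodeScores} object.
#' @examples
#' net <- ppiNetwork(c("A", "B"), c("B", "C"), c(1, 1))
#' randomWalkWithRestart(net, "A", restartProb = 0.5)
#' @export
randomWalkWithRestart <- function(network, seeds, restartProb = 0.7,
                                  tol = 1e-6, maxIter = 1000L,
                                  exactBelow = 500L) {
  stopifnot(restartProb > 0, restartProb <= 1)
  nodes <- network@nodes
  n <- length(nodes)
  mapped <- intersect(unique(seeds), nodes)
  if (length(mapped) == 0L)
    stop("no seed gene maps onto the network")
  if (length(mapped) < length(unique(seeds)))
    message(length(unique(seeds)) - length(mapped),
            " seed gene(s) absent from the network were dropped")
  e <- numeric(n)
  e[match(mapped, nodes)] <- 1 / length(mapped)
  if (restartProb == 1) {
    names(e) <- nodes
    return(new("NodeScores", scores = e, seeds = mapped))
  }
  A <- .adjacency(network)
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  inv <- ifelse(dangling, 0, 1 / deg)
  c0 <- restartProb
  if (n < exactBelow) {
    W <- as.matrix(A %*% Matrix::Diagonal(n, inv))
    if (any(dangling)) W[, dangling] <- e
    p <- solve(diag(n) - (1 - c0) * W, c0 * e)
    p <- as.numeric(p)
  } else {
    p <- e
    for (it in seq_len(maxIter)) {
      spread <- as.numeric(A %*% (p * inv)) + e * sum(p[dangling])
      pNew <- (1 - c0) * spread + c0 * e
      if (sum(abs(pNew - p)) < tol) { p <- pNew; break }
      p <- pNew
    }
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- nodes
  new("NodeScores", scores = p, seeds = mapped)
}

#' Pathway closeness score from a random-walk profile
#'
#' Averages the stationary visit probabilities over the pathway genes that
#' map onto the network, optionally multiplying each gene's probability by a
#' per-gene weight (e.g. its expression in the cell line, yielding the
#' expression-weighted variant used for mutation and CNV enrichment). Genes
#' without a supplied weight default to weight 1; pathway genes absent from
#' the network are excluded from the mean.
#'
#' @param nodeScores a \linkS4class{NodeScores} object.
#' @param pathway character vector of pathway genes.
#' @param geneWeights optional named numeric vector of gene weights.
#' @return mean weighted probability over mapped pathway genes, or NaN (with
#'   a warning) when the pathway does not intersect the network.
#' @export
pathwayCloseness <- function(nodeScores, pathway, geneWeights = NULL) {
  p <- nodeScores@scores
  mapped <- intersect(unique(pathway), names(p))
  if (length(mapped) == 0L) {
    warning("pathway has no genes on the network; returning NaN")
    return(NaN)
  }
  v <- p[mapped]
  if (!is.null(geneWeights)) {
    w <- rep(1, length(mapped))
    hit <- mapped %in% names(geneWeights)
    w[hit] <- geneWeights[mapped[hit]]
    v <- v * w
  }
  mean(v)
}
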