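## descending expression order with deterministic lexicographic tie-break
.rankProfile <- function(expr) {
  stopifnot(!is.null(names(expr)), length(expr) >= 2L)
  ord <- order(-expr, names(expr), method = "radix")
  expr[ord]
}

#' Single-sample GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov-style running sum for one gene set within one
#' sample's expression ranking. Genes are ordered by decreasing expression
#' (ties broken lexicographically by symbol, for determinism); at each rank
#' the cumulative \eqn{|expr|^\alpha}-weighted fraction of in-set genes
#' (P_hit) is compared with the cumulative uniform fraction of out-of-set
#' genes (P_miss), and the enrichment score is the sum of the differences:
#' \deqn{ES = \sum_{i=1}^{N} [P_{hit}(i) - P_{miss}(i)].}
#'
#' @param expr named numeric vector: one cell line's expression profile
#'   (log-TPM). Need not be pre-sorted.
#' @param geneSet character vector of pathway genes.
#' @param alpha rank weighting exponent (>= 0); 0 gives unweighted steps.
#' @return the enrichment score; 0 (with a warning) when the set does not
#'   intersect the profile. An error is raised when the set covers every
#'   profiled gene (the miss distribution is undefined).
#' @export
ssgseaES <- function(expr, geneSet, alpha = 0.25) {
  stopifnot(alpha >= 0)
  prof <- .rankProfile(expr)
  inSet <- names(prof) %in% geneSet
  nHit <- sum(inSet)
  if (nHit == 0L) {
    warning("gene set does not intersect the profile; ES = 0")
    return(0)
  }
  if (nHit == length(prof))
    stop("gene set covers the whole profile; miss distribution undefined")
  w <- abs(prof)^alpha
  pHit <- cumsum(w * inSet) / sum(w[inSet])
  pMiss <- cumsum(!inSet) / (length(prof) - nHit)
  sum(pHit - pMiss)
}

#' ssGSEA enrichment matrix over a pathway collection (EXP block)
#'
#' Scores every cell line's expression profile against every pathway and
#' normalizes each enrichment score by the number of pathway genes present
#' in the profile: \eqn{NES = ES / |S \cap profile|}. Pathways with no
#' mapped genes get NES 0 and are reported.
#'
#' When \code{nPerm > 0}, a gene-permutation z-score is additionally
#' computed per (cell, pathway) as a diagnostic (random same-size gene sets
#' scored on the same profile) and stored in \code{metadata$permZ}; the NES
#' values themselves are unaffected.
#'
#' @param expression cell x gene numeric matrix (log-TPM).
#' @param pathways a \linkS4class{PathwayCollection}.
#' @param alpha rank weighting exponent (default 0.25).
#' @param nPerm permutations for the optional diagnostic (0 = skip).
#' @param seed RNG seed for the diagnostic permutations.
#' @return an \linkS4class{EnrichmentMatrix} with block "EXP".
#' @export
ssgseaMatrix <- function(expression, pathways, alpha = 0.25, nPerm = 0L,
                         seed = 42L) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  cells <- rownames(expression)
  pwNames <- names(pathways@sets)
  genes <- colnames(expression)
  mappedSets <- lapply(pathways@sets, function(g) intersect(g, genes))
  sizes <- lengths(mappedSets)
  unmapped <- sum(sizes == 0L)
  NES <- matrix(0, nrow = length(cells), ncol = length(pwNames),
                dimnames = list(cells, pwNames))
  permZ <- if (nPerm > 0L) NES else NULL
  doCell <- function(prof) {
    inProf <- lapply(mappedSets, function(g) names(prof) %in% g)
    es <- vapply(seq_along(mappedSets), function(j) {
      if (sizes[j] == 0L) return(0)
      .esFromMask(prof, inProf[[j]], alpha)
    }, numeric(1))
    es
  }
  esToNes <- function(es) ifelse(sizes > 0L, es / pmax(sizes, 1L), 0)
  for (ci in seq_along(cells)) {
    prof <- .rankProfile(expression[ci, ])
    es <- doCell(prof)
    NES[ci, ] <- esToNes(es)
    if (nPerm > 0L) {
      permZ[ci, ] <- .withSeed(seed + ci, {
        vapply(seq_along(mappedSets), function(j) {
          k <- sizes[j]
          if (k == 0L) return(0)
          null <- vapply(seq_len(nPerm), function(b) {
            .esFromMask(prof,
                        seq_along(prof) %in% sample.int(length(prof), k),
                        alpha)
          }, numeric(1))
          sdn <- stats::sd(null)
          if (sdn == 0) 0 else (es[j] - mean(null)) / sdn
        }, numeric(1))
      })
    }
  }
  if (unmapped > 0L)
    message(unmapped, " pathway(s) with no genes in the profile; NES = 0")
  new("EnrichmentMatrix", scores = NES, block = "EXP",
      metadata = list(alpha = alpha, unmappedPathways = unmapped,
                      permZ = permZ))
}

## running-sum ES given a sorted profile and its in-set mask
.esFromMask <- function(prof, inSet, alpha) {
  nHit <- sum(inSet)
  if (nHit == 0L || nHit == length(prof)) return(0)
  w <- abs(prof)^alpha
  pHit <- cumsum(w * inSet) / sum(w[inSet])
  pMiss <- cumsum(!inSet) / (length(prof) - nHit)
  sum(pHit - pMiss)
}
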