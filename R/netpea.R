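## RNG hygiene: run expr under a seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Network-based pathway enrichment with permutation z-scores (NetPEA)
#'
#' For every entity (cell line or drug), its seed gene set is diffused over
#' the PPI network by random walk with restart; each pathway is then scored
#' by the mean stationary probability of its mapped genes (optionally
#' expression-weighted, see \code{\link{pathwayCloseness}}). Significance is
#' calibrated by a permutation null: \code{nPerm} random gene sets of the
#' same mapped size are drawn from the network node universe and scored
#' against the same walk profile, and the pathway score is reported as
#' \deqn{z = (s - \mu_{perm}) / \sigma_{perm}.}
#' Null distributions are cached per (entity, set size).
#'
#' Entities whose seed set does not map onto the network get a zero row;
#' pathways that do not intersect the network get zero scores; a null with
#' zero spread yields z = 0. All three events are counted in the result's
#' \code{metadata} and reported via warnings/messages.
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param seedSets named list, entity -> seed gene set (mutated genes,
#'   CNV-altered genes, or expanded drug targets).
#' @param pathways a \linkS4class{PathwayCollection}.
#' @param nPerm number of permutations (>= 2); the study default is 1000.
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @param geneWeights optional named list, entity -> named numeric gene
#'   weights (e.g. log-TPM expression) for the expression-weighted variant.
#'   NULL gives plain NetPEA.
#' @param block feature block tag for the result.
#' @param restartProb,tol passed to \code{\link{randomWalkWithRestart}}.
#' @return an \linkS4class{EnrichmentMatrix} of permutation z-scores,
#'   entities x pathways.
#' @export
netpeaEnrich <- function(network, seedSets, pathways, nPerm = 1000L,
                         seed = 42L, geneWeights = NULL, block = "MUT-Net",
                         restartProb = 0.7, tol = 1e-6) {
  stopifnot(nPerm >= 2L, length(pathways@sets) > 0L)
  if (is.null(names(seedSets)))
    stop("seedSets must be a named list")
  nodes <- network@nodes
  n <- length(nodes)
  pwNames <- names(pathways@sets)
  pwIdx <- lapply(pathways@sets, function(g) {
    idx <- match(unique(g), nodes)
    idx[!is.na(idx)]
  })
  Z <- matrix(0, nrow = length(seedSets), ncol = length(pwNames),
              dimnames = list(names(seedSets), pwNames))
  emptySeeds <- character()
  nanZeroed <- 0L
  sigmaZero <- 0L
  .withSeed(seed, {
    for (ent in names(seedSets)) {
      mapped <- intersect(unique(seedSets[[ent]]), nodes)
      if (length(mapped) == 0L) {
        emptySeeds <- c(emptySeeds, ent)
        next
      }
      ns <- randomWalkWithRestart(network, mapped,
                                  restartProb = restartProb, tol = tol)
      vals <- ns@scores
      if (!is.null(geneWeights) && !is.null(geneWeights[[ent]])) {
        w <- rep(1, n)
        gw <- geneWeights[[ent]]
        hit <- match(names(gw), nodes)
        ok <- !is.na(hit)
        w[hit[ok]] <- gw[ok]
        vals <- vals * w
      }
      sizes <- unique(lengths(pwIdx))
      sizes <- sizes[sizes > 0]
      nullStats <- lapply(stats::setNames(sizes, sizes), function(k) {
        idxm <- vapply(seq_len(nPerm),
                       function(i) sample.int(n, k), integer(k))
        sc <- if (k == 1L) vals[as.integer(idxm)]
              else colMeans(matrix(vals[idxm], nrow = k))
        c(mu = mean(sc), sigma = stats::sd(sc))
      })
      for (j in seq_along(pwIdx)) {
        idx <- pwIdx[[j]]
        if (length(idx) == 0L) { nanZeroed <- nanZeroed + 1L; next }
        s <- mean(vals[idx])
        st <- nullStats[[as.character(length(idx))]]
        if (st["sigma"] == 0) {
          sigmaZero <- sigmaZero + 1L
          Z[ent, j] <- 0
        } else {
          Z[ent, j] <- (s - st["mu"]) / st["sigma"]
        }
      }
    }
  })
  if (length(emptySeeds))
    warning(length(emptySeeds),
            " entit(ies) with no seed genes on the network; rows set to 0: ",
            paste(utils::head(emptySeeds, 5), collapse = ", "))
  if (sigmaZero > 0)
    warning(sigmaZero, " pathway score(s) had a zero-spread null; z set to 0")
  if (nanZeroed > 0)
    message(nanZeroed, " (entity, pathway) score(s) undefined and set to 0")
  new("EnrichmentMatrix", scores = Z, block = block,
      metadata = list(emptySeeds = emptySeeds, nanZeroed = nanZeroed,
                      sigmaZero = sigmaZero, nPerm = as.integer(nPerm),
                      seed = as.integer(seed)))
}
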