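## bundled panel of 20 valid drug-like SMILES; drawn from, never generated,
## so fixture molecules always parse
.SMILES_PANEL <- c(
  "CCO",                              # ethanol
  "c1ccccc1",                         # benzene
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "CN1CCCC1c1cccnc1",                 # nicotine
  "Oc1ccccc1",                        # phenol
  "Cc1ccccc1",                        # toluene
  "COc1ccccc1",                       # anisole
  "c1ccncc1",                         # pyridine
  "Nc1ccccc1",                        # aniline
  "OC(=O)c1ccccc1",                   # benzoic acid
  "c1ccc2ccccc2c1",                   # naphthalene
  "C=Cc1ccccc1",                      # styrene
  "CC(C)=O",                          # acetone
  "OCC(O)CO",                         # glycerol
  "NC(N)=O",                          # urea
  "c1cnc[nH]1",                       # imidazole
  "C1CCCCC1")                         # cyclohexane

#' Configuration of the synthetic fixture generator
#'
#' Defaults describe a desk-scale cell-line panel: 100 cells x 20 drugs
#' (2000 response pairs), 300 genes, 25 pathways of 8-15 genes, a PPI
#' network enriched for within-pathway edges, and a single planted driver
#' pathway whose per-cell activity drives the response with effect size
#' \code{beta} over Gaussian noise \code{noiseSd}.
#'
#' @param nGenes,nCells,nDrugs,nPathways panel dimensions.
#' @param pathwaySize integer range (min, max) of genes per pathway.
#' @param edgeDensity background edge probability of the PPI graph.
#' @param withinPathwayDensity edge probability between genes sharing a
#'   pathway (must exceed \code{edgeDensity}).
#' @param nDriverPathways number of distinct driver pathways drugs draw
#'   their driver from (1 = one shared driver).
#' @param beta response effect size per unit of driver-pathway activity.
#' @param noiseSd response noise standard deviation.
#' @param exprBaseMean,exprBaseSd per-gene baseline log-TPM distribution.
#' @param exprLoading expression shift per unit pathway activity.
#' @param exprNoiseSd per-(cell, gene) expression noise.
#' @param mutRange integer range of mutated genes per cell.
#' @param cnvRange integer range of copy-number-altered genes per cell.
#' @param seed RNG seed.
#' @return list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(nGenes = 300L, nCells = 100L, nDrugs = 20L,
                          nPathways = 25L, pathwaySize = c(8L, 15L),
                          edgeDensity = 0.02, withinPathwayDensity = 0.3,
                          nDriverPathways = 1L, beta = 2,
                          noiseSd = 0.3, exprBaseMean = 5,
                          exprBaseSd = 2, exprLoading = 1.5,
                          exprNoiseSd = 0.5, mutRange = c(5L, 50L),
                          cnvRange = c(10L, 40L), seed = 1L) {
  cfg <- list(nGenes = nGenes, nCells = nCells, nDrugs = nDrugs,
              nPathways = nPathways, pathwaySize = pathwaySize,
              edgeDensity = edgeDensity,
              withinPathwayDensity = withinPathwayDensity,
              nDriverPathways = nDriverPathways, beta = beta,
              noiseSd = noiseSd, exprBaseMean = exprBaseMean,
              exprBaseSd = exprBaseSd, exprLoading = exprLoading,
              exprNoiseSd = exprNoiseSd, mutRange = mutRange,
              cnvRange = cnvRange, seed = seed)
  stopifnot(cfg$nPathways >= 1L, cfg$nCells >= 1L, cfg$nDrugs >= 1L,
            is.finite(cfg$beta), max(pathwaySize) <= nGenes,
            withinPathwayDensity > edgeDensity)
  class(cfg) <- "fixtureConfig"
  cfg
}

#' Generate a complete synthetic dataset with a planted pathway effect
#'
#' Produces every input the pipeline consumes — pathways, a weighted PPI
#' network, expression / mutation / CNV omics, drug SMILES and targets, and
#' a response table — from one seeded draw, plus a ground-truth record of
#' the planted effect. The response model is
#' \deqn{r_{dc} = \beta \cdot a_{c, driver(d)} + \epsilon,\quad
#'       \epsilon \sim N(0, noiseSd^2)}
#' where \eqn{a} is the latent per-cell pathway activity that also shifts
#' the expression of pathway member genes and biases mutation / CNV draws
#' toward active pathways. Drug primary targets sit inside the drug's
#' driver pathway, so DG-Net enrichment points back at it.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @return list with elements \code{pathways}
#'   (\linkS4class{PathwayCollection}), \code{network}
#'   (\linkS4class{PPINetwork}), \code{omics} (\linkS4class{OmicsBundle}),
#'   \code{drugs} (\linkS4class{DrugTable}), \code{responses} (data.frame)
#'   and \code{groundTruth} (driver pathway per drug, activity matrix,
#'   beta, noiseSd).
#' @export
generateFixture <- function(config = fixtureConfig()) {
  stopifnot(inherits(config, "fixtureConfig"))
  .withSeed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$nGenes))
    cells <- sprintf("CL%03d", seq_len(config$nCells))
    drugs <- sprintf("D%02d", seq_len(config$nDrugs))
    pwNames <- sprintf("PW_%02d", seq_len(config$nPathways))

    sets <- lapply(seq_len(config$nPathways), function(i) {
      k <- sample(config$pathwaySize[1]:config$pathwaySize[2], 1L)
      sort(sample(genes, k))
    })
    names(sets) <- pwNames
    pathways <- new("PathwayCollection", sets = sets,
                    descriptions = stats::setNames(
                      rep("synthetic pathway", config$nPathways), pwNames))

    ## PPI: background Erdos-Renyi edges plus densified within-pathway edges
    pairs <- t(utils::combn(config$nGenes, 2L))
    pBg <- config$edgeDensity
    samePw <- rep(FALSE, nrow(pairs))
    for (s in sets) {
      idx <- match(s, genes)
      inSet <- pairs[, 1] %in% idx & pairs[, 2] %in% idx
      samePw <- samePw | inSet
    }
    prob <- ifelse(samePw, config$withinPathwayDensity, pBg)
    keep <- stats::runif(nrow(pairs)) < prob
    w <- sample(700:1000, sum(keep), replace = TRUE) / 1000
    network <- ppiNetwork(genes[pairs[keep, 1]], genes[pairs[keep, 2]],
                          w, extraNodes = genes)

    ## latent per-cell pathway activities
    A <- matrix(stats::rnorm(config$nCells * config$nPathways), nrow =
                  config$nCells, dimnames = list(cells, pwNames))

    base <- stats::rnorm(config$nGenes, config$exprBaseMean,
                         config$exprBaseSd)
    membership <- sapply(sets, function(s) genes %in% s)  # gene x pathway
    expr <- matrix(stats::rnorm(config$nCells * config$nGenes, 0,
                                config$exprNoiseSd),
                   nrow = config$nCells,
                   dimnames = list(cells, genes))
    expr <- expr + rep(base, each = config$nCells) +
      config$exprLoading * (A %*% t(membership))

    ## mutation / CNV draws biased toward the cell's active pathways
    geneWeight <- function(ci) {
      act <- A[ci, ] > 0.5
      1 + 2 * as.numeric(membership %*% act > 0)
    }
    mutList <- lapply(seq_len(config$nCells), function(ci) {
      k <- sample(config$mutRange[1]:config$mutRange[2], 1L)
      data.frame(cell = cells[ci],
                 gene = sample(genes, k, prob = geneWeight(ci)),
                 stringsAsFactors = FALSE)
    })
    mutations <- do.call(rbind, mutList)
    cnv <- matrix(0L, nrow = config$nCells, ncol = config$nGenes,
                  dimnames = list(cells, genes))
    for (ci in seq_len(config$nCells)) {
      k <- sample(config$cnvRange[1]:config$cnvRange[2], 1L)
      hit <- sample.int(config$nGenes, k, prob = geneWeight(ci))
      cnv[ci, hit] <- sample(c(-2L, -1L, 1L, 2L), k, replace = TRUE,
                             prob = c(0.15, 0.35, 0.35, 0.15))
    }
    omics <- new("OmicsBundle", expression = expr, mutations = mutations,
                 cnv = cnv)

    ## drugs: panel SMILES, primary targets inside the driver pathway
    driverPool <- sample(pwNames, config$nDriverPathways)
    driver <- stats::setNames(
      sample(driverPool, config$nDrugs, replace = TRUE), drugs)
    smiles <- stats::setNames(
      rep_len(.SMILES_PANEL, config$nDrugs), drugs)
    primary <- lapply(drugs, function(d) {
      s <- sets[[driver[[d]]]]
      sort(sample(s, min(length(s), sample(1:3, 1L))))
    })
    names(primary) <- drugs
    offTargets <- lapply(drugs, function(d)
      sort(sample(genes, sample(0:2, 1L))))
    names(offTargets) <- drugs
    drugTable <- new("DrugTable", smiles = smiles,
                     primaryTargets = primary, offTargets = offTargets)

    resp <- expand.grid(cell = cells, drug = drugs,
                        stringsAsFactors = FALSE)[, c("drug", "cell")]
    act <- A[cbind(match(resp$cell, cells),
                   match(driver[resp$drug], pwNames))]
    resp$response <- config$beta * act +
      stats::rnorm(nrow(resp), 0, config$noiseSd)
    resp <- resp[order(resp$drug, resp$cell), ]
    rownames(resp) <- NULL

    list(pathways = pathways, network = network, omics = omics,
         drugs = drugTable, responses = resp,
         groundTruth = list(driver = driver, activity = A,
                            beta = config$beta, noiseSd = config$noiseSd,
                            driverPool = driverPool))
  })
}

#' Write a generated fixture to disk in the pipeline's file formats
#'
#' Emits pathways.gmt, ppi.tsv, expression.tsv, mutations.tsv, cnv.tsv,
#' smiles.tsv, targets_primary.tsv, targets_off.tsv, response.tsv and a
#' ground_truth.json sidecar, all plain text, parseable by the package's
#' readers.
#'
#' @param fixture result of \code{\link{generateFixture}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeGMT(fixture$pathways, p("pathways.gmt"))
  writeEdgeList(fixture$network, p("ppi.tsv"))
  wide <- function(m, path) {
    df <- data.frame(cell = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wide(fixture$omics@expression, p("expression.tsv"))
  wide(fixture$omics@cnv, p("cnv.tsv"))
  utils::write.table(fixture$omics@mutations, p("mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(drug = names(fixture$drugs@smiles),
               smiles = unname(fixture$drugs@smiles)),
    p("smiles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  long <- function(lst, path) {
    df <- data.frame(
      drug = rep(names(lst), lengths(lst)),
      gene = unlist(lst, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  long(fixture$drugs@primaryTargets, p("targets_primary.tsv"))
  long(fixture$drugs@offTargets[lengths(fixture$drugs@offTargets) > 0],
       p("targets_off.tsv"))
  writeResponse(fixture$responses, p("response.tsv"))
  gt <- fixture$groundTruth
  jsonlite::write_json(
    list(driver = as.list(gt$driver), beta = gt$beta,
         noiseSd = gt$noiseSd, driverPool = gt$driverPool,
         activity = list(cells = rownames(gt$activity),
                         pathways = colnames(gt$activity),
                         values = unname(apply(gt$activity, 1, as.list)))),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Engineer all five feature blocks from a fixture (or real inputs)
#'
#' Convenience driver used by the experiments: CHEM fingerprints, DG-Net
#' enrichment of expanded targets (plain NetPEA), EXP ssGSEA, MUT-Net and
#' CNV-Net expression-weighted NetPEA.
#'
#' @param fixture list with elements pathways, network, omics, drugs (as
#'   returned by \code{\link{generateFixture}}).
#' @param nPerm permutations for the NetPEA nulls.
#' @param seed RNG seed.
#' @param nBits,radius CHEM fingerprint settings.
#' @param alpha ssGSEA exponent.
#' @return named list of the five blocks, ready for
#'   \code{\link{assembleFeatures}}.
#' @export
featurizeAll <- function(fixture, nPerm = 1000L, seed = 42L,
                         nBits = 256L, radius = 2L, alpha = 0.25) {
  exprW <- apply(fixture$omics@expression, 1L, identity,
                 simplify = FALSE)  # cell -> named gene weights
  mutSets <- split(fixture$omics@mutations$gene,
                   fixture$omics@mutations$cell)
  cnvSets <- cnvGeneSets(fixture$omics@cnv)
  dg <- expandTargets(fixture$drugs@primaryTargets,
                      fixture$drugs@offTargets, fixture$network)
  list(
    "CHEM" = fingerprintTable(fixture$drugs@smiles, radius = radius,
                              nBits = nBits),
    "DG-Net" = netpeaEnrich(fixture$network, dg@sets, fixture$pathways,
                            nPerm = nPerm, seed = seed, block = "DG-Net"),
    "EXP" = ssgseaMatrix(fixture$omics@expression, fixture$pathways,
                         alpha = alpha),
    "MUT-Net" = netpeaEnrich(fixture$network, mutSets, fixture$pathways,
                             nPerm = nPerm, seed = seed + 1L,
                             geneWeights = exprW, block = "MUT-Net"),
    "CNV-Net" = netpeaEnrich(fixture$network, cnvSets, fixture$pathways,
                             nPerm = nPerm, seed = seed + 2L,
                             geneWeights = exprW, block = "CNV-Net"))
}
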