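smallCfgFix <- fixtureConfig(nGenes = 120L, nCells = 25L, nDrugs = 6L,
                             nPathways = 8L, mutRange = c(5L, 20L),
                             cnvRange = c(5L, 20L), seed = 15L)

test_that("generation is deterministic given the seed", {
  a <- generateFixture(smallCfgFix)
  b <- generateFixture(smallCfgFix)
  expect_identical(a$responses, b$responses)
  expect_identical(a$omics@expression, b$omics@expression)
  expect_identical(networkEdges(a$network), networkEdges(b$network))
  expect_identical(a$groundTruth$driver, b$groundTruth$driver)
})

test_that("generated data satisfy their own container invariants", {
  fix <- generateFixture(smallCfgFix)
  expect_true(validObject(fix$pathways))
  expect_true(validObject(fix$network))
  expect_true(validObject(fix$omics))
  expect_equal(nrow(fix$responses), 6L * 25L)
  expect_false(any(duplicated(paste(fix$responses$drug,
                                    fix$responses$cell))))
  # every drug's primary targets sit inside its driver pathway
  gt <- fix$groundTruth
  for (d in names(gt$driver)) {
    expect_true(all(fix$drugs@primaryTargets[[d]] %in%
                      geneSets(fix$pathways)[[gt$driver[[d]]]]))
  }
})

test_that("within-pathway edge density exceeds the background density", {
  fix <- generateFixture(smallCfgFix)
  e <- networkEdges(fix$network)
  genes <- networkNodes(fix$network)
  inSame <- rep(FALSE, nrow(e))
  for (s in geneSets(fix$pathways))
    inSame <- inSame | (e$from %in% s & e$to %in% s)
  pairKey <- function(m) paste(m[, 1], m[, 2])
  allPairs <- t(utils::combn(genes, 2))
  samePwPair <- rep(FALSE, nrow(allPairs))
  for (s in geneSets(fix$pathways))
    samePwPair <- samePwPair |
      (allPairs[, 1] %in% s & allPairs[, 2] %in% s)
  densityIn <- sum(inSame) / sum(samePwPair)
  densityOut <- sum(!inSame) / sum(!samePwPair)
  expect_gt(densityIn, densityOut)
})

test_that("the planted driver pathway is visible in the EXP block", {
  fix <- generateFixture(fixtureConfig(nGenes = 150L, nCells = 40L,
                                       nDrugs = 4L, nPathways = 10L,
                                       seed = 16L))
  nes <- ssgseaMatrix(fix$omics@expression, fix$pathways)
  drv <- fix$groundTruth$driverPool[1]
  act <- fix$groundTruth$activity[, drv]
  rho <- stats::cor(scoreMatrix(nes)[names(act), drv], act,
                    method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("degenerate configurations are rejected", {
  expect_error(fixtureConfig(nCells = 0L))
  expect_error(fixtureConfig(pathwaySize = c(10L, 500L), nGenes = 100L))
  expect_error(fixtureConfig(withinPathwayDensity = 0.01,
                             edgeDensity = 0.02))
})

test_that("mutation burden per cell stays within the configured range", {
  fix <- generateFixture(smallCfgFix)
  counts <- table(fix$omics@mutations$cell)
  expect_true(all(counts >= 5L & counts <= 20L))
})
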