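# pathDRP — pathway-based, explainable drug response prediction

`pathDRP` predicts the sensitivity of cancer cell lines to drugs
(log-transformed IC50) from **pathway-level features** and explains every
prediction with Shapley values. Instead of feeding tens of thousands of
gene-level measurements to a model, it engineers five compact feature
blocks per (drug, cell) pair:

* **CHEM** — Morgan (circular) fingerprint bits of the drug structure;
* **DG-Net** — network pathway enrichment of the drug's targets, expanded
  with off-targets and their PPI neighbors;
* **EXP** — single-sample GSEA (ssGSEA) enrichment of the cell's
  expression profile, NES = ES / gene-set size;
* **MUT-Net** — expression-weighted network pathway enrichment of the
  cell's mutated genes;
* **CNV-Net** — the same for copy-number-altered genes (GISTIC score ≠ 0).

The two network blocks use **NetPEA**: a random walk with restart
`p = (1 − c)·W·p + c·e` diffuses a seed gene set over a weighted
protein–protein interaction network; each pathway is scored by the mean
stationary probability of its genes (optionally multiplied by per-gene
expression) and calibrated against a size-matched permutation null,
`z = (s − μ_perm)/σ_perm`. A fully connected ReLU network (Adam, dropout,
early stopping on an internal validation split) regresses the response;
repeated k-fold, leave-one-drug-out and leave-one-cell-out drivers report
MAE / RMSE / R² / PCC, a Laplace residual diagnostic, and a cross-dataset
error floor. Sampling Shapley attributions (exact local accuracy, exact
linear closed form) rank the pathways behind each prediction.

A seeded synthetic-data generator emits every input format the pipeline
consumes — pathways (GMT), a weighted PPI edge list, expression /
mutation / CNV tables, SMILES, target tables, responses — with a planted
pathway→response effect, so the entire pipeline is testable end to end
without any external download.

## Worked example

```r
library(pathDRP)

fix <- generateFixture(fixtureConfig(nGenes = 150L, nCells = 40L,
                                     nDrugs = 8L, nPathways = 12L,
                                     seed = 42L))
blocks   <- featurizeAll(fix, nPerm = 200L, seed = 1L)
features <- assembleFeatures(blocks, fix$responses)
features
#> FeatureMatrix: 320 pairs x 304 features
#>   [CHEM:256 DG-Net:12 EXP:12 MUT-Net:12 CNV-Net:12]

cfg  <- fnnConfig(hidden = c(64L, 32L), learningRate = 1e-3,
                  batchSize = 64L, maxEpochs = 80L, patience = 10L,
                  seed = 1L)
plan <- makeSplits(features@drug, features@cell, "kfold",
                   k = 5L, repeats = 1L, seed = 2L)
res  <- runExperiment(features, plan, cfg)
print(res$aggregate, digits = 3)
#>      metric  mean     sd
#> MAE     MAE 0.582 0.0570
#> RMSE   RMSE 0.710 0.0871
#> R2       R2 0.879 0.0391
#> PCC     PCC 0.949 0.0150
```

Cross-validated correlation of 0.95 on 320 pairs: the model recovers the
planted pathway effect. Explaining the most-sensitive pairs names the
pathway responsible:

```r
model <- trainFNN(features, cfg)
top   <- order(-response(features))[1:40]
attr  <- shapleyAttributions(model, scoreMatrix(features)[top, ],
                             scoreMatrix(features)[1:100, ],
                             nSamples = 10L, seed = 3L,
                             blocks = featureBlocks(features))
rankFeatures(attr, "positive", k = 3L)
#>         feature   block     score rank
#> 1     EXP:PW_10     EXP 1.1056365    1
#> 2 MUT-Net:PW_10 MUT-Net 0.8660057    2
#> 3 CNV-Net:PW_10 CNV-Net 0.2619346    3

fix$groundTruth$driverPool
#> [1] "PW_10"
```

The top positive contributors are the expression, mutation and CNV
enrichments of `PW_10` — exactly the pathway the generator planted as the
driver of drug response.

A thin CLI over the same functions lives at `inst/scripts/pathdrp`
(subcommands `simulate`, `featurize-chem`, `featurize-exp`,
`featurize-net`, `cv`).

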