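---
title: "Pathway-based drug response prediction: models and methods"
author: "pathDRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based drug response prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given a panel of cancer cell lines with molecular profiles (expression,
somatic mutations, copy-number alterations) and a set of drugs with known
structures and protein targets, predict the sensitivity of each (drug,
cell) pair — a log-transformed IC50 — and explain each prediction in terms
of biological pathways rather than individual genes. Pathway-level
features make the regression both more robust (hundreds of features
instead of tens of thousands of genes) and directly interpretable: a
feature is "activity of the NF-κB pathway in this cell line", not an
anonymous latent dimension.

`pathDRP` engineers five feature blocks per pair and regresses the
response with a fully connected network:

| block   | entity | content                                              |
|---------|--------|------------------------------------------------------|
| CHEM    | drug   | Morgan (circular) fingerprint bits of the structure  |
| DG-Net  | drug   | network pathway enrichment of expanded drug targets  |
| EXP     | cell   | ssGSEA normalized enrichment of the expression profile |
| MUT-Net | cell   | expression-weighted network enrichment of mutations  |
| CNV-Net | cell   | expression-weighted network enrichment of CNA genes  |

# Network pathway enrichment (NetPEA)

A seed gene set (a cell's mutated genes, its copy-number-altered genes, or
a drug's expanded targets) is diffused over a weighted protein-protein
interaction network by random walk with restart:

$$p = (1 - c)\,W p + c\,e$$

with $W$ the column-normalized weighted adjacency, $e$ uniform over the
mapped seeds, and restart probability $c$. The stationary $p$ measures
every node's closeness to the seed set. A pathway is scored by the mean of
$p$ over its member genes; for the mutation and CNV blocks each gene's
probability is first multiplied by its expression in that cell line
(log-TPM), coupling the walk to the cell's transcriptional state. The raw
score depends strongly on pathway size, so it is calibrated against a
permutation null: random gene sets of the same mapped size are drawn from
the network node universe and scored against the *same* walk vector, and
the reported value is $z = (s - \mu_{perm})/\sigma_{perm}$.

Numerical choices:

* **Restart probability** defaults to $c = 0.7$, the common convention for
  gene-network propagation; it is a config argument.
* **Solver.** Networks under 500 nodes use the direct solve
  $(I - (1-c)\tilde W)p = ce$; larger networks use power iteration to an
  L1 tolerance of $10^{-6}$ (cap 1000 iterations). Columns of isolated
  nodes are redistributed onto the restart vector so mass is conserved.
* **Permutation universe** is the full network node set, keyed on the
  number of pathway genes that actually map onto the network, with the
  null cached per (entity, set size). 1000 permutations is the default.
* **Degenerate cases.** Entities whose seeds miss the network entirely
  get a zero row; pathways disjoint from the network get zero scores; a
  zero-spread null yields $z = 0$. All three are counted in the result
  metadata — zeros rather than NaN, so the design matrix stays complete.

A genuinely open reading: the enrichment literature permutes either the
seed side or the pathway side. We permute pathway-side gene sets (random
sets scored against the fixed walk), which keeps one walk per entity and
makes the null exhaustively enumerable on small networks — the property
the test suite exploits. Expression weights are applied on the stored
log-TPM scale.

# Single-sample GSEA (EXP block)

Each cell's genes are ranked by decreasing expression (ties broken
lexicographically by symbol, for bit-reproducibility) and each pathway is
scored with the weighted running-sum statistic

$$ES = \sum_{i=1}^{N}\left[P_{hit}(i) - P_{miss}(i)\right],$$

where $P_{hit}$ accumulates $|x|^{\alpha}$ weights over in-set genes and
$P_{miss}$ accumulates uniformly over out-of-set genes. The reported value
is $NES = ES / |S \cap \text{profile}|$ — enrichment normalized by the
mapped set size. $\alpha$ defaults to 0.25, the standard single-sample
weighting. A gene-permutation $z$ per (cell, pathway) is available as an
optional diagnostic but is not part of the feature matrix.

# Chemical fingerprints (CHEM block)

Morgan/ECFP-type circular fingerprints are computed natively: SMILES are
canonicalized and parsed through OpenBabel, each atom starts from an
invariant tuple (atomic number, heavy degree, total bond order, formal
charge, implicit hydrogen count, ring membership), and identifiers are
iteratively re-hashed with the sorted (bond order, neighbor id) pairs up
to the configured radius (default 2, the ECFP4-equivalent). All
identifiers are folded modulo the bit length (default 256) into a binary
presence/absence vector. Canonicalizing before parsing guarantees that
any SMILES spelling of a molecule — including different kekulé spellings
of symmetric aromatic rings — produces identical bits. Because hash
functions differ across toolkits, conformance with a reference
implementation is asserted at the similarity-structure level (Tanimoto
correlation across a bundled panel), not bit-for-bit.

# Drug target expansion (DG-Net seeds)

Drug target lists are short (a handful of genes), too sparse to seed a
useful walk. Each drug's primary targets are united with curated
off-targets and expanded with their first-order PPI neighbors; the
expanded set seeds a *plain* (unweighted) NetPEA — drug features should
not depend on any particular cell's expression. Drugs with no usable
target information are dropped and reported. Neighbor expansion is
deliberately one hop: the walk itself propagates further influence.

# Model and evaluation

Features are concatenated per (drug, cell) pair — drug blocks broadcast
over cells and vice versa — and z-scored per column with population
statistics **fit on training rows only**; zero-variance columns are
dropped and recorded. `trainFNN` fits these statistics internally on
whatever rows it is given, so the cross-validation driver is leak-free by
construction: test folds never touch the normalization. Binary CHEM bits
are z-scored like every other column.

The regressor is a fully connected ReLU network trained with Adam on
minibatches under MSE loss, with dropout on hidden activations, a
held-out validation split (default 10% of the training rows, carved from
*within* the training fold) and early stopping with best-weight restore.
Package defaults are hidden widths [1024, 512, 256], dropout 0.1,
learning rate $10^{-4}$, batch 32, patience 30 — a DeepDSC-family
architecture. The experiments in the test suite and the acceptance script
use a smaller configuration matched to the synthetic study's 2000 pairs ×
~356 features: hidden [128, 64], learning rate $10^{-3}$, batch 64, at
most 150 epochs (40 for the leave-one-out sweeps, which train one model
per held-out entity). These are experiment-level choices; a larger study
warrants the package defaults.

Evaluation drivers cover repeated k-fold (default 10-fold × 5 repeats),
leave-one-drug-out (every pair of one drug held out) and
leave-one-cell-out, reporting MAE, RMSE, $R^2$ and Pearson correlation
per fold with means and both across-fold and across-repeat standard
deviations (the literature is ambiguous about which "±" is meant, so both
are reported). Two diagnostics complete the module: a Laplace residual
test (maximum-likelihood fit by median and mean absolute deviation,
Kolmogorov–Smirnov statistic against the fitted CDF — the
Anderson–Darling and Watson variants are out of scope, KS suffices for
the diagnostic role) and a cross-dataset *floor*: the MAE/RMSE between
two response tables on their shared pairs, the irreducible error of any
transfer experiment.

# Shapley explanations

Attributions use model-agnostic sampling (permutation) Shapley with
background replacement: "feature removed" means "set to a background
row's value". The base value is the mean prediction over the background
set; after sampling, the residual of the local-accuracy identity is
spread equally over features, so `base + sum(phi) = prediction` holds
exactly. For a linear model with a single background row the estimate is
exact for any number of permutations — the closed form
$\phi_i = w_i(x_i - b_i)$ — which the test suite uses as an oracle,
together with exhaustive coalition enumeration at three features.
Positive attributions push the prediction up; for responses stored as
increase in $-\log(\mathrm{IC50})$ that reads as *sensitizing*. The
global report ranks features by mean signed value across the explained
rows; explaining the most-sensitive pairs (highest observed response) is
the natural way to surface positively contributing pathways.

# The synthetic study

`generateFixture` emits every input format the pipeline consumes, from
one seeded draw, with a planted effect to recover:

* 300 genes, 100 cells, 20 drugs (2000 pairs), 25 pathways of 8–15 genes;
* a PPI network with background edge density 0.02 and within-pathway
  density 0.3 (propagation has to find pathway structure, so the graph
  contains some);
* latent per-cell pathway activities $a_{cP} \sim N(0,1)$ that shift the
  expression of member genes by 1.5 per activity unit over gene-level
  noise of SD 0.5, and bias mutation (5–50 genes/cell) and CNV (10–40
  genes/cell) draws toward active pathways;
* drugs drawn from a bundled panel of 20 valid drug-like SMILES, with
  primary targets sampled inside the drug's driver pathway;
* response $r_{dc} = \beta\,a_{c,driver(d)} + \varepsilon$ with
  $\beta = 2$ and $\varepsilon \sim N(0, 0.3^2)$ — a signal-to-noise
  ratio a strong targeted-agent screen might show.

By default all drugs share **one** driver pathway. With per-drug drivers
the response couples drug identity to cell state multiplicatively, and
recovering it tests the optimizer more than the feature engineering; a
single shared driver keeps the planted effect identifiable, which is what
the recovery and explainability checks need. `nDriverPathways` restores
the harder design. Ground truth (drivers, activities, $\beta$) is written
to a sidecar file so recovery tests never reach into generator internals.

What the generator does *not* emulate: cancer-type cluster structure,
realistic IC50 marginals, dose–response measurement error, gene–gene
correlation beyond pathway co-membership, and drug structures related to
their targets. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is correct and leak-free — not that it attains any
particular accuracy on real screens.

# Known limitations

* The ssGSEA normalization follows the "ES divided by set size" reading;
  other implementations normalize by a permutation statistic instead.
* Fingerprint bits are presence/absence; count-folded variants are not
  implemented.
* The network trains on CPU; at the package-default architecture and
  GDSC-scale data, expect hours, not minutes.
* The Laplace diagnostic's p-value treats the fitted location/scale as
  fixed, the usual (slightly conservative-biased) plug-in KS caveat.
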