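#' @import methods
NULL

#' Collection of named gene sets (pathways)
#'
#' Holds an ordered list of pathways, each a character vector of unique gene
#' symbols, plus a free-text description per set. This is the feature
#' vocabulary of the package: every enrichment block scores entities against
#' these sets.
#'
#' @slot sets named list of character vectors; names are pathway names.
#' @slot descriptions character vector parallel to \code{sets}.
#' @export
setClass("PathwayCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("PathwayCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return("collection must contain at least one set")
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    return("pathway names must be unique non-empty strings")
  if (length(object@descriptions) != length(s))
    return("one description per set required")
  for (i in seq_along(s)) {
    g <- s[[i]]
    if (length(g) == 0L) return(sprintf("set '%s' is empty", names(s)[i]))
    if (!is.character(g) || any(!nzchar(g)))
      return(sprintf("set '%s' has empty gene symbols", names(s)[i]))
    if (anyDuplicated(g))
      return(sprintf("set '%s' has duplicate genes", names(s)[i]))
  }
  TRUE
})

#' Weighted undirected protein-protein interaction network
#'
#' Edges carry weights in (0, 1] (rescaled STRING-style combined scores).
#' The edge table is stored in canonical orientation (from < to
#' lexicographically) with no self-loops and no duplicates.
#'
#' @slot nodes character vector of gene symbols.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
setClass("PPINetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% colnames(e)))
    return("edges must have columns from, to, weight")
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$weight <= 0)) return("edge weights must be > 0")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("duplicate edges present")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints missing from node list")
  }
  if (anyDuplicated(object@nodes)) return("duplicate nodes")
  TRUE
})

#' Omics data bundle for a panel of cell lines
#'
#' @slot expression cell x gene numeric matrix (log-TPM), finite after
#'   imputation.
#' @slot mutations data.frame with columns \code{cell}, \code{gene}; one row
#'   per mutated (cell, gene) pair.
#' @slot cnv cell x gene integer matrix of GISTIC levels in \{-2,...,2\}.
#' @export
setClass("OmicsBundle",
  representation(expression = "matrix", mutations = "data.frame",
                 cnv = "matrix"))

setValidity("OmicsBundle", function(object) {
  if (any(!is.finite(object@expression)))
    return("expression must be finite after imputation")
  if (!all(c("cell", "gene") %in% colnames(object@mutations)))
    return("mutations must have columns cell, gene")
  if (length(object@cnv) > 0 && !all(object@cnv %in% -2:2))
    return("cnv values must be GISTIC levels in {-2,-1,0,1,2}")
  TRUE
})

#' Drug annotation table: structures and target genes
#'
#' @slot smiles named character vector, drug id -> SMILES.
#' @slot primaryTargets named list, drug id -> character vector of genes.
#' @slot offTargets named list, drug id -> character vector of genes.
#' @export
setClass("DrugTable",
  representation(smiles = "character", primaryTargets = "list",
                 offTargets = "list"))

#' Stationary visit probabilities of a random walk with restart
#'
#' @slot scores named numeric vector over network nodes; non-negative, sums
#'   to one.
#' @slot seeds character vector of the restart genes that mapped onto the
#'   network.
#' @export
setClass("NodeScores",
  representation(scores = "numeric", seeds = "character"))

setValidity("NodeScores", function(object) {
  p <- object@scores
  if (is.null(names(p))) return("scores must be named by node")
  if (any(p < -1e-12)) return("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) return("probabilities must sum to 1")
  TRUE
})

#' Entity x pathway enrichment score matrix
#'
#' Rows are entities (cell lines or drugs), columns are pathways. Values are
#' permutation z-scores (DG-Net / MUT-Net / CNV-Net blocks) or normalized
#' enrichment scores (EXP block).
#'
#' @slot scores numeric matrix with entity rownames and pathway colnames.
#' @slot block one of "DG-Net", "EXP", "MUT-Net", "CNV-Net".
#' @slot metadata list of diagnostics (e.g. entities with empty seed sets,
#'   count of NaN scores zeroed).
#' @export
setClass("EnrichmentMatrix",
  representation(scores = "matrix", block = "character", metadata = "list"))

setValidity("EnrichmentMatrix", function(object) {
  if (!object@block %in% c("DG-Net", "EXP", "MUT-Net", "CNV-Net"))
    return("unknown feature block tag")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    return("scores must have entity rownames and pathway colnames")
  if (any(!is.finite(object@scores)))
    return("scores must be finite (NaN policy is applied at construction)")
  TRUE
})

#' Drug fingerprint block (CHEM features)
#'
#' @slot bits drug x bit binary matrix.
#' @slot radius Morgan radius used.
#' @slot nBits fingerprint length.
#' @slot dropped drug ids whose SMILES failed to parse.
#' @export
setClass("FingerprintBlock",
  representation(bits = "matrix", radius = "integer", nBits = "integer",
                 dropped = "character"))

setValidity("FingerprintBlock", function(object) {
  if (length(object@bits) > 0 && !all(object@bits %in% c(0L, 1L)))
    return("fingerprint entries must be 0/1")
  if (ncol(object@bits) != object@nBits)
    return("bit matrix width must equal nBits")
  TRUE
})

#' Expanded per-drug seed gene sets for DG-Net enrichment
#'
#' @slot sets named list, drug -> expanded gene set.
#' @slot provenance named list, drug -> named character vector mapping each
#'   gene to "primary", "off_target" or "neighbor".
#' @slot dropped drugs excluded for having no target information.
#' @export
setClass("DrugGeneSets",
  representation(sets = "list", provenance = "list", dropped = "character"))

#' Pair-level design matrix with labeled feature blocks
#'
#' One row per (drug, cell) response record for which every selected block
#' is available; columns carry a block tag.
#'
#' @slot data numeric matrix, rows = pairs, no missing values.
#' @slot blocks character vector, block tag per column.
#' @slot drug,cell character vectors, ids per row.
#' @slot response numeric response (log-transformed IC50) per row.
#' @export
setClass("FeatureMatrix",
  representation(data = "matrix", blocks = "character", drug = "character",
                 cell = "character", response = "numeric"))

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@data)
  if (length(object@drug) != n || length(object@cell) != n ||
      length(object@response) != n)
    return("row annotations must match the number of rows")
  if (length(object@blocks) != ncol(object@data))
    return("one block tag per column required")
  if (any(!is.finite(object@data))) return("feature values must be finite")
  if (any(!is.finite(object@response))) return("responses must be finite")
  TRUE
})

#' Per-column normalization statistics
#'
#' Means and population standard deviations fit on training rows only;
#' zero-variance columns are recorded and dropped when the stats are applied.
#'
#' @slot mean,sd named numeric vectors over retained columns.
#' @slot dropped names of zero-variance columns removed at fit time.
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric", dropped = "character"))

setValidity("NormalizationStats", function(object) {
  if (length(object@mean) != length(object@sd))
    return("mean and sd must have equal length")
  if (any(object@sd <= 0)) return("retained columns must have sd > 0")
  TRUE
})

#' Configuration of the fully connected network regressor
#'
#' @slot hidden integer vector of hidden layer widths (>= 1 layer).
#' @slot activation activation name ("relu").
#' @slot dropout dropout rate in [0, 1).
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot maxEpochs training epoch cap.
#' @slot patience early-stopping patience in epochs (>= 1).
#' @slot valFraction fraction of training rows held out for early stopping,
#'   in (0, 0.5].
#' @slot seed RNG seed controlling initialization, shuffling and dropout.
#' @export
setClass("FNNConfig",
  representation(hidden = "integer", activation = "character",
                 dropout = "numeric", learningRate = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", valFraction = "numeric",
                 seed = "integer"))

setValidity("FNNConfig", function(object) {
  if (length(object@hidden) < 1L || any(object@hidden < 1L))
    return("at least one hidden layer of width >= 1 required")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@valFraction <= 0 || object@valFraction > 0.5)
    return("valFraction must be in (0, 0.5]")
  TRUE
})

#' Trained neural-network regressor
#'
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot config the \linkS4class{FNNConfig} used.
#' @slot stats \linkS4class{NormalizationStats} applied at predict time
#'   (or NULL when the caller normalizes).
#' @slot schema ordered feature column labels expected at predict time.
#' @slot blocks block tag per schema column.
#' @slot history data.frame of per-epoch training and validation loss.
#' @export
setClass("FNNModel",
  representation(weights = "list", config = "FNNConfig", stats = "ANY",
                 schema = "character", blocks = "character",
                 history = "data.frame"))

#' Cross-validation / leave-one-out split plan
#'
#' @slot mode "kfold", "lodo" or "loco".
#' @slot folds list of lists with integer elements \code{train}, \code{test};
#'   for kfold, folds are grouped by repeat via the \code{repeat} element.
#' @slot k,repeats,seed plan parameters.
#' @export
setClass("SplitPlan",
  representation(mode = "character", folds = "list", k = "integer",
                 repeats = "integer", seed = "integer"))

#' Shapley attributions for a set of predictions
#'
#' Local accuracy holds per row: baseValue + sum of attributions equals the
#' model prediction (up to the enforced tolerance).
#'
#' @slot values sample x feature matrix of Shapley values.
#' @slot baseValue expected model output over the background set.
#' @slot blocks block tag per feature.
#' @slot predictions model output per sample.
#' @export
setClass("Attribution",
  representation(values = "matrix", baseValue = "numeric",
                 blocks = "character", predictions = "numeric"))

setValidity("Attribution", function(object) {
  if (length(object@blocks) != ncol(object@values))
    return("one block tag per feature required")
  if (length(object@predictions) != nrow(object@values))
    return("one prediction per sample required")
  TRUE
})
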