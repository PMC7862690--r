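#' @include AllClasses.R
NULL

#' Gene sets stored in a collection
#' @param x a \linkS4class{PathwayCollection}
#' @return named list of character vectors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' Node identifiers of a network
#' @param x a \linkS4class{PPINetwork}
#' @return character vector of gene symbols
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "PPINetwork", function(x) x@nodes)

#' Edge table of a network
#' @param x a \linkS4class{PPINetwork}
#' @return data.frame with columns from, to, weight
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "PPINetwork", function(x) x@edges)

#' Numeric score matrix of an enrichment or feature object
#' @param x an \linkS4class{EnrichmentMatrix}, \linkS4class{FingerprintBlock},
#'   \linkS4class{FeatureMatrix} or \linkS4class{Attribution}
#' @return numeric matrix
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "EnrichmentMatrix", function(x) x@scores)

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "FingerprintBlock", function(x) x@bits)

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "FeatureMatrix", function(x) x@data)

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "Attribution", function(x) x@values)

#' Feature block tag(s)
#' @param x an object carrying block labels
#' @return character scalar (EnrichmentMatrix) or vector per column
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname featureBlocks
#' @export
setMethod("featureBlocks", "EnrichmentMatrix", function(x) x@block)

#' @rdname featureBlocks
#' @export
setMethod("featureBlocks", "FeatureMatrix", function(x) x@blocks)

#' @rdname featureBlocks
#' @export
setMethod("featureBlocks", "Attribution", function(x) x@blocks)

#' Response vector of a feature matrix
#' @param x a \linkS4class{FeatureMatrix}
#' @return numeric vector of log-transformed IC50 values, one per row
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' @rdname response
#' @export
setMethod("response", "FeatureMatrix", function(x) x@response)

#' Drug / cell identifiers per row of a feature matrix
#' @param x a \linkS4class{FeatureMatrix}
#' @return data.frame with columns drug, cell
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "FeatureMatrix",
  function(x) data.frame(drug = x@drug, cell = x@cell,
                         stringsAsFactors = FALSE))

setMethod("show", "PathwayCollection", function(object) {
  sz <- lengths(object@sets)
  cat("PathwayCollection with", length(object@sets), "gene sets",
      sprintf("(sizes %d-%d)\n", min(sz), max(sz)))
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix [%s]: %d entities x %d pathways\n",
              object@block, nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "FingerprintBlock", function(object) {
  cat(sprintf(
    "FingerprintBlock: %d drugs x %d bits (radius %d)%s\n",
    nrow(object@bits), object@nBits, object@radius,
    if (length(object@dropped))
      sprintf(", %d dropped", length(object@dropped)) else ""))
})

setMethod("show", "FeatureMatrix", function(object) {
  tb <- table(factor(object@blocks, levels = unique(object@blocks)))
  cat(sprintf("FeatureMatrix: %d pairs x %d features [%s]\n",
              nrow(object@data), ncol(object@data),
              paste(sprintf("%s:%d", names(tb), tb), collapse = " ")))
})

setMethod("show", "FNNModel", function(object) {
  d <- vapply(object@weights, function(l) ncol(l$W), integer(1))
  cat(sprintf("FNNModel: %d -> %s -> 1, %d epochs trained\n",
              length(object@schema),
              paste(object@config@hidden, collapse = "-"),
              nrow(object@history)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan [%s]: %d folds\n", object@mode,
              length(object@folds)))
})

setMethod("show", "Attribution", function(object) {
  cat(sprintf("Attribution: %d samples x %d features, base value %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
})
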