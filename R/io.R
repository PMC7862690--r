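#' @importFrom data.table fread fwrite
#' @importFrom utils write.table
NULL

#' Read a GMT gene-set file
#'
#' Standard MSigDB-style format: one set per line, tab-separated fields
#' \code{name}, \code{description}, then one gene symbol per field.
#' Duplicate genes within a line are removed preserving first occurrence.
#'
#' @param path path to a GMT file.
#' @return a \linkS4class{PathwayCollection}.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("PID_X\tna\tG1\tG2", tf)
#' geneSets(readGMT(tf))
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    nm[i] <- f[1]
    desc[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop("duplicate pathway names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  names(desc) <- nm
  new("PathwayCollection", sets = sets, descriptions = desc)
}

#' Write a PathwayCollection to GMT
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  lines <- vapply(seq_along(collection@sets), function(i) {
    paste(c(names(collection@sets)[i], collection@descriptions[i],
            collection@sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## canonical undirected edge table: from < to, self-loops dropped,
## reversed duplicates merged keeping the maximum weight
.canonicalEdges <- function(from, to, weight) {
  keep <- from != to
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  if (length(from) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric()))
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   weight = as.numeric(w),
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$from, df$to), , drop = FALSE]
}

#' Construct a PPI network from an edge table
#'
#' Self-loops are dropped, reversed duplicate edges merged (maximum weight
#' kept). Nodes are the union of edge endpoints plus any extra isolated
#' nodes supplied.
#'
#' @param from,to character vectors of gene symbols.
#' @param weight numeric edge weights in (0, 1].
#' @param extraNodes optional isolated nodes to retain.
#' @return a \linkS4class{PPINetwork}.
#' @export
ppiNetwork <- function(from, to, weight, extraNodes = character()) {
  df <- .canonicalEdges(as.character(from), as.character(to),
                        as.numeric(weight))
  nodes <- sort(unique(c(df$from, df$to, extraNodes)))
  new("PPINetwork", nodes = nodes, edges = df)
}

#' Read a STRING-style weighted edge list
#'
#' Expects three columns: gene_a, gene_b, combined score. Scores are on the
#' STRING 0-1000 scale; edges with score below \code{scoreThreshold} are
#' discarded and surviving scores are rescaled into (0, 1] by dividing by
#' 1000. Orientation is ignored: reversed duplicates are merged keeping the
#' maximum weight, and self-loops are dropped.
#'
#' @param path path to a tab/space/comma separated file.
#' @param scoreThreshold minimum combined score kept (default 700, the
#'   STRING "high confidence" cut).
#' @param header whether the file has a header row (auto-detected when NA).
#' @return a \linkS4class{PPINetwork}.
#' @export
readEdgeList <- function(path, scoreThreshold = 700, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 3L) stop("edge list must have three columns")
  dt <- dt[, 1:3]
  score <- suppressWarnings(as.numeric(dt[[3]]))
  # a lone non-numeric first row is a header; auto-detect unless told
  hasHeader <- if (is.na(header)) {
    nrow(dt) > 1L && is.na(score[1]) && !anyNA(score[-1])
  } else header
  if (hasHeader) {
    dt <- dt[-1, , drop = FALSE]
    score <- score[-1]
  }
  if (any(is.na(score)))
    stop("non-numeric combined score at row(s): ",
         paste(utils::head(which(is.na(score)), 5), collapse = ", "))
  keep <- score >= scoreThreshold
  if (!any(keep)) stop("no edges survive the score threshold ",
                       scoreThreshold)
  net <- ppiNetwork(dt[[1]][keep], dt[[2]][keep], score[keep] / 1000)
  if (nrow(net@edges) == 0L) stop("network empty after filtering")
  net
}

#' Write a network as a STRING-style edge list
#'
#' @param network a \linkS4class{PPINetwork}.
#' @param path output path (TSV: gene_a, gene_b, combined_score 0-1000).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  e <- network@edges
  df <- data.frame(gene_a = e$from, gene_b = e$to,
                   combined_score = round(e$weight * 1000))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.readWideMatrix <- function(path, what) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop(what, " table must have id column plus genes")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Read expression, mutation and copy-number tables into an OmicsBundle
#'
#' Expression is a wide cell x gene table of log-TPM values; missing entries
#' are imputed with the per-gene mean across cells. Mutations are a long
#' (cell, gene) table; duplicate rows are collapsed. CNV is a wide cell x
#' gene table of GISTIC levels, validated to lie in \{-2,...,2\}.
#'
#' @param expressionPath,mutationPath,cnvPath file paths.
#' @return an \linkS4class{OmicsBundle}.
#' @export
readOmics <- function(expressionPath, mutationPath, cnvPath) {
  expr <- .readWideMatrix(expressionPath, "expression")
  mode(expr) <- "numeric"
  allNA <- colSums(!is.na(expr)) == 0L
  if (any(allNA))
    stop("expression gene(s) with no observed values (mean undefined): ",
         paste(colnames(expr)[allNA], collapse = ", "))
  if (anyNA(expr)) {
    mu <- colMeans(expr, na.rm = TRUE)
    idx <- which(is.na(expr), arr.ind = TRUE)
    expr[idx] <- mu[idx[, 2]]
  }
  mut <- data.table::fread(mutationPath, header = TRUE, data.table = FALSE)
  if (!all(c("cell", "gene") %in% colnames(mut)))
    stop("mutation table must have columns cell, gene")
  mut <- unique(mut[, c("cell", "gene")])
  rownames(mut) <- NULL
  cnv <- .readWideMatrix(cnvPath, "cnv")
  mode(cnv) <- "integer"
  bad <- !(cnv %in% -2:2)
  if (any(bad))
    stop("cnv values outside GISTIC levels {-2..2}: e.g. ",
         cnv[which(bad)[1]])
  new("OmicsBundle", expression = expr, mutations = mut, cnv = cnv)
}

#' Read a drug response table
#'
#' Expects columns \code{drug}, \code{cell}, \code{response} where the
#' response is log-transformed IC50 (the sign convention of the input is
#' preserved, not re-derived). Duplicate (drug, cell) records are collapsed
#' by their mean.
#'
#' @param path path to a delimited file.
#' @return data.frame with columns drug, cell, response; one row per pair.
#' @export
readResponse <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("drug", "cell", "response") %in% colnames(dt)))
    stop("response table must have columns drug, cell, response")
  resp <- suppressWarnings(as.numeric(dt$response))
  if (any(!is.finite(resp)))
    stop("non-numeric or missing response at row(s): ",
         paste(utils::head(which(!is.finite(resp)), 5), collapse = ", "))
  agg <- stats::aggregate(resp,
                          by = list(drug = as.character(dt$drug),
                                    cell = as.character(dt$cell)),
                          FUN = mean)
  names(agg)[3] <- "response"
  agg <- agg[order(agg$drug, agg$cell), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a drug response table
#' @param responses data.frame with columns drug, cell, response.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeResponse <- function(responses, path) {
  utils::write.table(responses[, c("drug", "cell", "response")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug -> SMILES table
#'
#' @param path delimited file with columns \code{drug}, \code{smiles}.
#' @return named character vector of SMILES. Drugs with empty SMILES are
#'   kept but flagged with a warning.
#' @export
readSmilesTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("drug", "smiles") %in% colnames(dt)))
    stop("SMILES table must have columns drug, smiles")
  sm <- as.character(dt$smiles)
  names(sm) <- as.character(dt$drug)
  empty <- !nzchar(sm) | is.na(sm)
  if (any(empty))
    warning("drug(s) with empty SMILES: ",
            paste(names(sm)[empty], collapse = ", "))
  sm
}

#' Read a long drug -> target-gene table
#'
#' @param path delimited file with columns \code{drug}, \code{gene}.
#' @return named list, drug -> character vector of unique target genes.
#' @export
readTargetTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("drug", "gene") %in% colnames(dt)))
    stop("target table must have columns drug, gene")
  split(as.character(dt$gene), as.character(dt$drug)) |>
    lapply(unique)
}

#' Write an enrichment matrix as TSV
#' @param x an \linkS4class{EnrichmentMatrix}.
#' @param path output path; rows = entities, columns = pathways.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentMatrix <- function(x, path) {
  df <- data.frame(entity = rownames(x@scores), x@scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an enrichment matrix written by \code{writeEnrichmentMatrix}
#' @param path input TSV path.
#' @param block feature block tag to attach.
#' @return an \linkS4class{EnrichmentMatrix}.
#' @export
readEnrichmentMatrix <- function(path, block) {
  m <- .readWideMatrix(path, "enrichment")
  mode(m) <- "numeric"
  new("EnrichmentMatrix", scores = m, block = block, metadata = list())
}
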