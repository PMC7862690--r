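#' Per-cell gene sets of copy-number-altered genes
#'
#' Genes with GISTIC score 0 (diploid) are excluded; both gains and losses
#' are kept. Cells with an all-zero row get an empty set (their CNV-Net
#' enrichment row becomes zeros) and are reported.
#'
#' @param cnv cell x gene integer matrix of GISTIC levels in \{-2,...,2\}.
#' @return named list, cell -> character vector of altered genes.
#' @export
cnvGeneSets <- function(cnv) {
  stopifnot(is.matrix(cnv), !is.null(rownames(cnv)),
            !is.null(colnames(cnv)))
  if (!all(cnv %in% -2:2)) stop("cnv values must be GISTIC levels {-2..2}")
  sets <- apply(cnv, 1L, function(r) colnames(cnv)[r != 0L],
                simplify = FALSE)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    message("cell(s) with no copy-number alterations: ",
            paste(utils::head(empty, 5), collapse = ", "))
  sets
}

.BLOCK_AXES <- c("CHEM" = "drug", "DG-Net" = "drug", "EXP" = "cell",
                 "MUT-Net" = "cell", "CNV-Net" = "cell")

#' Assemble feature blocks into the pair-level design matrix
#'
#' Joins per-drug blocks (CHEM, DG-Net) and per-cell blocks (EXP, MUT-Net,
#' CNV-Net) onto the (drug, cell) response records: drug-indexed rows are
#' broadcast across that drug's cells and vice versa. Pairs for which any
#' selected block is missing its entity row are dropped, with counts
#' reported. Passing \code{subset} reproduces ablation designs that use
#' only some of the blocks.
#'
#' @param blocks named list of entity x feature matrices (or
#'   \linkS4class{EnrichmentMatrix} / \linkS4class{FingerprintBlock}
#'   objects); names are block tags.
#' @param responses data.frame with columns drug, cell, response.
#' @param subset optional character vector of block tags to keep.
#' @param axes named character vector mapping block tag -> "drug" or
#'   "cell"; defaults cover the five standard blocks.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
assembleFeatures <- function(blocks, responses, subset = NULL,
                             axes = .BLOCK_AXES) {
  stopifnot(!is.null(names(blocks)))
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(blocks))
    if (length(missing)) stop("unknown block(s): ",
                              paste(missing, collapse = ", "))
    blocks <- blocks[subset]
  }
  mats <- lapply(blocks, function(b) {
    if (is(b, "EnrichmentMatrix")) scoreMatrix(b)
    else if (is(b, "FingerprintBlock")) scoreMatrix(b)
    else as.matrix(b)
  })
  tags <- names(mats)
  unknownAxis <- setdiff(tags, names(axes))
  if (length(unknownAxis))
    stop("no drug/cell axis known for block(s): ",
         paste(unknownAxis, collapse = ", "))
  drug <- as.character(responses$drug)
  cell <- as.character(responses$cell)
  keep <- rep(TRUE, nrow(responses))
  for (tg in tags) {
    ids <- if (axes[[tg]] == "drug") drug else cell
    keep <- keep & ids %in% rownames(mats[[tg]])
  }
  nDrop <- sum(!keep)
  if (nDrop > 0L)
    message(nDrop, " pair(s) dropped for missing feature block rows")
  if (!any(keep)) stop("no (drug, cell) pair has all selected blocks")
  drug <- drug[keep]; cell <- cell[keep]
  resp <- as.numeric(responses$response)[keep]
  parts <- lapply(tags, function(tg) {
    ids <- if (axes[[tg]] == "drug") drug else cell
    m <- mats[[tg]][ids, , drop = FALSE]
    colnames(m) <- paste(tg, colnames(mats[[tg]]), sep = ":")
    m
  })
  X <- do.call(cbind, parts)
  rownames(X) <- paste(drug, cell, sep = "|")
  blocksVec <- rep(tags, vapply(parts, ncol, integer(1)))
  new("FeatureMatrix", data = X, blocks = blocksVec, drug = drug,
      cell = cell, response = resp)
}

#' Z-score normalize feature columns
#'
#' In fit mode (\code{stats = NULL}) the per-column mean and population
#' standard deviation are computed on the given rows and applied;
#' zero-variance columns are dropped and recorded. In apply mode a
#' previously fitted \linkS4class{NormalizationStats} is applied unchanged,
#' so test rows never contribute to the statistics.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param stats optional \linkS4class{NormalizationStats} from a prior fit.
#' @return list with elements \code{features} (normalized
#'   \linkS4class{FeatureMatrix}) and \code{stats}.
#' @export
zscoreFeatures <- function(features, stats = NULL) {
  X <- features@data
  if (is.null(stats)) {
    mu <- colMeans(X)
    sg <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd
    dropped <- colnames(X)[sg == 0]
    keep <- sg > 0
    stats <- new("NormalizationStats", mean = mu[keep], sd = sg[keep],
                 dropped = dropped)
  } else {
    stopifnot(is(stats, "NormalizationStats"))
    missing <- setdiff(names(stats@mean), colnames(X))
    if (length(missing))
      stop("feature matrix lacks column(s) required by stats: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  cols <- names(stats@mean)
  Xn <- sweep(sweep(X[, cols, drop = FALSE], 2, stats@mean), 2,
              stats@sd, "/")
  fm <- new("FeatureMatrix", data = Xn,
            blocks = features@blocks[match(cols, colnames(X))],
            drug = features@drug, cell = features@cell,
            response = features@response)
  list(features = fm, stats = stats)
}

#' Subset a FeatureMatrix by row index
#' @param features a \linkS4class{FeatureMatrix}.
#' @param i integer or logical row index.
#' @return a \linkS4class{FeatureMatrix} with the selected rows.
#' @export
subsetRows <- function(features, i) {
  new("FeatureMatrix", data = features@data[i, , drop = FALSE],
      blocks = features@blocks, drug = features@drug[i],
      cell = features@cell[i], response = features@response[i])
}

#' Write a feature matrix with a two-row header (block tag, feature name)
#' @param features a \linkS4class{FeatureMatrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("block", "", "", features@blocks), collapse = "\t"),
             con)
  writeLines(paste(c("drug", "cell", "response",
                     colnames(features@data)), collapse = "\t"), con)
  utils::write.table(
    data.frame(features@drug, features@cell, features@response,
               features@data, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by \code{writeFeatureMatrix}
#' @param path input TSV path.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  blocks <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-(1:3)]
  cols <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-(1:3)]
  dt <- data.table::fread(path, skip = 2L, header = FALSE,
                          data.table = FALSE)
  X <- as.matrix(dt[, -(1:3), drop = FALSE])
  colnames(X) <- cols
  rownames(X) <- paste(dt[[1]], dt[[2]], sep = "|")
  new("FeatureMatrix", data = X, blocks = blocks,
      drug = as.character(dt[[1]]), cell = as.character(dt[[2]]),
      response = as.numeric(dt[[3]]))
}
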