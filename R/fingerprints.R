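#' @importFrom igraph graph_from_data_frame biconnected_components V
NULL

## deterministic integer hash of an integer vector, folded into [0, 2^31-2].
## Plain polynomial rolling hash; all arithmetic stays below 2^53 so the
## double-precision modulo is exact.
.hashInts <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

.ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                     P = 15, S = 16, Cl = 17, Br = 35, I = 53)

## Parse a SMILES string into an atom/bond graph via OpenBabel.
## The string is canonicalized first so that any SMILES variant of one
## molecule yields one kekulized graph (identical atom ordering and kekule
## assignment), which makes the downstream hashing representation-invariant.
.parseMolecule <- function(smiles) {
  can <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  can <- sub("\t.*$", "", sub("\n$", "", can))
  if (!nzchar(can)) stop("unparseable SMILES: '", smiles, "'")
  # single-atom molecules trip ChemmineR's bond-count validity warning
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  nAtoms <- length(elements)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a = integer(), b = integer(), order = integer())
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  info <- if (nrow(bonds) > 0L) {
    ChemmineR::bonds(sdf)
  } else {
    # bond-less molecule (single heavy atom): neutral, full implicit valence
    stdVal <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                S = 2, Cl = 1, Br = 1, I = 1)
    v <- unname(stdVal[elements]); v[is.na(v)] <- 0
    data.frame(atom = elements, Nbondcount = 0L, Nbondrule = as.integer(v),
               charge = 0L)
  }
  inRing <- rep(FALSE, nAtoms)
  if (nrow(bonds) > 0L) {
    g <- igraph::graph_from_data_frame(
      bonds[, c("a", "b")], directed = FALSE,
      vertices = data.frame(name = seq_len(nAtoms)))
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      if (length(comp) >= 3L)
        inRing[as.integer(names(comp))] <- TRUE
    }
  }
  z <- .ATOMIC_NUMBERS[elements]
  z[is.na(z)] <- 0
  list(
    atoms = data.frame(
      z = as.integer(z),
      degree = vapply(seq_len(nAtoms), function(i)
        sum(bonds$a == i | bonds$b == i), integer(1)),
      valence = as.integer(info$Nbondcount),
      charge = as.integer(info$charge),
      implicitH = pmax(0L, as.integer(info$Nbondrule) -
                            as.integer(info$Nbondcount)),
      inRing = as.integer(inRing)),
    bonds = bonds)
}

#' Morgan (circular, ECFP-type) fingerprint of a molecule
#'
#' Enumerates circular atom environments up to the given radius by
#' iterative neighborhood hashing. Each atom starts from an invariant
#' (atomic number, heavy-atom degree, total bond order, formal charge,
#' implicit hydrogen count, ring membership); at every iteration the
#' identifier is re-hashed together with the sorted (bond order, neighbor
#' identifier) pairs. All identifiers from all iterations are folded modulo
#' \code{nBits} into a binary presence/absence vector. SMILES input is
#' canonicalized before parsing, so any SMILES spelling of the same
#' molecule produces the same bits.
#'
#' @param smiles a SMILES string.
#' @param radius maximum environment radius (default 2, ECFP4-equivalent).
#' @param nBits fingerprint length (default 256).
#' @return integer 0/1 vector of length \code{nBits}.
#' @examples
#' fp <- morganFingerprint("CCO")
#' sum(fp)
#' @export
morganFingerprint <- function(smiles, radius = 2L, nBits = 256L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  mol <- .parseMolecule(smiles)
  a <- mol$atoms
  ids <- vapply(seq_len(nrow(a)), function(i) {
    .hashInts(c(a$z[i], a$degree[i], a$valence[i], a$charge[i],
                a$implicitH[i], a$inRing[i]))
  }, integer(1))
  allIds <- ids
  if (radius > 0L && nrow(mol$bonds) > 0L) {
    nbrs <- lapply(seq_len(nrow(a)), function(i) {
      sel <- mol$bonds$a == i | mol$bonds$b == i
      other <- ifelse(mol$bonds$a[sel] == i, mol$bonds$b[sel],
                      mol$bonds$a[sel])
      data.frame(atom = other, order = mol$bonds$order[sel])
    })
    for (it in seq_len(radius)) {
      newIds <- vapply(seq_len(nrow(a)), function(i) {
        nb <- nbrs[[i]]
        pairs <- cbind(nb$order, ids[nb$atom])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        .hashInts(c(it, ids[i], t(pairs)))
      }, integer(1))
      ids <- newIds
      allIds <- c(allIds, ids)
    }
  }
  bits <- integer(nBits)
  bits[unique(allIds %% nBits) + 1L] <- 1L
  bits
}

#' Fingerprint a table of drugs (CHEM block)
#'
#' Drugs whose SMILES fail to parse are dropped; the dropped ids are kept in
#' the result and reported. Row order follows the input order.
#'
#' @param smilesMap named character vector, drug id -> SMILES.
#' @param radius,nBits passed to \code{\link{morganFingerprint}}.
#' @return a \linkS4class{FingerprintBlock}.
#' @export
fingerprintTable <- function(smilesMap, radius = 2L, nBits = 256L) {
  if (length(smilesMap) == 0L) stop("empty SMILES map")
  if (is.null(names(smilesMap))) stop("smilesMap must be named by drug")
  rows <- list()
  dropped <- character()
  for (d in names(smilesMap)) {
    fp <- tryCatch(morganFingerprint(smilesMap[[d]], radius, nBits),
                   error = function(e) NULL)
    if (is.null(fp)) dropped <- c(dropped, d) else rows[[d]] <- fp
  }
  if (length(rows) == 0L)
    stop("no SMILES could be parsed; dropped: ",
         paste(dropped, collapse = ", "))
  if (length(dropped))
    message("dropped drug(s) with unparseable SMILES: ",
            paste(dropped, collapse = ", "))
  bits <- do.call(rbind, rows)
  colnames(bits) <- sprintf("bit%03d", seq_len(nBits) - 1L)
  new("FingerprintBlock", bits = bits, radius = as.integer(radius),
      nBits = as.integer(nBits), dropped = dropped)
}
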