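#' Expand drug targets with off-targets and PPI neighbors
#'
#' Builds the per-drug seed gene set used for DG-Net enrichment: the union
#' of primary targets and off-targets, expanded with the first-order PPI
#' neighbors of every member that maps onto the network. Target genes absent
#' from the network are retained in the set (they simply contribute no
#' neighbors). Drugs with no target information at all are dropped and
#' reported, mirroring the exclusion of drugs without usable targets.
#'
#' @param primary named list, drug -> primary target genes.
#' @param offTargets named list, drug -> off-target genes (may omit drugs).
#' @param network a \linkS4class{PPINetwork}.
#' @return a \linkS4class{DrugGeneSets} with per-gene provenance
#'   ("primary", "off_target" or "neighbor").
#' @examples
#' net <- ppiNetwork(c("A", "C"), c("B", "D"), c(1, 1))
#' expandTargets(list(d1 = "A"), list(d1 = "C"), net)
#' @export
expandTargets <- function(primary, offTargets = list(), network) {
  stopifnot(length(network@nodes) > 0L)
  drugs <- union(names(primary), names(offTargets))
  if (length(drugs) == 0L) stop("no drugs in target tables")
  e <- network@edges
  neighborsOf <- function(genes) {
    hit <- e$from %in% genes | e$to %in% genes
    setdiff(unique(c(e$from[hit], e$to[hit])), genes)
  }
  sets <- list()
  prov <- list()
  dropped <- character()
  for (d in drugs) {
    pri <- unique(as.character(primary[[d]]))
    off <- setdiff(unique(as.character(offTargets[[d]])), pri)
    base <- c(pri, off)
    if (length(base) == 0L) { dropped <- c(dropped, d); next }
    nb <- neighborsOf(base)
    sets[[d]] <- c(base, nb)
    prov[[d]] <- stats::setNames(
      c(rep("primary", length(pri)), rep("off_target", length(off)),
        rep("neighbor", length(nb))),
      c(pri, off, nb))
  }
  if (length(sets) == 0L) stop("every drug lacked target information")
  if (length(dropped))
    message("dropped drug(s) without target information: ",
            paste(dropped, collapse = ", "))
  new("DrugGeneSets", sets = sets, provenance = prov, dropped = dropped)
}
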