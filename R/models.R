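#' @include engine.R
NULL

# ----------------------------------------------------------------------
# Interaction catalogue
# ----------------------------------------------------------------------

#' Load a signed interaction table into a regulatory graph
#'
#' Reads a tab-separated interaction catalogue with header columns
#' \code{regulator}, \code{target}, \code{sign}, \code{mechanism},
#' \code{evidence} (PMID).  Signs must be one of \code{positive},
#' \code{negative}, \code{dual}; mechanisms one of \code{transcription},
#' \code{methylation}, \code{phosphorylation}, \code{dephosphorylation},
#' \code{proteolysis}, \code{complex_assembly}, \code{binding}.  The node
#' set is the union of all endpoints.
#'
#' The packaged catalogue of the 13-node core cell-cycle network (27
#' literature-curated interactions) ships as
#' \code{system.file("extdata", "table1_g2.tsv", package = "CauloLogic")}.
#'
#' @param path path to the TSV file.
#' @return a [RegulatoryGraph-class].
#' @examples
#' tsv <- system.file("extdata", "table1_g2.tsv", package = "CauloLogic")
#' g <- loadInteractions(tsv)
#' length(nodes(g))       # 13
#' nrow(interactions(g))  # 27
#' @export
loadInteractions <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("regulator", "target", "sign", "mechanism", "evidence")
  if (!all(need %in% names(ed)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  ed <- ed[, need, drop = FALSE]
  if (nrow(ed)) {
    if (any(!nzchar(ed$regulator)) || any(!nzchar(ed$target)))
      stop("empty regulator/target field in interaction table")
    bad <- setdiff(unique(ed$sign), .INTERACTION_SIGNS)
    if (length(bad))
      stop("unknown interaction sign(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(ed$mechanism), .INTERACTION_MECHANISMS)
    if (length(bad))
      stop("unknown mechanism(s): ", paste(bad, collapse = ", "))
  }
  new("RegulatoryGraph", nodes = unique(c(ed$regulator, ed$target)),
      edges = ed)
}

#' Reduce a regulatory graph to its core by pruning non-regulatory nodes
#'
#' Iteratively deletes nodes with out-degree zero (nodes that regulate
#' nothing; self-loops count as out-edges) together with their incident
#' edges, until no such node remains.  Non-regulatory nodes cannot feed
#' back into the dynamics, so removing them leaves the attractor structure
#' of the remaining core untouched.  The result is independent of deletion
#' order, and the operation is idempotent.
#'
#' @param graph a [RegulatoryGraph-class].
#' @return the pruned [RegulatoryGraph-class]; every surviving node has
#'   out-degree >= 1 (possibly the empty graph).
#' @rdname reduceToCore
#' @export
setMethod("reduceToCore", "RegulatoryGraph", function(graph) {
  nd <- graph@nodes
  ed <- graph@edges
  repeat {
    regulators <- unique(ed$regulator)
    drop <- setdiff(nd, regulators)
    if (!length(drop)) break
    nd <- setdiff(nd, drop)
    ed <- ed[ed$regulator %in% nd & ed$target %in% nd, , drop = FALSE]
  }
  new("RegulatoryGraph", nodes = nd, edges = ed)
})

# ----------------------------------------------------------------------
# Reference models
# ----------------------------------------------------------------------

#' The transcriptional/methylation subnetwork G2a (5 Boolean nodes)
#'
#' The Boolean model of the transcriptional core driving the cell-cycle
#' oscillation: master regulator CtrA, the cell-cycle regulator GcrA, the
#' replication initiator DnaA, the methyl-transferase CcrM and the CtrA
#' co-repressor SciP.  Rules:
#' \itemize{
#'   \item \code{CtrA_a' = GcrA OR (NOT CcrM AND NOT SciP)} --- CtrA is
#'     activated by GcrA and transcribed from its own promoter unless
#'     repressed by promoter methylation (CcrM) or by SciP.
#'   \item \code{GcrA' = DnaA AND NOT CtrA_a}
#'   \item \code{DnaA' = CtrA_a AND CcrM AND NOT GcrA AND NOT DnaA} ---
#'     transcription requires CtrA on a CcrM-methylated promoter and is
#'     repressed by GcrA and by DnaA itself.
#'   \item \code{CcrM' = CtrA_a AND NOT SciP AND NOT CcrM}
#'   \item \code{SciP' = CtrA_a AND NOT DnaA}
#' }
#' All 32 states flow into a single 4-state limit cycle that visits, in
#' order, (DnaA,SciP) -> (GcrA) -> (CtrA) -> (CtrA,CcrM,SciP), matching
#' the known succession of regulator activity over the swarmer cell cycle.
#'
#' @return a [LogicalNetwork-class] on \{CtrA_a, GcrA, DnaA, CcrM, SciP\}.
#' @examples
#' enumerateAttractors(buildG2a())
#' @export
buildG2a <- function() {
  logicalNetwork(
    c(CtrA_a = 1, GcrA = 1, DnaA = 1, CcrM = 1, SciP = 1),
    list(
      updateRule("CtrA_a", c("GcrA -> 1", "!CcrM & !SciP -> 1")),
      updateRule("GcrA",   "DnaA & !CtrA_a -> 1"),
      updateRule("DnaA",   "CtrA_a & CcrM & !GcrA & !DnaA -> 1"),
      updateRule("CcrM",   "CtrA_a & !SciP & !CcrM -> 1"),
      updateRule("SciP",   "CtrA_a & !DnaA -> 1")))
}

#' The phospho-proteolytic signaling subnetwork G2b (9 nodes, levels 0-2)
#'
#' The multi-valued model of the phosphorelay and proteolysis pathway that
#' decides cell fate.  Level semantics: 0 = absent/knocked out, 1 =
#' present/unphosphorylated, 2 = phosphorylated; for PleC, 2 = active
#' phosphatase and 1 = inactivated by DivK~P; for CpdR, 1 =
#' complex-promoting (unphosphorylated) and 2 = phosphorylated/inactive.
#' The PleC phosphatase dominates the DivJ kinase in the DivK and DivJ
#' rules (its case is tried first), which is required for the stability of
#' the swarmer-pole fixed point.
#'
#' The dynamics is bistable: all 8,748 states reach one of two fixed
#' points.  Point \code{i} (swarmer-pole micro-domain): CtrA, CckA, ChpT
#' and CpdR phosphorylated, DivK and DivJ unphosphorylated, no proteolytic
#' complex.  Point \code{j} (stalked-pole micro-domain): DivK and DivJ
#' phosphorylated, CckA/ChpT/CpdR unphosphorylated, ClpXP-RcdA assembled
#' and CtrA degraded.
#'
#' @return a [LogicalNetwork-class] on \{CtrA_b, DivK, DivJ, PleC, DivL,
#'   CckA, ChpT, CpdR, ClpXP_RcdA\}.
#' @examples
#' enumerateAttractors(buildG2b())  # exactly two fixed points
#' @export
buildG2b <- function() {
  logicalNetwork(
    c(CtrA_b = 2, DivK = 2, DivJ = 2, PleC = 2, DivL = 1,
      CckA = 2, ChpT = 2, CpdR = 2, ClpXP_RcdA = 1),
    list(
      updateRule("CtrA_b", c("ClpXP_RcdA==1 -> 0", "ChpT==2 -> 2"),
                 default = 1),
      updateRule("DivK", c("PleC==2 -> 1", "DivJ==2 -> 2"), default = 1),
      updateRule("DivJ", c("PleC==2 -> 1", "DivK==2 -> 2"), default = 1),
      updateRule("PleC", "DivK==2 -> 1", default = 2),
      updateRule("DivL", "DivK==2 -> 0", default = 1),
      updateRule("CckA", "DivL==1 -> 2", default = 1),
      updateRule("ChpT", "CckA==2 -> 2", default = 1),
      updateRule("CpdR", "ChpT==2 -> 2", default = 1),
      updateRule("ClpXP_RcdA", "CpdR==1 -> 1", default = 0)))
}

#' The combined 13-node core network G2
#'
#' Merges the transcriptional (G2a) and phospho-proteolytic (G2b)
#' subnetworks into one model by re-unifying their shared node CtrA as a
#' single three-level node: 0 = absent, 1 = present/unphosphorylated, 2 =
#' phosphorylated (transcriptionally active).  Transcriptional targets of
#' CtrA read its activity as \code{CtrA == 2}; CtrA itself is degraded when
#' the ClpXP-RcdA complex is assembled, transcribed only when the G2a
#' promoter logic \code{GcrA OR (NOT CcrM AND NOT SciP)} allows it, and
#' phosphorylated by ChpT~P.  All other rules are exactly those of
#' [buildG2a()] and [buildG2b()].
#'
#' The state space has \eqn{3^7 \cdot 2^6 = 139{,}968} states (seven
#' three-level nodes, six Boolean nodes).  This is the model on which the
#' Derrida criticality analysis runs.
#'
#' @return a 13-node [LogicalNetwork-class].
#' @seealso [derridaSlope()]
#' @export
buildG2Combined <- function() {
  logicalNetwork(
    c(CtrA = 2, GcrA = 1, DnaA = 1, CcrM = 1, SciP = 1,
      DivK = 2, DivJ = 2, PleC = 2, DivL = 1,
      CckA = 2, ChpT = 2, CpdR = 2, ClpXP_RcdA = 1),
    list(
      updateRule("CtrA", c("ClpXP_RcdA==1 -> 0",
                           "!GcrA & CcrM==1 -> 0",
                           "!GcrA & SciP==1 -> 0",
                           "ChpT==2 -> 2"),
                 default = 1),
      updateRule("GcrA", "DnaA & CtrA<=1 -> 1"),
      updateRule("DnaA", "CtrA==2 & CcrM & !GcrA & !DnaA -> 1"),
      updateRule("CcrM", "CtrA==2 & !SciP & !CcrM -> 1"),
      updateRule("SciP", "CtrA==2 & !DnaA -> 1"),
      updateRule("DivK", c("PleC==2 -> 1", "DivJ==2 -> 2"), default = 1),
      updateRule("DivJ", c("PleC==2 -> 1", "DivK==2 -> 2"), default = 1),
      updateRule("PleC", "DivK==2 -> 1", default = 2),
      updateRule("DivL", "DivK==2 -> 0", default = 1),
      updateRule("CckA", "DivL==1 -> 2", default = 1),
      updateRule("ChpT", "CckA==2 -> 2", default = 1),
      updateRule("CpdR", "ChpT==2 -> 2", default = 1),
      updateRule("ClpXP_RcdA", "CpdR==1 -> 1", default = 0)))
}

#' Reference fixed points of the G2b cell-fate switch
#'
#' Convenience accessor for the two stable steady states of [buildG2b()]:
#' \code{"swarmer"} (point i, CtrA phosphorylated, no proteolysis) and
#' \code{"stalked"} (point j, proteolytic complex assembled, CtrA absent).
#'
#' @param which \code{"swarmer"} or \code{"stalked"}.
#' @return a named integer state vector.
#' @export
g2bFixedPoint <- function(which = c("swarmer", "stalked")) {
  which <- match.arg(which)
  if (which == "swarmer")
    c(CtrA_b = 2L, DivK = 1L, DivJ = 1L, PleC = 2L, DivL = 1L,
      CckA = 2L, ChpT = 2L, CpdR = 2L, ClpXP_RcdA = 0L)
  else
    c(CtrA_b = 0L, DivK = 2L, DivJ = 2L, PleC = 1L, DivL = 0L,
      CckA = 1L, ChpT = 1L, CpdR = 1L, ClpXP_RcdA = 1L)
}
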