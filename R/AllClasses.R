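#' @import methods
NULL

#' UpdateRule: a discrete update function for one network node
#'
#' An \code{UpdateRule} encodes the logical function \eqn{f_i} that maps the
#' current levels of a node's regulators to the node's level at the next
#' synchronous time step.  The function is written as an ordered list of
#' cases; each case is a conjunction of threshold conditions
#' (\code{node == l}, \code{node >= l} or \code{node <= l}) paired with an
#' output level.  The first matching case wins; if no case matches, the
#' explicit \code{default} level is returned, so the rule is total over the
#' input space by construction.
#'
#' @slot target name of the node the rule updates.
#' @slot cases list of cases; each case is a \code{list(conditions =
#'   data.frame(node, relation, level), output = integer)}.  An empty
#'   \code{conditions} data frame matches every state.
#' @slot default integer level returned when no case matches.
#'
#' @seealso [updateRule()], [evaluateRule()], [truthTable()]
#' @export
setClass("UpdateRule",
  representation(target = "character", cases = "list", default = "integer"))

setValidity("UpdateRule", function(object) {
  msg <- character()
  if (length(object@target) != 1L || !nzchar(object@target))
    msg <- c(msg, "'target' must be a single non-empty node name")
  if (length(object@default) != 1L || is.na(object@default) ||
      object@default < 0L)
    msg <- c(msg, "'default' must be a single non-negative integer")
  for (cs in object@cases) {
    if (!is.list(cs) || !all(c("conditions", "output") %in% names(cs))) {
      msg <- c(msg, "each case needs 'conditions' and 'output'")
      next
    }
    cond <- cs$conditions
    if (!is.data.frame(cond) ||
        !all(c("node", "relation", "level") %in% names(cond)))
      msg <- c(msg, "case conditions must have node/relation/level columns")
    else if (nrow(cond) && !all(cond$relation %in% c("==", ">=", "<=")))
      msg <- c(msg, "condition relation must be one of ==, >=, <=")
    if (length(cs$output) != 1L || is.na(cs$output) || cs$output < 0L)
      msg <- c(msg, "case output must be a single non-negative integer")
  }
  if (length(msg)) msg else TRUE
})

#' LogicalNetwork: a synchronous multi-valued logical network
#'
#' The central data container of the package.  A network is a set of named
#' nodes, each carrying an integer activity level in \code{0..maxLevel}
#' (0 = absent, 1 = present/unphosphorylated, 2 = phosphorylated/active in
#' the cell-cycle models), one [UpdateRule-class] per node, and an optional
#' set of clamps.  Clamped nodes are held at a fixed level by
#' [successorState()] regardless of their rule, which is how knockouts
#' (clamp to 0) and constitutive expression (clamp to the maximal level)
#' are represented.
#'
#' Under synchronous updating the network defines a deterministic map on a
#' finite state space of size \code{prod(maxLevels + 1)}; see
#' [enumerateAttractors()].
#'
#' @slot nodes character vector of unique node names (defines state order).
#' @slot maxLevels named integer vector, maximal level per node (>= 1).
#' @slot rules named list of [UpdateRule-class] objects, one per node.
#' @slot clamps named integer vector of fixed levels (possibly empty).
#'
#' @seealso [logicalNetwork()], [buildG2a()], [buildG2b()],
#'   [buildG2Combined()], [applyPerturbation()]
#' @export
setClass("LogicalNetwork",
  representation(nodes = "character", maxLevels = "integer",
                 rules = "list", clamps = "integer"))

setValidity("LogicalNetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  if (!length(nd) || anyDuplicated(nd) || !all(nzchar(nd)))
    msg <- c(msg, "node names must be non-empty and unique")
  if (!identical(names(object@maxLevels), nd))
    msg <- c(msg, "'maxLevels' must be named exactly by the nodes, in order")
  if (any(is.na(object@maxLevels)) || any(object@maxLevels < 1L))
    msg <- c(msg, "every maxLevel must be an integer >= 1")
  if (!identical(names(object@rules), nd))
    msg <- c(msg, "need exactly one rule per node, named by the nodes")
  else {
    for (nm in nd) {
      r <- object@rules[[nm]]
      if (!is(r, "UpdateRule")) {
        msg <- c(msg, sprintf("rule for '%s' is not an UpdateRule", nm))
        next
      }
      if (!identical(r@target, nm))
        msg <- c(msg, sprintf("rule target '%s' does not match node '%s'",
                              r@target, nm))
      outs <- c(vapply(r@cases, function(cs) as.integer(cs$output), 1L),
                r@default)
      if (any(outs > object@maxLevels[[nm]]))
        msg <- c(msg, sprintf("rule for '%s' outputs above its maxLevel", nm))
      for (cs in r@cases) {
        cond <- cs$conditions
        if (!nrow(cond)) next
        bad <- !(cond$node %in% nd)
        if (any(bad))
          msg <- c(msg, sprintf("rule for '%s' references undeclared node(s): %s",
                                nm, paste(cond$node[bad], collapse = ", ")))
        ok <- cond$node %in% nd
        if (any(ok & (cond$level < 0L |
                      cond$level > object@maxLevels[cond$node])))
          msg <- c(msg, sprintf("rule for '%s' has out-of-range condition level",
                                nm))
      }
    }
  }
  cl <- object@clamps
  if (length(cl)) {
    if (is.null(names(cl)) || !all(names(cl) %in% nd))
      msg <- c(msg, "clamps must be named by declared nodes")
    else if (anyDuplicated(names(cl)))
      msg <- c(msg, "at most one clamp per node")
    else if (any(cl < 0L) || any(cl > object@maxLevels[names(cl)]))
      msg <- c(msg, "clamp levels must lie within each node's range")
  }
  if (length(msg)) msg else TRUE
})

#' Attractor: a fixed point or limit cycle of the synchronous dynamics
#'
#' @slot states integer matrix, one row per state on the cycle (columns =
#'   nodes).  Row \code{i + 1} is the successor of row \code{i}, and the
#'   successor of the last row is the first.  Cycles are stored in canonical
#'   rotation: the state with the smallest mixed-radix index comes first.
#' @slot kind \code{"fixed_point"} (one row) or \code{"limit_cycle"}.
#' @export
setClass("Attractor",
  representation(states = "matrix", kind = "character"))

setValidity("Attractor", function(object) {
  msg <- character()
  if (!nrow(object@states)) msg <- c(msg, "attractor must contain >= 1 state")
  ok <- if (nrow(object@states) == 1L) "fixed_point" else "limit_cycle"
  if (!identical(object@kind, ok))
    msg <- c(msg, sprintf("kind must be '%s' for %d state(s)",
                          ok, nrow(object@states)))
  if (length(msg)) msg else TRUE
})

#' AttractorReport: all attractors of a network with their basin sizes
#'
#' Produced by [enumerateAttractors()] and [bruteForceAttractors()].
#' Basin sizes always sum to the state-space size: the synchronous map is
#' deterministic, so every state belongs to exactly one basin.
#'
#' @slot attractors list of [Attractor-class] objects, ordered by the
#'   mixed-radix index of their first state.
#' @slot basinSizes numeric vector, one basin size per attractor.
#' @slot stateSpaceSize total number of states enumerated.
#' @export
setClass("AttractorReport",
  representation(attractors = "list", basinSizes = "numeric",
                 stateSpaceSize = "numeric"))

setValidity("AttractorReport", function(object) {
  msg <- character()
  if (length(object@attractors) != length(object@basinSizes))
    msg <- c(msg, "one basin size per attractor required")
  if (length(object@basinSizes) &&
      !isTRUE(all.equal(sum(object@basinSizes), object@stateSpaceSize)))
    msg <- c(msg, "basin sizes must sum to the state-space size")
  if (length(msg)) msg else TRUE
})

#' TransitionGraph: the functional graph of the synchronous map
#'
#' One vertex per state of the enumerated state space, one outgoing edge per
#' vertex pointing at its synchronous successor (out-degree exactly 1).
#' State indices are 0-based mixed-radix codes as produced by
#' [encodeState()].
#'
#' @slot successors numeric vector; entry \code{i} holds the 0-based index
#'   of the successor of state \code{i - 1}.
#' @slot labels character vector of human-readable state labels
#'   (node levels separated by dashes).
#' @slot nodes character vector of node names (column order of labels).
#' @export
setClass("TransitionGraph",
  representation(successors = "numeric", labels = "character",
                 nodes = "character"))

setValidity("TransitionGraph", function(object) {
  msg <- character()
  n <- length(object@successors)
  if (length(object@labels) != n)
    msg <- c(msg, "need one label per state")
  if (n && (any(object@successors < 0) || any(object@successors >= n)))
    msg <- c(msg, "successor indices out of range")
  if (length(msg)) msg else TRUE
})

#' DerridaMap: mean one-step perturbation size M(h) per initial size h
#'
#' For each initial Hamming distance \code{h} (number of nodes at which two
#' states differ), \code{M[h]} is the mean Hamming distance between the two
#' successors after one synchronous step, estimated from
#' \code{nSamples[h]} random (background, perturbed) state pairs.
#'
#' @slot h integer vector of initial perturbation sizes (in nodes).
#' @slot M mean one-step distances, same units and length as \code{h}.
#' @slot nSamples pairs sampled per h.
#' @slot stderr standard error of each M estimate.
#' @slot nNodes number of (unclamped) nodes, for the normalized map
#'   \code{M / nNodes} vs \code{h / nNodes}.
#' @slot seed the RNG seed used (NA if none was set).
#' @export
setClass("DerridaMap",
  representation(h = "numeric", M = "numeric", nSamples = "numeric",
                 stderr = "numeric", nNodes = "numeric", seed = "numeric"))

setValidity("DerridaMap", function(object) {
  msg <- character()
  if (length(object@h) != length(object@M))
    msg <- c(msg, "h and M must have equal length")
  if (any(object@M < 0) || any(object@M > object@nNodes))
    msg <- c(msg, "M values must lie in [0, nNodes]")
  if (length(msg)) msg else TRUE
})

#' RegimeEstimate: Derrida slope at h = 0 and dynamical-regime call
#'
#' The slope \code{m = dM/dh} at \code{h = 0} classifies the network's
#' dynamical regime: perturbations are absorbed for \code{m < 1} (ordered),
#' amplified for \code{m > 1} (chaotic), and marginally propagated at
#' \code{m = 1} (critical).  Estimates within \code{criticalBand} of 1 are
#' labeled critical.
#'
#' @slot slope estimated slope m (>= 0).
#' @slot se standard error of the estimate (0 for exact enumeration).
#' @slot regime one of \code{"ordered"}, \code{"critical"}, \code{"chaotic"}.
#' @slot method \code{"h1"} (finite difference through the origin using the
#'   h = 1 class), \code{"fit"} (least-squares line through the origin over
#'   h <= 3) or \code{"exact"} (full enumeration).
#' @slot samples number of sampled pairs (or enumerated perturbations).
#' @export
setClass("RegimeEstimate",
  representation(slope = "numeric", se = "numeric", regime = "character",
                 method = "character", samples = "numeric"))

#' RegulatoryGraph: a signed, mechanism-annotated interaction graph
#'
#' The static regulatory structure underlying a logical model: directed
#' edges labeled with a sign (\code{positive}, \code{negative}, or
#' \code{dual} for regulators that both activate and repress) and a
#' mechanism drawn from a closed vocabulary.
#'
#' @slot nodes character vector of node identifiers.
#' @slot edges data frame with columns \code{regulator}, \code{target},
#'   \code{sign}, \code{mechanism}, \code{evidence}.
#' @seealso [loadInteractions()], [reduceToCore()]
#' @export
setClass("RegulatoryGraph",
  representation(nodes = "character", edges = "data.frame"))

.INTERACTION_SIGNS <- c("positive", "negative", "dual")
.INTERACTION_MECHANISMS <- c("transcription", "methylation",
  "phosphorylation", "dephosphorylation", "proteolysis",
  "complex_assembly", "binding")

setValidity("RegulatoryGraph", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("regulator", "target", "sign", "mechanism", "evidence")
  if (!all(need %in% names(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (!all(ed$regulator %in% object@nodes) ||
        !all(ed$target %in% object@nodes))
      msg <- c(msg, "edge endpoints must be declared nodes")
    if (!all(ed$sign %in% .INTERACTION_SIGNS))
      msg <- c(msg, "unknown interaction sign")
    if (!all(ed$mechanism %in% .INTERACTION_MECHANISMS))
      msg <- c(msg, "unknown interaction mechanism")
  }
  if (length(msg)) msg else TRUE
})

#' PerturbationScan: attractor landscapes under single-node clamps
#'
#' Result of [knockoutScan()] or [overexpressionScan()]: the unperturbed
#' baseline [AttractorReport-class], one report per clamped node, and a
#' summary table diffing each perturbed landscape against the baseline.
#'
#' @slot baseline the unperturbed [AttractorReport-class].
#' @slot reports named list of per-node [AttractorReport-class] objects.
#' @slot summary data frame: node, mode, nAttractors, nFixedPoints,
#'   nCycles, attractorSummary.
#' @slot mode \code{"knockout"} or \code{"overexpression"}.
#' @export
setClass("PerturbationScan",
  representation(baseline = "AttractorReport", reports = "list",
                 summary = "data.frame", mode = "character"))
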