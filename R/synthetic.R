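#' @include criticality.R
NULL

#' Generate a random multi-valued logical network
#'
#' Draws a network from the classical N-K random ensemble generalized to
#' multi-valued nodes: every node receives exactly \code{kInputs} distinct
#' input nodes drawn uniformly (self-inputs allowed, as in the biological
#' models, e.g. DnaA self-repression), and a complete random truth table
#' whose outputs are i.i.d. draws from \code{bias} over \code{0..maxLevel}.
#' Rules are emitted in the engine's ordered-case representation (one
#' \code{==}-conjunction case per input combination), so generated rules
#' are total and respect level caps by construction.  Identical seeds give
#' identical networks, rule for rule.
#'
#' For the unbiased Boolean ensemble with \code{kInputs = 2} the expected
#' Derrida slope is \code{k * 2p(1-p) = 1}: the ensemble is critical,
#' which is the calibration check used in the test suite.
#'
#' @param nNodes number of nodes (named \code{x1..xn}).
#' @param kInputs exact in-degree of every node (\code{0 <= k < n}).
#' @param maxLevel level cap, a scalar or per-node vector (default 1,
#'   i.e. Boolean).
#' @param bias probability weights over output levels \code{0..max(maxLevel)}
#'   (default uniform); recycled per node and renormalized over each
#'   node's own range.
#' @param seed RNG seed.
#' @return a [LogicalNetwork-class].
#' @examples
#' net <- randomNetwork(6, 2, seed = 42)
#' enumerateAttractors(net)
#' @export
randomNetwork <- function(nNodes, kInputs, maxLevel = 1L, bias = NULL,
                          seed = NULL) {
  if (nNodes < 1) stop("'nNodes' must be >= 1")
  if (kInputs < 0 || kInputs >= nNodes)
    stop("'kInputs' must satisfy 0 <= k < nNodes")
  if (!is.null(seed)) set.seed(seed)
  caps <- rep_len(as.integer(maxLevel), nNodes)
  if (any(caps < 1)) stop("'maxLevel' must be >= 1")
  nd <- paste0("x", seq_len(nNodes))
  names(caps) <- nd
  ruleList <- vector("list", nNodes)
  for (i in seq_len(nNodes)) {
    p <- if (is.null(bias)) rep(1, caps[i] + 1L) else bias[seq_len(caps[i] + 1L)]
    if (anyNA(p) || any(p < 0) || sum(p) <= 0)
      stop("'bias' must be non-negative weights over 0..maxLevel")
    if (kInputs == 0L) {
      ruleList[[i]] <- updateRule(nd[i], character(),
        default = sample(0:caps[i], 1L, prob = p))
      next
    }
    inputs <- sample(nd, kInputs)          # distinct; self allowed
    combos <- expand.grid(lapply(inputs, function(nm) 0:caps[[nm]]),
                          KEEP.OUT.ATTRS = FALSE)
    names(combos) <- inputs
    outs <- sample(0:caps[i], nrow(combos), replace = TRUE, prob = p)
    cases <- lapply(seq_len(nrow(combos)), function(r) {
      list(conditions = data.frame(node = inputs, relation = "==",
                                   level = as.integer(combos[r, ]),
                                   stringsAsFactors = FALSE),
           output = as.integer(outs[r]))
    })
    ruleList[[i]] <- new("UpdateRule", target = nd[i], cases = cases,
                         default = 0L)
  }
  logicalNetwork(caps, ruleList)
}

#' Brute-force attractor enumeration (independent oracle)
#'
#' Simulates a trajectory from every state of the space using the scalar
#' rule evaluator, with visited-set cycle detection, and assembles the
#' attractors and basin sizes.  The output is canonicalized identically to
#' [enumerateAttractors()] (same rotation and ordering), but the algorithm
#' and the evaluation path are independent: this function goes through
#' [evaluateRule()] state by state, so it cross-checks both the
#' vectorized evaluator and the pointer-doubling cycle finder.
#'
#' @param network a [LogicalNetwork-class].
#' @param sizeCap refuse state spaces larger than this (default 1e5; this
#'   is an oracle for small networks, not a production path).
#' @return an [AttractorReport-class].
#' @export
bruteForceAttractors <- function(network, sizeCap = 1e5) {
  N <- .checkSizeCap(network, sizeCap)
  nd <- network@nodes
  clampIdx <- match(names(network@clamps), nd)
  succOf <- integer(N)                   # memoised scalar successors
  scalarSucc <- function(i) {
    if (succOf[i]) return(succOf[i])
    s <- drop(.decodeIndices(network, i - 1))
    nxt <- vapply(network@rules, evaluateRule, 1L, state = s)
    if (length(clampIdx)) nxt[clampIdx] <- network@clamps
    j <- as.integer(encodeState(network, nxt)) + 1L
    succOf[i] <<- j
    j
  }
  attrId <- integer(N)                   # 0 = unresolved
  cycles <- list()
  for (start in seq_len(N)) {
    if (attrId[start]) next
    path <- integer(0)
    pos <- new.env(hash = TRUE, parent = emptyenv())
    s <- start
    while (attrId[s] == 0L && is.null(pos[[as.character(s)]])) {
      assign(as.character(s), length(path) + 1L, envir = pos)
      path <- c(path, s)
      s <- scalarSucc(s)
    }
    if (attrId[s]) {
      id <- attrId[s]
    } else {                             # new cycle found within path
      at <- pos[[as.character(s)]]
      cyc <- path[at:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      id <- length(cycles)
    }
    attrId[path] <- id
  }
  firsts <- vapply(cycles, min, 1)
  ord <- order(firsts)
  cycles <- lapply(cycles[ord], function(cyc) {
    k <- which.min(cyc)
    c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
  })
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  basins <- tabulate(remap[attrId], nbins = length(cycles))
  atts <- lapply(cycles, function(cyc) {
    st <- .decodeIndices(network, cyc - 1)
    new("Attractor", states = st,
        kind = if (nrow(st) == 1L) "fixed_point" else "limit_cycle")
  })
  new("AttractorReport", attractors = atts, basinSizes = as.numeric(basins),
      stateSpaceSize = as.numeric(N))
}

#' Built-in benchmark networks
#'
#' A named collection of small networks with exactly known dynamics, used
#' throughout the test suite, plus the three cell-cycle models:
#' \describe{
#'   \item{identity5}{five Boolean nodes copying themselves; every state
#'     is a fixed point and the Derrida map is \code{M(h) = h} exactly.}
#'   \item{constant3}{three nodes with constant rules; a single fixed
#'     point attracts everything and \code{M(h) = 0}.}
#'   \item{negationRing3}{the 3-node negation ring \code{x1' = !x3,
#'     x2' = !x1, x3' = !x2}: one 2-cycle and one 6-cycle, slope 1.}
#'   \item{toggle2}{the toggle switch \code{x' = !y, y' = !x}: fixed
#'     points (0,1) and (1,0) plus the 2-cycle (0,0) <-> (1,1).}
#'   \item{g2a, g2b, g2}{the cell-cycle models of [buildG2a()],
#'     [buildG2b()] and [buildG2Combined()].}
#' }
#'
#' @return a named list of [LogicalNetwork-class] objects.
#' @export
builtinFixtures <- function() {
  idRules <- lapply(paste0("x", 1:5), function(nm)
    updateRule(nm, paste0(nm, ">=1 -> 1")))
  identity5 <- logicalNetwork(stats::setNames(rep(1L, 5), paste0("x", 1:5)),
                              idRules)
  constant3 <- logicalNetwork(
    c(x1 = 1, x2 = 1, x3 = 1),
    list(updateRule("x1", character(), default = 1L),
         updateRule("x2", character(), default = 0L),
         updateRule("x3", character(), default = 1L)))
  negationRing3 <- logicalNetwork(
    c(x1 = 1, x2 = 1, x3 = 1),
    list(updateRule("x1", "!x3 -> 1"),
         updateRule("x2", "!x1 -> 1"),
         updateRule("x3", "!x2 -> 1")))
  toggle2 <- logicalNetwork(
    c(x = 1, y = 1),
    list(updateRule("x", "!y -> 1"), updateRule("y", "!x -> 1")))
  list(identity5 = identity5, constant3 = constant3,
       negationRing3 = negationRing3, toggle2 = toggle2,
       g2a = buildG2a(), g2b = buildG2b(), g2 = buildG2Combined())
}

#' Expand a node's update rule into an explicit truth table
#'
#' Enumerates every combination of the levels of the nodes the rule
#' references (its inputs) and evaluates the rule on each, producing the
#' raw truth table that the ordered-case representation encodes.  Used as
#' the semantic ground truth when comparing two rule representations
#' (e.g. after a file round trip).  A rule referencing no nodes yields a
#' single default row.
#'
#' @param network a [LogicalNetwork-class].
#' @param node name of the node whose rule to expand; if missing, a named
#'   list of tables for every node is returned.
#' @return a data frame with one column per input node plus
#'   \code{output}, or a named list of such data frames.
#' @export
truthTable <- function(network, node) {
  if (missing(node)) {
    out <- lapply(network@nodes, function(nm) truthTable(network, nm))
    names(out) <- network@nodes
    return(out)
  }
  rule <- network@rules[[node]]
  if (is.null(rule)) stop("unknown node '", node, "'")
  ins <- unique(unlist(lapply(rule@cases, function(cs) cs$conditions$node)))
  ins <- network@nodes[network@nodes %in% ins]     # network order
  if (!length(ins))
    return(data.frame(output = rule@default))
  combos <- expand.grid(lapply(ins, function(nm) 0:network@maxLevels[[nm]]),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- ins
  out <- vapply(seq_len(nrow(combos)), function(r) {
    evaluateRule(rule, stats::setNames(as.integer(combos[r, ]), ins))
  }, 1L)
  cbind(combos, output = out)
}
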