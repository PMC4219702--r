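#' @include AllClasses.R
NULL

# ----------------------------------------------------------------------
# Constructors
# ----------------------------------------------------------------------

#' Construct an update rule from threshold-condition cases
#'
#' Builds an [UpdateRule-class] from condition strings.  Each case has the
#' form \code{"cond1 & cond2 & ... -> level"}, where a condition is
#' \code{"Node==l"}, \code{"Node>=l"}, \code{"Node<=l"}, the shorthand
#' \code{"Node"} (meaning \code{Node >= 1}, i.e. present) or \code{"!Node"}
#' (meaning \code{Node == 0}, i.e. absent).  Cases are tried in order and
#' the first match wins; \code{default} is returned when none matches, so
#' the rule is total.  A level of 0 always means absent/knocked out, so
#' conditions evaluate naturally on clamped-to-zero nodes.
#'
#' @param target name of the node this rule updates.
#' @param cases character vector of case strings (may be empty for a
#'   constant rule).
#' @param default integer level used when no case matches.
#' @return an [UpdateRule-class].
#' @examples
#' # DnaA transcription: requires CtrA with a CcrM-methylated promoter,
#' # repressed by GcrA and by its own product
#' updateRule("DnaA", "CtrA_a & CcrM & !GcrA & !DnaA -> 1", default = 0)
#' @export
updateRule <- function(target, cases = character(), default = 0L) {
  parsed <- lapply(cases, .parseCase)
  new("UpdateRule", target = target, cases = parsed,
      default = as.integer(default))
}

.parseCase <- function(text) {
  parts <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed rule case (need 'conditions -> level'): ", text)
  out <- suppressWarnings(as.integer(trimws(parts[2])))
  if (is.na(out)) stop("malformed output level in rule case: ", text)
  lits <- trimws(strsplit(parts[1], "&", fixed = TRUE)[[1]])
  lits <- lits[nzchar(lits)]
  cond <- do.call(rbind, lapply(lits, .parseLiteral))
  if (is.null(cond))
    cond <- data.frame(node = character(), relation = character(),
                       level = integer(), stringsAsFactors = FALSE)
  list(conditions = cond, output = out)
}

.parseLiteral <- function(lit) {
  m <- regmatches(lit, regexec("^([!]?)([A-Za-z_][A-Za-z0-9_]*)\\s*(==|>=|<=)?\\s*([0-9]+)?$", lit))[[1]]
  if (!length(m)) stop("cannot parse rule condition: '", lit, "'")
  neg <- m[2] == "!"
  node <- m[3]
  rel <- m[4]
  lev <- m[5]
  if (neg) {
    if (nzchar(rel) || nzchar(lev))
      stop("'!' shorthand takes a bare node name: '", lit, "'")
    rel <- "=="; lev <- "0"
  } else if (!nzchar(rel)) {
    if (nzchar(lev)) stop("cannot parse rule condition: '", lit, "'")
    rel <- ">="; lev <- "1"
  } else if (!nzchar(lev)) {
    stop("missing level in rule condition: '", lit, "'")
  }
  data.frame(node = node, relation = rel, level = as.integer(lev),
             stringsAsFactors = FALSE)
}

.deparseCase <- function(cs) {
  cond <- cs$conditions
  lhs <- if (nrow(cond))
    paste(paste0(cond$node, cond$relation, cond$level), collapse = " & ")
  else ""
  paste0(lhs, " -> ", cs$output)
}

#' Construct a synchronous multi-valued logical network
#'
#' @param maxLevels named integer vector giving each node's maximal level
#'   (names define the node order of states).
#' @param rules list of [UpdateRule-class] objects (any order), or a named
#'   list/character of rule-case vectors which will be passed through
#'   [updateRule()] with \code{defaults}.
#' @param clamps optional named integer vector of fixed levels.
#' @param defaults named integer vector of per-node default levels, used
#'   only when \code{rules} is given as case strings.
#' @return a validated [LogicalNetwork-class].
#' @examples
#' # two-node toggle switch: x' = NOT y, y' = NOT x
#' tog <- logicalNetwork(
#'   c(x = 1, y = 1),
#'   list(updateRule("x", "!y -> 1"), updateRule("y", "!x -> 1")))
#' enumerateAttractors(tog)
#' @export
logicalNetwork <- function(maxLevels, rules, clamps = integer(),
                           defaults = NULL) {
  nd <- names(maxLevels)
  if (is.null(nd)) stop("'maxLevels' must be a named vector")
  if (!all(vapply(rules, is, TRUE, "UpdateRule"))) {
    if (is.null(names(rules)) || !setequal(names(rules), nd))
      stop("rule case lists must be named by the nodes")
    rules <- lapply(nd, function(nm)
      updateRule(nm, rules[[nm]],
                 default = if (is.null(defaults)) 0L else defaults[[nm]]))
  }
  names(rules) <- vapply(rules, function(r) r@target, "")
  rules <- rules[nd]
  cl <- as.integer(clamps)
  names(cl) <- names(clamps)
  new("LogicalNetwork", nodes = nd,
      maxLevels = stats::setNames(as.integer(maxLevels), nd),
      rules = rules, clamps = cl)
}

# ----------------------------------------------------------------------
# State encoding (mixed radix, first node most significant)
# ----------------------------------------------------------------------

.stateSpaceSizeNet <- function(network) prod(network@maxLevels + 1)

#' @rdname accessors
setMethod("stateSpaceSize", "LogicalNetwork",
          function(x) .stateSpaceSizeNet(x))

.checkState <- function(network, state) {
  if (length(state) != length(network@nodes))
    stop("state must assign a level to every node")
  if (!is.null(names(state))) {
    if (!setequal(names(state), network@nodes))
      stop("state names do not match the network's nodes")
    state <- state[network@nodes]
  }
  state <- as.integer(state)
  if (any(is.na(state)) || any(state < 0L) ||
      any(state > network@maxLevels))
    stop("state has a level outside some node's range")
  stats::setNames(state, network@nodes)
}

#' Encode and decode states as mixed-radix indices
#'
#' States are enumerated in mixed radix with the first node most
#' significant, so the encoded order coincides with lexicographic order of
#' the level vectors and the all-zero state has index 0.  \code{encodeState}
#' and \code{decodeState} are exact inverses over the full state space.
#'
#' @param network a [LogicalNetwork-class].
#' @param state named (or network-ordered) integer vector of levels.
#' @param index 0-based state index in \code{[0, stateSpaceSize)}.
#' @return \code{encodeState}: a 0-based numeric index;
#'   \code{decodeState}: a named integer state vector.
#' @examples
#' net <- buildG2a()
#' encodeState(net, c(CtrA_a = 0, GcrA = 0, DnaA = 0, CcrM = 0, SciP = 0))
#' decodeState(net, 31)
#' @export
encodeState <- function(network, state) {
  state <- .checkState(network, state)
  radix <- network@maxLevels + 1
  idx <- 0
  for (i in seq_along(state)) idx <- idx * radix[[i]] + state[[i]]
  idx
}

#' @rdname encodeState
#' @export
decodeState <- function(network, index) {
  N <- .stateSpaceSizeNet(network)
  if (length(index) != 1L || is.na(index) || index < 0 || index >= N)
    stop("state index out of range [0, ", N, ")")
  drop(.decodeIndices(network, index))
}

# indices: 0-based numeric vector -> matrix (length(indices) x n)
.decodeIndices <- function(network, indices) {
  radix <- network@maxLevels + 1
  n <- length(radix)
  out <- matrix(0L, nrow = length(indices), ncol = n,
                dimnames = list(NULL, network@nodes))
  rest <- indices
  for (i in n:1) {
    out[, i] <- as.integer(rest %% radix[[i]])
    rest <- rest %/% radix[[i]]
  }
  out
}

# S: integer matrix (m x n) -> 0-based numeric indices
.encodeMatrix <- function(network, S) {
  radix <- network@maxLevels + 1
  idx <- numeric(nrow(S))
  for (i in seq_along(radix)) idx <- idx * radix[[i]] + S[, i]
  idx
}

# ----------------------------------------------------------------------
# Rule evaluation
# ----------------------------------------------------------------------

#' Evaluate one update rule on a single state
#'
#' Returns the output level of the first matching case, or the rule's
#' default when no case matches.  Clamps are deliberately ignored here:
#' clamping is applied by [successorState()], so a clamped node's rule can
#' still be inspected.
#'
#' @param rule an [UpdateRule-class].
#' @param state named integer vector of node levels; must cover every node
#'   the rule references.
#' @return an integer level.
#' @examples
#' r <- updateRule("DnaA", "CtrA_a & CcrM & !GcrA & !DnaA -> 1")
#' evaluateRule(r, c(CtrA_a = 1, CcrM = 1, GcrA = 0, DnaA = 0))
#' @export
evaluateRule <- function(rule, state) {
  if (is.null(names(state))) stop("'state' must be a named vector")
  for (cs in rule@cases) {
    cond <- cs$conditions
    ok <- TRUE
    for (j in seq_len(nrow(cond))) {
      nm <- cond$node[j]
      if (is.na(match(nm, names(state))))
        stop("rule references undeclared node '", nm, "'")
      v <- state[[nm]]
      ok <- switch(cond$relation[j],
                   "==" = v == cond$level[j],
                   ">=" = v >= cond$level[j],
                   "<=" = v <= cond$level[j])
      if (!ok) break
    }
    if (ok) return(as.integer(cs$output))
  }
  rule@default
}

# vectorised rule evaluation over a state matrix (m x n, named columns)
.evalRuleMatrix <- function(rule, S) {
  m <- nrow(S)
  out <- rep(rule@default, m)
  open <- rep(TRUE, m)
  for (cs in rule@cases) {
    if (!any(open)) break
    cond <- cs$conditions
    hit <- open
    for (j in seq_len(nrow(cond))) {
      v <- S[, cond$node[j]]
      hit <- hit & switch(cond$relation[j],
                          "==" = v == cond$level[j],
                          ">=" = v >= cond$level[j],
                          "<=" = v <= cond$level[j])
      if (!any(hit)) break
    }
    out[hit] <- cs$output
    open <- open & !hit
  }
  out
}

# synchronous step for a whole state matrix; clamps override
.successorMatrix <- function(network, S) {
  out <- matrix(0L, nrow = nrow(S), ncol = ncol(S),
                dimnames = dimnames(S))
  for (i in seq_along(network@nodes))
    out[, i] <- .evalRuleMatrix(network@rules[[i]], S)
  if (length(network@clamps))
    for (nm in names(network@clamps))
      out[, nm] <- network@clamps[[nm]]
  out
}

#' Synchronous successor of a state
#'
#' Applies every node's update rule simultaneously to \code{state};
#' clamped nodes are set to their clamp level instead.  The map is a pure
#' function of the state.
#'
#' @param network a [LogicalNetwork-class].
#' @param state named (or network-ordered) integer level vector.
#' @return the successor state, a named integer vector.
#' @examples
#' net <- buildG2a()
#' # "only GcrA expressed" advances to "CtrA is the only active protein"
#' successorState(net, c(CtrA_a = 0, GcrA = 1, DnaA = 0, CcrM = 0, SciP = 0))
#' @export
successorState <- function(network, state) {
  state <- .checkState(network, state)
  S <- matrix(state, nrow = 1, dimnames = list(NULL, network@nodes))
  stats::setNames(drop(.successorMatrix(network, S)), network@nodes)
}

#' Trajectory of the synchronous dynamics from a start state
#'
#' Iterates the successor map until a state repeats, returning the visited
#' states (one per row) up to and including the first revisited state.  The
#' final segment between the two occurrences of the repeated state is the
#' attractor the trajectory has reached; a fixed point yields a two-row
#' trajectory (the state and itself).
#'
#' @param network a [LogicalNetwork-class].
#' @param state the start state.
#' @param maxSteps safety bound on the number of steps; the default
#'   (state-space size + 1) guarantees a revisit.
#' @return integer matrix of states, rows \code{t0, t1, ...}.
#' @export
trajectory <- function(network, state,
                       maxSteps = .stateSpaceSizeNet(network) + 1) {
  if (maxSteps < 1) stop("'maxSteps' must be >= 1")
  state <- .checkState(network, state)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows <- list(state)
  assign(as.character(encodeState(network, state)), 1L, envir = seen)
  s <- state
  for (t in seq_len(maxSteps)) {
    s <- successorState(network, s)
    rows[[length(rows) + 1L]] <- s
    key <- as.character(encodeState(network, s))
    if (!is.null(seen[[key]])) {
      out <- do.call(rbind, rows)
      rownames(out) <- paste0("t", seq_len(nrow(out)) - 1L)
      return(out)
    }
    assign(key, 1L, envir = seen)
  }
  stop("internal error: no state revisited within ", maxSteps, " steps")
}

# ----------------------------------------------------------------------
# Exhaustive attractor / basin enumeration
# ----------------------------------------------------------------------

.checkSizeCap <- function(network, sizeCap) {
  N <- .stateSpaceSizeNet(network)
  if (N > sizeCap)
    stop("state space has ", format(N, big.mark = ","),
         " states, above the size cap of ", format(sizeCap, big.mark = ","),
         "; raise 'sizeCap' to force exhaustive enumeration")
  N
}

# 1-based successor table over the full state space
.successorTable <- function(network) {
  N <- .stateSpaceSizeNet(network)
  S <- .decodeIndices(network, seq_len(N) - 1)
  .encodeMatrix(network, .successorMatrix(network, S)) + 1
}

# given the 1-based successor table, identify cycles and basins
.attractorsFromTable <- function(network, succ) {
  N <- length(succ)
  # pointer doubling: after ceiling(log2(N)) squarings every state is
  # mapped >= N steps ahead, i.e. into its attractor cycle
  reach <- succ
  steps <- 1
  while (steps < N) {
    reach <- reach[reach]
    steps <- steps * 2
  }
  attrStates <- sort(unique(reach))
  onCycle <- logical(N)
  onCycle[attrStates] <- TRUE
  cycleId <- integer(N)
  cycles <- list()
  for (s in attrStates) {
    if (cycleId[s]) next
    cyc <- s
    nxt <- succ[s]
    while (nxt != s) {
      cyc <- c(cyc, nxt)
      nxt <- succ[nxt]
    }
    cycles[[length(cycles) + 1L]] <- cyc
    cycleId[cyc] <- length(cycles)
  }
  # canonical order: by smallest encoded state on each cycle
  firsts <- vapply(cycles, min, 1)
  ord <- order(firsts)
  cycles <- lapply(cycles[ord], function(cyc) {
    k <- which.min(cyc)                       # canonical rotation
    c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
  })
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  basins <- tabulate(remap[cycleId[reach]], nbins = length(cycles))
  atts <- lapply(cycles, function(cyc) {
    st <- .decodeIndices(network, cyc - 1)
    new("Attractor", states = st,
        kind = if (nrow(st) == 1L) "fixed_point" else "limit_cycle")
  })
  new("AttractorReport", attractors = atts, basinSizes = as.numeric(basins),
      stateSpaceSize = as.numeric(N))
}

#' Enumerate all attractors and basins of the synchronous dynamics
#'
#' Exhaustively enumerates the full discrete state space, computes every
#' state's synchronous successor, and extracts all attractors (fixed points
#' and limit cycles) of the resulting functional graph together with their
#' basin sizes.  Cycle states are found by pointer doubling on the
#' successor table (squaring the map until every state has been iterated
#' past its transient), after which cycles are walked explicitly.
#' Attractors are reported in canonical order: each cycle is rotated so its
#' lexicographically smallest state comes first, and attractors are sorted
#' by that state's index.
#'
#' Clamped networks are enumerated over the full product space; clamp
#' dominance guarantees every attractor state carries the clamp levels.
#'
#' @param network a [LogicalNetwork-class].
#' @param sizeCap refuse state spaces larger than this (the analyses here
#'   are exhaustive by design; there is no silent sampling fallback).
#' @return an [AttractorReport-class].
#' @examples
#' enumerateAttractors(buildG2a())  # one 4-state limit cycle, basin 32
#' @rdname enumerateAttractors
#' @export
setMethod("enumerateAttractors", "LogicalNetwork",
  function(network, sizeCap = 1e7) {
    .checkSizeCap(network, sizeCap)
    .attractorsFromTable(network, .successorTable(network))
  })

#' Full transition-state graph of a network
#'
#' Builds the functional graph over the complete state space: one vertex
#' per state, one edge from each state to its synchronous successor.
#'
#' @param network a [LogicalNetwork-class].
#' @param sizeCap refuse state spaces larger than this.
#' @return a [TransitionGraph-class]; indices are 0-based state codes.
#' @seealso [exportTransitionGraph()] for DOT/GraphML output.
#' @rdname transitionGraph
#' @export
setMethod("transitionGraph", "LogicalNetwork",
  function(network, sizeCap = 1e7) {
    N <- .checkSizeCap(network, sizeCap)
    S <- .decodeIndices(network, seq_len(N) - 1)
    succ <- .encodeMatrix(network, .successorMatrix(network, S))
    labels <- apply(S, 1L, paste, collapse = "-")
    new("TransitionGraph", successors = succ, labels = labels,
        nodes = network@nodes)
  })
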