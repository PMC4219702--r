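#' @include models.R
NULL

#' Clamp a node to simulate knockout or constitutive expression
#'
#' A knockout (written \eqn{\Delta}) clamps the node to level 0 for the
#' whole simulation; constitutive (over-)expression, written (+), clamps it
#' to its maximal level (for three-level nodes that is the
#' active/phosphorylated form).  The original network is not modified.
#'
#' @param network a [LogicalNetwork-class].
#' @param node name of the node to clamp.
#' @param mode \code{"knockout"} or \code{"overexpression"}.
#' @return a new [LogicalNetwork-class] with the clamp added.
#' @examples
#' dk <- applyPerturbation(buildG2b(), "DivK", "knockout")
#' clamps(dk)
#' @export
applyPerturbation <- function(network, node,
                              mode = c("knockout", "overexpression")) {
  mode <- match.arg(mode)
  if (!node %in% network@nodes)
    stop("unknown node '", node, "'")
  if (node %in% names(network@clamps))
    stop("node '", node, "' is already clamped (conflicting perturbation)")
  lev <- if (mode == "knockout") 0L else network@maxLevels[[node]]
  cl <- c(network@clamps, stats::setNames(lev, node))
  initialize(network, clamps = cl)
}

.scanSummaryRow <- function(node, mode, report) {
  kinds <- vapply(report@attractors, function(a) a@kind, "")
  desc <- vapply(seq_along(report@attractors), function(i) {
    a <- report@attractors[[i]]
    st <- a@states[1L, ]
    sprintf("%s[L%d,basin%s]{%s}", substr(a@kind, 1, 2), nrow(a@states),
            format(report@basinSizes[i]),
            paste0(names(st), "=", st, collapse = ","))
  }, "")
  data.frame(node = node, mode = mode,
             nAttractors = length(kinds),
             nFixedPoints = sum(kinds == "fixed_point"),
             nCycles = sum(kinds == "limit_cycle"),
             attractorSummary = paste(desc, collapse = " | "),
             stringsAsFactors = FALSE)
}

.perturbationScan <- function(network, mode, sizeCap) {
  baseline <- enumerateAttractors(network, sizeCap)
  targets <- setdiff(network@nodes, names(network@clamps))
  reports <- list()
  rows <- list(.scanSummaryRow("(none)", "baseline", baseline))
  for (nm in targets) {
    rep_i <- enumerateAttractors(applyPerturbation(network, nm, mode),
                                 sizeCap)
    reports[[nm]] <- rep_i
    rows[[length(rows) + 1L]] <- .scanSummaryRow(nm, mode, rep_i)
  }
  new("PerturbationScan", baseline = baseline, reports = reports,
      summary = do.call(rbind, rows), mode = mode)
}

#' Single-node knockout and overexpression scans
#'
#' Recomputes the full attractor landscape under a clamp of each node in
#' turn (knockout: clamp to 0; overexpression: clamp to the maximal level)
#' and summarises each landscape against the unperturbed baseline.  On the
#' phospho-proteolytic subnetwork this reproduces the classical mutant
#' phenotypes: \eqn{\Delta}divK and \eqn{\Delta}divJ each collapse the
#' bistable switch to a single swarmer-like fixed point with no CtrA
#' proteolysis, \eqn{\Delta}clpXP-rcdA abolishes CtrA degradation while
#' leaving phosphorylation intact, and \eqn{\Delta}cpdR leaves the
#' proteolytic complex unassembled.
#'
#' @param network a [LogicalNetwork-class].
#' @param sizeCap passed to [enumerateAttractors()].
#' @return a [PerturbationScan-class].
#' @examples
#' ko <- knockoutScan(buildG2b())
#' subset(ko@summary, node == "DivK")$nAttractors   # 1
#' @export
knockoutScan <- function(network, sizeCap = 1e7)
  .perturbationScan(network, "knockout", sizeCap)

#' @rdname knockoutScan
#' @export
overexpressionScan <- function(network, sizeCap = 1e7)
  .perturbationScan(network, "overexpression", sizeCap)

#' The swarmer-to-stalked differentiation switch protocol
#'
#' During differentiation the phosphatase PleC at the flagellated pole is
#' replaced by the kinase DivJ.  The protocol emulates this replacement on
#' the cell-fate network: start from a resting state (by default the
#' swarmer-pole fixed point), transiently clamp a set of nodes (by default
#' \code{PleC = 0, DivJ = 2}), iterate the clamped dynamics, release the
#' clamps, and iterate to convergence.  With the default clamps the system
#' leaves the swarmer attractor and settles in the stalked-pole fixed
#' point: a system-level switch between the two attractors.
#'
#' @param network the cell-fate network ([buildG2b()]).
#' @param clampLevels named integer vector of transient clamps.
#' @param start resting start state; default is the swarmer fixed point
#'   (the fixed-point attractor whose first node is at its maximal level).
#' @param holdSteps how long the clamps are held: \code{NULL} (default)
#'   holds them until the clamped dynamics converges; an integer holds
#'   them for exactly that many steps (a pulse).
#' @return a list with elements \code{trace} (integer state matrix, one
#'   row per step), \code{phase} (character vector: \code{"hold"} /
#'   \code{"release"} per row), \code{start}, \code{afterHold} (state when
#'   the clamps are released), \code{final} (resting state after release),
#'   and \code{switched} (\code{TRUE} if \code{final} differs from
#'   \code{start}).
#' @examples
#' sw <- switchExperiment(buildG2b())
#' sw$final   # the stalked-pole fixed point j
#' @export
switchExperiment <- function(network,
                             clampLevels = c(PleC = 0L, DivJ = 2L),
                             start = NULL, holdSteps = NULL) {
  if (is.null(start)) {
    rep0 <- enumerateAttractors(network)
    fps <- Filter(function(a) a@kind == "fixed_point", rep0@attractors)
    if (!length(fps)) stop("network has no fixed point to start from")
    lead <- vapply(fps, function(a) a@states[1L, 1L], 1L)
    start <- fps[[which.max(lead)]]@states[1L, ]
  }
  start <- .checkState(network, start)
  bad <- setdiff(names(clampLevels), network@nodes)
  if (length(bad)) stop("unknown clamp node(s): ", paste(bad, collapse = ", "))

  clamped <- initialize(network,
    clamps = c(network@clamps,
               stats::setNames(as.integer(clampLevels), names(clampLevels))))
  N <- .stateSpaceSizeNet(network)

  runPhase <- function(net, s0, maxSteps) {
    rows <- list()
    s <- s0
    seen <- new.env(hash = TRUE, parent = emptyenv())
    assign(as.character(encodeState(net, s)), TRUE, envir = seen)
    for (t in seq_len(maxSteps)) {
      s <- successorState(net, s)
      rows[[t]] <- s
      key <- as.character(encodeState(net, s))
      if (!is.null(seen[[key]])) break
      assign(key, TRUE, envir = seen)
    }
    do.call(rbind, rows)
  }

  # hold phase: first step applies the clamps to the start state
  holdTrace <- if (is.null(holdSteps)) {
    runPhase(clamped, start, N + 1)
  } else {
    if (holdSteps < 1) stop("'holdSteps' must be >= 1")
    s <- start
    out <- matrix(0L, holdSteps, length(start),
                  dimnames = list(NULL, network@nodes))
    for (t in seq_len(holdSteps)) {
      s <- successorState(clamped, s)
      out[t, ] <- s
    }
    out
  }
  afterHold <- stats::setNames(holdTrace[nrow(holdTrace), ], network@nodes)
  releaseTrace <- runPhase(network, afterHold, N + 1)
  final <- stats::setNames(releaseTrace[nrow(releaseTrace), ],
                           network@nodes)
  trace <- rbind(matrix(start, 1, dimnames = list(NULL, network@nodes)),
                 holdTrace, releaseTrace)
  list(trace = trace,
       phase = c("start", rep("hold", nrow(holdTrace)),
                 rep("release", nrow(releaseTrace))),
       start = start, afterHold = afterHold, final = final,
       switched = !identical(unname(final), unname(start)))
}
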