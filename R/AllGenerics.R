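#' @include AllClasses.R
NULL

#' Accessors for network and report objects
#'
#' Small accessor generics: \code{nodes()} returns node names,
#' \code{maxLevels()} the per-node level caps, \code{rules()} the list of
#' update rules, \code{clamps()} the fixed-level clamps,
#' \code{attractors()} the list of attractors in a report,
#' \code{basinSizes()} their basin sizes, \code{stateSpaceSize()} the
#' number of states, \code{attractorStates()} the state matrix of an
#' attractor and \code{attractorKind()} its kind, \code{interactions()}
#' the edge table of a regulatory graph.
#'
#' @param x the object.
#' @return the slot contents described above.
#' @examples
#' net <- buildG2a()
#' nodes(net)
#' maxLevels(net)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("maxLevels", function(x) standardGeneric("maxLevels"))

#' @rdname accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname accessors
#' @export
setGeneric("clamps", function(x) standardGeneric("clamps"))

#' @rdname accessors
#' @export
setGeneric("attractors", function(x) standardGeneric("attractors"))

#' @rdname accessors
#' @export
setGeneric("basinSizes", function(x) standardGeneric("basinSizes"))

#' @rdname accessors
#' @export
setGeneric("stateSpaceSize", function(x) standardGeneric("stateSpaceSize"))

#' @rdname accessors
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' @rdname accessors
#' @export
setGeneric("attractorKind", function(x) standardGeneric("attractorKind"))

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname enumerateAttractors
#' @export
setGeneric("enumerateAttractors",
  function(network, sizeCap = 1e7) standardGeneric("enumerateAttractors"))

#' @rdname transitionGraph
#' @export
setGeneric("transitionGraph",
  function(network, sizeCap = 1e7) standardGeneric("transitionGraph"))

#' @rdname reduceToCore
#' @export
setGeneric("reduceToCore", function(graph) standardGeneric("reduceToCore"))

# -- accessor methods ---------------------------------------------------

#' @rdname accessors
setMethod("nodes", "LogicalNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("maxLevels", "LogicalNetwork", function(x) x@maxLevels)

#' @rdname accessors
setMethod("rules", "LogicalNetwork", function(x) x@rules)

#' @rdname accessors
setMethod("clamps", "LogicalNetwork", function(x) x@clamps)

#' @rdname accessors
setMethod("nodes", "RegulatoryGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("interactions", "RegulatoryGraph", function(x) x@edges)

#' @rdname accessors
setMethod("attractors", "AttractorReport", function(x) x@attractors)

#' @rdname accessors
setMethod("basinSizes", "AttractorReport", function(x) x@basinSizes)

#' @rdname accessors
setMethod("stateSpaceSize", "AttractorReport", function(x) x@stateSpaceSize)

#' @rdname accessors
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @rdname accessors
setMethod("attractorKind", "Attractor", function(x) x@kind)

# -- show methods -------------------------------------------------------

setMethod("show", "LogicalNetwork", function(object) {
  cat(sprintf("LogicalNetwork with %d node(s), state space %s\n",
              length(object@nodes),
              format(.stateSpaceSizeNet(object), big.mark = ",")))
  caps <- paste0(object@nodes, "(0..", object@maxLevels, ")")
  cat("  nodes: ", paste(caps, collapse = " "), "\n", sep = "")
  if (length(object@clamps))
    cat("  clamps: ",
        paste0(names(object@clamps), "=", object@clamps, collapse = " "),
        "\n", sep = "")
})

setMethod("show", "Attractor", function(object) {
  cat(sprintf("%s of length %d\n", object@kind, nrow(object@states)))
  print(object@states)
})

setMethod("show", "AttractorReport", function(object) {
  k <- length(object@attractors)
  kinds <- vapply(object@attractors, function(a) a@kind, "")
  cat(sprintf("AttractorReport: %d attractor(s) (%d fixed point(s), %d cycle(s)) over %s states\n",
              k, sum(kinds == "fixed_point"), sum(kinds == "limit_cycle"),
              format(object@stateSpaceSize, big.mark = ",")))
  for (i in seq_len(k)) {
    a <- object@attractors[[i]]
    cat(sprintf("  [%d] %s, length %d, basin %s\n", i, a@kind,
                nrow(a@states),
                format(object@basinSizes[i], big.mark = ",")))
  }
})

setMethod("show", "TransitionGraph", function(object) {
  cat(sprintf("TransitionGraph over %s states (out-degree 1), %d node(s)\n",
              format(length(object@successors), big.mark = ","),
              length(object@nodes)))
})

setMethod("show", "DerridaMap", function(object) {
  cat(sprintf("DerridaMap over h = %s (n = %d nodes)\n",
              paste(range(object@h), collapse = ".."), object@nNodes))
  print(data.frame(h = object@h, M = round(object@M, 4),
                   stderr = signif(object@stderr, 3),
                   n_samples = object@nSamples))
})

setMethod("show", "RegimeEstimate", function(object) {
  cat(sprintf("Derrida slope m = %.4f (se %.4f, method %s): %s regime\n",
              object@slope, object@se, object@method, object@regime))
})

setMethod("show", "RegulatoryGraph", function(object) {
  cat(sprintf("RegulatoryGraph: %d node(s), %d interaction(s)\n",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "PerturbationScan", function(object) {
  cat(sprintf("PerturbationScan (%s) over %d node(s)\n",
              object@mode, nrow(object@summary)))
  print(object@summary[, c("node", "nAttractors", "nFixedPoints", "nCycles")])
})
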