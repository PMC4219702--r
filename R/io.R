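#' @include synthetic.R
NULL

.networkToList <- function(network) {
  list(
    format = "caulologic-model-v1",
    nodes = lapply(network@nodes, function(nm)
      list(name = nm, max_level = unname(network@maxLevels[[nm]]))),
    rules = lapply(network@nodes, function(nm) {
      r <- network@rules[[nm]]
      list(target = nm,
           cases = as.list(vapply(r@cases, .deparseCase, "")),
           default = unname(r@default))
    }),
    clamps = as.list(network@clamps))
}

.networkFromList <- function(x) {
  if (is.null(x$nodes) || is.null(x$rules))
    stop("model file must declare 'nodes' and 'rules'")
  nd <- vapply(x$nodes, function(n) n$name, "")
  caps <- stats::setNames(vapply(x$nodes, function(n)
    as.integer(n$max_level), 1L), nd)
  ruleList <- lapply(x$rules, function(r)
    updateRule(r$target, unlist(r$cases),
               default = if (is.null(r$default)) 0L else r$default))
  clamps <- integer()
  if (length(x$clamps)) {
    clamps <- vapply(x$clamps, as.integer, 1L)
    names(clamps) <- names(x$clamps)
  }
  logicalNetwork(caps, ruleList, clamps = clamps)
}

#' Read and write logical models in a declarative YAML/JSON format
#'
#' Models are stored as a plain-text document with \code{nodes} (name and
#' maximal level), \code{rules} (ordered case strings in the syntax of
#' [updateRule()], e.g. \code{"CtrA==2 & CcrM>=1 -> 1"}, plus a default
#' level) and optional \code{clamps}.  Reading a written file reconstructs
#' the network exactly (identical nodes, rules and clamps), and the
#' packaged reference model files under
#' \code{system.file("extdata", "models", package = "CauloLogic")} load
#' identically to the programmatic builders.
#'
#' @param path file path; the format is chosen by extension
#'   (\code{.json} for JSON, anything else YAML) unless \code{format}
#'   is given.
#' @param network a [LogicalNetwork-class] (for writing).
#' @param format \code{"yaml"} or \code{"json"}.
#' @return \code{readLogicalModel}: a [LogicalNetwork-class];
#'   \code{writeLogicalModel}: \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLogicalModel(buildG2a(), f)
#' identical(readLogicalModel(f), buildG2a())
#' @export
readLogicalModel <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  x <- switch(match.arg(format, c("yaml", "json")),
              yaml = yaml::read_yaml(path),
              json = jsonlite::read_json(path, simplifyVector = FALSE))
  .networkFromList(x)
}

#' @rdname readLogicalModel
#' @export
writeLogicalModel <- function(network, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  x <- .networkToList(network)
  switch(match.arg(format, c("yaml", "json")),
         yaml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     pretty = TRUE))
  invisible(path)
}

#' Export a transition graph to DOT or GraphML
#'
#' Writes the full transition-state graph with states labeled by their
#' node levels (dash-separated, in node order), for rendering with
#' Graphviz or import into graph tools.
#'
#' @param tg a [TransitionGraph-class] from [transitionGraph()].
#' @param path output file.
#' @param format \code{"dot"} or \code{"graphml"} (default by extension).
#' @return \code{path}, invisibly.
#' @export
exportTransitionGraph <- function(tg, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "dot"
  format <- match.arg(format, c("dot", "graphml"))
  n <- length(tg@successors)
  g <- igraph::make_graph(
    rbind(seq_len(n), tg@successors + 1), n = n, directed = TRUE)
  igraph::V(g)$label <- tg@labels
  igraph::V(g)$name <- tg@labels
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Write an attractor report to CSV or JSON
#'
#' The CSV has one row per attractor state with columns
#' \code{attractor}, \code{kind}, \code{period}, \code{step},
#' \code{basin_size}, and one column per node; a format-version header
#' row comment is included.  The JSON mirrors the
#' [AttractorReport-class] structure.
#'
#' @param report an [AttractorReport-class].
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"} (default by extension).
#' @return \code{path}, invisibly.
#' @export
writeAttractorReport <- function(report, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  rows <- do.call(rbind, lapply(seq_along(report@attractors), function(i) {
    a <- report@attractors[[i]]
    cbind(data.frame(attractor = i, kind = a@kind,
                     period = nrow(a@states),
                     step = seq_len(nrow(a@states)),
                     basin_size = report@basinSizes[i]),
          as.data.frame(a@states))
  }))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# caulologic-attractor-report-v1", con)
    utils::write.csv(rows, con, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(format = "caulologic-attractor-report-v1",
           state_space_size = report@stateSpaceSize,
           attractors = lapply(seq_along(report@attractors), function(i) {
             a <- report@attractors[[i]]
             list(kind = a@kind, period = nrow(a@states),
                  basin_size = report@basinSizes[i],
                  states = apply(a@states, 1L, as.list))
           })),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Plot a Derrida map
#'
#' Plots M(h) against h with the diagonal reference line M = h; the slope
#' of the curve at the origin relative to the diagonal shows the
#' dynamical regime at a glance.
#'
#' @param x a [DerridaMap-class].
#' @param normalized plot M/n vs h/n instead of node counts.
#' @param ... passed to [plot()].
#' @return invisibly, \code{NULL}.
#' @export
plotDerridaMap <- function(x, normalized = FALSE, ...) {
  h <- c(0, x@h); M <- c(0, x@M)
  if (normalized) { h <- h / x@nNodes; M <- M / x@nNodes }
  lim <- c(0, max(h))
  graphics::plot(h, M, type = "b", pch = 16, xlim = lim, ylim = lim,
                 xlab = if (normalized) "h(t)/n" else "h(t) [nodes]",
                 ylab = if (normalized) "M(h)/n" else "M(h) [nodes]", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(NULL)
}
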