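#' @include perturbations.R
NULL

#' Hamming distance between two states
#'
#' The number of nodes at which the two states differ.  For multi-valued
#' nodes a difference counts once regardless of the level gap (levels 1 vs
#' 2 contribute 1, just like 0 vs 2): this is the standard generalization
#' used in Derrida analysis of multi-valued networks.
#'
#' @param s1,s2 named integer state vectors over the same node set.
#' @return an integer in \code{0..n}.
#' @export
hammingDistance <- function(s1, s2) {
  if (length(s1) != length(s2))
    stop("states must cover the same nodes")
  if (!is.null(names(s1)) && !is.null(names(s2))) {
    if (!setequal(names(s1), names(s2)))
      stop("states must cover the same nodes")
    s2 <- s2[names(s1)]
  }
  sum(s1 != s2)
}

.unclampedNodes <- function(network)
  setdiff(network@nodes, names(network@clamps))

#' Randomly perturb a state at an exact Hamming distance
#'
#' Picks \code{h} distinct nodes uniformly at random and reassigns each a
#' level drawn uniformly from its allowed levels excluding the current
#' one, so the result lies at Hamming distance exactly \code{h} from the
#' input.  Clamped nodes may be picked like any other (their levels are
#' free at time 0); the clamp then erases the difference at the next
#' synchronous step.  Uses R's RNG; call \code{set.seed()} for
#' reproducibility.
#'
#' @param network a [LogicalNetwork-class].
#' @param state the background state.
#' @param h number of nodes to perturb (\code{1 <= h <= n}).
#' @return the perturbed state.
#' @export
perturbState <- function(network, state, h = 1L) {
  state <- .checkState(network, state)
  if (h < 1 || h > length(network@nodes))
    stop("'h' must be between 1 and the number of nodes (",
         length(network@nodes), ")")
  pick <- sample(network@nodes, h)
  for (nm in pick) {
    alts <- setdiff(0:network@maxLevels[[nm]], state[[nm]])
    state[[nm]] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }
  state
}

# -- vectorised sampling helpers ---------------------------------------

# m uniform background states as a matrix; clamped nodes at clamp level
.sampleBackgrounds <- function(network, m) {
  N <- .stateSpaceSizeNet(network)
  S <- if (N <= .Machine$integer.max) {
    .decodeIndices(network, sample.int(N, m, replace = TRUE) - 1)
  } else {
    out <- matrix(0L, m, length(network@nodes),
                  dimnames = list(NULL, network@nodes))
    for (i in seq_along(network@nodes))
      out[, i] <- sample.int(network@maxLevels[[i]] + 1L, m,
                             replace = TRUE) - 1L
    out
  }
  if (length(network@clamps))
    for (nm in names(network@clamps))
      S[, nm] <- network@clamps[[nm]]
  S
}

# perturb each row of S at exactly h of the free columns
.perturbMatrix <- function(network, S, h, freeIdx) {
  m <- nrow(S)
  caps <- network@maxLevels
  # choose h distinct free columns per row: iterated masked max-draw
  u <- matrix(stats::runif(m * length(freeIdx)), m)
  chosen <- matrix(FALSE, m, length(freeIdx))
  for (rep in seq_len(h)) {
    pick <- max.col(ifelse(chosen, -1, u))
    chosen[cbind(seq_len(m), pick)] <- TRUE
  }
  S2 <- S
  for (k in seq_along(freeIdx)) {
    rows <- which(chosen[, k])
    if (!length(rows)) next
    j <- freeIdx[k]
    cur <- S[rows, j]
    # uniform over 0..cap excluding cur: draw 0..cap-1 and shift past cur
    draw <- sample.int(caps[[j]], length(rows), replace = TRUE) - 1L
    S2[rows, j] <- draw + (draw >= cur)
  }
  S2
}

#' Estimate the Derrida map of a network
#'
#' For each initial perturbation size \code{h}, draws \code{samplesPerH}
#' background states uniformly over the state space, perturbs each at
#' exactly \code{h} nodes, advances both states one synchronous step, and
#' records the mean Hamming distance \code{M(h)} between the successors.
#' \code{M(0) = 0} holds exactly (the map is deterministic).  Identical
#' seeds give bit-identical maps.
#'
#' On clamped (knocked-out / constitutively expressed) networks,
#' background states carry the clamp levels; perturbations still pick
#' among all \code{n} nodes uniformly, but a perturbation landing on a
#' clamped node is erased by the clamp after one step, so clamped nodes
#' never count as differing in \code{M}.
#'
#' @param network a [LogicalNetwork-class].
#' @param samplesPerH state pairs sampled per h value.
#' @param seed RNG seed (optional but recommended).
#' @param hValues which perturbation sizes to sample; defaults to
#'   \code{1..n}.
#' @return a [DerridaMap-class].
#' @examples
#' dm <- derridaMap(buildG2a(), samplesPerH = 2000, seed = 1)
#' dm
#' @export
derridaMap <- function(network, samplesPerH = 20000, seed = NULL,
                       hValues = NULL) {
  if (samplesPerH < 1) stop("'samplesPerH' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  allIdx <- seq_along(network@nodes)
  if (is.null(hValues)) hValues <- allIdx
  if (any(hValues < 1) || any(hValues > length(allIdx)))
    stop("'hValues' must lie in 1..", length(allIdx))
  M <- se <- numeric(length(hValues))
  for (k in seq_along(hValues)) {
    S1 <- .sampleBackgrounds(network, samplesPerH)
    S2 <- .perturbMatrix(network, S1, hValues[k], allIdx)
    d <- rowSums(.successorMatrix(network, S1) !=
                 .successorMatrix(network, S2))
    M[k] <- mean(d)
    se[k] <- stats::sd(d) / sqrt(samplesPerH)
  }
  new("DerridaMap", h = as.numeric(hValues), M = M,
      nSamples = rep(as.numeric(samplesPerH), length(hValues)),
      stderr = se, nNodes = length(allIdx),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

.classifyRegime <- function(m, criticalBand) {
  if (abs(m - 1) <= criticalBand) "critical"
  else if (m < 1) "ordered"
  else "chaotic"
}

#' Derrida slope at h = 0 and dynamical-regime classification
#'
#' Estimates \code{m = dM(h)/dh} at \code{h = 0}.  Since \code{M(0) = 0}
#' exactly and h is discrete, the default estimator is the finite
#' difference through the origin using the \code{h = 1} class alone:
#' \code{m = M(1)}, the network's average single-node perturbation
#' sensitivity (averaged over background state, perturbed node and
#' replacement level).  \code{method = "fit"} instead fits a least-squares
#' line through the origin over \code{h <= 3}, as a sensitivity check on
#' the discretization.
#'
#' Perturbations are absorbed for \code{m < 1} (ordered regime) and
#' amplified for \code{m > 1} (chaotic); estimates within
#' \code{criticalBand} of 1 are called critical.
#'
#' @param network a [LogicalNetwork-class].
#' @param samples background/perturbation pairs to sample (per h class).
#' @param seed RNG seed.
#' @param method \code{"h1"} (default) or \code{"fit"}.
#' @param criticalBand half-width of the critical band around m = 1.
#' @return a [RegimeEstimate-class].
#' @examples
#' derridaSlope(buildG2Combined(), samples = 5000, seed = 1)
#' @export
derridaSlope <- function(network, samples = 20000, seed = NULL,
                         method = c("h1", "fit"), criticalBand = 0.05) {
  method <- match.arg(method)
  hv <- if (method == "h1") 1L else seq_len(min(3L, length(network@nodes)))
  dm <- derridaMap(network, samplesPerH = samples, seed = seed,
                   hValues = hv)
  if (method == "h1") {
    slope <- dm@M[1]
    se <- dm@stderr[1]
  } else {
    w <- 1 / pmax(dm@stderr, .Machine$double.eps)^2
    slope <- sum(w * dm@h * dm@M) / sum(w * dm@h^2)
    se <- sqrt(1 / sum(w * dm@h^2))
  }
  new("RegimeEstimate", slope = slope, se = se,
      regime = .classifyRegime(slope, criticalBand), method = method,
      samples = as.numeric(samples) * length(hv))
}

#' Exact Derrida slope by full enumeration (oracle)
#'
#' Computes \code{m = M(1)} exactly by enumerating every (background
#' state, perturbed node, replacement level) triple over the full state
#' space, weighting replacement levels uniformly within each node and
#' nodes uniformly.  Serves as the independent oracle against which the
#' sampled estimator of [derridaSlope()] is validated on small networks.
#'
#' @param network a [LogicalNetwork-class].
#' @param sizeCap refuse state spaces larger than this.
#' @param criticalBand as in [derridaSlope()].
#' @return a [RegimeEstimate-class] with \code{se = 0} and
#'   \code{method = "exact"}.
#' @export
exactDerridaSlope <- function(network, sizeCap = 1e5,
                              criticalBand = 0.05) {
  N <- .checkSizeCap(network, sizeCap)
  S <- .decodeIndices(network, seq_len(N) - 1)
  if (length(network@clamps)) {
    for (nm in names(network@clamps)) S[, nm] <- network@clamps[[nm]]
    S <- unique(S)                       # clamped coordinates collapse
  }
  FS <- .successorMatrix(network, S)
  total <- 0
  count <- 0
  for (j in seq_along(network@nodes)) {
    cap <- network@maxLevels[[j]]
    acc <- numeric(nrow(S))
    for (lev in 0:cap) {
      rows <- which(S[, j] != lev)
      if (!length(rows)) next
      S2 <- S[rows, , drop = FALSE]
      S2[, j] <- lev
      d <- rowSums(FS[rows, , drop = FALSE] !=
                   .successorMatrix(network, S2))
      acc[rows] <- acc[rows] + d
    }
    total <- total + sum(acc) / cap      # cap = #alternative levels
    count <- count + nrow(S)
  }
  m <- total / count
  new("RegimeEstimate", slope = m, se = 0,
      regime = .classifyRegime(m, criticalBand), method = "exact",
      samples = as.numeric(count))
}

#' Derrida slope under each single-node knockout
#'
#' Clamps each node to 0 in turn and re-estimates the Derrida slope,
#' quantifying how each deletion shifts the network's dynamical regime.
#' On the combined 13-node cell-cycle network, only the deletions of
#' gcrA, divJ and sciP move the network to a more ordered regime
#' (slope at or below wild type).
#'
#' @param network a [LogicalNetwork-class].
#' @param samples pairs sampled per estimate.
#' @param seed RNG seed; the whole scan runs on one seeded stream and is
#'   reproducible.
#' @param criticalBand as in [derridaSlope()].
#' @return a data frame with columns \code{node} (\code{"(wild-type)"}
#'   first, then one row per knockout), \code{m}, \code{se},
#'   \code{regime}, ordered by \code{m} within the knockouts.
#' @export
knockoutDerridaScan <- function(network, samples = 20000, seed = NULL,
                                criticalBand = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  wt <- derridaSlope(network, samples = samples, seed = NULL,
                     criticalBand = criticalBand)
  rows <- lapply(.unclampedNodes(network), function(nm) {
    est <- derridaSlope(applyPerturbation(network, nm, "knockout"),
                        samples = samples, seed = NULL,
                        criticalBand = criticalBand)
    data.frame(node = nm, m = est@slope, se = est@se,
               regime = est@regime, stringsAsFactors = FALSE)
  })
  ko <- do.call(rbind, rows)
  ko <- ko[order(ko$m), , drop = FALSE]
  out <- rbind(data.frame(node = "(wild-type)", m = wt@slope, se = wt@se,
                          regime = wt@regime, stringsAsFactors = FALSE),
               ko)
  rownames(out) <- NULL
  out
}
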