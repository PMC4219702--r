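# shared helpers: canonical report signatures and tiny reference networks

reportSignature <- function(rep) {
  list(cycles = lapply(attractors(rep), function(a) unname(attractorStates(a))),
       kinds = vapply(attractors(rep), attractorKind, ""),
       basins = unname(basinSizes(rep)),
       size = stateSpaceSize(rep))
}

expect_same_report <- function(a, b) {
  expect_equal(reportSignature(a), reportSignature(b))
}

# the isolated (DivK, DivJ, PleC) phospho-switch core
switchCoreNetwork <- function() {
  logicalNetwork(
    c(DivK = 2, DivJ = 2, PleC = 2),
    list(
      updateRule("DivK", c("PleC==2 -> 1", "DivJ==2 -> 2"), default = 1),
      updateRule("DivJ", c("PleC==2 -> 1", "DivK==2 -> 2"), default = 1),
      updateRule("PleC", "DivK==2 -> 1", default = 2)))
}

# mixed ensemble of small random networks used by the oracle-equivalence
# property tests: Boolean and ternary, varying n and k
randomTestEnsemble <- function(nNetworks, seedBase = 1000L) {
  lapply(seq_len(nNetworks), function(i) {
    n <- 3L + (i %% 6L)                      # 3..8 nodes
    k <- i %% min(3L, n)                     # 0..2 inputs
    lev <- if (i %% 4L == 0L) 2L else 1L     # every 4th network ternary
    randomNetwork(n, k, maxLevel = lev, seed = seedBase + i)
  })
}
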