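tableFixture <- function() {
  system.file("extdata", "table1_g2.tsv", package = "CauloLogic")
}

test_that("the packaged interaction catalogue loads to 13 nodes / 27 edges", {
  g <- loadInteractions(tableFixture())
  expect_length(nodes(g), 13)
  expect_equal(nrow(interactions(g)), 27)
  expect_setequal(nodes(g),
    c("CtrA", "GcrA", "DnaA", "CcrM", "SciP", "DivK", "DivJ", "PleC",
      "DivL", "CckA", "ChpT", "CpdR", "ClpXP_RcdA"))
  # a few literature anchors: CtrA represses gcrA; ClpXP degrades CtrA
  ed <- interactions(g)
  expect_equal(ed$sign[ed$regulator == "CtrA" & ed$target == "GcrA"],
               "negative")
  expect_equal(ed$mechanism[ed$regulator == "ClpXP_RcdA"], "proteolysis")
})

test_that("interaction vocabulary and shape are validated", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("regulator\ttarget\tsign\tmechanism\tevidence",
               "a\tb\tupwards\ttranscription\t1"), bad)
  expect_error(loadInteractions(bad), "unknown interaction sign")
  writeLines(c("regulator\ttarget\tsign\tmechanism\tevidence",
               "a\tb\tpositive\ttelepathy\t1"), bad)
  expect_error(loadInteractions(bad), "unknown mechanism")
  writeLines(c("regulator\ttarget\tsign\tmechanism\tevidence",
               "\tb\tpositive\ttranscription\t1"), bad)
  expect_error(loadInteractions(bad), "empty regulator/target")
  # empty table -> empty graph
  writeLines("regulator\ttarget\tsign\tmechanism\tevidence", bad)
  g <- loadInteractions(bad)
  expect_length(nodes(g), 0)
  expect_equal(nrow(interactions(g)), 0)
})

test_that("core reduction prunes non-regulatory nodes to exhaustion", {
  mk <- function(reg, tgt) {
    new("RegulatoryGraph", nodes = unique(c(reg, tgt)),
        edges = data.frame(regulator = reg, target = tgt,
                           sign = "positive", mechanism = "transcription",
                           evidence = "0", stringsAsFactors = FALSE))
  }
  # a -> b -> c collapses completely (c, then b, then a)
  chain <- reduceToCore(mk(c("a", "b"), c("b", "c")))
  expect_length(nodes(chain), 0)
  # a 2-cycle survives, its dead-end leaf does not
  cyc <- reduceToCore(mk(c("a", "b", "a"), c("b", "a", "x")))
  expect_setequal(nodes(cyc), c("a", "b"))
  expect_equal(nrow(interactions(cyc)), 2)
  # self-loops count as out-edges
  self <- reduceToCore(mk("a", "a"))
  expect_equal(nodes(self), "a")

  g <- loadInteractions(tableFixture())
  core <- reduceToCore(g)
  # the packaged catalogue is already fully regulatory
  expect_setequal(nodes(core), nodes(g))
  # idempotence, and no out-degree-0 node in any result
  expect_identical(reduceToCore(core), core)
  expect_true(all(nodes(core) %in% interactions(core)$regulator))
})

test_that("the transcriptional subnetwork has the unique 4-state cycle", {
  g2a <- buildG2a()
  rep <- enumerateAttractors(g2a)
  expect_length(attractors(rep), 1)
  cyc <- attractors(rep)[[1]]
  expect_equal(attractorKind(cyc), "limit_cycle")
  expect_equal(nrow(attractorStates(cyc)), 4)
  expect_equal(basinSizes(rep), 32)

  # the cycle visits DnaA+SciP -> GcrA -> CtrA -> CtrA+CcrM+SciP in order
  st <- attractorStates(cyc)
  a <- which(apply(st, 1, function(s) all(s == c(0, 0, 1, 0, 1))))
  expect_length(a, 1)
  ordered <- st[((a - 1 + 0:3) %% 4) + 1, ]
  expect_equal(unname(ordered),
               matrix(c(0L, 0L, 1L, 0L, 1L,
                        0L, 1L, 0L, 0L, 0L,
                        1L, 0L, 0L, 0L, 0L,
                        1L, 0L, 0L, 1L, 1L), 4, byrow = TRUE))

  # no spurious resting state: the all-zero state moves (CtrA turns on)
  zero <- stats::setNames(rep(0L, 5), nodes(g2a))
  expect_equal(successorState(g2a, zero)[["CtrA_a"]], 1L)
})

test_that("the cell-fate subnetwork is bistable with the two pole states", {
  g2b <- buildG2b()
  expect_equal(stateSpaceSize(g2b), 8748)   # 3^7 * 2^2
  rep <- enumerateAttractors(g2b)
  expect_length(attractors(rep), 2)
  expect_true(all(vapply(attractors(rep), attractorKind, "") == "fixed_point"))
  fps <- lapply(attractors(rep), function(a) drop(attractorStates(a)))
  expect_true(any(vapply(fps, identical, TRUE, g2bFixedPoint("swarmer"))))
  expect_true(any(vapply(fps, identical, TRUE, g2bFixedPoint("stalked"))))
  # and they are genuine fixed points of the rules
  for (w in c("swarmer", "stalked"))
    expect_equal(successorState(g2b, g2bFixedPoint(w)), g2bFixedPoint(w))
})

test_that("the DivK/DivJ/PleC core is a two-state switch on present/phospho levels", {
  core <- switchCoreNetwork()
  states <- expand.grid(DivK = 1:2, DivJ = 1:2, PleC = 1:2)
  finals <- apply(states, 1, function(s) {
    tr <- trajectory(core, stats::setNames(as.integer(s), names(states)))
    paste(tr[nrow(tr), ], collapse = "")
  })
  # every restricted start converges to (1,1,2) or (2,2,1); no cycles
  expect_true(all(finals %in% c("112", "221")))
  expect_equal(successorState(core, c(DivK = 1, DivJ = 1, PleC = 2)),
               c(DivK = 1L, DivJ = 1L, PleC = 2L))
  expect_equal(successorState(core, c(DivK = 2, DivJ = 2, PleC = 1)),
               c(DivK = 2L, DivJ = 2L, PleC = 1L))
  restrictedCycles <- vapply(seq_len(nrow(states)), function(r) {
    tr <- trajectory(core, stats::setNames(as.integer(states[r, ]),
                                           names(states)))
    k <- apply(tr, 1, paste, collapse = "")
    # length of the terminal cycle in the trajectory
    length(k) - match(k[length(k)], k)
  }, 1L)
  expect_true(all(restrictedCycles == 1))   # all fixed points, no cycles
})

test_that("the combined 13-node model merges the subnetworks consistently", {
  g2 <- buildG2Combined()
  expect_length(nodes(g2), 13)
  expect_equal(stateSpaceSize(g2), 139968)  # 3^7 * 2^6
  expect_equal(sum(maxLevels(g2) == 2), 7)

  # under ClpXP = 0 and ChpT = 2 the transcriptional half reproduces the
  # Boolean subnetwork with CtrA level 2 playing the role of CtrA_a = 1
  g2a <- buildG2a()
  clamped <- applyPerturbation(
    applyPerturbation(g2, "ClpXP_RcdA", "knockout"),
    "ChpT", "overexpression")
  aNodes <- c("CtrA_a", "GcrA", "DnaA", "CcrM", "SciP")
  cNodes <- c("CtrA", "GcrA", "DnaA", "CcrM", "SciP")
  for (i in 0:31) {
    sa <- decodeState(g2a, i)
    sc <- stats::setNames(rep(0L, 13), nodes(g2))
    sc["CtrA"] <- if (sa[["CtrA_a"]] == 1) 2L else 0L
    sc[cNodes[-1]] <- sa[aNodes[-1]]
    sc["ChpT"] <- 2L                     # consistent with its clamp
    nxtA <- successorState(g2a, sa)
    nxtC <- successorState(clamped, sc)
    expect_equal(unname(nxtC["CtrA"] == 2), unname(nxtA["CtrA_a"] == 1))
    expect_equal(unname(nxtC[cNodes[-1]]), unname(nxtA[aNodes[-1]]))
  }
})
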