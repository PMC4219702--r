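test_that("mixed-radix state encoding is a bijection onto the full space", {
  net <- logicalNetwork(
    c(a = 1, b = 2),
    list(updateRule("a", character()), updateRule("b", character())))
  expect_equal(stateSpaceSize(net), 6)
  expect_equal(encodeState(net, c(a = 0, b = 0)), 0)
  idx <- vapply(0:5, function(i) encodeState(net, decodeState(net, i)), 1)
  expect_equal(idx, 0:5)

  g2a <- buildG2a()
  expect_equal(stateSpaceSize(g2a), 32)
  rt <- vapply(0:31, function(i) encodeState(g2a, decodeState(g2a, i)), 1)
  expect_equal(rt, as.numeric(0:31))
  # encoded order is lexicographic: first node most significant
  expect_equal(decodeState(g2a, 16),
               c(CtrA_a = 1L, GcrA = 0L, DnaA = 0L, CcrM = 0L, SciP = 0L))

  expect_error(decodeState(g2a, 32), "out of range")
  expect_error(decodeState(g2a, -1), "out of range")
  expect_error(encodeState(g2a, c(CtrA_a = 2, GcrA = 0, DnaA = 0,
                                  CcrM = 0, SciP = 0)), "range")
})

test_that("rule evaluation follows first-match-wins with explicit default", {
  dnaA <- rules(buildG2a())$DnaA
  # transcription needs CtrA on a methylated promoter, no GcrA, no DnaA
  expect_equal(evaluateRule(dnaA, c(CtrA_a = 1, CcrM = 1, GcrA = 0, DnaA = 0)), 1L)
  # self-repression: DnaA present blocks its own transcription
  expect_equal(evaluateRule(dnaA, c(CtrA_a = 1, CcrM = 1, GcrA = 0, DnaA = 1)), 0L)
  expect_equal(evaluateRule(dnaA, c(CtrA_a = 0, CcrM = 1, GcrA = 0, DnaA = 0)), 0L)
  expect_error(evaluateRule(dnaA, c(CtrA_a = 1)), "undeclared node")

  # ordered cases: an earlier case shadows a later one
  r <- updateRule("x", c("y==2 -> 1", "y>=1 -> 2"), default = 0)
  expect_equal(evaluateRule(r, c(y = 2)), 1L)
  expect_equal(evaluateRule(r, c(y = 1)), 2L)
  expect_equal(evaluateRule(r, c(y = 0)), 0L)

  # clamping is applied by the successor map, not by rule evaluation
  net <- buildG2b()
  ko <- applyPerturbation(net, "DivL", "knockout")
  st <- g2bFixedPoint("swarmer")
  expect_equal(evaluateRule(rules(ko)$DivL, st), 1L)   # rule still says 1
  expect_equal(successorState(ko, st)[["DivL"]], 0L)   # clamp wins
})

test_that("the synchronous successor reproduces the cell-cycle progression", {
  g2a <- buildG2a()
  b <- c(CtrA_a = 0L, GcrA = 1L, DnaA = 0L, CcrM = 0L, SciP = 0L)
  cc <- c(CtrA_a = 1L, GcrA = 0L, DnaA = 0L, CcrM = 0L, SciP = 0L)
  d <- c(CtrA_a = 1L, GcrA = 0L, DnaA = 0L, CcrM = 1L, SciP = 1L)
  a <- c(CtrA_a = 0L, GcrA = 0L, DnaA = 1L, CcrM = 0L, SciP = 1L)
  expect_equal(successorState(g2a, b), cc)   # GcrA-only -> CtrA-only
  expect_equal(successorState(g2a, d), a)    # division state -> DnaA+SciP
  # repeated calls agree (pure function)
  expect_identical(successorState(g2a, b), successorState(g2a, b))

  # with every node clamped the successor is the clamp vector
  allClamped <- logicalNetwork(
    c(x = 1, y = 2),
    list(updateRule("x", "y>=1 -> 1"), updateRule("y", "x>=1 -> 2")),
    clamps = c(x = 1, y = 0))
  expect_equal(successorState(allClamped, c(x = 0, y = 2)),
               c(x = 1L, y = 0L))
})

test_that("trajectories terminate at the first revisited state", {
  g2a <- buildG2a()
  zero <- stats::setNames(rep(0L, 5), nodes(g2a))
  tr <- trajectory(g2a, zero)
  expect_lte(nrow(tr), 5 + 2)   # enters the 4-cycle within a few steps
  # last row revisits an earlier row
  keys <- apply(tr, 1, paste, collapse = "")
  expect_true(keys[length(keys)] %in% keys[-length(keys)])

  # from a fixed point: (state, itself)
  i <- g2bFixedPoint("swarmer")
  tr2 <- trajectory(buildG2b(), i)
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2[1, ], tr2[2, ])

  expect_error(trajectory(g2a, zero, maxSteps = 0), "maxSteps")
})

test_that("attractor enumeration recovers the known small-network landscapes", {
  fx <- builtinFixtures()

  ring <- enumerateAttractors(fx$negationRing3)
  expect_equal(vapply(attractors(ring), function(a) nrow(attractorStates(a)), 1L),
               c(2L, 6L))
  expect_equal(sort(basinSizes(ring)), c(2, 6))
  # the 2-cycle is {000, 111}
  expect_equal(attractorStates(attractors(ring)[[1]]),
               matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 2, byrow = TRUE,
                      dimnames = list(NULL, c("x1", "x2", "x3"))))

  tog <- enumerateAttractors(fx$toggle2)
  kinds <- vapply(attractors(tog), attractorKind, "")
  expect_equal(sort(kinds), c("fixed_point", "fixed_point", "limit_cycle"))
  fps <- lapply(Filter(function(a) attractorKind(a) == "fixed_point",
                       attractors(tog)), attractorStates)
  expect_setequal(lapply(fps, function(m) paste(m, collapse = "")),
                  list("01", "10"))

  cst <- enumerateAttractors(fx$constant3)
  expect_equal(length(attractors(cst)), 1L)
  expect_equal(basinSizes(cst), 8)
  expect_equal(drop(attractorStates(attractors(cst)[[1]])),
               c(x1 = 1L, x2 = 0L, x3 = 1L))

  idr <- enumerateAttractors(fx$identity5)
  expect_equal(length(attractors(idr)), 32L)
  expect_true(all(basinSizes(idr) == 1))

  # determinism
  expect_same_report(enumerateAttractors(fx$negationRing3),
                     enumerateAttractors(fx$negationRing3))
})

test_that("reported cycles are genuine minimal cycles partitioning the space", {
  nets <- c(builtinFixtures()[c("negationRing3", "toggle2", "g2a", "g2b")],
            randomTestEnsemble(10, seedBase = 5000L))
  for (net in nets) {
    rep <- enumerateAttractors(net)
    expect_equal(sum(basinSizes(rep)), stateSpaceSize(rep))
    for (a in attractors(rep)) {
      st <- attractorStates(a)
      L <- nrow(st)
      s <- st[1, ]
      for (t in seq_len(L)) {
        s <- successorState(net, s)
        if (t < L) expect_false(all(s == st[1, ]))  # never return early
        else expect_equal(unname(s), unname(st[1, ]))
      }
      # canonical rotation: first state has the smallest index
      idx <- apply(st, 1, function(row) encodeState(net, row))
      expect_equal(which.min(idx), 1L)
    }
    # attractors ordered by their first state's index
    firsts <- vapply(attractors(rep), function(a)
      encodeState(net, attractorStates(a)[1, ]), 1)
    expect_equal(firsts, sort(firsts))
  }
})

test_that("clamped nodes hold their clamp level in every attractor state", {
  g2b <- buildG2b()
  for (spec in list(c("DivK", "knockout"), c("PleC", "knockout"),
                    c("CckA", "overexpression"))) {
    net <- applyPerturbation(g2b, spec[1], spec[2])
    rep <- enumerateAttractors(net)
    lev <- clamps(net)[[spec[1]]]
    for (a in attractors(rep))
      expect_true(all(attractorStates(a)[, spec[1]] == lev))
  }
})

test_that("the transition graph is the out-degree-1 functional graph", {
  g2a <- buildG2a()
  tg <- transitionGraph(g2a)
  expect_length(tg@successors, 32)                 # one edge per state
  expect_true(all(tg@successors >= 0 & tg@successors < 32))
  # consistent with the successor map on a sample of states
  for (i in c(0, 7, 19, 31)) {
    s <- decodeState(g2a, i)
    expect_equal(tg@successors[i + 1],
                 encodeState(g2a, successorState(g2a, s)))
  }

  tgb <- transitionGraph(buildG2b())
  expect_length(tgb@successors, 8748)
  # self-loop states are exactly the fixed points
  expect_equal(sum(tgb@successors == seq_along(tgb@successors) - 1), 2L)

  expect_error(enumerateAttractors(buildG2Combined(), sizeCap = 1000),
               "size cap")
  expect_error(transitionGraph(buildG2Combined(), sizeCap = 1000),
               "size cap")
})
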