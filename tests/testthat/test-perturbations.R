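test_that("perturbations clamp without mutating the original network", {
  g2b <- buildG2b()
  ko <- applyPerturbation(g2b, "DivK", "knockout")
  expect_equal(clamps(ko), c(DivK = 0L))
  oe <- applyPerturbation(g2b, "DivK", "overexpression")
  expect_equal(clamps(oe), c(DivK = 2L))
  expect_length(clamps(g2b), 0)          # original untouched
  expect_error(applyPerturbation(g2b, "NoSuchGene", "knockout"),
               "unknown node")
  expect_error(applyPerturbation(ko, "DivK", "overexpression"),
               "already clamped")
})

test_that("transcriptional-network mutants match the known phenotypes", {
  g2a <- buildG2a()
  # ccrM deletion is lethal: DnaA is never expressed
  dccrM <- enumerateAttractors(applyPerturbation(g2a, "CcrM", "knockout"))
  for (a in attractors(dccrM))
    expect_true(all(attractorStates(a)[, "DnaA"] == 0))
  # constitutive CtrA: every attractor state keeps CtrA on
  octrA <- enumerateAttractors(
    applyPerturbation(g2a, "CtrA_a", "overexpression"))
  for (a in attractors(octrA))
    expect_true(all(attractorStates(a)[, "CtrA_a"] == 1))
})

test_that("cell-fate-network deletions reproduce the mutant table", {
  g2b <- buildG2b()
  ko <- knockoutScan(g2b)
  expect_equal(ko@mode, "knockout")
  expect_length(ko@reports, 9)

  # baseline equals a plain enumeration of the raw network
  expect_same_report(ko@baseline, enumerateAttractors(g2b))

  # DivK deletion: a single fixed point, no proteolysis, CtrA~P present
  dk <- ko@reports$DivK
  expect_length(attractors(dk), 1)
  expect_equal(attractorKind(attractors(dk)[[1]]), "fixed_point")
  fp <- drop(attractorStates(attractors(dk)[[1]]))
  expect_equal(fp[["ClpXP_RcdA"]], 0L)
  expect_equal(fp[["CtrA_b"]], 2L)

  # DivJ deletion: single attractor equal to the swarmer state elsewhere
  dj <- ko@reports$DivJ
  expect_length(attractors(dj), 1)
  fpj <- drop(attractorStates(attractors(dj)[[1]]))
  i <- g2bFixedPoint("swarmer")
  keep <- setdiff(names(i), "DivJ")
  expect_equal(fpj[keep], i[keep])

  # PleC deletion: both pole fixed points persist (bistability preserved);
  # losing the phosphatase additionally frees a DivK/DivJ flip-flop cycle
  dp <- ko@reports$PleC
  fps <- Filter(function(a) attractorKind(a) == "fixed_point",
                attractors(dp))
  expect_length(fps, 2)
  fpStates <- lapply(fps, function(a) drop(attractorStates(a)))
  j <- g2bFixedPoint("stalked")
  keep <- setdiff(names(i), "PleC")
  expect_true(any(vapply(fpStates, function(s) all(s[keep] == i[keep]), TRUE)))
  expect_true(any(vapply(fpStates, function(s) all(s[keep] == j[keep]), TRUE)))

  # protease-complex deletion: CtrA is never absent in any attractor
  for (a in attractors(ko@reports$ClpXP_RcdA))
    expect_true(all(attractorStates(a)[, "CtrA_b"] != 0))
  # cpdR deletion: the proteolytic complex is never assembled
  for (a in attractors(ko@reports$CpdR))
    expect_true(all(attractorStates(a)[, "ClpXP_RcdA"] == 0))
  # divL / cckA / chpT deletions: CtrA is never phosphorylated
  for (nm in c("DivL", "CckA", "ChpT"))
    for (a in attractors(ko@reports[[nm]]))
      expect_true(all(attractorStates(a)[, "CtrA_b"] != 2))

  # every scan entry respects clamp dominance
  for (nm in names(ko@reports))
    for (a in attractors(ko@reports[[nm]]))
      expect_true(all(attractorStates(a)[, nm] == 0))
  expect_equal(nrow(ko@summary), 10)     # baseline + 9 knockouts
})

test_that("overexpression scans respect clamp dominance and determinism", {
  g2a <- buildG2a()
  oe <- overexpressionScan(g2a)
  for (nm in names(oe@reports))
    for (a in attractors(oe@reports[[nm]]))
      expect_true(all(attractorStates(a)[, nm] == maxLevels(g2a)[[nm]]))
  oe2 <- overexpressionScan(g2a)
  expect_equal(oe@summary, oe2@summary)
})

test_that("the PleC-to-DivJ replacement switches swarmer to stalked", {
  g2b <- buildG2b()
  i <- g2bFixedPoint("swarmer")
  j <- g2bFixedPoint("stalked")

  sw <- switchExperiment(g2b)            # default: start i, clamp PleC=0 DivJ=2
  expect_equal(sw$start, i)
  expect_equal(sw$final, j)
  expect_true(sw$switched)

  # applied at the stalked state the protocol is a no-op
  swj <- switchExperiment(g2b, start = j)
  expect_equal(swj$final, j)
  expect_false(swj$switched)
})

test_that("holding DivK phosphorylated switches; a one-step pulse does not", {
  g2b <- buildG2b()
  i <- g2bFixedPoint("swarmer")
  j <- g2bFixedPoint("stalked")

  # a transient one-step DivK~P pulse relaxes back to the swarmer state:
  # with PleC still active the phosphatase re-establishes the pole
  pulse <- switchExperiment(g2b, clampLevels = c(DivK = 2L), start = i,
                            holdSteps = 1)
  expect_equal(pulse$final, i)
  # holding DivK~P until the clamped system rests drives the full cascade
  # into the stalked basin before release
  hold <- switchExperiment(g2b, clampLevels = c(DivK = 2L), start = i)
  expect_equal(hold$final, j)

  expect_error(switchExperiment(g2b, clampLevels = c(Flagellum = 1L)),
               "unknown clamp node")
})
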