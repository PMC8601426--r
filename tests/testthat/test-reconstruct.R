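test_that("configuration guards the phantomness limit on l0", {
  expect_error(reconstructionConfig(l0 = 0.3), "phantomness")
  expect_s3_class(reconstructionConfig(l0 = 0.3, allowShortL0 = TRUE),
                  "ReconstructionConfig")
  expect_equal(reconstructionConfig(l0 = 0.5)$satisfyRadius, 0.65)
  expect_equal(reconstructionConfig(solvent = "good")$params@aPS, 25)
})

test_that("restrained system: bond bookkeeping and initial overstretch", {
  cfg <- reconstructionConfig(seed = 2)

  empty <- ContactMap(matrix(integer(), 0, 2), 32)
  sys <- buildRestrainedSystem(empty, cfg = cfg)
  expect_equal(sum(sys$topo@bondType == 1L), 0)
  expect_equal(sum(sys$topo@bondType == 0L), 31)

  cm <- syntheticContactMap(512, 300 / 512, seed = 3)  # 300 contacts
  sys <- buildRestrainedSystem(cm, cfg = cfg)
  expect_equal(sum(sys$topo@bondType == 0L), 511)
  expect_equal(sum(sys$topo@bondType == 1L), 300)
  expect_equal(nBeads(sys$topo), round(512 / 0.1))
  # box sized for the total bead count at density 3
  expect_equal(sys$state@box, (5120 / 3)^(1 / 3))

  # most restraints start overstretched on a random-walk start
  rl <- DPDfold:::bond_lengths(sys$state@positions,
                               sys$topo@bonds[sys$topo@bondType == 1L, ,
                                              drop = FALSE])
  expect_gt(mean(rl > 2 * cfg$l0), 0.5)

  expect_error(buildRestrainedSystem(
    new("ContactMap", nBeads = 700L, pairs = rbind(c(5L, 600L)),
        multiplicity = integer(), metadata = list()),
    chains = IRanges::IRanges(1, 512), cfg = cfg), "cover")
})

test_that("a single-chain system with no restraints equilibrates trivially", {
  empty <- ContactMap(matrix(integer(), 0, 2), 2)
  cfg <- reconstructionConfig(seed = 5, stepBudget = 6000)
  sys <- buildRestrainedSystem(empty, cfg = cfg)
  res <- equilibrateReconstruction(sys, cfg)
  expect_s4_class(res, "ReconstructionResult")
  expect_length(res@backboneLengths, 1)
  expect_length(res@restraintLengths, 0)
  expect_true(is.na(res@restraintSatisfaction))
})

test_that("reconstruction relaxes restraints to backbone-like lengths", {
  # dense gold-standard map: after equilibration the backbone and restraint
  # bond-length distributions should coincide
  rec <- recon_globule_512()
  r <- rec$result
  expect_true(r@converged)
  mb <- median(r@backboneLengths)
  mr <- median(r@restraintLengths)
  expect_equal(mr / mb, 1, tolerance = 0.05)
  expect_equal(mb, 0.65, tolerance = 0.05)
  expect_gt(r@restraintSatisfaction, 0.3)
  # provenance carries the run facts
  expect_true(r@provenance$stepsRun > 0)
})

test_that("dense maps reproduce the gold standard within the ceiling", {
  rec <- recon_globule_512()
  acc <- conformationAccuracy(rec$result@conformation, rec$gold)
  expect_gt(acc, 60)
  expect_lt(acc, 96)

  # self-consistency: most input contacts are present in the reconstruction
  cmr <- contactsFromConformation(rec$result@conformation, rContact = 0.8)
  k1 <- paste(rec$map@pairs[, 1], rec$map@pairs[, 2])
  k2 <- paste(cmr@pairs[, 1], cmr@pairs[, 2])
  expect_gte(mean(k1 %in% k2), 0.8)
})

test_that("replicate reconstructions agree more than random conformations", {
  gold <- mooreCurve(2, latticeConstant = 0.65)
  cm <- contactsFromConformation(gold, rContact = 0.68)
  cfg <- reconstructionConfig(seed = 40, stepBudget = 20000)
  out <- reconstruct(cm, cfg = cfg, nReplicates = 2)
  expect_length(out$results, 2)
  pairAcc <- out$summary$meanPairwiseAccuracy
  rand <- Conformation(DPDfold:::random_walk_coords(64, 10, 0.65,
                                                    wrap = FALSE))
  randAcc <- conformationAccuracy(out$results[[1]]@conformation, rand)
  expect_gt(pairAcc, randAcc)
  expect_gt(pairAcc, 40)

  # an information-free map reconstructs an unrelated conformation
  none <- ContactMap(matrix(integer(), 0, 2), 64)
  free <- reconstruct(none, cfg = cfg, nReplicates = 1)
  freeAcc <- conformationAccuracy(free$results[[1]]@conformation, gold)
  goldAcc <- conformationAccuracy(out$results[[1]]@conformation, gold)
  expect_gt(goldAcc, freeAcc + 20)
})
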