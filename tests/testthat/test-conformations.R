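test_that("random walk geometry: step length, box-volume rule, determinism", {
  rw <- randomWalk(2, concentration = 0.1, stepLen = 0.7, seed = 1)
  d <- coords(rw)[1, ] - coords(rw)[2, ]
  d <- d - boxEdge(rw) * round(d / boxEdge(rw))  # walks are box-wrapped
  expect_equal(sqrt(sum(d^2)), 0.7, tolerance = 1e-12)

  rw <- randomWalk(4096, concentration = 0.1, seed = 2)
  expect_equal(boxEdge(rw), (40960 / 3)^(1 / 3), tolerance = 1e-12)
  expect_equal(boxEdge(rw), 23.9, tolerance = 0.01)

  expect_identical(coords(randomWalk(64, 0.2, seed = 7)),
                   coords(randomWalk(64, 0.2, seed = 7)))
  expect_error(randomWalk(4, concentration = 1, stepLen = 5), "box edge")
})

test_that("Moore curve is a closed unit-step Hamiltonian path on the cube", {
  expect_equal(nBeads(mooreCurve(1)), 8)
  expect_equal(nBeads(mooreCurve(4)), 4096)

  for (o in 1:3) {
    co <- coords(mooreCurve(o))
    L <- 2^o
    # every lattice site visited exactly once (exhaustive enumeration)
    sites <- paste(co[, 1], co[, 2], co[, 3])
    all_sites <- do.call(paste, expand.grid(0:(L - 1), 0:(L - 1), 0:(L - 1)))
    expect_setequal(sites, all_sites)
    # unit steps, including the closing step
    steps <- sqrt(rowSums(diff(co)^2))
    expect_true(all(steps == 1))
    expect_equal(sqrt(sum((co[1, ] - co[nrow(co), ])^2)), 1)
  }

  # deterministic; reversal is another valid closed space-filling path
  expect_identical(coords(mooreCurve(3)), coords(mooreCurve(3)))
  rev <- coords(mooreCurve(3))[512:1, ]
  expect_true(all(sqrt(rowSums(diff(rev)^2)) == 1))

  # lattice constant rescales bond lengths
  co <- coords(mooreCurve(2, latticeConstant = 0.65))
  expect_equal(unique(round(sqrt(rowSums(diff(co)^2)), 12)), 0.65)

  expect_error(mooreCurve(8), "refused")
})

test_that("globule generator collapses the chain into one dense droplet", {
  g <- gold_globule_512()
  expect_true(attr(g, "converged"))
  co <- coords(g)
  # single cluster at linkage radius rC
  expect_gte(DPDfold:::largest_cluster_fraction(co, 1.0), 0.99)
  # chain connectivity preserved
  expect_lt(max(sqrt(rowSums(diff(co)^2))), 2)
  # compact: Rg of a space-filling droplet of 512 beads at reduced density
  expect_lt(radiusOfGyration(g), 3.5)

  g0 <- generateGlobule(64, nSteps = 0, seed = 1)
  expect_false(attr(g0, "converged"))
})

test_that("globule size scales as n^(1/3)", {
  g512 <- gold_globule_512()
  g64 <- gold_globule_64()
  ratio <- radiusOfGyration(g512) / radiusOfGyration(g64)
  expect_equal(ratio, 2, tolerance = 0.15)  # (512/64)^(1/3)
})

test_that("solution generator: bead accounting and coil expansion", {
  s <- generateSolution(64, concentration = 0.10, nSteps = 2000, seed = 3)
  expect_equal(nBeads(s), 64)
  # melt: no solvent at concentration 1 (system equals the chain)
  topoMelt <- dpdTopology(IRanges::IRanges(1, 8),
                          nSolvent = round(8 / 1.0) - 8)
  expect_equal(sum(topoMelt@species == 1L), 0)
  # good solvent coil is larger than the poor-solvent globule
  coil <- generateSolution(64, concentration = 0.10, nSteps = 6000,
                           seed = 21)
  expect_gt(radiusOfGyration(coil), radiusOfGyration(gold_globule_64()))
})

test_that("globule generation requires poor solvent", {
  expect_error(generateGlobule(32, params = DPDParams(aPS = 25)),
               "poor solvent")
})
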