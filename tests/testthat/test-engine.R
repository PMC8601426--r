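test_that("non-bonded force law: cutoff semantics and contact amplitude", {
  par <- DPDParams()
  mk <- function(r) {
    topo <- dpdTopology(IRanges::IRanges(1, 1), nSolvent = 1)
    st <- simState(rbind(c(2, 2, 2), c(2 + r, 2, 2)), box = 10)
    list(st = st, topo = topo)
  }
  # at exactly the cutoff all three components vanish
  s <- mk(1.0)
  f <- dpdForces(s$st, s$topo, par, step = 1, seed = 9, method = "brute")
  expect_equal(max(abs(f)), 0)
  # conservative amplitude tends to a_ij at contact (linear soft law)
  s <- mk(1e-6)
  topoPP <- dpdTopology(IRanges::IRanges(c(1, 2), c(1, 2)))  # both polymer
  f <- dpdForces(s$st, topoPP, par, components = "conservative")
  expect_equal(sqrt(sum(f[1, ]^2)), par@aPP, tolerance = 1e-5)
  # polymer-solvent pair feels aPS
  s <- mk(0.5)
  f <- dpdForces(s$st, s$topo, par, components = "conservative")
  expect_equal(sqrt(sum(f[1, ]^2)), par@aPS * 0.5, tolerance = 1e-10)
})

test_that("cell-list forces equal brute force and obey Newton's third law", {
  for (n in c(10, 100)) {
    sb <- solvent_box(n)
    f1 <- dpdForces(sb$state, sb$topo, DPDParams(), step = 3, seed = 42,
                    method = "cell")
    f2 <- dpdForces(sb$state, sb$topo, DPDParams(), step = 3, seed = 42,
                    method = "brute")
    expect_equal(f1, f2, tolerance = 1e-12)
    expect_lt(max(abs(colSums(f1))), 1e-10 * n)
  }
})

test_that("bond forces: rest length, linear spring, term-by-term oracle", {
  par <- DPDParams()  # k = 40, l0 = 0.5
  topo <- dpdTopology(IRanges::IRanges(1, 2))
  atRest <- simState(rbind(c(1, 1, 1), c(1.5, 1, 1)), box = 10)
  f <- dpdForces(atRest, topo, par, components = "bond")
  expect_equal(max(abs(f)), 0)
  stretched <- simState(rbind(c(1, 1, 1), c(1 + par@bondL0 + 1, 1, 1)),
                        box = 10)
  f <- dpdForces(stretched, topo, par, components = "bond")
  expect_equal(f[1, 1], 40)           # pulled toward the partner
  expect_equal(f[2, 1], -40)
  # 3-bond chain: force on each bead equals the sum of per-bond closed forms
  co <- rbind(c(0, 0, 0), c(0.7, 0, 0), c(0.7, 0.4, 0), c(1.0, 0.4, 0.6))
  topo4 <- dpdTopology(IRanges::IRanges(1, 4))
  f <- dpdForces(simState(co, box = 20), topo4, par, components = "bond")
  oracle <- matrix(0, 4, 3)
  for (b in 1:3) {
    d <- co[b, ] - co[b + 1, ]
    r <- sqrt(sum(d^2))
    fb <- -par@bondK * (r - par@bondL0) * d / r
    oracle[b, ] <- oracle[b, ] + fb
    oracle[b + 1, ] <- oracle[b + 1, ] - fb
  }
  expect_equal(f, oracle, tolerance = 1e-12)
})

test_that("topology construction rejects invalid bonds", {
  expect_error(dpdTopology(IRanges::IRanges(1, 4),
                           restraints = rbind(c(2L, 2L))),
               "identical")
  # restraints duplicating backbone are dropped, not duplicated
  topo <- dpdTopology(IRanges::IRanges(1, 4),
                      restraints = rbind(c(1L, 2L), c(1L, 3L)))
  expect_equal(sum(topo@bondType == 1L), 1L)
  expect_error(dpdTopology(IRanges::IRanges(1, 4),
                           restraints = rbind(c(1L, 9L))), "beyond")
})

test_that("integration: identity at zero steps, determinism, momentum", {
  sb <- solvent_box(60, seed = 4)
  out0 <- dpdRun(sb$state, sb$topo, DPDParams(), nSteps = 0, seed = 1)
  expect_identical(out0$state@positions, sb$state@positions)
  r1 <- dpdRun(sb$state, sb$topo, DPDParams(), nSteps = 200, seed = 5)
  r2 <- dpdRun(sb$state, sb$topo, DPDParams(), nSteps = 200, seed = 5)
  expect_identical(r1$state@positions, r2$state@positions)
  expect_identical(r1$state@velocities, r2$state@velocities)
  r3 <- dpdRun(sb$state, sb$topo, DPDParams(), nSteps = 200, seed = 6)
  expect_false(identical(r1$state@positions, r3$state@positions))
  # pairwise forces conserve momentum; initial momentum is zero
  expect_lt(max(abs(colSums(r1$state@velocities))), 1e-8)
})

test_that("a runaway bead aborts with an unstable-integration signal", {
  box <- boxEdgeForDensity(30)
  topo <- dpdTopology(IRanges::IRanges(1, 2), nSolvent = 28)
  vel <- matrix(0, 30, 3); vel[1, 1] <- 100 * box
  st <- simState(with_seed_matrix(30, box, 1), vel, box)
  expect_error(dpdRun(st, topo, DPDParams(), nSteps = 5, seed = 1),
               "unstable integration")
})

test_that("measureTemperature is the mean kinetic energy per DOF", {
  st <- simState(matrix(0, 50, 3), matrix(0, 50, 3), box = 10)
  expect_equal(measureTemperature(st), 0)
  v <- maxwellVelocities(20000, kT = 1, seed = 8)
  expect_equal(measureTemperature(v), 1, tolerance = 0.03)
  expect_equal(measureTemperature(2 * v), 4 * measureTemperature(v))
})

test_that("short thermostatted run relaxes to the target temperature", {
  n <- 375
  box <- boxEdgeForDensity(n)
  topo <- dpdTopology(IRanges::IRanges(1, 2), nSolvent = n - 2)
  st <- simState(with_seed_matrix(n, box, 3),
                 maxwellVelocities(n, kT = 0.5, seed = 4), box)  # cold start
  out <- dpdRun(st, topo, DPDParams(), nSteps = 3000, seed = 7,
                monitorEvery = 100)
  late <- out$monitor$temperature[out$monitor$step > 1500]
  expect_equal(mean(late), 1, tolerance = 0.05)
})

test_that("Flory-Huggins mapping from repulsion amplitudes", {
  expect_equal(chiFromRepulsion(55, 25, 3), 8.58)
  expect_equal(chiFromRepulsion(25, 25, 3), 0)
  expect_equal(chiFromRepulsion(35, 25, 3), 2.86)
  expect_error(chiFromRepulsion(55, 25, rho = 2), "rho = 3")
  expect_warning(chiFromRepulsion(20, 25, 3), "good-solvent")
})

test_that("chains are phantom at l0 = 0.5 but not at l0 = 0.2", {
  # Hopf-linked rings of equal radius pushed apart by soft repulsion:
  # crossing is possible only when consecutive beads leave a passable gap
  expect_equal(abs(linked_rings_run(0.5, seed = 5)), 0)
  expect_equal(abs(linked_rings_run(0.2, seed = 5)), 1)
})

test_that("DPD parameter validity and config round trip", {
  expect_error(DPDParams(rC = -1), "rC")
  expect_error(DPDParams(bondL0 = 3), "bondL0")
  expect_error(DPDParams(dt = 0), "dt")
  cfgFile <- tempfile()
  writeLines(c("aPS = 25", "bondL0 = 0.8", "# comment", "n_steps = 100",
               "seed = 3"), cfgFile)
  p <- readDPDConfig(cfgFile)
  expect_equal(p@aPS, 25)
  expect_equal(p@bondL0, 0.8)
  expect_equal(attr(p, "extra")$n_steps, "100")
})
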