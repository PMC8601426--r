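#' Build a bead-spring system topology
#'
#' Assembles the species labels and bond list for a DPD system: backbone
#' bonds between consecutive beads of each polymer chain, optional restraint
#' bonds (contact-derived), and trailing solvent beads.
#'
#' @param chains [IRanges::IRanges] (or 2-column matrix of start/end) of
#'   polymer chain bead ranges; must tile `1..nPolymer` without gaps.
#' @param nSolvent number of solvent beads appended after the polymer beads.
#' @param restraints optional integer matrix (m x 2) of restraint bond
#'   partners (1-based polymer bead indices). Restraints duplicating a
#'   backbone bond are dropped; self-bonds are an error.
#' @return a [Topology].
#' @examples
#' topo <- dpdTopology(IRanges::IRanges(1, 10), nSolvent = 90,
#'                     restraints = rbind(c(1, 10)))
#' topo
#' @export
dpdTopology <- function(chains, nSolvent = 0L, restraints = NULL) {
  if (is.matrix(chains)) chains <- IRanges::IRanges(chains[, 1], chains[, 2])
  nPoly <- sum(IRanges::width(chains))
  idx <- unlist(lapply(seq_along(chains), function(i)
    seq(IRanges::start(chains)[i], IRanges::end(chains)[i])))
  if (!setequal(idx, seq_len(nPoly)) || anyDuplicated(idx))
    stop("chains must tile bead indices 1..nPolymer")
  n <- nPoly + as.integer(nSolvent)
  backbone <- do.call(rbind, lapply(seq_along(chains), function(i) {
    s <- IRanges::start(chains)[i]; e <- IRanges::end(chains)[i]
    if (e > s) cbind(s:(e - 1L), (s + 1L):e) else NULL
  }))
  if (is.null(backbone)) backbone <- matrix(integer(), 0, 2)
  if (!is.null(restraints) && nrow(restraints) > 0) {
    restraints <- cbind(pmin(restraints[, 1], restraints[, 2]),
                        pmax(restraints[, 1], restraints[, 2]))
    if (any(restraints[, 1] == restraints[, 2]))
      stop("restraint bond between identical bead indices")
    if (any(restraints > nPoly))
      stop("restraint references a bead beyond the polymer")
    bbKey <- paste(backbone[, 1], backbone[, 2])
    keep <- !(paste(restraints[, 1], restraints[, 2]) %in% bbKey)
    restraints <- restraints[keep, , drop = FALSE]
    restraints <- restraints[!duplicated(paste(restraints[, 1],
                                               restraints[, 2])), ,
                             drop = FALSE]
  } else restraints <- matrix(integer(), 0, 2)
  bonds <- rbind(backbone, restraints)
  storage.mode(bonds) <- "integer"
  new("Topology", nBeads = as.integer(n), bonds = bonds,
      bondType = c(rep(0L, nrow(backbone)), rep(1L, nrow(restraints))),
      species = c(rep(0L, nPoly), rep(1L, as.integer(nSolvent))),
      chains = chains)
}

#' Create a simulation state
#'
#' Positions are true-space coordinates: the engine wraps copies into the
#' periodic box for non-bonded interactions, while bonds always act on the
#' true displacements (the image-flag convention of standard MD codes).
#'
#' @param positions n x 3 coordinate matrix.
#' @param velocities n x 3 velocity matrix; defaults to zero.
#' @param box cubic box edge length.
#' @return a [SimState].
#' @export
simState <- function(positions, velocities = NULL, box) {
  positions <- as.matrix(positions)
  if (is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3)
  new("SimState", positions = positions, velocities = as.matrix(velocities),
      box = as.numeric(box))
}

#' Maxwell-Boltzmann velocities with zero total momentum
#'
#' @param n bead count.
#' @param kT temperature (bead mass 1).
#' @param seed optional integer seed.
#' @return n x 3 matrix.
#' @export
maxwellVelocities <- function(n, kT = 1, seed = NULL) {
  with_local_seed(seed, {
    v <- matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3)
    sweep(v, 2, colMeans(v))  # remove centre-of-mass drift
  })
}

#' Box edge from bead count and density
#'
#' `edge = (nTotal / rho)^(1/3)` for a cubic box at reduced density `rho`.
#'
#' @param nTotal total bead count.
#' @param rho bead number density.
#' @return the box edge length.
#' @export
boxEdgeForDensity <- function(nTotal, rho = 3) (nTotal / rho)^(1 / 3)

#' Evaluate DPD forces on a configuration
#'
#' Computes per-bead force vectors for any subset of the force components:
#' soft conservative repulsion `a_ij (1 - r/rC)` below the cutoff, the
#' dissipative friction force `-gamma (1 - r/rC)^2 (e . v_rel) e`, the
#' random force `sigma (1 - r/rC) theta e / sqrt(dt)` with
#' `sigma = sqrt(2 gamma kT)`, and harmonic bond forces `-k (r - l0) e`.
#' Forces are pairwise antisymmetric, so the total force is zero up to
#' round-off. Per-pair random variates are a pure hash of
#' `(seed, step, i, j)`: the cell-list and brute-force paths agree bitwise.
#'
#' @param state a [SimState].
#' @param topo a [Topology].
#' @param params a [DPDParams].
#' @param components character subset of
#'   `c("conservative", "dissipative", "random", "bond")`.
#' @param step,seed integers keying the random-force stream.
#' @param method `"cell"` (linked cells) or `"brute"` (all pairs); both give
#'   identical results.
#' @return n x 3 matrix of forces.
#' @export
dpdForces <- function(state, topo, params = DPDParams(),
                      components = c("conservative", "dissipative",
                                     "random", "bond"),
                      step = 0L, seed = 0L, method = c("cell", "brute")) {
  method <- match.arg(method)
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(nBeads(state) == nBeads(topo))
  cpp_dpd_forces(state@positions, state@velocities, state@box,
                 topo@species, topo@bonds - 1L, params_as_list(params),
                 as.integer(step), as.numeric(seed),
                 "conservative" %in% components,
                 "dissipative" %in% components,
                 "random" %in% components,
                 "bond" %in% components,
                 method == "brute")
}

#' Run DPD time integration
#'
#' Advances the system with the modified velocity-Verlet scheme (velocity
#' prediction factor `lambdaVV`) under cubic periodic boundaries. The run is
#' fully deterministic given the inputs and `seed`. Optionally monitors
#' kinetic temperature, per-chain radius of gyration and median
#' backbone/restraint bond lengths, and stops early once the chosen
#' statistic is stationary: over the trailing 20\% of checkpoints, the
#' median of its second half differs from the median of its first half by
#' less than `tol` (relative).
#'
#' @param state a [SimState].
#' @param topo a [Topology].
#' @param params a [DPDParams].
#' @param nSteps maximum number of steps (>= 0).
#' @param seed integer seed for the pairwise random forces.
#' @param monitorEvery checkpoint interval in steps (0 = only the final
#'   state, no convergence checks).
#' @param convergeOn `"none"`, `"rg"` or `"restraint"` (falls back to the
#'   backbone median when there are no restraints).
#' @param tol relative stationarity tolerance (default 0.01).
#' @param minSteps earliest step at which convergence may be declared.
#' @return list with `state` ([SimState]), `stepsRun`, `converged`, and
#'   `monitor` (data.frame of checkpoint statistics).
#' @examples
#' topo <- dpdTopology(IRanges::IRanges(1, 5), nSolvent = 76)
#' box <- boxEdgeForDensity(81)
#' st <- simState(matrix(runif(81 * 3) * box, ncol = 3),
#'                maxwellVelocities(81, seed = 1), box)
#' out <- dpdRun(st, topo, DPDParams(), nSteps = 10, seed = 1)
#' @export
dpdRun <- function(state, topo, params = DPDParams(), nSteps, seed = 0L,
                   monitorEvery = 0L,
                   convergeOn = c("none", "rg", "restraint"),
                   tol = 0.01, minSteps = 0L) {
  convergeOn <- match.arg(convergeOn)
  stopifnot(nSteps >= 0, nBeads(state) == nBeads(topo))
  if (nSteps == 0)
    return(list(state = state, stepsRun = 0L, converged = FALSE,
                monitor = NULL))
  mode <- match(convergeOn, c("none", "rg", "restraint")) - 1L
  if (mode > 0 && monitorEvery <= 0) monitorEvery <- 1000L
  res <- cpp_dpd_run(state@positions, state@velocities, state@box,
                     topo@species, topo@bonds - 1L, topo@bondType,
                     params_as_list(params), as.integer(nSteps),
                     as.numeric(seed),
                     IRanges::start(topo@chains) - 1L,
                     IRanges::end(topo@chains) - 1L,
                     as.integer(monitorEvery), mode, tol,
                     as.integer(minSteps))
  list(state = new("SimState", positions = res$positions,
                   velocities = res$velocities, box = state@box),
       stepsRun = res$stepsRun, converged = res$converged,
       monitor = as.data.frame(res$monitor))
}

#' Instantaneous kinetic temperature
#'
#' Mean kinetic energy per degree of freedom, `sum(v^2) / (3 n)` with bead
#' mass 1 -- equals `kT` for a well-thermostatted system.
#'
#' @param state a [SimState] (or an n x 3 velocity matrix).
#' @return a scalar temperature in reduced units.
#' @export
measureTemperature <- function(state) {
  v <- if (is(state, "SimState")) state@velocities else as.matrix(state)
  if (nrow(v) < 2) stop("need at least 2 beads")
  sum(v^2) / (3 * nrow(v))
}
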