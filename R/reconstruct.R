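#' Reconstruction configuration
#'
#' @param l0 backbone/restraint bond rest length. The default 0.5 is the
#'   reference choice; 0.8 maximises accuracy on dense gold-standard
#'   globules. Values at or below 0.3 destroy chain phantomness (strands can
#'   no longer cross and the system gets kinetically trapped), so they are
#'   rejected unless `allowShortL0 = TRUE`.
#' @param concentration polymer volume fraction of the reconstruction box
#'   (default 0.1, a nucleus-like chromatin concentration).
#' @param solvent `"poor"` (globular; recommended at resolutions of ~10 kb
#'   and below, where effective chromatin concentration approaches 100\%) or
#'   `"good"` (coil-like targets).
#' @param stepBudget maximum integration steps; default scales linearly in
#'   chain length, `1e5 * nBeads / 512`.
#' @param tol convergence tolerance on the trailing-window relative range of
#'   the restraint-bond median length.
#' @param satisfyRadius distance below which a restraint counts as
#'   satisfied; default `1.3 * l0`, the typical equilibrium bond stretch
#'   under soft repulsion (0.65 at l0 = 0.5).
#' @param seed integer base seed.
#' @param params optional [DPDParams] overriding the force field (its
#'   `bondL0` is set to `l0`).
#' @param allowShortL0 override the phantomness guard.
#' @return a list of class `"ReconstructionConfig"`.
#' @export
reconstructionConfig <- function(l0 = 0.5, concentration = 0.1,
                                 solvent = c("poor", "good"),
                                 stepBudget = NULL, tol = 0.01,
                                 satisfyRadius = NULL, seed = 1L,
                                 params = NULL, allowShortL0 = FALSE) {
  solvent <- match.arg(solvent)
  if (l0 <= 0.3 && !allowShortL0)
    stop("l0 <= 0.3 loses chain phantomness; set allowShortL0 = TRUE to override")
  stopifnot(l0 > 0, concentration > 0, concentration <= 1)
  if (is.null(params))
    params <- DPDParams(aPS = if (solvent == "poor") 55 else 25)
  params@bondL0 <- l0
  structure(list(l0 = l0, concentration = concentration, solvent = solvent,
                 stepBudget = stepBudget, tol = tol,
                 satisfyRadius = if (is.null(satisfyRadius)) 1.3 * l0
                                 else satisfyRadius,
                 seed = as.integer(seed), params = params,
                 allowShortL0 = allowShortL0),
            class = "ReconstructionConfig")
}

#' Build the restrained random-walk system for a contact map
#'
#' Creates the reconstruction starting state: an independent random walk per
#' chain (wrapped in a box sized for the configured polymer concentration at
#' density `rho`), solvent beads filled in uniformly, and one restraint bond
#' per contact pair with the same stiffness and rest length as the backbone
#' bonds. Most restraints are heavily over-stretched at this point; that is
#' expected -- equilibration lets them regain their normal length because
#' the soft chain is phantom.
#'
#' @param cmap a [ContactMap].
#' @param chains [IRanges::IRanges] of chain bead ranges; default one chain
#'   over all beads.
#' @param cfg a [reconstructionConfig()].
#' @param seed integer seed for the walk and velocities (defaults to
#'   `cfg$seed`).
#' @return list with `state` ([SimState]), `topo` ([Topology]) and `params`.
#' @export
buildRestrainedSystem <- function(cmap, chains = NULL,
                                  cfg = reconstructionConfig(),
                                  seed = cfg$seed) {
  n <- cmap@nBeads
  if (is.null(chains)) chains <- IRanges::IRanges(1L, n)
  if (is.matrix(chains)) chains <- IRanges::IRanges(chains[, 1], chains[, 2])
  if (sum(IRanges::width(chains)) != n)
    stop("chains must cover exactly the ", n, " beads of the contact map")
  if (nrow(cmap@pairs) && max(cmap@pairs) > n) {
    bad <- cmap@pairs[which(cmap@pairs[, 2] > n)[1], ]
    stop("contact (", bad[1], ", ", bad[2], ") references an out-of-range bead")
  }
  params <- cfg$params
  nTotal <- as.integer(round(n / cfg$concentration))
  nSolvent <- nTotal - n
  box <- boxEdgeForDensity(nTotal, params@rho)
  coords <- with_local_seed(seed, {
    poly <- do.call(rbind, lapply(seq_along(chains), function(c)
      random_walk_coords(IRanges::width(chains)[c], box, cfg$l0,
                         wrap = FALSE)))
    solv <- if (nSolvent > 0)
      matrix(runif(3 * nSolvent) * box, nSolvent, 3) else NULL
    rbind(poly, solv)
  })
  vel <- maxwellVelocities(nTotal, params@kT,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  topo <- dpdTopology(chains, nSolvent = nSolvent, restraints = cmap@pairs)
  list(state = simState(coords, vel, box), topo = topo, params = params)
}

bond_lengths <- function(positions, bonds) {
  if (nrow(bonds) == 0) return(numeric())
  d <- positions[bonds[, 1], , drop = FALSE] -
       positions[bonds[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Equilibrate a restrained system into a reconstruction
#'
#' Runs DPD until the median restraint-bond length is stationary (drift
#' below `cfg$tol` across the trailing 20\% of checkpoints) or the step
#' budget is exhausted. Over-stretched restraints contract toward the normal
#' bond length as the phantom chain untangles. The returned conformation has
#' solvent stripped and chains unwrapped.
#'
#' @param system list from [buildRestrainedSystem()].
#' @param cfg the [reconstructionConfig()] used to build it.
#' @param seed integer seed for the thermostat stream (defaults to
#'   `cfg$seed`).
#' @return a [ReconstructionResult].
#' @export
equilibrateReconstruction <- function(system, cfg = reconstructionConfig(),
                                      seed = cfg$seed) {
  topo <- system$topo
  nPoly <- sum(topo@species == 0L)
  budget <- cfg$stepBudget
  if (is.null(budget)) budget <- as.integer(round(1e5 * nPoly / 512))
  run <- dpdRun(system$state, topo, system$params, nSteps = budget,
                seed = if (is.null(seed)) 0L else seed,
                monitorEvery = 1000L, convergeOn = "restraint",
                tol = cfg$tol, minSteps = min(budget, 5000L))
  pos <- run$state@positions
  box <- run$state@box
  bb <- bond_lengths(pos, topo@bonds[topo@bondType == 0L, , drop = FALSE])
  rs <- bond_lengths(pos, topo@bonds[topo@bondType == 1L, , drop = FALSE])
  polyCoords <- pos[seq_len(nPoly), , drop = FALSE]
  polyCoords <- sweep(polyCoords, 2, colMeans(polyCoords))
  conf <- Conformation(polyCoords, chains = topo@chains, box = box)
  new("ReconstructionResult",
      conformation = conf,
      restraintSatisfaction = if (length(rs))
        mean(rs <= cfg$satisfyRadius) else NA_real_,
      backboneLengths = bb, restraintLengths = rs,
      converged = run$converged,
      provenance = list(config = cfg[setdiff(names(cfg), "params")],
                        seed = seed, stepsRun = run$stepsRun,
                        monitor = run$monitor,
                        package = as.character(packageVersion("DPDfold"))))
}

#' Reconstruct conformations from a contact map
#'
#' The full pipeline: build the restrained random-walk system, equilibrate
#' it, repeat over `nReplicates` independent seeds (replicate `i` uses seed
#' `cfg$seed + i`). When more than one replicate is run, the summary
#' reports the mean/min/max pairwise accuracy among replicates -- a measure
#' of how tightly the contact map pins down the structure.
#'
#' @param cmap a [ContactMap].
#' @param chains optional chain ranges (default one chain).
#' @param cfg a [reconstructionConfig()].
#' @param nReplicates number of independent reconstructions.
#' @return list with `results` (list of [ReconstructionResult]) and
#'   `summary` (data.frame of pairwise replicate accuracies, or NULL).
#' @examples
#' \donttest{
#' gold <- mooreCurve(3, latticeConstant = 0.65)
#' cm <- contactsFromConformation(gold, rContact = 0.65)
#' rec <- reconstruct(cm, cfg = reconstructionConfig(seed = 7),
#'                    nReplicates = 1)
#' conformationAccuracy(rec$results[[1]]@conformation, gold)
#' }
#' @export
reconstruct <- function(cmap, chains = NULL, cfg = reconstructionConfig(),
                        nReplicates = 1L) {
  results <- lapply(seq_len(nReplicates), function(i) {
    sd <- cfg$seed + i
    sys <- buildRestrainedSystem(cmap, chains, cfg, seed = sd)
    equilibrateReconstruction(sys, cfg, seed = sd)
  })
  summary <- NULL
  if (nReplicates > 1) {
    acc <- c()
    for (i in seq_len(nReplicates - 1))
      for (j in (i + 1):nReplicates)
        acc <- c(acc, conformationAccuracy(results[[i]]@conformation,
                                           results[[j]]@conformation))
    summary <- data.frame(meanPairwiseAccuracy = mean(acc),
                          minPairwiseAccuracy = min(acc),
                          maxPairwiseAccuracy = max(acc))
  }
  list(results = results, summary = summary)
}
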