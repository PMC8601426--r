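#' Specification of an in-silico benchmark experiment
#'
#' Describes a gold-standard conformation, a swept variable and a grid, and
#' the reconstruction configuration. Every run derived from a spec is fully
#' reproducible from `baseSeed`: replicate `i` uses `baseSeed + i`.
#'
#' @param goldKind `"moore"`, `"globule"` or `"solution"`.
#' @param n gold-standard chain length (512 is the desk-scale default; full
#'   publication-grade curves use 4096).
#' @param sweep swept variable: `"rContact"` or `"fraction"`.
#' @param grid sorted, non-empty numeric grid of sweep values.
#' @param replicates independent runs per grid point (>= 1).
#' @param baseSeed integer base seed.
#' @param rContact contact radius used when `sweep = "fraction"` (default
#'   1.25x the equilibrium bond length of `cfg`, comfortably inside the
#'   first non-bonded coordination shell).
#' @param concentration polymer concentration of solution gold standards.
#' @param goldSteps optional step budget for simulated gold standards.
#' @param cfg a [reconstructionConfig()].
#' @return a list of class `"ExperimentSpec"`.
#' @export
experimentSpec <- function(goldKind = c("moore", "globule", "solution"),
                           n = 512, sweep = c("fraction", "rContact"),
                           grid, replicates = 1L, baseSeed = 1L,
                           rContact = NULL, concentration = 0.1,
                           goldSteps = NULL,
                           cfg = reconstructionConfig(seed = baseSeed)) {
  goldKind <- match.arg(goldKind)
  sweep <- match.arg(sweep)
  stopifnot(length(grid) >= 1, !is.unsorted(grid), replicates >= 1)
  if (is.null(rContact)) rContact <- 1.25 * cfg$satisfyRadius
  structure(list(goldKind = goldKind, n = n, sweep = sweep, grid = grid,
                 replicates = as.integer(replicates),
                 baseSeed = as.integer(baseSeed), rContact = rContact,
                 concentration = concentration, goldSteps = goldSteps,
                 cfg = cfg),
            class = "ExperimentSpec")
}

make_gold <- function(spec, seed) {
  switch(spec$goldKind,
    moore = {
      order <- round(log(spec$n) / log(8))
      if (8^order != spec$n)
        stop("Moore gold standard needs n = 8^order")
      mooreCurve(order, latticeConstant = spec$cfg$satisfyRadius)
    },
    globule = generateGlobule(spec$n, concentration = spec$concentration,
                              nSteps = spec$goldSteps, seed = seed),
    solution = generateSolution(spec$n, spec$concentration,
                                nSteps = spec$goldSteps, seed = seed))
}

# gold standards are deterministic (moore) or reusable across replicates
# (globule); solutions fluctuate, so each replicate gets its own run
run_sweep <- function(spec) {
  perReplicateGold <- spec$goldKind == "solution"
  goldShared <- if (!perReplicateGold) make_gold(spec, spec$baseSeed)
  rows <- list()
  for (rep in seq_len(spec$replicates)) {
    repSeed <- spec$baseSeed + rep
    gold <- if (perReplicateGold) make_gold(spec, repSeed) else goldShared
    fullMap <- if (spec$sweep == "fraction")
      contactsFromConformation(gold, spec$rContact)
    for (g in spec$grid) {
      cmap <- if (spec$sweep == "rContact")
        contactsFromConformation(gold, g)
      else
        sampleContacts(fullMap, g, seed = repSeed)
      x <- contactsPerBead(cmap)
      cfg <- spec$cfg
      cfg$seed <- repSeed
      res <- tryCatch(reconstruct(cmap, cfg = cfg, nReplicates = 1),
                      error = function(e)
                        stop("sweep value ", g, ": ", conditionMessage(e)))
      acc <- conformationAccuracy(res$results[[1]]@conformation, gold)
      rows[[length(rows) + 1]] <- data.frame(
        variable = spec$sweep, value = g, replicate = rep, x = x,
        accuracy = acc)
    }
  }
  do.call(rbind, rows)
}

#' Contact-radius sweep
#'
#' Derives contact maps from one gold standard at each radius of the grid,
#' reconstructs, and scores accuracy against the gold standard. Reducing the
#' radius keeps only the closest -- the most structure-defining -- contacts,
#' so accuracy degrades more slowly along this axis than under random
#' dropout at equal contacts per bead.
#'
#' @param spec an [experimentSpec()] with `sweep = "rContact"`.
#' @return an [AccuracyCurve] (per-replicate raw points retained; no fit --
#'   the exponential model describes dropout, not radius, sweeps).
#' @export
runRadiusSweep <- function(spec) {
  stopifnot(inherits(spec, "ExperimentSpec"), spec$sweep == "rContact")
  pts <- run_sweep(spec)
  new("AccuracyCurve", points = pts, fit = list())
}

#' Contact-dropout sweep
#'
#' Randomly subsamples the gold-standard contact map at each retained
#' fraction of the grid, reconstructs, scores accuracy, and fits the
#' exponential accuracy model to the pooled points (when they suffice).
#'
#' @param spec an [experimentSpec()] with `sweep = "fraction"`.
#' @return an [AccuracyCurve] with per-replicate points and, when the
#'   pooled points support it, the `(A, beta, aMax)` fit.
#' @export
runDropoutSweep <- function(spec) {
  stopifnot(inherits(spec, "ExperimentSpec"), spec$sweep == "fraction")
  pts <- run_sweep(spec)
  fit <- tryCatch(fitAccuracyCurve(pts), error = function(e) list())
  new("AccuracyCurve", points = pts, fit = fit)
}

#' Expected-accuracy table for a binned contact map
#'
#' Applies the exponential accuracy model to the observed contacts per bead,
#' per chromosome and overall -- the a-priori estimate of how well a 3D
#' reconstruction of each chromosome can possibly match reality given the
#' data sparsity.
#'
#' @param map a [ContactMap] from [binPairs()].
#' @param bins the matching [GenomicBinTable].
#' @param ... model constants passed to [expectedAccuracy()].
#' @return data.frame with one row per chromosome plus `"all"`.
#' @export
estimateAccuracyTable <- function(map, bins, ...) {
  ch <- chainRanges(bins)
  chainOf <- integer(map@nBeads)
  for (c in seq_along(ch))
    chainOf[IRanges::start(ch)[c]:IRanges::end(ch)[c]] <- c
  p <- map@pairs
  rows <- lapply(seq_along(ch), function(c) {
    inChain <- chainOf[p[, 1]] == c & chainOf[p[, 2]] == c
    nb <- IRanges::width(ch)[c]
    x <- sum(inChain) / nb
    data.frame(chrom = names(ch)[c], nBeads = nb, contacts = sum(inChain),
               contactsPerBead = x, expectedAccuracy = expectedAccuracy(x, ...))
  })
  xAll <- nrow(p) / map@nBeads
  rbind(do.call(rbind, rows),
        data.frame(chrom = "all", nBeads = map@nBeads, contacts = nrow(p),
                   contactsPerBead = xAll,
                   expectedAccuracy = expectedAccuracy(xAll, ...)))
}
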