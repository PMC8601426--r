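#' Construct a Conformation
#'
#' @param coords n x 3 numeric matrix of bead positions.
#' @param chains [IRanges::IRanges] (or 2-column start/end matrix) of chain
#'   bead ranges; defaults to a single chain over all beads.
#' @param box periodic box edge the conformation lives in (`NA` for
#'   analytical conformations).
#' @param bins optional per-bead [GenomicRanges::GRanges] annotation.
#' @return a [Conformation].
#' @export
Conformation <- function(coords, chains = NULL, box = NA_real_, bins = NULL) {
  coords <- as.matrix(coords)
  if (is.null(chains)) chains <- IRanges::IRanges(1L, nrow(coords))
  if (is.matrix(chains)) chains <- IRanges::IRanges(chains[, 1], chains[, 2])
  new("Conformation", coords = coords, chains = chains,
      box = as.numeric(box), bins = bins)
}

#' Radius of gyration
#'
#' Root-mean-square bead distance from the centre of mass.
#'
#' @param x a [Conformation] or an n x 3 coordinate matrix.
#' @return a scalar.
#' @export
radiusOfGyration <- function(x) {
  m <- if (is(x, "Conformation")) x@coords else as.matrix(x)
  sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
}

# unwrap periodic coordinates so each chain is spatially contiguous:
# walk the chain accumulating minimum-image displacements
unwrap_chains <- function(coords, chains, box) {
  out <- coords
  for (c in seq_along(chains)) {
    a <- IRanges::start(chains)[c]; b <- IRanges::end(chains)[c]
    if (b == a) next
    d <- coords[(a + 1):b, , drop = FALSE] -
         coords[a:(b - 1), , drop = FALSE]
    d <- d - box * round(d / box)
    cum <- apply(d, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    out[a:b, ] <- rbind(coords[a, , drop = FALSE],
                        sweep(cum, 2, coords[a, ], FUN = "+"))
  }
  out
}

random_walk_coords <- function(n, box, stepLen, wrap = TRUE) {
  steps <- matrix(rnorm(3 * (n - 1)), n - 1, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * stepLen
  pos <- rbind(runif(3) * box, steps)
  pos <- apply(pos, 2, cumsum)
  if (wrap) pos <- pos - box * floor(pos / box)
  pos
}

# random walk confined to a ball (rejection on the step direction): the
# compact start used for globule gold standards, so poor-solvent collapse
# proceeds locally into one droplet instead of percolating through the
# periodic box (a metastable interface-free column)
ball_walk_coords <- function(n, stepLen, radius, center) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- center
  for (i in 2:n) {
    repeat {
      d <- rnorm(3)
      cand <- pos[i - 1, ] + d / sqrt(sum(d^2)) * stepLen
      if (sum((cand - center)^2) <= radius^2) break
    }
    pos[i, ] <- cand
  }
  pos
}

#' Random-walk starting conformation
#'
#' A freely-jointed random walk of `nBeads` beads with fixed step length,
#' wrapped into a cubic periodic box whose edge follows from the target
#' polymer volume fraction: `edge = (nBeads / (concentration * rho))^(1/3)`.
#' This is the initial state of every reconstruction.
#'
#' @param nBeads number of beads.
#' @param concentration polymer fraction of total beads in the eventual
#'   system (0 < c <= 1); sets the box size.
#' @param stepLen bond step length.
#' @param seed integer seed (deterministic walk).
#' @param rho bead number density.
#' @return a [Conformation] (coordinates wrapped; consecutive beads are at
#'   minimum-image distance `stepLen`).
#' @examples
#' rw <- randomWalk(4096, concentration = 0.1, seed = 1)
#' boxEdge(rw)  # (40960 / 3)^(1/3) = 23.9
#' @export
randomWalk <- function(nBeads, concentration = 0.1, stepLen = 0.5,
                       seed = NULL, rho = 3) {
  stopifnot(nBeads >= 2, concentration > 0, concentration <= 1, stepLen > 0)
  box <- boxEdgeForDensity(nBeads / concentration, rho)
  if (box < stepLen)
    stop("concentration too high: box edge ", signif(box, 4),
         " is smaller than the step length")
  coords <- with_local_seed(seed, random_walk_coords(nBeads, box, stepLen))
  Conformation(coords, box = box)
}

## ---- 3D Hilbert / Moore space-filling curves --------------------------

# Skilling's transpose-to-axes algorithm, vectorised over all indices.
# Returns an M x 3 integer matrix of lattice coordinates in [0, 2^order).
hilbert3d <- function(order) {
  b <- as.integer(order)
  M <- 8^b
  d <- seq_len(M) - 1
  # transposed representation: axis i bit q = bit (3q + 2 - i) of d
  X <- matrix(0L, M, 3)
  for (q in 0:(b - 1))
    for (i in 0:2) {
      bit <- (d %/% 2^(3 * q + (2 - i))) %% 2
      X[, i + 1] <- X[, i + 1] + as.integer(bit) * 2L^q
    }
  N <- 2L^b
  # Gray decode
  t <- X[, 3] %/% 2L
  X[, 3] <- bitwXor(X[, 3], X[, 2])
  X[, 2] <- bitwXor(X[, 2], X[, 1])
  X[, 1] <- bitwXor(X[, 1], t)
  # undo excess work
  Q <- 2L
  while (Q != N) {
    P <- Q - 1L
    for (i in 3:1) {
      hi <- bitwAnd(X[, i], Q) != 0L
      t <- bitwAnd(bitwXor(X[, 1], X[, i]), P)
      X[hi, 1] <- bitwXor(X[hi, 1], P)
      X[!hi, 1] <- bitwXor(X[!hi, 1], t[!hi])
      X[!hi, i] <- bitwXor(X[!hi, i], t[!hi])
    }
    Q <- Q * 2L
  }
  X
}

# the 48 signed axis permutations of the cube, as (perm, sign) pairs
cube_isometries <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- vector("list", 48)
  k <- 1
  for (p in perms) for (s in seq_len(nrow(signs))) {
    out[[k]] <- list(perm = p, sign = signs[s, ])
    k <- k + 1
  }
  out
}

apply_isometry <- function(xyz, iso, L) {
  y <- xyz[, iso$perm, drop = FALSE]
  for (a in 1:3) if (iso$sign[a] < 0) y[, a] <- (L - 1) - y[, a]
  y
}

# Gray-code cycle of the 8 octants (closed: last and first differ in 1 bit)
MOORE_OCTANTS <- rbind(
  c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0),
  c(1, 1, 0), c(1, 1, 1), c(1, 0, 1), c(1, 0, 0))

# Backtracking search for octant isometries (+ optional traversal reversal)
# such that consecutive order-(m-1) Hilbert blocks join with unit steps and
# the whole path closes. Deterministic (fixed enumeration order).
solve_moore_layout <- function(p0, p1, L) {
  isos <- cube_isometries()
  opts <- list()
  for (i in seq_along(isos)) for (rev in c(FALSE, TRUE)) {
    e <- apply_isometry(rbind(p0, p1), isos[[i]], L)
    if (rev) e <- e[2:1, , drop = FALSE]
    opts[[length(opts) + 1]] <- list(iso = isos[[i]], rev = rev,
                                     ein = e[1, ], eout = e[2, ])
  }
  offs <- MOORE_OCTANTS * L
  adj <- function(a, b) sum(abs(a - b)) == 1
  sol <- vector("list", 8)
  search <- function(k, prev_out, first_in) {
    for (o in opts) {
      gin <- o$ein + offs[k, ]; gout <- o$eout + offs[k, ]
      if (k > 1 && !adj(prev_out, gin)) next
      if (k == 8 && !adj(gout, first_in)) next
      sol[[k]] <<- o
      if (k == 8) return(TRUE)
      if (search(k + 1, gout, if (k == 1) gin else first_in)) return(TRUE)
    }
    FALSE
  }
  if (!search(1, NULL, NULL)) stop("no closed Moore layout found")
  sol
}

#' Closed 3D Moore space-filling curve
#'
#' An analytical gold-standard conformation: a closed Hamiltonian path on
#' the `2^order` cubic lattice built from eight rotated order-(order-1)
#' Hilbert blocks arranged around a Gray-code octant cycle. The curve has
#' `8^order` beads, visits every lattice site exactly once, every
#' consecutive pair (and the last-first pair) is at lattice distance 1, and
#' it is deterministic -- no randomness is involved. Lattice coordinates are
#' multiplied by `latticeConstant`, so the curve can serve as a gold
#' standard at any bond length.
#'
#' @param order integer >= 1; orders >= 8 are refused (8^8 beads would be
#'   16.7M).
#' @param latticeConstant spacing between adjacent lattice sites
#'   (the resulting bond length).
#' @return a [Conformation] (single chain, non-periodic).
#' @examples
#' mc <- mooreCurve(4)
#' nBeads(mc)  # 8^4 = 4096
#' @export
mooreCurve <- function(order, latticeConstant = 1) {
  order <- as.integer(order)
  stopifnot(order >= 1)
  if (order >= 8) stop("order >= 8 refused (memory guard)")
  if (order == 1) {
    xyz <- MOORE_OCTANTS
  } else {
    L <- 2L^(order - 1L)
    h <- hilbert3d(order - 1L)
    layout <- solve_moore_layout(h[1, ], h[nrow(h), ], L)
    blocks <- vector("list", 8)
    for (k in 1:8) {
      o <- layout[[k]]
      b <- apply_isometry(h, o$iso, L)
      if (o$rev) b <- b[nrow(b):1, , drop = FALSE]
      blocks[[k]] <- sweep(b, 2, MOORE_OCTANTS[k, ] * L, FUN = "+")
    }
    xyz <- do.call(rbind, blocks)
  }
  steps <- rowSums(abs(diff(xyz)))
  closing <- sum(abs(xyz[1, ] - xyz[nrow(xyz), ]))
  if (any(steps != 1) || closing != 1)
    stop("internal error: Moore construction violated unit-step closure")
  Conformation(xyz * latticeConstant)
}

## ---- DPD-equilibrated gold standards ----------------------------------

# union-find single-linkage clustering; returns size of largest cluster
largest_cluster_fraction <- function(coords, radius) {
  n <- nrow(coords)
  pr <- cpp_contact_pairs(coords, radius) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pr)) for (k in seq_len(nrow(pr))) {
    a <- find(pr[k, 1]); b <- find(pr[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  max(tabulate(roots)) / n
}

default_gold_steps <- function(nBeads)
  max(20000L, as.integer(round(2e5 * nBeads / 4096)))

equilibrate_chain <- function(nBeads, concentration, params, nSteps, seed,
                              convergeOn = "rg", start = c("box", "ball")) {
  start <- match.arg(start)
  nTotal <- as.integer(round(nBeads / concentration))
  nSolvent <- nTotal - nBeads
  box <- boxEdgeForDensity(nTotal, params@rho)
  coords <- with_local_seed(seed, {
    poly <- if (start == "ball")
      ball_walk_coords(nBeads, params@bondL0,
                       radius = 1.3 * (3 * nBeads /
                                       (4 * pi * params@rho))^(1 / 3),
                       center = rep(box / 2, 3))
    else random_walk_coords(nBeads, box, params@bondL0, wrap = FALSE)
    solv <- if (nSolvent > 0) matrix(runif(3 * nSolvent) * box,
                                     nSolvent, 3) else NULL
    rbind(poly, solv)
  })
  vel <- maxwellVelocities(nTotal, params@kT,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  topo <- dpdTopology(IRanges::IRanges(1L, nBeads), nSolvent = nSolvent)
  st <- simState(coords, vel, box)
  run <- dpdRun(st, topo, params, nSteps = nSteps,
                seed = if (is.null(seed)) 0L else seed,
                monitorEvery = 1000L, convergeOn = convergeOn,
                tol = 0.01, minSteps = min(nSteps, 5000L))
  # positions are true-space already; centre the polymer for tidiness
  polyCoords <- run$state@positions[seq_len(nBeads), , drop = FALSE]
  polyCoords <- sweep(polyCoords, 2, colMeans(polyCoords))
  conf <- Conformation(polyCoords, box = box)
  list(conf = conf, run = run)
}

#' Equilibrium globule gold standard
#'
#' Collapses a random walk under poor-solvent DPD conditions (polymer-solvent
#' repulsion exceeding polymer-polymer) into a single dense droplet -- the
#' model of a chromosome at resolutions of about 10 kb and below, where
#' effective chromatin concentration approaches 100\%. The starting walk is
#' confined to a ball slightly larger than the final droplet so the collapse
#' proceeds locally into one globule instead of arresting in a metastable
#' column percolating through the periodic box. The run stops when the
#' radius of gyration plateaus (drift < 1\% across the trailing 20\% of
#' checkpoints) or the step budget is exhausted.
#'
#' The returned conformation carries attributes `converged` (Rg plateau
#' reached *and* >= 99\% of beads in one spatial cluster at linkage radius
#' `rC`) and `monitor` (checkpoint trace).
#'
#' @param nBeads chain length.
#' @param params a [DPDParams]; must satisfy `aPS > aPP` (poor solvent).
#' @param concentration polymer fraction of total beads (sets box size).
#' @param nSteps step budget; default `max(2e4, 2e5 * nBeads / 4096)`.
#' @param seed integer seed.
#' @return a [Conformation] (polymer only, unwrapped).
#' @export
generateGlobule <- function(nBeads, params = DPDParams(),
                            concentration = 0.1, nSteps = NULL,
                            seed = NULL) {
  stopifnot(nBeads >= 2, concentration > 0, concentration <= 1)
  if (params@aPS <= params@aPP)
    stop("globule generation needs poor solvent: aPS > aPP")
  if (is.null(nSteps)) nSteps <- default_gold_steps(nBeads)
  if (nSteps == 0) {
    conf <- randomWalk(nBeads, concentration, params@bondL0, seed,
                       params@rho)
    attr(conf, "converged") <- FALSE
    return(conf)
  }
  res <- equilibrate_chain(nBeads, concentration, params, nSteps, seed,
                           convergeOn = "rg", start = "ball")
  conf <- res$conf
  single <- largest_cluster_fraction(conf@coords, params@rC) >= 0.99
  attr(conf, "converged") <- res$run$converged && single
  attr(conf, "monitor") <- res$run$monitor
  conf
}

#' Polymer solution gold standard
#'
#' Equilibrates a chain in neutral/good solvent (`aPS = aPP` by default) at
#' a requested polymer volume fraction; the coil-like result models
#' chromatin at lower effective concentrations. The polymer-bead fraction of
#' total beads equals `concentration` exactly (up to rounding);
#' `concentration = 1` gives a melt with no solvent. Solutions fluctuate, so
#' benchmark points are averaged over independent `replicate` runs.
#'
#' @param nBeads chain length.
#' @param concentration polymer volume fraction (0 < c <= 1).
#' @param params a [DPDParams]; defaults to the athermal `aPS = 25`.
#' @param nSteps step budget (default as [generateGlobule()]).
#' @param seed integer base seed.
#' @param replicate replicate index; run seed is `seed + replicate`.
#' @return a [Conformation] with `converged` and `monitor` attributes.
#' @export
generateSolution <- function(nBeads, concentration, params = DPDParams(aPS = 25),
                             nSteps = NULL, seed = NULL, replicate = 0L) {
  stopifnot(nBeads >= 2, concentration > 0, concentration <= 1)
  if (is.null(nSteps)) nSteps <- default_gold_steps(nBeads)
  runSeed <- if (is.null(seed)) NULL else as.integer(seed + replicate)
  res <- equilibrate_chain(nBeads, concentration, params,
                           max(1L, nSteps), runSeed, convergeOn = "rg")
  conf <- res$conf
  attr(conf, "converged") <- res$run$converged
  attr(conf, "monitor") <- res$run$monitor
  conf
}
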