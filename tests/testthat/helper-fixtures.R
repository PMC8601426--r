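# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 512-bead equilibrium globule under reference poor-solvent conditions;
# reused by the bond-statistics, scaling and self-consistency tests
gold_globule_512 <- function()
  cached("globule512", generateGlobule(512, seed = 21))

gold_globule_64 <- function()
  cached("globule64", generateGlobule(64, seed = 21))

# one reconstruction of the dense (r_contact = 0.8) globule contact map
recon_globule_512 <- function() cached("recon512", {
  gold <- gold_globule_512()
  cm <- contactsFromConformation(gold, rContact = 0.8)
  res <- reconstruct(cm, cfg = reconstructionConfig(seed = 11),
                     nReplicates = 1)
  list(gold = gold, map = cm, result = res$results[[1]])
})

# small periodic solvent-only system for force/integrator tests
solvent_box <- function(n = 100, seed = 2) {
  box <- boxEdgeForDensity(n)
  topo <- dpdTopology(IRanges::IRanges(1, 10), nSolvent = n - 10,
                      restraints = rbind(c(1L, 9L), c(2L, 7L)))
  st <- simState(with_seed_matrix(n, box, seed),
                 maxwellVelocities(n, seed = seed + 1), box)
  list(state = st, topo = topo, box = box)
}

with_seed_matrix <- function(n, box, seed) {
  with_seed(seed, matrix(runif(n * 3) * box, n, 3))
}

# exact linking number of two closed polygonal curves (signed crossings of
# the xy projection)
linking_number <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B); total <- 0
  for (i in seq_len(nA)) {
    a1 <- A[i, ]; a2 <- A[if (i == nA) 1 else i + 1, ]
    da <- a2 - a1
    for (j in seq_len(nB)) {
      b1 <- B[j, ]; b2 <- B[if (j == nB) 1 else j + 1, ]
      db <- b2 - b1
      den <- da[1] * db[2] - da[2] * db[1]
      if (abs(den) < 1e-12) next
      s <- ((b1[1] - a1[1]) * db[2] - (b1[2] - a1[2]) * db[1]) / den
      t <- ((b1[1] - a1[1]) * da[2] - (b1[2] - a1[2]) * da[1]) / den
      if (s <= 0 || s > 1 || t <= 0 || t > 1) next
      za <- a1[3] + s * da[3]; zb <- b1[3] + t * db[3]
      total <- total + sign(den) * (if (za > zb) 1 else -1)
    }
  }
  total / 2
}

# two Hopf-linked rings of equal radius, pushed apart by mutual soft
# repulsion (ring identities carried by the two species labels); returns
# the final linking number
linked_rings_run <- function(l0, nSteps = 40000, seed = 5, R = 1.3,
                             aCross = 35) {
  box <- 20; c0 <- box / 2
  n <- max(8L, as.integer(round(2 * pi * R / l0)))
  th <- 2 * pi * (seq_len(n) - 1) / n
  A <- cbind(c0 + R * cos(th), c0 + R * sin(th), c0)
  B <- cbind(c0 + R + R * cos(th), c0, c0 + R * sin(th))
  bb <- rbind(cbind(1:(n - 1), 2:n), cbind((n + 1):(2 * n - 1), (n + 2):(2 * n)))
  cl <- rbind(c(1L, n), c(n + 1L, 2L * n))
  bonds <- rbind(bb, cl); storage.mode(bonds) <- "integer"
  topo <- new("Topology", nBeads = as.integer(2 * n), bonds = bonds,
              bondType = c(rep(0L, nrow(bb)), rep(1L, 2L)),
              species = c(rep(0L, n), rep(1L, n)),
              chains = IRanges::IRanges(c(1L, as.integer(n + 1)),
                                        c(as.integer(n), as.integer(2 * n))))
  par <- DPDParams(aPP = 25, aSS = 25, aPS = aCross, bondL0 = l0)
  st <- simState(rbind(A, B), maxwellVelocities(2 * n, seed = seed), box)
  run <- dpdRun(st, topo, par, nSteps = nSteps, seed = seed)
  pos <- run$state@positions
  linking_number(pos[seq_len(n), ], pos[(n + 1):(2 * n), ])
}

# local-seed helper used by stochastic property tests
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
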