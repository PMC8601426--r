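#' Synthetic contact map with power-law distance decay
#'
#' Emulates the statistics of a single-cell Hi-C contact map: a sparse
#' symmetric set of pairs whose genomic-separation distribution follows a
#' power law `P(s) ~ s^decay` (contact probability decays with genomic
#' distance), at a tunable density of contacts per bead. Observed
#' single-nucleus data span roughly 0.001 to 1 contacts per bead.
#'
#' @param nBeads number of beads.
#' @param contactsPerBead target density; the map holds
#'   `round(contactsPerBead * nBeads)` unique pairs.
#' @param decay power-law exponent of the separation distribution
#'   (negative; default -1).
#' @param seed integer seed.
#' @return a [ContactMap].
#' @export
syntheticContactMap <- function(nBeads, contactsPerBead, decay = -1,
                                seed = NULL) {
  stopifnot(nBeads >= 4, contactsPerBead >= 0)
  target <- as.integer(round_half_away(contactsPerBead * nBeads))
  seps <- 2:(nBeads - 1)
  maxPairs <- sum(nBeads - seps)
  if (target > maxPairs)
    stop("unreachable density: ", target, " contacts requested but only ",
         maxPairs, " non-adjacent pairs exist")
  w <- seps^decay
  with_local_seed(seed, {
    got <- matrix(integer(), 0, 2)
    while (nrow(got) < target) {
      need <- (target - nrow(got)) * 2 + 10
      s <- sample(seps, need, replace = TRUE, prob = w)
      i <- floor(runif(need) * (nBeads - s)) + 1L
      cand <- rbind(got, cbind(i, i + s))
      cand <- cand[!duplicated(paste(cand[, 1], cand[, 2])), , drop = FALSE]
      got <- cand
    }
    ContactMap(got[seq_len(target), , drop = FALSE], nBeads)
  })
}

#' Synthetic single-cell distance map
#'
#' Distance map of a random-walk conformation with a fraction of beads
#' hidden (rows/columns set to missing), emulating oligopaint microscopy
#' data where some probes fail in a given cell.
#'
#' @param nBeads number of beads.
#' @param missingFraction fraction of beads with no observations.
#' @param seed integer seed.
#' @return a [DistanceMap] with a mask.
#' @export
syntheticDistanceMap <- function(nBeads, missingFraction = 0.2,
                                 seed = NULL) {
  with_local_seed(seed, {
    conf <- randomWalk(nBeads, concentration = 0.3, stepLen = 0.5,
                       seed = NULL)
    d <- distanceMap(unwrap_conf(conf))
    nMiss <- as.integer(round_half_away(missingFraction * nBeads))
    miss <- sample.int(nBeads, nMiss)
    mask <- matrix(TRUE, nBeads, nBeads)
    mask[miss, ] <- FALSE
    mask[, miss] <- FALSE
    new("DistanceMap", values = d@values, normalized = FALSE, mask = mask)
  })
}

unwrap_conf <- function(conf) {
  if (!is.finite(conf@box)) return(conf)
  Conformation(unwrap_chains(conf@coords, conf@chains, conf@box),
               chains = conf@chains, box = conf@box, bins = conf@bins)
}

#' Write a seeded synthetic fixture file
#'
#' Deterministic generator of small test inputs:
#' * `"scHiC_pairs"`: a 4-column pairs TSV (plus a sibling `.chrom.sizes`
#'   file) for one synthetic chromosome, with power-law separation decay.
#'   Params: `nBeads`, `contactsPerBead`, `decay`, `resolution` (bp),
#'   `chrom`.
#' * `"contact_map"`: a bead-level contact map TSV. Params: `nBeads`,
#'   `contactsPerBead`, `decay`.
#' * `"distance_map"`: a dense matrix with `NaN` missing entries. Params:
#'   `nBeads`, `missingFraction`.
#'
#' @param kind fixture type.
#' @param params named list of generator parameters (see above).
#' @param seed integer seed.
#' @param path output file path.
#' @return `path`, invisibly. For `"scHiC_pairs"` the chrom.sizes path is
#'   attached as attribute `chromSizes`.
#' @export
makeFixture <- function(kind = c("scHiC_pairs", "contact_map",
                                 "distance_map"),
                        params = list(), seed = 1L, path) {
  kind <- match.arg(kind)
  p <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  switch(kind,
    contact_map = {
      cm <- syntheticContactMap(p("nBeads", 512), p("contactsPerBead", 0.5),
                                p("decay", -1), seed)
      writeContactMap(cm, path)
    },
    distance_map = {
      dm <- syntheticDistanceMap(p("nBeads", 100),
                                 p("missingFraction", 0.2), seed)
      writeDistanceMap(dm, path)
    },
    scHiC_pairs = {
      nBeads <- p("nBeads", 512)
      res <- p("resolution", 10000)
      chrom <- p("chrom", "chr1")
      cm <- syntheticContactMap(nBeads, p("contactsPerBead", 0.5),
                                p("decay", -1), seed)
      # bead b covers [ (b-1)*res, b*res ); place positions mid-bin
      pos <- function(b) (b - 1) * res + floor(res / 2)
      pr <- cm@pairs
      lines <- paste(chrom, pos(pr[, 1]), chrom, pos(pr[, 2]), sep = "\t")
      writeLines(c("# synthetic single-cell pairs fixture", lines), path)
      csPath <- paste0(path, ".chrom.sizes")
      writeLines(paste(chrom, nBeads * res, sep = "\t"), csPath)
      attr(path, "chromSizes") <- csPath
    })
  invisible(path)
}
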