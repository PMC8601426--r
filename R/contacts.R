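#' Construct a ContactMap
#'
#' Pairs are canonicalised to `i < j`; self-pairs are an error and duplicate
#' rows are collapsed (multiplicities summed).
#'
#' @param pairs m x 2 matrix of bead index pairs (1-based), or a
#'   zero-row matrix for an empty map.
#' @param nBeads number of beads the map is defined over.
#' @param multiplicity optional per-pair counts.
#' @param metadata optional list of auxiliary data.
#' @return a [ContactMap].
#' @export
ContactMap <- function(pairs, nBeads, multiplicity = NULL,
                       metadata = list()) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(integer(), 0, 2)
  storage.mode(pairs) <- "integer"
  if (nrow(pairs)) {
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    key <- paste(pairs[, 1], pairs[, 2])
    if (anyDuplicated(key)) {
      if (is.null(multiplicity)) multiplicity <- rep(1L, nrow(pairs))
      multiplicity <- as.integer(rowsum(as.numeric(multiplicity), key,
                                        reorder = FALSE))
      pairs <- pairs[!duplicated(key), , drop = FALSE]
    }
  }
  new("ContactMap", nBeads = as.integer(nBeads), pairs = pairs,
      multiplicity = if (is.null(multiplicity)) integer() else
        as.integer(multiplicity),
      metadata = metadata)
}

# round half away from zero, so sampled counts are platform-reproducible
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Derive a contact map from a conformation
#'
#' A contact is any non-bonded bead pair at Euclidean distance
#' `<= rContact` (inclusive threshold). Backbone-adjacent pairs are
#' excluded: they are always in contact and would merely duplicate backbone
#' bonds when used as restraints.
#'
#' @param conf a [Conformation] (coordinates used as-is, no periodic
#'   wrapping).
#' @param rContact contact radius (> 0).
#' @return a [ContactMap].
#' @examples
#' cm <- contactsFromConformation(mooreCurve(3), rContact = 1.0)
#' contactsPerBead(cm)
#' @export
contactsFromConformation <- function(conf, rContact) {
  stopifnot(is(conf, "Conformation"), rContact > 0)
  pr <- cpp_contact_pairs(conf@coords, rContact) + 1L
  if (nrow(pr)) {
    ch <- conf@chains
    chainOf <- integer(nBeads(conf))
    for (c in seq_along(ch))
      chainOf[IRanges::start(ch)[c]:IRanges::end(ch)[c]] <- c
    adjacent <- (pr[, 2] - pr[, 1] == 1L) &
      (chainOf[pr[, 1]] == chainOf[pr[, 2]])
    pr <- pr[!adjacent, , drop = FALSE]
  }
  ContactMap(pr, nBeads(conf))
}

#' Randomly subsample a contact map
#'
#' Uniform sample without replacement of `round(fraction * m)` pairs
#' (half-away-from-zero rounding), emulating single-cell contact dropout.
#'
#' @param cmap a [ContactMap].
#' @param fraction fraction of pairs to keep, in `[0, 1]`.
#' @param seed integer seed (deterministic sample).
#' @return a [ContactMap].
#' @export
sampleContacts <- function(cmap, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  m <- nrow(cmap@pairs)
  k <- as.integer(round_half_away(fraction * m))
  keep <- with_local_seed(seed, sort(sample.int(m, k)))
  ContactMap(cmap@pairs[keep, , drop = FALSE], cmap@nBeads,
             metadata = cmap@metadata)
}

#' Subsample a bulk contact map by multiplicity with a per-bead cap
#'
#' Contact events are drawn with probability proportional to pair
#' multiplicity (without replacement from the event multiset); a draw is
#' greedily rejected when either endpoint already participates in
#' `maxPerBin` accepted contacts. Drawing stops after
#' `round(fraction * sum(multiplicity))` accepted draws or when the events
#' are exhausted (a short output is allowed and reported via a message).
#'
#' This models targeted bulk assays (capture-C-like input) where a sparse,
#' single-cell-like contact set is sampled from deep population data under
#' the physical constraint that one genome bin can only touch a small number
#' of partners in one cell (the reference protocol uses `maxPerBin = 2`).
#'
#' @param cmap a [ContactMap] with multiplicities.
#' @param fraction fraction of total contact events to accept.
#' @param maxPerBin maximum accepted contacts per bead (>= 1; `Inf` for no
#'   cap).
#' @param seed integer seed.
#' @return a [ContactMap] with multiplicities of accepted draws.
#' @export
sampleBulkContacts <- function(cmap, fraction, maxPerBin = 2, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, maxPerBin >= 1)
  mult <- cmap@multiplicity
  if (!length(mult)) stop("sampleBulkContacts needs a map with multiplicities")
  total <- sum(mult)
  target <- as.integer(round_half_away(fraction * total))
  # expand to events and take a multiplicity-weighted order: a uniform
  # permutation of the event multiset IS the weighted sequential draw
  events <- rep.int(seq_len(nrow(cmap@pairs)), mult)
  ord <- with_local_seed(seed, sample(events))
  degree <- integer(cmap@nBeads)
  accCount <- integer(nrow(cmap@pairs))
  nAcc <- 0L
  for (e in ord) {
    if (nAcc >= target) break
    i <- cmap@pairs[e, 1]; j <- cmap@pairs[e, 2]
    if (degree[i] >= maxPerBin || degree[j] >= maxPerBin) next
    degree[i] <- degree[i] + 1L
    degree[j] <- degree[j] + 1L
    accCount[e] <- accCount[e] + 1L
    nAcc <- nAcc + 1L
  }
  if (nAcc < target)
    message("sampleBulkContacts: accepted ", nAcc, " of ", target,
            " requested draws (cap exhausted)")
  keep <- accCount > 0L
  ContactMap(cmap@pairs[keep, , drop = FALSE], cmap@nBeads,
             multiplicity = accCount[keep], metadata = cmap@metadata)
}

#' Shuffle a contact map preserving the genomic-separation profile
#'
#' The randomised control for map-similarity comparisons: for every bead
#' separation `s = j - i` the output holds the same number of pairs as the
#' input, with positions re-drawn uniformly (without replacement) among the
#' valid `(i, i + s)` slots. The contact-frequency-versus-distance profile
#' is therefore preserved exactly while all positional structure is
#' destroyed.
#'
#' @param cmap a [ContactMap].
#' @param seed integer seed.
#' @return a [ContactMap].
#' @export
shuffleContactMap <- function(cmap, seed = NULL) {
  p <- cmap@pairs
  if (!nrow(p)) return(cmap)
  n <- cmap@nBeads
  seps <- p[, 2] - p[, 1]
  out <- with_local_seed(seed, {
    do.call(rbind, lapply(split(seps, seps), function(ss) {
      s <- ss[1]
      nslots <- n - s
      cnt <- length(ss)
      stopifnot(cnt <= nslots)  # input maps cannot exceed slot capacity
      i <- sort(sample.int(nslots, cnt))
      cbind(i, i + s)
    }))
  })
  ContactMap(out, n, metadata = cmap@metadata)
}

#' Threshold a (possibly masked) distance map into contacts
#'
#' For oligopaint-style microscopy data: a pair is a contact iff its
#' distance is observed and `<= threshold`. Beads with no observed entries
#' at all are reported in the result's `metadata$maskedBeads`, so later
#' comparisons can mask the reconstructed map with the same pattern as the
#' experimental one.
#'
#' @param dmap a [DistanceMap] (use `NA` for missing entries) or a plain
#'   matrix with `NA`s.
#' @param threshold contact distance threshold (> 0).
#' @return a [ContactMap].
#' @export
contactsFromDistanceMap <- function(dmap, threshold) {
  stopifnot(threshold > 0)
  v <- if (is(dmap, "DistanceMap")) dmap@values else as.matrix(dmap)
  if (is(dmap, "DistanceMap") && !is.null(dmap@mask)) v[!dmap@mask] <- NA
  n <- nrow(v)
  ut <- which(upper.tri(v) & !is.na(v) & v <= threshold, arr.ind = TRUE)
  maskedBeads <- which(vapply(seq_len(n), function(i)
    all(is.na(v[i, -i])), TRUE))
  ContactMap(ut[, c(1, 2), drop = FALSE], n,
             metadata = list(maskedBeads = maskedBeads))
}

## ---- genomic binning ----------------------------------------------------

#' Bin genomic contact records into a bead-level contact map
#'
#' Tiles each chromosome into fixed-width bins (`floor(pos / resolution)`,
#' 0-based half-open; the last bin may be short), assigns one polymer chain
#' per chromosome, and maps every contact record to a bead pair. Duplicate
#' records collapse to unique pairs with multiplicities retained. Intra-bin
#' and bin-adjacent contacts are dropped (they carry no restraint
#' information beyond the backbone). Records with unknown chromosomes or
#' out-of-range positions are skipped and counted.
#'
#' @param pairsRecords data.frame with columns `chrom1, pos1, chrom2, pos2`
#'   (as from [readPairs()]).
#' @param chromSizes data.frame with columns `chrom, length` (as from
#'   [readChromSizes()]).
#' @param resolution bin width in bp.
#' @param trans keep or drop inter-chromosomal contacts (default keep).
#' @return list with `map` (a [ContactMap]), `bins` (a [GenomicBinTable])
#'   and `skipped` (named counts of dropped records).
#' @export
binPairs <- function(pairsRecords, chromSizes, resolution,
                     trans = c("keep", "drop")) {
  trans <- match.arg(trans)
  stopifnot(resolution > 0)
  chroms <- as.character(chromSizes$chrom)
  sizes <- setNames(as.numeric(chromSizes$length), chroms)
  nbins <- setNames(pmax(1L, as.integer(ceiling(sizes / resolution))),
                    chroms)
  offset <- setNames(c(0L, cumsum(nbins))[seq_along(chroms)], chroms)
  nBeadsTotal <- sum(nbins)

  p <- pairsRecords
  knownChrom <- p$chrom1 %in% chroms & p$chrom2 %in% chroms
  nUnknown <- sum(!knownChrom)
  p <- p[knownChrom, , drop = FALSE]
  inRange <- p$pos1 >= 0 & p$pos1 < sizes[p$chrom1] &
             p$pos2 >= 0 & p$pos2 < sizes[p$chrom2]
  nOut <- sum(!inRange)
  p <- p[inRange, , drop = FALSE]
  if (trans == "drop") {
    keep <- p$chrom1 == p$chrom2
    p <- p[keep, , drop = FALSE]
  }
  b1 <- offset[p$chrom1] + floor(p$pos1 / resolution) + 1L
  b2 <- offset[p$chrom2] + floor(p$pos2 / resolution) + 1L
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  # intra-bin and bin-adjacent (same chromosome) carry no information
  near <- hi - lo <= 1L & p$chrom1 == p$chrom2
  nNear <- sum(near)
  lo <- lo[!near]; hi <- hi[!near]
  cm <- if (length(lo))
    ContactMap(cbind(lo, hi), nBeadsTotal,
               multiplicity = rep(1L, length(lo)))
  else ContactMap(matrix(integer(), 0, 2), nBeadsTotal)

  starts <- unlist(lapply(chroms, function(c)
    seq(0, by = resolution, length.out = nbins[c])))
  ends <- unlist(lapply(chroms, function(c)
    pmin(seq(resolution, by = resolution, length.out = nbins[c]), sizes[c])))
  gr <- GenomicRanges::GRanges(
    rep(chroms, nbins),
    IRanges::IRanges(start = starts + 1, end = ends))  # GRanges is 1-based
  S4Vectors::mcols(gr)$bead <- seq_len(nBeadsTotal)
  chainsIR <- IRanges::IRanges(offset + 1L, offset + nbins)
  names(chainsIR) <- chroms
  bt <- new("GenomicBinTable", bins = gr, chains = chainsIR,
            resolution = as.numeric(resolution))
  if (nUnknown + nOut > 0)
    message("binPairs: skipped ", nUnknown, " unknown-chromosome and ",
            nOut, " out-of-range record(s)")
  list(map = cm, bins = bt,
       skipped = c(unknownChrom = nUnknown, outOfRange = nOut,
                   nearDiagonal = nNear))
}
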