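test_that("contact derivation: radius semantics and all-pairs oracle", {
  # straight rod at bond length 1: no non-bonded pair within 0.5
  rod <- Conformation(cbind(0:9, 0, 0))
  expect_equal(nrow(contactPairs(contactsFromConformation(rod, 0.5))), 0)

  # inclusive threshold: pair at exactly rContact is present
  tri <- Conformation(rbind(c(0, 0, 0), c(5, 0, 0), c(0.8, 0, 0)))
  cm <- contactsFromConformation(tri, 0.8)
  expect_true(any(cm@pairs[, 1] == 1 & cm@pairs[, 2] == 3))

  # backbone-adjacent pairs are excluded
  pair <- Conformation(cbind(c(0, 0.3), 0, 0))
  expect_equal(nrow(contactPairs(contactsFromConformation(pair, 1))), 0)

  # brute-force double-loop oracle on the order-2 Moore curve
  mc <- mooreCurve(2)
  cm <- contactsFromConformation(mc, 1.0)
  co <- coords(mc)
  oracle <- list()
  for (i in 1:63) for (j in (i + 1):64) {
    if (j - i == 1) next
    if (sqrt(sum((co[i, ] - co[j, ])^2)) <= 1.0)
      oracle[[length(oracle) + 1]] <- c(i, j)
  }
  expect_equal(unname(cm@pairs), do.call(rbind, oracle))
})

test_that("contacts per bead: definition and monotonicity in radius", {
  empty <- ContactMap(matrix(integer(), 0, 2), 100)
  expect_equal(contactsPerBead(empty), 0)
  cm <- syntheticContactMap(4096, 0.5, seed = 1)
  expect_equal(contactsPerBead(cm), 2048 / 4096)
  mc <- mooreCurve(2)
  xs <- vapply(seq(0.8, 2.2, by = 0.2), function(r)
    contactsPerBead(contactsFromConformation(mc, r)), 1.0)
  expect_true(all(diff(xs) >= 0))
  expect_gt(tail(xs, 1), xs[1])
})

test_that("uniform contact dropout: exact counts and unbiased retention", {
  cm <- syntheticContactMap(2000, 0.5, seed = 3)  # 1000 pairs
  expect_identical(contactPairs(sampleContacts(cm, 1, seed = 1)),
                   contactPairs(cm))
  expect_equal(nrow(contactPairs(sampleContacts(cm, 0, seed = 1))), 0)
  half <- sampleContacts(cm, 0.5, seed = 1)
  expect_equal(nrow(contactPairs(half)), 500)

  # each pair retained with frequency ~ fraction across seeds
  small <- syntheticContactMap(100, 0.4, seed = 4)  # 40 pairs
  keys <- paste(small@pairs[, 1], small@pairs[, 2])
  hits <- setNames(numeric(length(keys)), keys)
  for (s in 1:200) {
    kept <- sampleContacts(small, 0.5, seed = s)
    kk <- paste(kept@pairs[, 1], kept@pairs[, 2])
    hits[kk] <- hits[kk] + 1
  }
  freq <- hits / 200
  expect_true(all(freq > 0.3 & freq < 0.7))  # hypergeometric, sd ~ 0.035
  expect_equal(mean(freq), 0.5, tolerance = 1e-9)
})

test_that("weighted bulk sampling honours multiplicity and the per-bead cap", {
  pairs <- rbind(c(1L, 3L), c(2L, 5L), c(4L, 8L), c(6L, 9L))
  cm <- ContactMap(pairs, 10, multiplicity = c(5L, 5L, 5L, 5L))
  # uniform weights + no cap: reduces to a plain sample of the right size
  out <- sampleBulkContacts(cm, 0.4, maxPerBin = Inf, seed = 1)
  expect_equal(sum(contactMultiplicity(out)), 8)  # 0.4 * 20 draws

  # cap of 2: every bead participates in at most 2 accepted contacts
  dense <- syntheticContactMap(30, 2, seed = 5)
  denseM <- ContactMap(dense@pairs, 30,
                       multiplicity = rep(3L, nrow(dense@pairs)))
  capped <- sampleBulkContacts(denseM, 0.8, maxPerBin = 2, seed = 2)
  degree <- tabulate(c(rep(capped@pairs[, 1], capped@multiplicity),
                       rep(capped@pairs[, 2], capped@multiplicity)), 30)
  expect_true(all(degree <= 2))

  # 9:1 weights, one draw: heavy pair selected ~90% of the time
  two <- ContactMap(rbind(c(1L, 3L), c(2L, 4L)), 5,
                    multiplicity = c(9L, 1L))
  heavy <- 0
  for (s in 1:300) {
    one <- sampleBulkContacts(two, 0.1, maxPerBin = 2, seed = s)  # 1 draw
    if (any(one@pairs[, 1] == 1)) heavy <- heavy + 1
  }
  expect_equal(heavy / 300, 0.9, tolerance = 0.07)
})

test_that("separation-preserving shuffle keeps the decay profile exactly", {
  n <- 40
  sat <- ContactMap(cbind(1:(n - 1), 2:n), n)  # saturated s = 1 diagonal
  expect_equal(shuffleContactMap(sat, seed = 1)@pairs, sat@pairs)

  cm <- syntheticContactMap(300, 0.8, seed = 6)
  sh <- shuffleContactMap(cm, seed = 7)
  expect_equal(nrow(sh@pairs), nrow(cm@pairs))
  expect_identical(table(cm@pairs[, 2] - cm@pairs[, 1]),
                   table(sh@pairs[, 2] - sh@pairs[, 1]))
  expect_false(identical(sh@pairs, cm@pairs))

  # positions within a separation class are re-drawn ~uniformly over slots
  one_sep <- ContactMap(cbind(seq(1, 50, by = 2), seq(1, 50, by = 2) + 10),
                        60)
  counts <- numeric(50)  # slots for s = 10
  for (s in 1:120) {
    sh <- shuffleContactMap(one_sep, seed = s)
    counts[sh@pairs[, 1]] <- counts[sh@pairs[, 1]] + 1
  }
  expect_equal(mean(counts), 120 * 25 / 50, tolerance = 1e-9)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("genomic binning: floor rule, near-diagonal drops, skip counts", {
  cs <- data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 5e5))
  rec <- data.frame(chrom1 = "chr1", pos1 = 150000,
                    chrom2 = "chr1", pos2 = 450000)
  out <- binPairs(rec, cs, resolution = 200000)
  expect_equal(unname(out$map@pairs[1, ]), c(1L, 3L))  # bins 0 and 2

  sameBin <- data.frame(chrom1 = "chr1", pos1 = 10, chrom2 = "chr1",
                        pos2 = 20)
  expect_equal(nrow(binPairs(sameBin, cs, 200000)$map@pairs), 0)

  # 10-record hand-enumerated fixture
  rec10 <- data.frame(
    chrom1 = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr1", "chr1",
               "chr3", "chr1", "chr1"),
    pos1 = c(50000, 50000, 850000, 10000, 100000, 50000, 999999,
             100, 2e6, 610000),
    chrom2 = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr1", "chr2",
               "chr3", "chr1", "chr1"),
    pos2 = c(450000, 450000, 50000, 450000, 120000, 450000, 100,
             200, 100, 10000))
  suppressMessages(out <- binPairs(rec10, cs, 200000))
  # chr1 has 5 bins (1..5), chr2 has 3 (6..8)
  expect_equal(IRanges::width(chainRanges(out$bins)), c(5L, 3L))
  expect_equal(out$skipped[["unknownChrom"]], 1)   # chr3
  expect_equal(out$skipped[["outOfRange"]], 1)     # pos 2e6 on chr1
  expected <- rbind(c(1L, 3L),  # 50000-450000 (three identical records)
                    c(1L, 5L),  # 850000-50000 reversed
                    c(6L, 8L),  # chr2 10000-450000
                    c(5L, 6L),  # trans chr1:999999 - chr2:100 (kept: bead
                                #   adjacency only applies within a chain)
                    c(1L, 4L))  # 610000-10000 reversed
    # chr2 100000-120000 same bin -> dropped
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(out$map@pairs), key(expected))
  # duplicated records kept as multiplicity
  dup <- which(out$map@pairs[, 1] == 1 & out$map@pairs[, 2] == 3)
  expect_equal(out$map@multiplicity[dup], 3L)
  # trans dropping
  suppressMessages(noTrans <- binPairs(rec10, cs, 200000, trans = "drop"))
  expect_false(any(paste(noTrans$map@pairs[, 1], noTrans$map@pairs[, 2])
                   %in% "5 6"))
  # bins tile the chromosomes; the last bin may be short
  gr <- genomicBins(out$bins)
  expect_equal(sum(IRanges::width(gr)), 1.5e6)
})

test_that("distance-map thresholding with missing data", {
  m <- matrix(NA_real_, 4, 4)
  expect_equal(nrow(contactsFromDistanceMap(m, 1)@pairs), 0)
  expect_equal(contactsFromDistanceMap(m, 1)@metadata$maskedBeads, 1:4)

  m <- matrix(c(0, 5, 0.5, 5, 0, 5, 0.5, 5, 0), 3, 3)
  cm <- contactsFromDistanceMap(m, 1)
  expect_equal(unname(cm@pairs), rbind(c(1L, 3L)))

  dm <- syntheticDistanceMap(50, missingFraction = 0.2, seed = 9)
  counts <- vapply(c(0.5, 1, 2, 4),
                   function(th) nrow(contactsFromDistanceMap(dm, th)@pairs),
                   1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("ContactMap invariants: canonical order, no self pairs, no dups", {
  cm <- ContactMap(rbind(c(5L, 2L), c(2L, 5L), c(1L, 3L)), 6)
  expect_equal(nrow(cm@pairs), 2)
  expect_true(all(cm@pairs[, 1] < cm@pairs[, 2]))
  expect_equal(cm@multiplicity[cm@pairs[, 1] == 2], 2L)
  expect_error(ContactMap(rbind(c(2L, 2L)), 5), "self")
  expect_error(ContactMap(rbind(c(1L, 9L)), 5), "range")
})
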