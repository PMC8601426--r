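test_that("distance map: values, Rg normalization, isometry invariance", {
  two <- Conformation(rbind(c(0, 0, 0), c(3, 0, 0)))
  d <- distanceMap(two)
  expect_equal(d@values, rbind(c(0, 3), c(3, 0)))
  dn <- distanceMap(two, normalize = TRUE)
  expect_equal(dn@values[1, 2], 2)  # d / Rg with Rg = d/2

  conf <- mooreCurve(2)
  d0 <- distanceMap(conf)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- Conformation(sweep(coords(conf) %*% rot, 2, c(5, -2, 1), "+"))
  expect_equal(distanceMap(moved)@values, d0@values, tolerance = 1e-10)
  expect_equal(distanceMap(mirrorConformation(conf))@values, d0@values,
               tolerance = 1e-12)
  expect_error(distanceMap(Conformation(rbind(c(0, 0, 0)))), "2 beads")
})

test_that("IMJ: identity, scale algebra, masks, size guard", {
  conf <- mooreCurve(2)
  d <- distanceMap(conf)
  expect_equal(imj(d, d), 0)

  v <- d@values
  expect_equal(imj(v, matrix(0, nrow(v), ncol(v))), 1)  # vs all-zeros

  for (c in c(0.5, 2, 3)) # scalar multiple: |1 - c| / (1 + c)
    expect_equal(imj(v, c * v), abs(1 - c) / (1 + c), tolerance = 1e-12)

  # Rg normalization makes the metric scale-invariant
  scaled <- Conformation(coords(conf) * 7)
  expect_equal(imj(distanceMap(scaled, normalize = TRUE),
                   distanceMap(conf, normalize = TRUE)), 0,
               tolerance = 1e-12)

  # masked entries are excluded from both norms
  mask <- matrix(TRUE, nrow(v), ncol(v)); mask[1, ] <- mask[, 1] <- FALSE
  dm1 <- new("DistanceMap", values = v, normalized = FALSE, mask = mask)
  dm2 <- new("DistanceMap", values = 2 * v, normalized = FALSE, mask = NULL)
  expect_equal(imj(dm1, dm2), 1 / 3, tolerance = 1e-12)

  expect_error(imj(v, v[1:10, 1:10]), "size")
})

test_that("random-matrix IMJ baseline matches the closed form sqrt(1/7)", {
  est <- imjRandomBaseline(500, reps = 4, seed = 3)
  expect_equal(est, sqrt(1 / 7), tolerance = 0.01)
  # size stability
  est2 <- imjRandomBaseline(1000, reps = 2, seed = 4)
  expect_lt(abs(est - est2), 0.01)
})

test_that("accuracy normalization endpoints and linearity", {
  expect_equal(accuracyFromIMJ(0), 100)
  expect_equal(accuracyFromIMJ(0.378), 0)
  expect_equal(accuracyFromIMJ(0.189), 50)
  expect_lt(accuracyFromIMJ(0.5), 0)  # below random: negative, not clipped
})

test_that("exponential accuracy model: intercept, asymptote, monotonicity", {
  expect_equal(expectedAccuracy(0), (1 - 0.642) * 93.7)
  expect_equal(expectedAccuracy(1e6), 93.7)
  expect_equal(expectedAccuracy(0.239), (1 - 0.642 / exp(1)) * 93.7)
  x <- seq(0, 3, by = 0.1)
  expect_true(all(diff(expectedAccuracy(x)) > 0))
})

test_that("accuracy-curve fit recovers the generating constants", {
  x <- seq(0.05, 2.5, length.out = 12)
  noiseless <- data.frame(x = x, accuracy = expectedAccuracy(x))
  f <- fitAccuracyCurve(noiseless)
  expect_equal(f$A, 0.642, tolerance = 1e-6)
  expect_equal(f$beta, 0.239, tolerance = 1e-6)
  expect_equal(f$aMax, 93.7, tolerance = 1e-6)

  noisy <- with_seed(42, data.frame(
    x = seq(0.05, 2.5, length.out = 20),
    accuracy = expectedAccuracy(seq(0.05, 2.5, length.out = 20)) +
      rnorm(20, sd = 2)))
  f <- fitAccuracyCurve(noisy)
  expect_lt(abs(f$A - 0.642) / 0.642, 0.15)
  expect_lt(abs(f$beta - 0.239) / 0.239, 0.15)
  expect_lt(abs(f$aMax - 93.7) / 93.7, 0.15)

  expect_error(fitAccuracyCurve(noiseless[1:3, ]), "4 points")
})

test_that("contact-map similarity: spearman and IMJ-accuracy directions", {
  cm <- syntheticContactMap(80, 1.2, seed = 8)
  expect_equal(mapSimilarity(cm, cm, method = "spearman"), 1)
  expect_equal(mapSimilarity(cm, cm, method = "imj"), 100)

  sh <- shuffleContactMap(cm, seed = 9)
  expect_lt(mapSimilarity(cm, sh, method = "imj"),
            mapSimilarity(cm, cm, method = "imj"))
  expect_lt(mapSimilarity(cm, sh, method = "spearman"), 1)

  # disjoint maps of equal density score at or below zero similarity
  a <- ContactMap(rbind(c(1L, 3L), c(2L, 4L)), 5)
  b <- ContactMap(rbind(c(1L, 4L), c(2L, 5L)), 5)
  expect_lte(mapSimilarity(a, b, method = "imj"), 0)

  full <- ContactMap(t(combn(4, 2)), 4)  # all-constant upper triangle
  expect_error(mapSimilarity(full, full, method = "spearman"),
               "all-constant")
  expect_error(mapSimilarity(a, ContactMap(rbind(c(1L, 3L)), 9)), "bead")
})

test_that("mirror reflection flips chirality but not distances", {
  tetra <- Conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.9, 0),
                              c(0.5, 0.3, 0.8)))
  m <- mirrorConformation(tetra)
  expect_equal(imj(distanceMap(tetra), distanceMap(m)), 0, tolerance = 1e-12)
  expect_identical(coords(mirrorConformation(m)), coords(tetra))
  vol <- function(co) det(rbind(co[2, ] - co[1, ], co[3, ] - co[1, ],
                                co[4, ] - co[1, ]))
  expect_equal(vol(coords(m)), -vol(coords(tetra)))
})
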