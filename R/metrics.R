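#' Distance map of a conformation
#'
#' All-pairs Euclidean distance matrix of the beads (coordinates used as-is,
#' no periodic wrapping). With `normalize = TRUE` the matrix is divided by
#' the radius of gyration of the polymer, which removes the spatial scale
#' and makes maps from differently-scaled methods comparable. The map is
#' invariant under rigid motion and mirror reflection of the conformation.
#'
#' @param conf a [Conformation] (or an n x 3 coordinate matrix).
#' @param normalize divide by the radius of gyration.
#' @param mask optional logical matrix of observed entries.
#' @return a [DistanceMap].
#' @export
distanceMap <- function(conf, normalize = FALSE, mask = NULL) {
  m <- if (is(conf, "Conformation")) conf@coords else as.matrix(conf)
  if (nrow(m) < 2) stop("need at least 2 beads")
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- NULL
  if (normalize) d <- d / radiusOfGyration(m)
  new("DistanceMap", values = d, normalized = normalize, mask = mask)
}

#' Wrap a plain matrix as a DistanceMap
#'
#' `NA` entries become the mask (e.g. oligopaint data with missing
#' rows/columns).
#'
#' @param values symmetric non-negative matrix, zero diagonal; `NA` =
#'   unobserved.
#' @param normalized whether values are already Rg-normalized.
#' @return a [DistanceMap].
#' @export
asDistanceMap <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  mask <- NULL
  if (anyNA(values)) {
    mask <- !is.na(values)
    values[!mask] <- 0
  }
  new("DistanceMap", values = values, normalized = normalized, mask = mask)
}

#' Modified Jaccard Index between two distance maps
#'
#' `IMJ = ||(D - D')/2|| / ||(D + D')/2||` with the Frobenius (element-wise
#' Euclidean) norm. It is 0 for identical matrices and grows with
#' dissimilarity; for non-negative inputs it lies in `[0, 1]`. When either
#' map carries a mask, the masks are intersected and only jointly observed
#' entries enter both norms, so a reconstruction can be compared to an
#' experimental map with missing data under the same pattern.
#'
#' @param d1,d2 [DistanceMap]s of equal size (or plain matrices).
#' @return a scalar in `[0, 1]`.
#' @examples
#' d <- distanceMap(mooreCurve(2))
#' imj(d, d)  # 0: identical structures
#' @export
imj <- function(d1, d2) {
  v1 <- if (is(d1, "DistanceMap")) d1@values else as.matrix(d1)
  v2 <- if (is(d2, "DistanceMap")) d2@values else as.matrix(d2)
  if (!all(dim(v1) == dim(v2))) stop("distance maps differ in size")
  keep <- NULL
  m1 <- if (is(d1, "DistanceMap")) d1@mask else NULL
  m2 <- if (is(d2, "DistanceMap")) d2@mask else NULL
  if (!is.null(m1) || !is.null(m2)) {
    keep <- if (is.null(m1)) m2 else if (is.null(m2)) m1 else (m1 & m2)
    v1 <- v1[keep]; v2 <- v2[keep]
  }
  minus <- sum(((v1 - v2) / 2)^2)
  plus <- sum(((v1 + v2) / 2)^2)
  if (plus == 0) return(0)
  sqrt(minus / plus)
}

#' Monte Carlo baseline IMJ of random symmetric matrices
#'
#' Mean IMJ over `reps` pairs of independent symmetric matrices with iid
#' uniform `[0, 1]` entries. This is the "zero similarity" reference level
#' used to normalise IMJ into an accuracy. Analytically the large-n limit is
#' `sqrt(E[(X - Y)^2] / E[(X + Y)^2]) = sqrt(1/7) = 0.37796` for X, Y ~
#' U(0, 1), matching the conventional 0.378; the estimate is essentially
#' size-independent.
#'
#' @param n matrix size (>= 100 for a stable estimate).
#' @param reps number of independent pairs.
#' @param seed integer seed.
#' @return the mean IMJ.
#' @export
imjRandomBaseline <- function(n = 2000, reps = 10, seed = NULL) {
  stopifnot(n >= 100, reps >= 1)
  with_local_seed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      m1 <- random_symmetric(n)
      m2 <- random_symmetric(n)
      imj(m1, m2)
    }, 1.0))
  })
}

random_symmetric <- function(n) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- runif(sum(ut))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Reconstruction accuracy from an IMJ value
#'
#' Linear normalisation of IMJ against the random baseline:
#' `A = (imjR - imj12) / imjR * 100%`. Identical structures (IMJ = 0) give
#' 100\%; random similarity (IMJ = imjR) gives 0\%. Values below the random
#' baseline come out negative and are reported raw, not clipped.
#'
#' @param imj12 IMJ between the two structures.
#' @param imjR the random baseline (0.378 by convention; see
#'   [imjRandomBaseline()]).
#' @return accuracy in percent.
#' @export
accuracyFromIMJ <- function(imj12, imjR = 0.378) {
  stopifnot(imjR > 0)
  (imjR - imj12) / imjR * 100
}

#' Accuracy of one conformation against another
#'
#' Convenience wrapper: Rg-normalised distance maps, IMJ, then accuracy.
#'
#' @param conf,ref [Conformation]s with equal bead counts.
#' @param imjR the random IMJ baseline.
#' @return accuracy in percent.
#' @export
conformationAccuracy <- function(conf, ref, imjR = 0.378) {
  accuracyFromIMJ(imj(distanceMap(conf, normalize = TRUE),
                      distanceMap(ref, normalize = TRUE)), imjR)
}

#' Expected reconstruction accuracy at a given contact density
#'
#' The exponential accuracy model
#' `accuracy(x) = (1 - A * exp(-x / beta)) * aMax`, where `x` is the number
#' of contacts per bead. `aMax` is the accuracy ceiling set by thermal
#' fluctuations of the reconstructed structure, `A` fixes the zero-contact
#' intercept, and `beta` is the characteristic contact density of the
#' exponential recovery. Defaults are the reference constants for DPD
#' reconstruction of dense globules at N = 4096
#' (A = 0.642, beta = 0.239, aMax = 93.7).
#'
#' @param x contacts per bead (>= 0); vectorised.
#' @param A dimensionless amplitude in `[0, 1]`.
#' @param beta characteristic contacts per bead (> 0).
#' @param aMax accuracy ceiling in percent.
#' @return expected accuracy in percent.
#' @examples
#' expectedAccuracy(0)     # 33.5: information-free floor
#' expectedAccuracy(1)     # near the ceiling
#' @export
expectedAccuracy <- function(x, A = 0.642, beta = 0.239, aMax = 93.7) {
  stopifnot(all(x >= 0), beta > 0)
  (1 - A * exp(-x / beta)) * aMax
}

#' Fit the exponential accuracy model to sweep points
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' `accuracy = (1 - A exp(-x/beta)) * aMax` with `0 <= A <= 1`,
#' `beta > 0` and `0 < aMax <= 100`.
#'
#' @param points data.frame with columns `x` and `accuracy`, or an
#'   [AccuracyCurve].
#' @return list with elements `A`, `beta`, `aMax` and `residualSS`.
#' @export
fitAccuracyCurve <- function(points) {
  if (is(points, "AccuracyCurve")) points <- points@points
  points <- points[complete.cases(points[, c("x", "accuracy")]), ]
  if (nrow(points) < 4)
    stop("need at least 4 points to fit the 3-parameter model")
  if (length(unique(points$x)) < 3)
    stop("points must span a range of contact densities")
  aMax0 <- min(100, max(points$accuracy) + 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      accuracy ~ (1 - A * exp(-x / beta)) * aMax,
      data = points,
      start = list(A = 0.5, beta = max(0.1, median(points$x) / 2),
                   aMax = aMax0),
      lower = c(A = 0, beta = 1e-6, aMax = 1e-6),
      upper = c(A = 1, beta = Inf, aMax = 100),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("accuracy-curve fit failed to converge: ",
                             conditionMessage(e)))
  co <- coef(fit)
  list(A = unname(co["A"]), beta = unname(co["beta"]),
       aMax = unname(co["aMax"]),
       residualSS = sum(residuals(fit)^2))
}

#' Similarity of two contact maps
#'
#' For `method = "imj"`, the maps are densified to symmetric 0/1 matrices
#' and the IMJ-based accuracy (percent) is returned; for
#' `method = "spearman"`, the Spearman rank correlation over the upper
#' triangle. Used to compare reconstructed maps against merged experimental
#' maps and their separation-preserving shuffles.
#'
#' @param cmap1,cmap2 [ContactMap]s over the same bead count.
#' @param method `"imj"` or `"spearman"`.
#' @param imjR the random IMJ baseline (used by `"imj"`).
#' @return a scalar similarity.
#' @export
mapSimilarity <- function(cmap1, cmap2, method = c("imj", "spearman"),
                          imjR = 0.378) {
  method <- match.arg(method)
  if (cmap1@nBeads != cmap2@nBeads) stop("contact maps differ in bead count")
  d1 <- densify(cmap1); d2 <- densify(cmap2)
  if (method == "imj") return(accuracyFromIMJ(imj(d1, d2), imjR))
  u1 <- d1[upper.tri(d1)]; u2 <- d2[upper.tri(d2)]
  if (length(unique(u1)) < 2 || length(unique(u2)) < 2)
    stop("spearman similarity undefined for an all-constant map")
  cor(u1, u2, method = "spearman")
}

densify <- function(cmap) {
  n <- cmap@nBeads
  m <- matrix(0, n, n)
  p <- cmap@pairs
  if (nrow(p)) {
    m[p] <- 1
    m[p[, c(2, 1), drop = FALSE]] <- 1
  }
  m
}

#' Mirror-reflect a conformation
#'
#' Negates one coordinate axis. Distance maps (hence IMJ and accuracy) are
#' invariant under reflection, so a reconstruction is only defined up to
#' chirality; this helper flips it for visual comparison.
#'
#' @param conf a [Conformation].
#' @param axis which axis to negate (1 = x).
#' @return a [Conformation].
#' @export
mirrorConformation <- function(conf, axis = 1L) {
  co <- conf@coords
  co[, axis] <- -co[, axis]
  Conformation(co, chains = conf@chains, box = conf@box, bins = conf@bins)
}
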