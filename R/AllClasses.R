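setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' DPD force-field and integrator parameters
#'
#' Container for the dissipative-particle-dynamics constants. All quantities
#' are in reduced DPD units: the non-bonded cutoff `rC` defines the length
#' unit, `kT` the energy unit and bead mass is 1. The amplitude of the random
#' force is never stored; it is derived from the fluctuation-dissipation
#' relation `sigma = sqrt(2 * gamma * kT)`.
#'
#' @slot aPP,aPS,aSS conservative repulsion amplitudes for polymer-polymer,
#'   polymer-solvent and solvent-solvent bead pairs. Defaults
#'   `aPP = aSS = 25`, `aPS = 55` specify a poor solvent
#'   (Flory-Huggins chi = 8.58 at density 3, see [chiFromRepulsion()]).
#' @slot rC non-bonded interaction cutoff (1.0 by convention).
#' @slot bondK harmonic bond stiffness (40).
#' @slot bondL0 unperturbed bond length (0.5 by default; values at or below
#'   0.3 destroy chain phantomness).
#' @slot gamma dissipative friction coefficient (4.5, the standard choice).
#' @slot kT thermostat temperature (1).
#' @slot dt integration time step (0.04; soft potentials permit a step about
#'   an order of magnitude larger than in conventional molecular dynamics).
#' @slot rho bead number density (3, the standard DPD reduced density; the
#'   chi mapping used by [chiFromRepulsion()] is calibrated at this value).
#' @slot lambdaVV velocity-prediction factor of the modified velocity-Verlet
#'   integrator (0.65).
#' @slot gaussianTheta logical; if `FALSE` (default) the per-pair random
#'   variate is uniform on `[-sqrt(3), sqrt(3)]` (unit variance), if `TRUE`
#'   a standard Gaussian.
#'
#' @seealso [DPDParams()] for the user constructor.
#' @exportClass DPDParams
setClass("DPDParams",
  representation(aPP = "numeric", aPS = "numeric", aSS = "numeric",
                 rC = "numeric", bondK = "numeric", bondL0 = "numeric",
                 gamma = "numeric", kT = "numeric", dt = "numeric",
                 rho = "numeric", lambdaVV = "numeric",
                 gaussianTheta = "logical"))

setValidity("DPDParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1 && is.finite(x)
  for (s in c("aPP", "aPS", "aSS", "rC", "bondK", "bondL0", "gamma", "kT",
              "dt", "rho", "lambdaVV"))
    if (!one(slot(object, s))) msg <- c(msg, paste0(s, " must be a finite scalar"))
  if (length(msg)) return(msg)
  if (object@rC <= 0) msg <- c(msg, "rC must be > 0")
  if (object@bondK <= 0) msg <- c(msg, "bondK must be > 0")
  if (object@bondL0 < 0 || object@bondL0 > 2 * object@rC)
    msg <- c(msg, "bondL0 must lie in [0, 2*rC]")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@rho <= 0) msg <- c(msg, "rho must be > 0")
  if (length(msg)) msg else TRUE
})

#' Bead-spring system topology
#'
#' Bead identities and bonds of a DPD system: polymer chains (consecutive
#' beads bonded along the backbone), optional restraint bonds derived from a
#' contact map, and solvent beads. Species are coded 0 = polymer,
#' 1 = solvent; bond types 0 = backbone, 1 = restraint.
#'
#' @slot nBeads total bead count (polymer + solvent).
#' @slot bonds integer matrix, one row per bond, columns i, j (1-based).
#' @slot bondType integer vector, 0 backbone / 1 restraint.
#' @slot species integer vector per bead, 0 polymer / 1 solvent.
#' @slot chains [IRanges::IRanges] of polymer chain bead ranges.
#'
#' @seealso [dpdTopology()]
#' @exportClass Topology
setClass("Topology",
  representation(nBeads = "integer", bonds = "matrix", bondType = "integer",
                 species = "integer", chains = "IRanges"))

setValidity("Topology", function(object) {
  msg <- character()
  b <- object@bonds
  if (ncol(b) != 2) msg <- c(msg, "bonds must have two columns")
  if (nrow(b) != length(object@bondType))
    msg <- c(msg, "bondType length must match bond count")
  if (length(object@species) != object@nBeads)
    msg <- c(msg, "species length must equal nBeads")
  if (nrow(b) > 0) {
    if (any(b < 1 | b > object@nBeads))
      msg <- c(msg, "bond indices out of range")
    else {
      if (any(b[, 1] == b[, 2]))
        msg <- c(msg, "bond between identical bead indices")
      key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate bonds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Instantaneous simulation state
#'
#' Bead positions and velocities in a cubic periodic box.
#'
#' @slot positions numeric matrix (n x 3), DPD length units.
#' @slot velocities numeric matrix (n x 3).
#' @slot box cubic box edge length; coordinates are wrapped into
#'   `[0, box)` for force evaluation.
#'
#' @seealso [simState()]
#' @exportClass SimState
setClass("SimState",
  representation(positions = "matrix", velocities = "matrix",
                 box = "numeric"))

setValidity("SimState", function(object) {
  msg <- character()
  if (ncol(object@positions) != 3 || ncol(object@velocities) != 3)
    msg <- c(msg, "positions and velocities must have 3 columns")
  if (!all(dim(object@positions) == dim(object@velocities)))
    msg <- c(msg, "positions and velocities must have identical dimensions")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "non-finite coordinates")
  if (!all(is.finite(object@velocities)))
    msg <- c(msg, "non-finite velocities")
  if (length(object@box) != 1 || !is.finite(object@box) || object@box <= 0)
    msg <- c(msg, "box must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' A polymer conformation
#'
#' Bead coordinates of one or more polymer chains, with optional genomic
#' annotation linking beads to genome bins. Coordinates are unwrapped
#' (contiguous in space along each chain), so plain Euclidean distances are
#' meaningful.
#'
#' @slot coords numeric matrix (n x 3) of bead positions, DPD length units.
#' @slot chains [IRanges::IRanges]; disjoint half-open-free bead index
#'   ranges (1-based, inclusive) covering all beads; consecutive beads
#'   within a chain are backbone-bonded.
#' @slot box edge length of the periodic box the conformation was generated
#'   in, or `NA` for analytical conformations.
#' @slot bins optional [GenomicRanges::GRanges], one range per bead, in bead
#'   order, carrying the genomic bin each bead represents.
#'
#' @seealso [Conformation()]
#' @exportClass Conformation
setClass("Conformation",
  representation(coords = "matrix", chains = "IRanges", box = "numeric",
                 bins = "GRangesOrNULL"))

setValidity("Conformation", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  n <- nrow(object@coords)
  ch <- object@chains
  idx <- unlist(lapply(seq_along(ch), function(i)
    seq(IRanges::start(ch)[i], IRanges::end(ch)[i])))
  if (length(idx) != n || anyDuplicated(idx) || !setequal(idx, seq_len(n)))
    msg <- c(msg, "chains must disjointly cover all beads exactly once")
  if (!is.null(object@bins) && length(object@bins) != n)
    msg <- c(msg, "bins must annotate every bead")
  if (length(msg)) msg else TRUE
})

#' A single-cell contact map
#'
#' A set of unique unordered bead-index pairs over `nBeads` beads, optionally
#' with per-pair multiplicities (for bulk data). Self-pairs and duplicate
#' pairs are invalid; the map is symmetric by construction.
#'
#' @slot nBeads number of beads the map is defined over.
#' @slot pairs integer matrix (m x 2), rows `(i, j)` with `i < j`, 1-based.
#' @slot multiplicity integer vector of per-pair counts (length 0 when the
#'   map is binary).
#' @slot metadata list of auxiliary information (e.g. a `mask` of beads with
#'   no observations when imported from a distance map).
#'
#' @seealso [ContactMap()]
#' @exportClass ContactMap
setClass("ContactMap",
  representation(nBeads = "integer", pairs = "matrix",
                 multiplicity = "integer", metadata = "list"))

setValidity("ContactMap", function(object) {
  msg <- character()
  p <- object@pairs
  if (ncol(p) != 2) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) > 0) {
    if (any(p < 1 | p > object@nBeads)) msg <- c(msg, "bead index out of range")
    else {
      if (any(p[, 1] >= p[, 2]))
        msg <- c(msg, "pairs must satisfy i < j (no self-pairs)")
      if (anyDuplicated(paste(p[, 1], p[, 2]))) msg <- c(msg, "duplicate pairs")
    }
  }
  if (length(object@multiplicity) &&
      length(object@multiplicity) != nrow(p))
    msg <- c(msg, "multiplicity must have one entry per pair")
  if (length(msg)) msg else TRUE
})

#' A bead-to-genome bin table
#'
#' Bijection between polymer beads and fixed-width genomic bins obtained by
#' tiling each chromosome at a chosen resolution. One polymer chain per
#' chromosome; bins are 0-based half-open in genomic coordinates.
#'
#' @slot bins [GenomicRanges::GRanges] of the bins in bead order, with a
#'   `bead` metadata column.
#' @slot chains [IRanges::IRanges] of bead ranges, one per chromosome.
#' @slot resolution bin width in bp.
#'
#' @exportClass GenomicBinTable
setClass("GenomicBinTable",
  representation(bins = "GRanges", chains = "IRanges",
                 resolution = "numeric"))

#' A distance map
#'
#' Symmetric matrix of Euclidean bead-bead distances, optionally normalized
#' by the radius of gyration of the polymer (making comparisons
#' scale-invariant), and optionally masked where entries are unobserved.
#'
#' @slot values symmetric non-negative numeric matrix with zero diagonal.
#' @slot normalized logical; `TRUE` when divided by the radius of gyration.
#' @slot mask optional logical matrix, `TRUE` = observed.
#'
#' @seealso [distanceMap()], [imj()]
#' @exportClass DistanceMap
setClass("DistanceMap",
  representation(values = "matrix", normalized = "logical",
                 mask = "matrixOrNULL"))

setValidity("DistanceMap", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (any(abs(v - t(v)) > 1e-8, na.rm = TRUE)) msg <- c(msg, "values must be symmetric")
    if (any(diag(v) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
    if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "distances must be non-negative")
  }
  if (!is.null(object@mask) && !all(dim(object@mask) == dim(v)))
    msg <- c(msg, "mask dimensions must match values")
  if (length(msg)) msg else TRUE
})

#' Result of one reconstruction run
#'
#' @slot conformation the reconstructed [Conformation] (solvent stripped,
#'   chains unwrapped).
#' @slot restraintSatisfaction fraction of restraint bonds whose final
#'   length is at or below the satisfaction radius.
#' @slot backboneLengths final backbone bond lengths.
#' @slot restraintLengths final restraint bond lengths.
#' @slot converged logical; `FALSE` when the step budget ran out before the
#'   restraint-length median went stationary.
#' @slot provenance list: configuration snapshot, seed, steps run, monitor
#'   trace.
#'
#' @exportClass ReconstructionResult
setClass("ReconstructionResult",
  representation(conformation = "Conformation",
                 restraintSatisfaction = "numeric",
                 backboneLengths = "numeric",
                 restraintLengths = "numeric",
                 converged = "logical",
                 provenance = "list"))

#' An accuracy-versus-contacts curve
#'
#' Points of reconstruction accuracy (percent) against contacts per bead,
#' with an optional exponential model fit (see [expectedAccuracy()]).
#'
#' @slot points data.frame with at least columns `x` (contacts per bead) and
#'   `accuracy` (percent); sweep metadata columns (swept variable,
#'   replicate) are retained.
#' @slot fit list with elements `A`, `beta`, `aMax` when fitted, else empty.
#'
#' @seealso [fitAccuracyCurve()], [runDropoutSweep()]
#' @exportClass AccuracyCurve
setClass("AccuracyCurve",
  representation(points = "data.frame", fit = "list"))

setValidity("AccuracyCurve", function(object) {
  p <- object@points
  if (!all(c("x", "accuracy") %in% names(p)))
    return("points needs columns 'x' and 'accuracy'")
  if (nrow(p) && any(p$x < 0)) return("x must be >= 0")
  TRUE
})
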