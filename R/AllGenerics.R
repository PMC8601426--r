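#' @name accessors
#' @title Accessors for DPDfold data classes
#'
#' @description
#' `nBeads()` returns the bead count; `coords()` the n x 3 coordinate
#' matrix; `chainRanges()` the [IRanges::IRanges] of chain bead ranges;
#' `boxEdge()` the cubic box edge; `contactPairs()` the m x 2 matrix of
#' unordered contact pairs; `contactMultiplicity()` per-pair counts;
#' `genomicBins()` the per-bead [GenomicRanges::GRanges] annotation (or
#' `NULL`).
#'
#' @param x a DPDfold object.
#' @return See description per accessor.
#' @examples
#' conf <- mooreCurve(2)
#' nBeads(conf)
#' head(coords(conf))
NULL

#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("chainRanges", function(x) standardGeneric("chainRanges"))

#' @rdname accessors
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname accessors
#' @export
setGeneric("contactMultiplicity", function(x)
  standardGeneric("contactMultiplicity"))

#' @rdname accessors
#' @export
setGeneric("genomicBins", function(x) standardGeneric("genomicBins"))

#' Contacts per bead
#'
#' Number of unique contacts divided by the number of beads -- the data
#' quality covariate that reconstruction accuracy depends on.
#'
#' @param x a [ContactMap].
#' @return a scalar, `nrow(contactPairs(x)) / nBeads(x)`.
#' @examples
#' cm <- ContactMap(rbind(c(1, 3), c(2, 4)), nBeads = 4)
#' contactsPerBead(cm)  # 0.5
#' @export
setGeneric("contactsPerBead", function(x) standardGeneric("contactsPerBead"))

#' @rdname accessors
setMethod("nBeads", "Conformation", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("nBeads", "ContactMap", function(x) x@nBeads)
#' @rdname accessors
setMethod("nBeads", "Topology", function(x) x@nBeads)
#' @rdname accessors
setMethod("nBeads", "SimState", function(x) nrow(x@positions))
#' @rdname accessors
setMethod("nBeads", "DistanceMap", function(x) nrow(x@values))

#' @rdname accessors
setMethod("coords", "Conformation", function(x) x@coords)
#' @rdname accessors
setMethod("coords", "SimState", function(x) x@positions)

#' @rdname accessors
setMethod("chainRanges", "Conformation", function(x) x@chains)
#' @rdname accessors
setMethod("chainRanges", "Topology", function(x) x@chains)
#' @rdname accessors
setMethod("chainRanges", "GenomicBinTable", function(x) x@chains)

#' @rdname accessors
setMethod("boxEdge", "Conformation", function(x) x@box)
#' @rdname accessors
setMethod("boxEdge", "SimState", function(x) x@box)

#' @rdname accessors
setMethod("contactPairs", "ContactMap", function(x) x@pairs)
#' @rdname accessors
setMethod("contactMultiplicity", "ContactMap", function(x) x@multiplicity)
#' @rdname accessors
setMethod("genomicBins", "Conformation", function(x) x@bins)
#' @rdname accessors
setMethod("genomicBins", "GenomicBinTable", function(x) x@bins)

setMethod("contactsPerBead", "ContactMap", function(x) {
  if (x@nBeads == 0) stop("contact map over zero beads")
  nrow(x@pairs) / x@nBeads
})

#' @rdname accessors
#' @aliases show,DPDParams-method show,Conformation-method
#'   show,ContactMap-method show,Topology-method show,SimState-method
#'   show,DistanceMap-method show,ReconstructionResult-method
#'   show,AccuracyCurve-method show,GenomicBinTable-method
#' @exportMethod show
setMethod("show", "DPDParams", function(object) {
  cat("DPDParams (reduced units)\n")
  cat(sprintf("  repulsion a: pp=%g ps=%g ss=%g  cutoff rC=%g  rho=%g\n",
              object@aPP, object@aPS, object@aSS, object@rC, object@rho))
  cat(sprintf("  bonds: k=%g l0=%g\n", object@bondK, object@bondL0))
  cat(sprintf("  thermostat: gamma=%g kT=%g (sigma=%g)  dt=%g lambda=%g\n",
              object@gamma, object@kT, sqrt(2 * object@gamma * object@kT),
              object@dt, object@lambdaVV))
})

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d beads in %d chain(s)",
              nrow(object@coords), length(object@chains)))
  if (is.finite(object@box)) cat(sprintf(", box %.3g", object@box))
  if (!is.null(object@bins))
    cat(sprintf(", %d genomic bins", length(object@bins)))
  cat("\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d unique pairs over %d beads (%.4g per bead)%s\n",
              nrow(object@pairs), object@nBeads,
              nrow(object@pairs) / max(1L, object@nBeads),
              if (length(object@multiplicity)) ", with multiplicities" else ""))
})

setMethod("show", "Topology", function(object) {
  cat(sprintf(
    "Topology: %d beads (%d polymer, %d solvent), %d backbone + %d restraint bonds\n",
    object@nBeads, sum(object@species == 0L), sum(object@species == 1L),
    sum(object@bondType == 0L), sum(object@bondType == 1L)))
})

setMethod("show", "SimState", function(object) {
  cat(sprintf("SimState: %d beads, box %.4g\n", nrow(object@positions),
              object@box))
})

setMethod("show", "DistanceMap", function(object) {
  cat(sprintf("DistanceMap: %d x %d%s%s\n", nrow(object@values),
              ncol(object@values),
              if (object@normalized) ", Rg-normalized" else "",
              if (!is.null(object@mask))
                sprintf(", %d masked entries", sum(!object@mask)) else ""))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf(
    "ReconstructionResult: %d beads, %sconverged, restraint satisfaction %.3f\n",
    nBeads(object@conformation), if (object@converged) "" else "NOT ",
    object@restraintSatisfaction))
})

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve: %d points", nrow(object@points)))
  if (length(object@fit))
    cat(sprintf("; fit A=%.3f beta=%.3f aMax=%.1f%%", object@fit$A,
                object@fit$beta, object@fit$aMax))
  cat("\n")
})

setMethod("show", "GenomicBinTable", function(object) {
  cat(sprintf("GenomicBinTable: %d bins at %g bp over %d chromosome(s)\n",
              length(object@bins), object@resolution, length(object@chains)))
})
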