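#' Create a DPD parameter set
#'
#' Defaults correspond to the poor-solvent chromatin setup: soft repulsion
#' `aPP = aSS = 25` between like beads and `aPS = 55` between polymer and
#' solvent (Flory-Huggins chi = 8.58 at density 3), cutoff `rC = 1`, harmonic
#' bonds with stiffness 40 and rest length 0.5, friction 4.5, `kT = 1`,
#' time step 0.04 and the modified velocity-Verlet prediction factor 0.65.
#'
#' @param aPP,aPS,aSS conservative repulsion amplitudes.
#' @param rC non-bonded cutoff.
#' @param bondK,bondL0 harmonic bond stiffness and rest length.
#' @param gamma dissipative friction.
#' @param kT thermostat temperature.
#' @param dt integration time step.
#' @param rho bead number density.
#' @param lambdaVV velocity-prediction factor.
#' @param gaussianTheta use Gaussian instead of uniform pair variates.
#' @return a [DPDParams] object.
#' @examples
#' DPDParams()                      # poor solvent (globule-forming)
#' DPDParams(aPS = 25)              # athermal solvent (coils)
#' @export
DPDParams <- function(aPP = 25, aPS = 55, aSS = 25, rC = 1.0, bondK = 40,
                      bondL0 = 0.5, gamma = 4.5, kT = 1.0, dt = 0.04,
                      rho = 3.0, lambdaVV = 0.65, gaussianTheta = FALSE) {
  new("DPDParams", aPP = as.numeric(aPP), aPS = as.numeric(aPS),
      aSS = as.numeric(aSS), rC = as.numeric(rC), bondK = as.numeric(bondK),
      bondL0 = as.numeric(bondL0), gamma = as.numeric(gamma),
      kT = as.numeric(kT), dt = as.numeric(dt), rho = as.numeric(rho),
      lambdaVV = as.numeric(lambdaVV),
      gaussianTheta = isTRUE(gaussianTheta))
}

#' Read a flat key = value configuration file into DPDParams
#'
#' Unknown keys are returned in the `extra` attribute (e.g. `n_steps`,
#' `seed`), so a single file can configure a whole run.
#'
#' @param path file of `key = value` lines; `#` comments allowed.
#' @return a [DPDParams]; attribute `extra` holds non-parameter keys.
#' @export
readDPDConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- names(formals(DPDParams))
  args <- lapply(vals[keys %in% known], function(v) as.numeric(v))
  names(args) <- keys[keys %in% known]
  if ("gaussianTheta" %in% names(args))
    args$gaussianTheta <- args$gaussianTheta != 0
  p <- do.call(DPDParams, args)
  extra <- as.list(vals[!keys %in% known])
  names(extra) <- keys[!keys %in% known]
  attr(p, "extra") <- extra
  p
}

params_as_list <- function(params) {
  list(aPP = params@aPP, aPS = params@aPS, aSS = params@aSS, rC = params@rC,
       bondK = params@bondK, bondL0 = params@bondL0, gamma = params@gamma,
       kT = params@kT, dt = params@dt, lambdaVV = params@lambdaVV,
       gaussianTheta = params@gaussianTheta)
}

#' Flory-Huggins parameter implied by DPD repulsion amplitudes
#'
#' Maps the excess repulsion between unlike beads to the Flory-Huggins
#' incompatibility parameter using the standard linear calibration at
#' reduced bead density 3: `chi = 0.286 * (aCross - aSame)`. With the
#' default poor-solvent amplitudes (55, 25) this gives chi = 8.58.
#'
#' @param aCross repulsion amplitude between unlike species (polymer-solvent).
#' @param aSame repulsion amplitude between like species.
#' @param rho bead number density; only the calibrated density 3 is
#'   supported.
#' @return the Flory-Huggins chi (dimensionless).
#' @examples
#' chiFromRepulsion(55, 25)  # 8.58: poor solvent, globular polymer
#' chiFromRepulsion(25, 25)  # 0: athermal
#' @export
chiFromRepulsion <- function(aCross, aSame, rho = 3) {
  stopifnot(is.numeric(aCross), is.numeric(aSame))
  if (!isTRUE(all.equal(rho, 3)))
    stop("chi mapping is calibrated at rho = 3 only")
  if (aCross < aSame)
    warning("aCross < aSame: good-solvent regime (negative chi)")
  0.286 * (aCross - aSame)
}
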