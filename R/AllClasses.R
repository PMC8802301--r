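#' @import methods
NULL

## ---------------------------------------------------------------------------
## Umbrella window and thermodynamic condition
## ---------------------------------------------------------------------------

#' Umbrella window specification
#'
#' One umbrella-sampling window: a harmonic restraint centred at `d0`
#' (Angstrom) with force constant `k` (kcal mol^-1 A^-2). The restraint
#' energy convention is decided at evaluation time (see [biasEnergy()]).
#'
#' @slot d0 restraint centre, Angstrom (> 0)
#' @slot k force constant, kcal mol^-1 A^-2 (>= 0)
#' @slot label window identifier
#' @export
setClass("WindowSpec",
  representation(d0 = "numeric", k = "numeric", label = "character"),
  prototype(label = NA_character_)
)

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || !is.finite(object@d0) || object@d0 <= 0)
    msg <- c(msg, "'d0' must be a single positive finite value (Angstrom)")
  if (length(object@k) != 1L || !is.finite(object@k) || object@k < 0)
    msg <- c(msg, "'k' must be a single non-negative finite value")
  if (length(msg)) msg else TRUE
})

#' @param d0 restraint centre, Angstrom
#' @param k force constant, kcal mol^-1 A^-2
#' @param label window identifier (defaults to `"d0=<value>"`)
#' @return `WindowSpec()` returns a \linkS4class{WindowSpec}.
#' @rdname WindowSpec-class
#' @examples
#' WindowSpec(d0 = 4, k = 2)
#' @export
WindowSpec <- function(d0, k = 2, label = sprintf("d0=%.2f", d0)) {
  new("WindowSpec", d0 = as.numeric(d0), k = as.numeric(k),
      label = as.character(label))
}

#' Thermodynamic condition
#'
#' Temperature and ionic strength at which a set of windows was sampled.
#'
#' @slot temperature absolute temperature, K (> 0)
#' @slot ionicStrength ionic strength, mol/dm^3 (>= 0)
#' @export
setClass("Condition",
  representation(temperature = "numeric", ionicStrength = "numeric")
)

setValidity("Condition", function(object) {
  msg <- character()
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "'temperature' must be a single positive value (K)")
  if (length(object@ionicStrength) != 1L || !is.finite(object@ionicStrength) ||
      object@ionicStrength < 0)
    msg <- c(msg, "'ionicStrength' must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' @param temperature K
#' @param ionicStrength mol/dm^3
#' @return `Condition()` returns a \linkS4class{Condition}.
#' @rdname Condition-class
#' @examples
#' Condition(298, 0.4)
#' @export
Condition <- function(temperature, ionicStrength = 0) {
  new("Condition", temperature = as.numeric(temperature),
      ionicStrength = as.numeric(ionicStrength))
}

## ---------------------------------------------------------------------------
## Ground-truth model potential
## ---------------------------------------------------------------------------

#' Synthetic ground-truth potential of mean force
#'
#' An analytic stand-in for the true distance PMF of an associating
#' hydrophobic dimer: a diverging repulsive wall plus up to three Gaussian
#' features — the contact minimum (CM), the desolvation maximum (DM) and the
#' solvent-separated minimum (SSM). The CM depth depends quadratically on
#' temperature and linearly on ionic strength,
#' `depth(T, IS) = a + b*T + c*T^2 + depthISSlope * IS`,
#' and the CM Gaussian amplitude is rescaled per condition so the potential
#' value at `cmPos` equals that depth exactly. The wall is
#' `(wallScale / (xi - wallPos))^12`, so the potential diverges as `xi`
#' approaches `wallPos` from above and decays to zero at large separation.
#'
#' DM and SSM are optional: `NA` positions disable them (the hexane-like
#' preset has only a CM; the adamantane-like preset has all three).
#'
#' @slot cmPos,cmWidth CM Gaussian centre and width, Angstrom
#' @slot dmPos,dmHeight,dmWidth DM Gaussian (NA position = absent)
#' @slot ssmPos,ssmDepth,ssmWidth SSM Gaussian (NA position = absent)
#' @slot wallPos,wallScale repulsive-wall offset and scale, Angstrom
#' @slot depthTQuad numeric(3): (a, b, c) of the CM-depth temperature law
#' @slot depthISSlope kcal mol^-1 (mol/dm^3)^-1
#' @seealso [modelPMF()], [cmDepth()], [hexanePreset()], [adamantanePreset()]
#' @export
setClass("ModelPotential",
  representation(
    cmPos = "numeric", cmWidth = "numeric",
    dmPos = "numeric", dmHeight = "numeric", dmWidth = "numeric",
    ssmPos = "numeric", ssmDepth = "numeric", ssmWidth = "numeric",
    wallPos = "numeric", wallScale = "numeric",
    depthTQuad = "numeric", depthISSlope = "numeric"
  )
)

setValidity("ModelPotential", function(object) {
  msg <- character()
  if (length(object@depthTQuad) != 3L || anyNA(object@depthTQuad))
    msg <- c(msg, "'depthTQuad' must be three finite coefficients (a, b, c)")
  if (object@wallPos <= 0 || object@wallScale <= 0)
    msg <- c(msg, "'wallPos' and 'wallScale' must be positive")
  if (object@cmPos <= object@wallPos)
    msg <- c(msg, "'cmPos' must lie above the repulsive wall")
  if (!is.na(object@dmPos) && object@dmPos <= object@cmPos)
    msg <- c(msg, "'dmPos' must exceed 'cmPos'")
  if (!is.na(object@ssmPos) &&
      (is.na(object@dmPos) || object@ssmPos <= object@dmPos))
    msg <- c(msg, "'ssmPos' requires a DM and must exceed 'dmPos'")
  if (length(msg)) msg else TRUE
})

#' @param cmPos,cmWidth,dmPos,dmHeight,dmWidth,ssmPos,ssmDepth,ssmWidth,wallPos,wallScale,depthTQuad,depthISSlope see slots
#' @return `ModelPotential()` returns a \linkS4class{ModelPotential}.
#' @rdname ModelPotential-class
#' @export
ModelPotential <- function(cmPos, depthTQuad, depthISSlope = 0,
                           cmWidth = 0.6,
                           dmPos = NA_real_, dmHeight = NA_real_, dmWidth = 0.5,
                           ssmPos = NA_real_, ssmDepth = NA_real_,
                           ssmWidth = 0.6,
                           wallPos = cmPos - 2.5, wallScale = 1.3) {
  new("ModelPotential",
      cmPos = as.numeric(cmPos), cmWidth = as.numeric(cmWidth),
      dmPos = as.numeric(dmPos), dmHeight = as.numeric(dmHeight),
      dmWidth = as.numeric(dmWidth),
      ssmPos = as.numeric(ssmPos), ssmDepth = as.numeric(ssmDepth),
      ssmWidth = as.numeric(ssmWidth),
      wallPos = as.numeric(wallPos), wallScale = as.numeric(wallScale),
      depthTQuad = as.numeric(depthTQuad),
      depthISSlope = as.numeric(depthISSlope))
}

## ---------------------------------------------------------------------------
## Sampled series and study container
## ---------------------------------------------------------------------------

#' Reaction-coordinate time series for one window
#'
#' Samples of the restrained distance coordinate for one umbrella window at
#' one (temperature, ionic strength) condition. Times are synthetic: sample
#' index times the 0.2 ps save stride of the emulated protocol.
#'
#' @slot window the \linkS4class{WindowSpec} sampled under
#' @slot condition the \linkS4class{Condition}
#' @slot times ps, strictly increasing
#' @slot xi sampled distances, Angstrom, same length as `times`
#' @slot seed integer seed the series was generated with (NA if read from file)
#' @export
setClass("ReactionCoordinateSeries",
  representation(window = "WindowSpec", condition = "Condition",
                 times = "numeric", xi = "numeric", seed = "integer"),
  prototype(seed = NA_integer_)
)

setValidity("ReactionCoordinateSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@xi))
    msg <- c(msg, "'times' and 'xi' must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (length(object@xi) && any(object@xi <= 0))
    msg <- c(msg, "all 'xi' must be positive distances")
  if (length(msg)) msg else TRUE
})

#' @param window,condition,times,xi,seed see slots
#' @return `ReactionCoordinateSeries()` returns a
#'   \linkS4class{ReactionCoordinateSeries}.
#' @rdname ReactionCoordinateSeries-class
#' @export
ReactionCoordinateSeries <- function(window, condition, xi,
                                     times = seq_along(xi) * 0.2,
                                     seed = NA_integer_) {
  new("ReactionCoordinateSeries", window = window, condition = condition,
      times = as.numeric(times), xi = as.numeric(xi),
      seed = as.integer(seed))
}

#' A complete synthetic umbrella-sampling study
#'
#' One \linkS4class{ReactionCoordinateSeries} per (window, condition) cell of
#' a full window-ladder x temperature x ionic-strength grid, together with
#' the generating \linkS4class{ModelPotential} and protocol.
#'
#' @slot series named list of series, one per grid cell
#' @slot groundTruth the generating \linkS4class{ModelPotential}
#' @slot protocol the generating protocol (list; see [studyProtocol()])
#' @slot seed master seed
#' @export
setClass("StudyDataset",
  representation(series = "list", groundTruth = "ModelPotential",
                 protocol = "list", seed = "integer")
)

setValidity("StudyDataset", function(object) {
  ok <- vapply(object@series, is, logical(1), "ReactionCoordinateSeries")
  if (!all(ok)) return("'series' must contain only ReactionCoordinateSeries")
  key <- vapply(object@series, function(s)
    sprintf("%s|%g|%g", s@window@label, s@condition@temperature,
            s@condition@ionicStrength), character(1))
  if (anyDuplicated(key))
    return("duplicate (window, condition) cells in 'series'")
  TRUE
})

## ---------------------------------------------------------------------------
## Histograms and PMF profiles
## ---------------------------------------------------------------------------

#' Per-window histograms on a common grid
#'
#' Binned counts of the reaction coordinate for every window of one
#' condition, on one shared edge grid with half-open bins
#' `[edge_j, edge_{j+1})`. Samples outside the grid are dropped and the
#' dropped count recorded, so `retained + dropped` equals the series length
#' for every window.
#'
#' @slot binEdges strictly increasing edges, Angstrom
#' @slot counts integer matrix, windows x bins
#' @slot nTotal per-window retained sample counts
#' @slot dropped per-window out-of-range sample counts
#' @slot windows list of \linkS4class{WindowSpec}, matching `counts` rows
#' @slot condition the shared \linkS4class{Condition}
#' @export
setClass("HistogramSet",
  representation(binEdges = "numeric", counts = "matrix",
                 nTotal = "integer", dropped = "integer",
                 windows = "list", condition = "Condition")
)

setValidity("HistogramSet", function(object) {
  msg <- character()
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "'binEdges' must be strictly increasing")
  if (ncol(object@counts) != length(object@binEdges) - 1L)
    msg <- c(msg, "'counts' must have one column per bin")
  if (nrow(object@counts) != length(object@windows) ||
      nrow(object@counts) != length(object@nTotal))
    msg <- c(msg, "'counts', 'windows' and 'nTotal' disagree on window count")
  if (any(object@counts < 0)) msg <- c(msg, "negative counts")
  if (any(rowSums(object@counts) != object@nTotal))
    msg <- c(msg, "'nTotal' must equal per-window retained counts")
  if (length(msg)) msg else TRUE
})

#' Potential of mean force profile
#'
#' The free-energy profile F(xi) on bin centres, with the per-window WHAM
#' shift constants f_i, optional bootstrap uncertainties, and baseline
#' metadata. `F` is `NA` for bins to which no window contributed counts;
#' downstream code must skip those bins.
#'
#' @slot binCenters Angstrom
#' @slot F kcal/mol per bin (NA for empty bins)
#' @slot Ferr optional per-bin standard error, kcal/mol (NA if not computed)
#' @slot counts total (all-window) counts per bin
#' @slot windowShifts WHAM constants f_i, kcal/mol, gauge f_1 = 0
#' @slot baselineRange closed distance range averaged to zero, or c(NA, NA)
#' @slot condition the \linkS4class{Condition}
#' @slot converged logical: did WHAM meet its tolerance
#' @slot iterations WHAM iterations used
#' @export
setClass("PMFProfile",
  representation(binCenters = "numeric", F = "numeric", Ferr = "numeric",
                 counts = "numeric", windowShifts = "numeric",
                 baselineRange = "numeric", condition = "Condition",
                 converged = "logical", iterations = "integer"),
  prototype(baselineRange = c(NA_real_, NA_real_), converged = NA,
            iterations = 0L)
)

setValidity("PMFProfile", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@F) != n || length(object@counts) != n)
    msg <- c(msg, "'F' and 'counts' must match 'binCenters' in length")
  if (length(object@Ferr) && length(object@Ferr) != n)
    msg <- c(msg, "'Ferr' must be empty or match 'binCenters'")
  if (length(object@baselineRange) != 2L)
    msg <- c(msg, "'baselineRange' must have length 2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PMF features
## ---------------------------------------------------------------------------

#' Located extrema of a PMF profile
#'
#' Positions and values of the contact minimum (always present), and of the
#' desolvation maximum and solvent-separated minimum when the profile has
#' them. Values are read from the unsmoothed profile; absent features carry
#' NA positions and `hasDM`/`hasSSM` flags.
#'
#' @slot cmPos,cmDepth contact minimum, Angstrom and kcal/mol
#' @slot dmPos,dmHeight desolvation maximum (NA if absent)
#' @slot ssmPos,ssmDepth solvent-separated minimum (NA if absent)
#' @slot hasDM,hasSSM presence flags
#' @export
setClass("PMFFeatures",
  representation(cmPos = "numeric", cmDepth = "numeric",
                 dmPos = "numeric", dmHeight = "numeric",
                 ssmPos = "numeric", ssmDepth = "numeric",
                 hasDM = "logical", hasSSM = "logical")
)

setValidity("PMFFeatures", function(object) {
  msg <- character()
  if (object@hasDM && !(object@cmPos < object@dmPos))
    msg <- c(msg, "DM must lie beyond the CM")
  if (object@hasSSM && (!object@hasDM || !(object@dmPos < object@ssmPos)))
    msg <- c(msg, "SSM requires a DM and must lie beyond it")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Thermodynamic fits
## ---------------------------------------------------------------------------

#' Quadratic temperature fit of the contact-minimum free energy
#'
#' Coefficients of `dF(T) = a + b*T + c*T^2` fitted to the contact-minimum
#' depth across temperatures at one ionic strength, with their covariance.
#' All derived excess quantities (entropy, energy, heat capacity) come from
#' this fit via [thermoState()].
#'
#' @slot coef named numeric(3): a (kcal/mol), b (kcal mol^-1 K^-1),
#'   c (kcal mol^-1 K^-2)
#' @slot cov 3x3 covariance of (a, b, c)
#' @slot nPoints number of (T, dF) points fitted
#' @slot conditionIS ionic strength the fit belongs to, mol/dm^3
#' @slot weighted whether per-point sigmas were used
#' @export
setClass("ThermoFit",
  representation(coef = "numeric", cov = "matrix", nPoints = "integer",
                 conditionIS = "numeric", weighted = "logical")
)

setValidity("ThermoFit", function(object) {
  msg <- character()
  if (length(object@coef) != 3L)
    msg <- c(msg, "'coef' must be (a, b, c)")
  if (!all(dim(object@cov) == c(3L, 3L)))
    msg <- c(msg, "'cov' must be 3x3")
  else if (!anyNA(object@cov)) {
    if (max(abs(object@cov - t(object@cov))) > 1e-8 * (1 + max(abs(object@cov))))
      msg <- c(msg, "'cov' must be symmetric")
    ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      msg <- c(msg, "'cov' must be positive semidefinite")
  }
  if (object@nPoints < 3L) msg <- c(msg, "'nPoints' must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Excess thermodynamic state at one temperature
#'
#' Excess free energy, energy, entropy and heat capacity of contact-minimum
#' formation evaluated from a \linkS4class{ThermoFit} at one temperature,
#' with first-order propagated errors. The identity `dF = dU - T*dS` holds
#' by construction. Heat capacity is in cal mol^-1 K^-1; everything else in
#' kcal-based units.
#'
#' @slot temperature K
#' @slot dF,dU kcal/mol
#' @slot dS kcal mol^-1 K^-1
#' @slot dCv cal mol^-1 K^-1
#' @slot dFerr,dUerr,dSerr,dCverr propagated standard errors, same units
#' @export
setClass("ThermoState",
  representation(temperature = "numeric", dF = "numeric", dU = "numeric",
                 dS = "numeric", dCv = "numeric",
                 dFerr = "numeric", dUerr = "numeric", dSerr = "numeric",
                 dCverr = "numeric")
)

setValidity("ThermoState", function(object) {
  if (abs(object@dF - (object@dU - object@temperature * object@dS)) > 1e-10)
    "thermodynamic identity dF = dU - T*dS violated"
  else TRUE
})

#' Linear ionic-strength fit of the contact-minimum free energy
#'
#' `dF(IS) = intercept + slope * IS` at one temperature. A negative slope
#' means the contact minimum deepens with added salt (salting-out). With
#' exactly two points the fit is saturated: coefficients are exact but the
#' residual-based covariance is undefined and flagged.
#'
#' @slot slope kcal mol^-1 (mol/dm^3)^-1
#' @slot intercept kcal/mol
#' @slot cov 2x2 covariance of (intercept, slope); NA when saturated
#' @slot conditionT K
#' @slot saturated TRUE when fitted to exactly two points (unweighted)
#' @export
setClass("IonicFit",
  representation(slope = "numeric", intercept = "numeric", cov = "matrix",
                 conditionT = "numeric", saturated = "logical")
)

setValidity("IonicFit", function(object) {
  if (!all(dim(object@cov) == c(2L, 2L))) "'cov' must be 2x2" else TRUE
})

## ---------------------------------------------------------------------------
## Pipeline report
## ---------------------------------------------------------------------------

#' Full-study analysis report
#'
#' Everything the pipeline produces over a (temperature x ionic strength)
#' grid: per-condition PMF profiles, the feature table, per-ionic-strength
#' temperature fits with the derived 298 K states, per-temperature ionic
#' fits, a per-cell status table and provenance.
#'
#' @slot profiles named list of \linkS4class{PMFProfile} ("T<K>_IS<M>")
#' @slot features data.frame: T_K, IS_M, cm/dm/ssm positions and values
#' @slot thermoFits named list of \linkS4class{ThermoFit} per ionic strength
#' @slot thermoStates named list of \linkS4class{ThermoState} (298 K) per IS
#' @slot ionicFits named list of \linkS4class{IonicFit} per temperature
#' @slot status data.frame: one row per grid cell with stage outcomes
#' @slot protocol generating/analysis protocol
#' @slot seed master seed
#' @slot version package version string
#' @export
setClass("StudyReport",
  representation(profiles = "list", features = "data.frame",
                 thermoFits = "list", thermoStates = "list",
                 ionicFits = "list", status = "data.frame",
                 protocol = "list", seed = "integer", version = "character")
)
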