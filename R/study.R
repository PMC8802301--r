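#' Study protocols and presets
#'
#' A study protocol is a plain list declaring everything needed to generate
#' and analyse one umbrella-sampling study: the ground-truth model, the
#' window ladder (restraint centres, shared force constant), the
#' temperature and ionic-strength grids, per-window sample count, WHAM and
#' feature-location settings, and the baseline range.
#'
#' The two presets mirror the emulated protocol: nine temperatures
#' (273--373 K), five ionic strengths (0--2 mol/dm^3), force constant
#' 2 kcal mol^-1 A^-2 and 50,000 samples per window. The hexane-like preset
#' uses the 11-window ladder 4.0, 5.0, ..., 14.0 A, a contact-minimum-only
#' model and baseline 12--13.5 A; the adamantane-like preset uses the
#' 24-window ladder (4.0--18.0 A, dense 0.5 A spacing through the barrier
#' region), a model with CM, DM and SSM, and baseline 14--15.4 A. Ground
#' truth depth laws are chosen to reproduce the qualitative thermodynamics
#' of hydrophobic association: CM deepening with temperature and with salt,
#' positive excess energy and entropy and negative excess heat capacity at
#' 298 K (about -40 cal mol^-1 K^-1 hexane-like, -20 adamantane-like).
#'
#' @param model a \linkS4class{ModelPotential}
#' @param ladder restraint centres d0, Angstrom
#' @param k force constant shared by all windows, kcal mol^-1 A^-2
#' @param temperatures K
#' @param ionicStrengths mol/dm^3
#' @param nSamples retained samples per window
#' @param baselineRange closed range averaged to zero, Angstrom
#' @param binWidth histogram bin width, Angstrom
#' @param range histogram range; `NULL` = `min(d0) - 1` to `max(d0) + 2`
#' @param thin sampler thinning stride
#' @param biasConvention see [biasEnergy()]
#' @param referenceT temperature for the reported thermodynamic state, K
#' @param nBoot bootstrap replicates for PMF uncertainties (0 = off)
#' @param blockLen moving-block bootstrap block length, samples
#' @param whamTol,whamMaxIter WHAM convergence settings
#' @param smoothWindow,minProminence feature-location settings
#' @param name protocol label
#' @return a protocol list
#' @seealso [generateStudy()], [runPipeline()]
#' @export
studyProtocol <- function(model, ladder, k = 2,
                          temperatures = c(273, 285, 298, 310, 323, 335,
                                           348, 360, 373),
                          ionicStrengths = c(0, 0.4, 1, 1.5, 2),
                          nSamples = 50000L, baselineRange,
                          binWidth = 0.1, range = NULL, thin = 5L,
                          biasConvention = c("k_sq", "half_k_sq"),
                          referenceT = 298, nBoot = 0L, blockLen = 100L,
                          whamTol = 1e-7, whamMaxIter = 100000L,
                          smoothWindow = 3L, minProminence = 0.05,
                          name = "custom") {
  biasConvention <- match.arg(biasConvention)
  stopifnot(is(model, "ModelPotential"), length(ladder) >= 1,
            all(ladder > 0), k >= 0, length(baselineRange) == 2L)
  list(name = name, model = model, ladder = as.numeric(ladder),
       k = as.numeric(k), temperatures = as.numeric(temperatures),
       ionicStrengths = as.numeric(ionicStrengths),
       nSamples = as.integer(nSamples),
       baselineRange = as.numeric(baselineRange),
       binWidth = as.numeric(binWidth),
       range = if (is.null(range)) NULL else as.numeric(range),
       thin = as.integer(thin), biasConvention = biasConvention,
       referenceT = as.numeric(referenceT), nBoot = as.integer(nBoot),
       blockLen = as.integer(blockLen), whamTol = as.numeric(whamTol),
       whamMaxIter = as.integer(whamMaxIter),
       smoothWindow = as.integer(smoothWindow),
       minProminence = as.numeric(minProminence))
}

#' @rdname studyProtocol
#' @param ... overrides passed on to [studyProtocol()]
#' @export
hexanePreset <- function(...) {
  model <- ModelPotential(
    cmPos = 5.5, cmWidth = 0.6,
    wallPos = 3.0, wallScale = 1.3,
    depthTQuad = c(8.0, -0.052, 6.7e-5), depthISSlope = -0.15)
  args <- list(model = model, ladder = seq(4, 14, by = 1), k = 2,
               baselineRange = c(12, 13.5), name = "hexane-like")
  over <- list(...)
  do.call(studyProtocol, utils::modifyList(args, over))
}

#' @rdname studyProtocol
#' @export
adamantanePreset <- function(...) {
  model <- ModelPotential(
    cmPos = 6.5, cmWidth = 0.6,
    dmPos = 8.0, dmHeight = 0.6, dmWidth = 0.5,
    ssmPos = 9.8, ssmDepth = -0.35, ssmWidth = 0.6,
    wallPos = 3.8, wallScale = 1.5,
    depthTQuad = c(4.0, -0.0301, 3.36e-5), depthISSlope = -0.10)
  args <- list(model = model,
               ladder = c(4, 5, seq(6, 15, by = 0.5), 16, 17, 18), k = 2,
               baselineRange = c(14, 15.4), name = "adamantane-like")
  over <- list(...)
  do.call(studyProtocol, utils::modifyList(args, over))
}

.protocolWindows <- function(protocol) {
  lapply(seq_along(protocol$ladder), function(i)
    WindowSpec(d0 = protocol$ladder[i], k = protocol$k,
               label = sprintf("w%02d", i)))
}

.protocolConditions <- function(protocol) {
  grid <- expand.grid(temperature = protocol$temperatures,
                      ionicStrength = protocol$ionicStrengths,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    Condition(grid$temperature[i], grid$ionicStrength[i]))
}

.cellKey <- function(temperature, ionicStrength, label = NULL) {
  base <- sprintf("T%g_IS%g", temperature, ionicStrength)
  if (is.null(label)) base else paste(base, label, sep = "_")
}

## Deterministic per-series seed from the master seed; kept inside 32-bit
## integer range (R seeds are 32-bit).
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(index)) %% 2147483647L)
}

#' Generate a complete synthetic umbrella-sampling study
#'
#' Samples every (window, temperature, ionic strength) cell of the
#' protocol's grid with [sampleWindow()], deriving one deterministic seed
#' per series from the master seed. The result is a pure function of
#' (protocol, seed).
#'
#' @param protocol a protocol list, see [studyProtocol()]
#' @param seed master integer seed
#' @return a \linkS4class{StudyDataset}
#' @examples
#' p <- hexanePreset(temperatures = c(288, 298), ionicStrengths = 0,
#'                   nSamples = 200)
#' generateStudy(p, seed = 1)
#' @export
generateStudy <- function(protocol, seed) {
  if (anyDuplicated(protocol$ladder))
    stop("generateStudy: duplicated restraint centres in the ladder")
  condKeys <- paste(rep(protocol$temperatures,
                        times = length(protocol$ionicStrengths)),
                    rep(protocol$ionicStrengths,
                        each = length(protocol$temperatures)))
  if (anyDuplicated(condKeys))
    stop("generateStudy: duplicated (temperature, ionic strength) conditions")

  windows <- .protocolWindows(protocol)
  conditions <- .protocolConditions(protocol)
  series <- vector("list", length(windows) * length(conditions))
  keys <- character(length(series))
  idx <- 0L
  for (cond in conditions) {
    for (w in windows) {
      idx <- idx + 1L
      series[[idx]] <- sampleWindow(
        protocol$model, w, cond, nSamples = protocol$nSamples,
        seed = .deriveSeed(seed, idx), thin = protocol$thin,
        biasConvention = protocol$biasConvention)
      keys[idx] <- .cellKey(cond@temperature, cond@ionicStrength, w@label)
    }
  }
  names(series) <- keys
  new("StudyDataset", series = series, groundTruth = protocol$model,
      protocol = protocol, seed = as.integer(seed))
}
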