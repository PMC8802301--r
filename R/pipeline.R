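#' Run the full analysis pipeline over a study grid
#'
#' Orchestrates generate (or load) -> histogram -> WHAM -> baseline ->
#' feature location for every (temperature, ionic strength) cell, then the
#' thermodynamic stage: a quadratic temperature fit per ionic strength with
#' the derived state at the reference temperature, and a linear ionic-
#' strength fit per temperature. A failure in one cell (for example
#' unconverged WHAM or a missing series file) is recorded in the status
#' table without aborting the rest of the grid.
#'
#' @param config a protocol list (see [studyProtocol()]) or the path to a
#'   YAML study configuration (see [readStudyConfig()])
#' @param seed master integer seed (used only in synthetic mode)
#' @param mode `"synthetic"` generates the series from the protocol's
#'   ground-truth model; `"from-files"` reads one series file per
#'   (window, condition) cell from `seriesDir`
#' @param seriesDir directory of series files for `"from-files"` mode,
#'   named as written by [writeStudySeries()]
#' @param verbose emit one status line per stage per cell
#' @return a \linkS4class{StudyReport}
#' @examples
#' p <- hexanePreset(temperatures = c(278, 298, 318), ionicStrengths = 0,
#'                   nSamples = 2000)
#' rep <- runPipeline(p, seed = 7)
#' featureTable(rep)
#' @export
runPipeline <- function(config, seed = 1L,
                        mode = c("synthetic", "from-files"),
                        seriesDir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  protocol <- if (is.character(config)) readStudyConfig(config) else config
  if (!is.list(protocol) || is.null(protocol$ladder) ||
      is.null(protocol$model))
    stop("runPipeline: malformed config: need at least 'model' and 'ladder'")
  say <- function(...) if (verbose) message(sprintf(...))

  windows <- .protocolWindows(protocol)
  conditions <- .protocolConditions(protocol)

  seriesByKey <- NULL
  if (mode == "synthetic") {
    dataset <- generateStudy(protocol, seed)
    seriesByKey <- dataset@series
  } else {
    if (is.null(seriesDir))
      stop("runPipeline: 'seriesDir' is required in from-files mode")
  }

  profileList <- list()
  featRows <- list()
  statRows <- list()
  for (cond in conditions) {
    key <- .cellKey(cond@temperature, cond@ionicStrength)
    cellSeries <- vector("list", length(windows))
    res <- tryCatch({
      for (i in seq_along(windows)) {
        skey <- .cellKey(cond@temperature, cond@ionicStrength,
                         windows[[i]]@label)
        cellSeries[[i]] <- if (mode == "synthetic") seriesByKey[[skey]]
        else {
          f <- file.path(seriesDir, paste0(skey, ".dat"))
          if (!file.exists(f)) stop("missing series file: ", f)
          readSeriesFile(f)
        }
      }
      pmf <- if (protocol$nBoot > 0L) {
        bootstrapPMF(cellSeries, binWidth = protocol$binWidth,
                     range = protocol$range, nBoot = protocol$nBoot,
                     blockLen = protocol$blockLen,
                     seed = .deriveSeed(seed, 999983L + length(statRows)),
                     baselineRange = protocol$baselineRange,
                     tol = protocol$whamTol, maxIter = protocol$whamMaxIter,
                     biasConvention = protocol$biasConvention)
      } else {
        h <- buildHistograms(cellSeries, binWidth = protocol$binWidth,
                             range = protocol$range)
        p0 <- whamSolve(h, tol = protocol$whamTol,
                        maxIter = protocol$whamMaxIter,
                        biasConvention = protocol$biasConvention)
        subtractBaseline(p0, protocol$baselineRange)
      }
      feat <- findExtrema(pmf, smoothWindow = protocol$smoothWindow,
                          minProminence = protocol$minProminence)
      list(pmf = pmf, feat = feat)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      say("[%s] FAILED: %s", key, conditionMessage(res))
      statRows[[key]] <- data.frame(
        T_K = cond@temperature, IS_M = cond@ionicStrength, stage = "pmf",
        ok = FALSE, message = conditionMessage(res))
      next
    }
    pmf <- res$pmf; feat <- res$feat
    profileList[[key]] <- pmf
    cmErr <- NA_real_
    if (length(pmf@Ferr)) {
      iCM <- which.min(abs(pmf@binCenters - feat@cmPos))
      cmErr <- pmf@Ferr[iCM]
    }
    featRows[[key]] <- data.frame(
      T_K = cond@temperature, IS_M = cond@ionicStrength,
      cm_pos = feat@cmPos, cm_depth = feat@cmDepth, cm_depth_err = cmErr,
      dm_pos = feat@dmPos, dm_height = feat@dmHeight,
      ssm_pos = feat@ssmPos, ssm_depth = feat@ssmDepth)
    statRows[[key]] <- data.frame(
      T_K = cond@temperature, IS_M = cond@ionicStrength, stage = "pmf",
      ok = TRUE,
      message = sprintf("wham %d iterations, converged=%s, CM %.2f A",
                        pmf@iterations, pmf@converged, feat@cmPos))
    say("[%s] wham %d it (converged=%s), CM at %.2f A depth %.3f",
        key, pmf@iterations, pmf@converged, feat@cmPos, feat@cmDepth)
  }
  features <- if (length(featRows)) do.call(rbind, c(featRows,
                                                     make.row.names = FALSE))
  else data.frame()

  ## thermodynamic stage
  thermoFitsL <- list(); thermoStatesL <- list(); ionicFitsL <- list()
  if (nrow(features) == 0L) {
    statRows[["thermo"]] <- data.frame(
      T_K = NA_real_, IS_M = NA_real_, stage = "thermo", ok = FALSE,
      message = "no features to fit")
  } else {
    useSigma <- all(!is.na(features$cm_depth_err)) &&
      all(features$cm_depth_err > 0)
    if (length(unique(features$T_K)) >= 3L) {
      for (isv in sort(unique(features$IS_M))) {
        sub <- features[features$IS_M == isv, ]
        fit <- fitFreeEnergyVsTemperature(
          sub$T_K, sub$cm_depth,
          sigma = if (useSigma) sub$cm_depth_err else NULL,
          ionicStrength = isv)
        k <- sprintf("IS%g", isv)
        thermoFitsL[[k]] <- fit
        thermoStatesL[[k]] <- thermoState(fit, protocol$referenceT)
      }
      statRows[["thermoT"]] <- data.frame(
        T_K = NA_real_, IS_M = NA_real_, stage = "thermo", ok = TRUE,
        message = sprintf("quadratic dF(T) fits at %d ionic strengths",
                          length(thermoFitsL)))
    } else {
      statRows[["thermoT"]] <- data.frame(
        T_K = NA_real_, IS_M = NA_real_, stage = "thermo", ok = TRUE,
        message = "insufficient temperatures for the quadratic fit (need >= 3); PMFs and features still emitted")
      say("thermo stage skipped: insufficient temperatures")
    }
    if (length(unique(features$IS_M)) >= 2L) {
      for (tv in sort(unique(features$T_K))) {
        sub <- features[features$T_K == tv, ]
        ionicFitsL[[sprintf("T%g", tv)]] <- fitFreeEnergyVsIonicStrength(
          sub$IS_M, sub$cm_depth,
          sigma = if (useSigma) sub$cm_depth_err else NULL,
          temperature = tv)
      }
    }
  }

  status <- do.call(rbind, c(statRows, make.row.names = FALSE))
  new("StudyReport", profiles = profileList, features = features,
      thermoFits = thermoFitsL, thermoStates = thermoStatesL,
      ionicFits = ionicFitsL, status = status,
      protocol = protocol, seed = as.integer(seed),
      version = as.character(utils::packageVersion("hydrotherm")))
}

#' Read a YAML study configuration
#'
#' A single declarative file describing a study. An optional top-level
#' `preset:` ("hexane" or "adamantane") supplies defaults; the sections
#' `model`, `ladder`, `conditions`, `sampling`, `wham`, `features`,
#' `thermo` and `io` override individual values.
#'
#' @param path YAML file path
#' @return a protocol list, see [studyProtocol()]
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("readStudyConfig: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("readStudyConfig: malformed config file")

  args <- list()
  if (!is.null(cfg$model)) {
    m <- cfg$model
    args$model <- ModelPotential(
      cmPos = m$cm_pos,
      depthTQuad = as.numeric(unlist(m$depth_t_quad)),
      depthISSlope = if (is.null(m$depth_is_slope)) 0 else m$depth_is_slope,
      cmWidth = if (is.null(m$cm_width)) 0.6 else m$cm_width,
      dmPos = if (is.null(m$dm_pos)) NA_real_ else m$dm_pos,
      dmHeight = if (is.null(m$dm_height)) NA_real_ else m$dm_height,
      dmWidth = if (is.null(m$dm_width)) 0.5 else m$dm_width,
      ssmPos = if (is.null(m$ssm_pos)) NA_real_ else m$ssm_pos,
      ssmDepth = if (is.null(m$ssm_depth)) NA_real_ else m$ssm_depth,
      ssmWidth = if (is.null(m$ssm_width)) 0.6 else m$ssm_width,
      wallPos = if (is.null(m$wall_pos)) m$cm_pos - 2.5 else m$wall_pos,
      wallScale = if (is.null(m$wall_scale)) 1.3 else m$wall_scale)
  }
  grab <- function(section, key, target) {
    v <- cfg[[section]][[key]]
    if (!is.null(v)) args[[target]] <<- if (length(v) > 1L)
      as.numeric(unlist(v)) else v
  }
  grab("ladder", "d0", "ladder")
  grab("ladder", "k", "k")
  grab("conditions", "temperatures", "temperatures")
  grab("conditions", "ionic_strengths", "ionicStrengths")
  grab("sampling", "n_samples", "nSamples")
  grab("sampling", "thin", "thin")
  grab("sampling", "bias_convention", "biasConvention")
  grab("wham", "bin_width", "binWidth")
  grab("wham", "range", "range")
  grab("wham", "tol", "whamTol")
  grab("wham", "max_iter", "whamMaxIter")
  grab("wham", "n_boot", "nBoot")
  grab("wham", "block_len", "blockLen")
  grab("features", "smooth_window", "smoothWindow")
  grab("features", "min_prominence", "minProminence")
  grab("thermo", "reference_t", "referenceT")
  grab("io", "baseline_range", "baselineRange")

  if (!is.null(cfg$preset)) {
    preset <- match.arg(cfg$preset, c("hexane", "adamantane"))
    fn <- if (preset == "hexane") hexanePreset else adamantanePreset
    do.call(fn, args)
  } else {
    if (is.null(args$model) || is.null(args$ladder) ||
        is.null(args$baselineRange))
      stop("readStudyConfig: without 'preset', the config must declare ",
           "'model', 'ladder' and io 'baseline_range'")
    do.call(studyProtocol, args)
  }
}
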