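.tsvNum <- function(x) ifelse(is.na(x), "", formatC(x, digits = 10,
                                                    format = "g"))

#' Write a PMF profile as TSV
#'
#' Columns `xi_A  F_kcal_mol  F_err_kcal_mol  n_counts`, preceded by `#`
#' metadata lines (condition, baseline range, convergence). Undefined bins
#' have empty F fields.
#'
#' @param pmf a \linkS4class{PMFProfile}
#' @param path output file
#' @return `path`, invisibly
#' @export
writePMFTable <- function(pmf, path) {
  stopifnot(is(pmf, "PMFProfile"))
  err <- if (length(pmf@Ferr)) pmf@Ferr else rep(NA_real_,
                                                 length(pmf@binCenters))
  hdr <- c(sprintf("# T_K: %g", pmf@condition@temperature),
           sprintf("# IS_M: %g", pmf@condition@ionicStrength),
           sprintf("# baseline_range_A: %g %g", pmf@baselineRange[1],
                   pmf@baselineRange[2]),
           sprintf("# converged: %s (%d iterations)", pmf@converged,
                   pmf@iterations),
           paste("xi_A", "F_kcal_mol", "F_err_kcal_mol", "n_counts",
                 sep = "\t"))
  body <- paste(.tsvNum(pmf@binCenters), .tsvNum(pmf@F), .tsvNum(err),
                .tsvNum(pmf@counts), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the per-condition feature table as TSV
#'
#' Columns `T_K IS_M cm_pos cm_depth cm_depth_err dm_pos dm_height
#' ssm_pos ssm_depth`; absent features leave empty fields.
#'
#' @param features the feature `data.frame` of a \linkS4class{StudyReport}
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFeatureTable <- function(features, path) {
  cols <- c("T_K", "IS_M", "cm_pos", "cm_depth", "cm_depth_err",
            "dm_pos", "dm_height", "ssm_pos", "ssm_depth")
  lines <- paste(cols, collapse = "\t")
  if (nrow(features)) {
    body <- apply(features[, cols], 1L,
                  function(r) paste(.tsvNum(as.numeric(r)), collapse = "\t"))
    lines <- c(lines, unname(body))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the thermodynamic tables of a report
#'
#' `thermo_by_IS.tsv` has one row per ionic strength: the quadratic
#' coefficients (a, b, c), the reference-temperature state (dF, dU, dS in
#' kcal-based units, dCv in cal mol^-1 K^-1) and the propagated errors.
#' `thermo_vs_T.tsv` tabulates dF, dU and -T*dS against temperature per
#' ionic strength. `ionic_fits.tsv` has one row per temperature with the
#' linear ionic-strength fit.
#'
#' @param report a \linkS4class{StudyReport}
#' @param dir output directory (created if needed)
#' @return the written paths, invisibly
#' @export
writeThermoTables <- function(report, dir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refT <- report@protocol$referenceT

  p1 <- file.path(dir, "thermo_by_IS.tsv")
  rows <- paste(c("IS_M", "a", "b", "c",
                  sprintf(c("dF%g", "dU%g", "dS%g", "dCv%g"), refT),
                  "err_a", "err_b", "err_c",
                  sprintf(c("err_dF%g", "err_dU%g", "err_dS%g", "err_dCv%g"),
                          refT)), collapse = "\t")
  for (k in names(report@thermoFits)) {
    fit <- report@thermoFits[[k]]
    st <- report@thermoStates[[k]]
    se <- sqrt(pmax(0, diag(fit@cov)))
    rows <- c(rows, paste(.tsvNum(c(fit@conditionIS, fit@coef,
                                    st@dF, st@dU, st@dS, st@dCv, se,
                                    st@dFerr, st@dUerr, st@dSerr,
                                    st@dCverr)), collapse = "\t"))
  }
  writeLines(rows, p1)

  p2 <- file.path(dir, "thermo_vs_T.tsv")
  rows <- paste(c("IS_M", "T_K", "dF", "dU", "minus_TdS"), collapse = "\t")
  for (k in names(report@thermoFits)) {
    fit <- report@thermoFits[[k]]
    for (tv in sort(unique(report@features$T_K))) {
      st <- thermoState(fit, tv)
      rows <- c(rows, paste(.tsvNum(c(fit@conditionIS, tv, st@dF, st@dU,
                                      -tv * st@dS)), collapse = "\t"))
    }
  }
  writeLines(rows, p2)

  p3 <- file.path(dir, "ionic_fits.tsv")
  rows <- paste(c("T_K", "intercept", "slope", "err_intercept",
                  "err_slope"), collapse = "\t")
  for (k in names(report@ionicFits)) {
    fit <- report@ionicFits[[k]]
    se <- sqrt(pmax(0, diag(fit@cov)))
    rows <- c(rows, paste(.tsvNum(c(fit@conditionT, fit@intercept,
                                    fit@slope, se)), collapse = "\t"))
  }
  writeLines(rows, p3)
  invisible(c(p1, p2, p3))
}

#' Write every table of a study report
#'
#' PMF TSVs (one per condition, `pmf_T<K>_IS<M>.tsv`), the feature table,
#' the thermodynamic tables and the status log.
#'
#' @param report a \linkS4class{StudyReport}
#' @param dir output directory
#' @return the written paths, invisibly
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in names(report@profiles)) {
    p <- file.path(dir, sprintf("pmf_%s.tsv", k))
    writePMFTable(report@profiles[[k]], p)
    paths <- c(paths, p)
  }
  fp <- file.path(dir, "features.tsv")
  writeFeatureTable(report@features, fp)
  paths <- c(paths, fp, writeThermoTables(report, dir))
  sp <- file.path(dir, "status.tsv")
  utils::write.table(report@status, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sp))
}
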