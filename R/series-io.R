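## Plain-text window series format: '#' header lines carrying the window
## and condition metadata, then two whitespace-separated columns
## time_ps  distance_A. Values are printed with 17 significant digits so a
## write/read round trip is exact.

.seriesHeaderKeys <- c("d0_A", "k_kcal_mol_A2", "T_K", "IS_M")

#' Read and write window series files
#'
#' One file per umbrella window: header lines `# key: value` declaring
#' `d0_A`, `k_kcal_mol_A2`, `T_K`, `IS_M` (plus optional `label` and
#' `seed`), followed by two whitespace-delimited numeric columns,
#' `time_ps` and `distance_A`. Writing then reading reproduces the series
#' exactly.
#'
#' @param series a \linkS4class{ReactionCoordinateSeries}
#' @param path file path
#' @return `readSeriesFile()` returns a
#'   \linkS4class{ReactionCoordinateSeries}; `writeSeriesFile()` returns
#'   `path` invisibly.
#' @examples
#' s <- ReactionCoordinateSeries(WindowSpec(4, 2), Condition(298),
#'                               xi = c(4.1, 3.9, 4.0))
#' f <- tempfile(fileext = ".dat")
#' writeSeriesFile(s, f)
#' readSeriesFile(f)
#' @export
writeSeriesFile <- function(series, path) {
  stopifnot(is(series, "ReactionCoordinateSeries"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- c(
    sprintf("# label: %s", series@window@label),
    sprintf("# d0_A: %s", num(series@window@d0)),
    sprintf("# k_kcal_mol_A2: %s", num(series@window@k)),
    sprintf("# T_K: %s", num(series@condition@temperature)),
    sprintf("# IS_M: %s", num(series@condition@ionicStrength)),
    sprintf("# seed: %s", series@seed),
    "# time_ps  distance_A")
  body <- paste(num(series@times), num(series@xi), sep = "  ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeSeriesFile
#' @export
readSeriesFile <- function(path) {
  if (!file.exists(path)) stop("readSeriesFile: no such file: ", path)
  lines <- readLines(path)
  isHdr <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[isHdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  missing <- setdiff(.seriesHeaderKeys, names(meta))
  if (length(missing))
    stop("readSeriesFile: missing header key(s): ",
         paste(missing, collapse = ", "))

  dataLineNo <- which(!isHdr & nzchar(trimws(lines)))
  times <- xi <- numeric(length(dataLineNo))
  for (i in seq_along(dataLineNo)) {
    fields <- strsplit(trimws(lines[dataLineNo[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals))
      stop("readSeriesFile: non-numeric data row at line ", dataLineNo[i],
           " of ", path)
    times[i] <- vals[1]; xi[i] <- vals[2]
  }
  window <- WindowSpec(d0 = as.numeric(meta$d0_A),
                       k = as.numeric(meta$k_kcal_mol_A2),
                       label = if (is.null(meta$label)) NA_character_
                               else meta$label)
  cond <- Condition(as.numeric(meta$T_K), as.numeric(meta$IS_M))
  seed <- if (is.null(meta$seed)) NA_integer_ else
    suppressWarnings(as.integer(meta$seed))
  ReactionCoordinateSeries(window = window, condition = cond,
                           xi = xi, times = times, seed = seed)
}

#' Write every series of a study to a directory
#'
#' One file per (window, condition) cell, named
#' `T<K>_IS<M>_<label>.dat`.
#'
#' @param dataset a \linkS4class{StudyDataset}
#' @param dir output directory (created if needed)
#' @return the file paths, invisibly
#' @export
writeStudySeries <- function(dataset, dir) {
  stopifnot(is(dataset, "StudyDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(dataset@series), ".dat"))
  for (i in seq_along(paths))
    writeSeriesFile(dataset@series[[i]], paths[i])
  invisible(paths)
}
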