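## Reading and writing ECG records, beat annotations and metric tables.

#' Construct an ECG record
#'
#' @param voltages samples x leads numeric matrix in nV, columns named with
#'   standard 12-lead names (aliases L/R/F accepted).
#' @param samplingRate sampling rate in Hz (> 260).
#' @param subjectId subject identifier.
#' @param groupLabel `"control"`, `"patient"` or `NA`.
#' @return an [ECGRecord-class].
#' @examples
#' v <- cbind(II = sin(1:1000 / 50), V6 = cos(1:1000 / 50)) * 1e6
#' ecgRecord(v, 1000, subjectId = "demo")
#' @export
ecgRecord <- function(voltages, samplingRate, subjectId = "",
                      groupLabel = NA_character_) {
  voltages <- as.matrix(voltages)
  storage.mode(voltages) <- "double"
  colnames(voltages) <- normalizeLeadNames(colnames(voltages))
  new("ECGRecord", voltages = voltages, samplingRate = samplingRate,
      subjectId = subjectId, groupLabel = groupLabel)
}

#' Construct a beat annotation
#'
#' @param beats strictly increasing 1-based R-peak sample indices.
#' @param source free-text provenance.
#' @return a [BeatAnnotation-class].
#' @export
beatAnnotation <- function(beats, source = "") {
  new("BeatAnnotation", beats = as.integer(beats), source = source)
}

#' Read a plain delimited multi-lead ECG record
#'
#' One numeric column per lead, comma- or tab-separated, optional header
#' row of lead names. The neutral stand-in for sensor export formats.
#'
#' @param path file path.
#' @param samplingRate sampling rate in Hz.
#' @param leadNames lead names; taken from the header row when `NULL`.
#' @param unitScale multiplier taking file values to nV (e.g. `1e6` for a
#'   file in mV).
#' @param subjectId,groupLabel forwarded to the record.
#' @return an [ECGRecord-class].
#' @export
readDelimitedRecord <- function(path, samplingRate, leadNames = NULL,
                                unitScale = 1, subjectId = "",
                                groupLabel = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty record file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncols <- length(cells[[1]])
  firstRow <- 1L
  first <- suppressWarnings(as.numeric(cells[[1]]))
  if (anyNA(first)) {          # header row of lead names
    if (is.null(leadNames))
      leadNames <- gsub("^\"|\"$", "", trimws(cells[[1]]))
    firstRow <- 2L
  }
  if (is.null(leadNames))
    stop("leadNames must be given when the file has no header row")
  rows <- cells[firstRow:length(cells)]
  if (any(lengths(rows) != ncols))
    stop("ragged rows: data row ",
         which(lengths(rows) != ncols)[1], " has ",
         lengths(rows)[lengths(rows) != ncols][1], " cells, expected ", ncols)
  m <- suppressWarnings(matrix(as.numeric(unlist(rows, use.names = FALSE)),
                               ncol = ncols, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("non-numeric value in data row ", bad, " of ", path)
  }
  colnames(m) <- normalizeLeadNames(leadNames)
  ecgRecord(m * unitScale, samplingRate, subjectId = subjectId,
            groupLabel = groupLabel)
}

#' Write a record as delimited text
#'
#' @param record an [ECGRecord-class].
#' @param path output file.
#' @param unitScale divisor taking internal nV values to the file unit
#'   (default 1: file stays in nV).
#' @param sep field separator.
#' @export
writeDelimitedRecord <- function(record, path, unitScale = 1, sep = ",") {
  v <- voltages(record) / unitScale
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(v), collapse = sep), con)
  write.table(format(v, digits = 15, scientific = FALSE, trim = TRUE),
              con, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a beat annotation from one-index-per-line text
#'
#' @param path text file with one 1-based sample index per line; `#`
#'   comment lines are ignored.
#' @return a [BeatAnnotation-class].
#' @export
readBeatAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  idx <- suppressWarnings(as.integer(lines))
  if (anyNA(idx)) stop("non-integer beat index in ", path)
  beatAnnotation(idx, source = path)
}

#' Write a beat annotation as one-index-per-line text
#'
#' @param annotation a [BeatAnnotation-class].
#' @param path output file.
#' @export
writeBeatAnnotation <- function(annotation, path) {
  writeLines(as.character(beatTimes(annotation)), path)
  invisible(path)
}

#' Write a per-subject (or per-beat) metrics table
#'
#' Plain CSV with a header row; numeric cells carry enough digits to
#' round-trip losslessly at 12 significant figures.
#'
#' @param rows data.frame of metric rows sharing one schema.
#' @param path output file.
#' @export
writeMetricsTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.12g", out[[j]])
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write metrics table to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read back a metrics table written by [writeMetricsTable()]
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readMetricsTable <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
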