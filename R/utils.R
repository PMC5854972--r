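## Internal helpers: lead-name normalization, logging, resampling.

#' Normalize lead names
#'
#' Maps the augmented-limb aliases L, R, F to aVL, aVR, aVF and validates
#' against the standard 12-lead set.
#'
#' @param leads character vector of lead names.
#' @return normalized character vector.
#' @export
normalizeLeadNames <- function(leads) {
  idx <- match(leads, names(.LEAD_ALIASES))
  leads[!is.na(idx)] <- .LEAD_ALIASES[idx[!is.na(idx)]]
  leads
}

## Minimal leveled logger. Messages go through message() so they can be
## suppressed or sinked; the pipeline additionally copies them to a file.
.logLevels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
.hfqrsEnv <- new.env(parent = emptyenv())
.hfqrsEnv$level <- "info"
.hfqrsEnv$logFile <- NULL

#' Set package log verbosity
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @param file optional path; log lines are appended there as well.
#' @return the previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warn", "quiet"),
                        file = NULL) {
  level <- match.arg(level)
  old <- .hfqrsEnv$level
  .hfqrsEnv$level <- level
  .hfqrsEnv$logFile <- file
  invisible(old)
}

hfLog <- function(level, ...) {
  if (.logLevels[[level]] < .logLevels[[.hfqrsEnv$level]]) return(invisible())
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (!is.null(.hfqrsEnv$logFile))
    cat(line, "\n", file = .hfqrsEnv$logFile, append = TRUE, sep = "")
  message(line)
  invisible()
}

#' Resample a record to 1 kHz
#'
#' The spectral analysis fixes a temporal definition of 1 kHz; records
#' acquired at other (integer) rates are polyphase-resampled. A no-op at
#' 1000 Hz.
#'
#' @param record an [ECGRecord-class].
#' @return an `ECGRecord` at 1000 Hz.
#' @export
resampleTo1kHz <- function(record) {
  fs <- samplingRate(record)
  if (fs == 1000) return(record)
  if (abs(fs - round(fs)) > 1e-9)
    stop("resampling requires an integer sampling rate, got ", fs)
  fs <- as.integer(round(fs))
  g <- .gcd(1000L, fs)
  p <- 1000L %/% g
  q <- fs %/% g
  hfLog("info", "resampling record '", subjectId(record), "' from ", fs,
        " Hz to 1000 Hz (x", p, "/", q, ")")
  v <- voltages(record)
  out <- vapply(seq_len(ncol(v)),
                function(j) signal::resample(v[, j], p, q),
                numeric(ceiling(nrow(v) * p / q)))
  colnames(out) <- colnames(v)
  new("ECGRecord", voltages = out, samplingRate = 1000,
      subjectId = record@subjectId, groupLabel = record@groupLabel)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Remove a mains interference component with a notch filter
#'
#' Zero-phase second-order Butterworth band-stop around the mains
#' frequency, applied to every lead. The acquisition chain this package
#' targets notches 50 Hz; records from other grids can pass 60.
#'
#' @param record an [ECGRecord-class].
#' @param freqHz notch center (default 50).
#' @param bwHz stop-band width (default 4).
#' @return the filtered `ECGRecord`.
#' @export
applyNotchFilter <- function(record, freqHz = 50, bwHz = 4) {
  fs <- samplingRate(record)
  bf <- signal::butter(2, c(freqHz - bwHz / 2, freqHz + bwHz / 2) / (fs / 2),
                       type = "stop")
  v <- voltages(record)
  out <- apply(v, 2L, function(x) signal::filtfilt(bf$b, bf$a, x))
  colnames(out) <- colnames(v)
  new("ECGRecord", voltages = out, samplingRate = fs,
      subjectId = record@subjectId, groupLabel = record@groupLabel)
}

## Next power of two >= n
.nextPow2 <- function(n) 2L^ceiling(log2(n))
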