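## Minimal WFDB (PhysioNet) record I/O: header (.hea) parsing plus the
## 16-bit two's-complement signal format ("format 16"), which covers the
## fixtures this package needs. Gains are applied so voltages come out in
## nV; a writer is provided so tests can build round-trip fixtures.

#' Read a WFDB record (header + format-16 signal file)
#'
#' Parses `<record>.hea` and the referenced interleaved 16-bit
#' little-endian signal file. Sample values v with gain g (ADC units per
#' mV) and baseline b are converted as (v - b)/g mV = (v - b)/g * 1e6 nV.
#'
#' @param path record path with or without the `.hea` extension.
#' @param subjectId,groupLabel forwarded to the record; `subjectId`
#'   defaults to the WFDB record name.
#' @return an [ECGRecord-class].
#' @export
readWFDBRecord <- function(path, subjectId = NULL,
                           groupLabel = NA_character_) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea)
  lines <- trimws(readLines(hea, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("unparseable WFDB header (empty): ", hea)

  head <- strsplit(lines[[1]], "[ \t]+")[[1]]
  if (length(head) < 2L) stop("unparseable WFDB header line: ", lines[[1]])
  recName <- sub("/.*$", "", head[[1]])
  nsig <- suppressWarnings(as.integer(head[[2]]))
  if (is.na(nsig)) stop("unparseable signal count in ", hea)
  if (nsig < 1L) stop("WFDB record declares zero signals: ", hea)
  fs <- if (length(head) >= 3L)
    suppressWarnings(as.numeric(sub("/.*$", "", head[[3]]))) else 250
  nsamp <- if (length(head) >= 4L)
    suppressWarnings(as.integer(head[[4]])) else NA_integer_
  if (length(lines) < 1L + nsig)
    stop("WFDB header lists ", nsig, " signals but has too few lines: ", hea)

  sig <- lapply(lines[1L + seq_len(nsig)], .parseWFDBSignalLine, hea = hea)
  datFiles <- unique(vapply(sig, `[[`, "", "file"))
  if (length(datFiles) != 1L)
    stop("only single-file WFDB records are supported (", hea, ")")
  if (any(vapply(sig, `[[`, 0, "format") != 16))
    stop("unsupported WFDB signal format (only format 16 is supported): ", hea)

  dat <- file.path(dirname(hea), datFiles)
  if (!file.exists(dat)) stop("WFDB signal file missing: ", dat)
  raw <- readBin(dat, "integer", n = file.size(dat) %/% 2L, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) %% nsig != 0L)
    stop("WFDB signal file length is not a multiple of the signal count: ", dat)
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  if (!is.na(nsamp) && nrow(m) != nsamp)
    stop("WFDB sample count mismatch: header says ", nsamp, ", file has ",
         nrow(m))
  gains <- vapply(sig, `[[`, 0, "gain")
  base <- vapply(sig, `[[`, 0, "baseline")
  ## (adc - baseline)/gain is mV; internal unit is nV
  volts <- sweep(sweep(m, 2L, base, "-"), 2L, gains, "/") * 1e6
  colnames(volts) <- normalizeLeadNames(vapply(sig, `[[`, "", "name"))
  ecgRecord(volts, fs,
            subjectId = if (is.null(subjectId)) recName else subjectId,
            groupLabel = groupLabel)
}

.parseWFDBSignalLine <- function(line, hea) {
  f <- strsplit(line, "[ \t]+")[[1]]
  if (length(f) < 2L) stop("unparseable WFDB signal line in ", hea, ": ", line)
  fmt <- suppressWarnings(as.numeric(sub("[x:+].*$", "", f[[2]])))
  gainField <- if (length(f) >= 3L) f[[3]] else "200"
  gainStr <- sub("/.*$", "", gainField)          # strip units suffix
  baseline <- NA_real_
  if (grepl("\\(", gainStr)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainStr))
    gainStr <- sub("\\(.*$", "", gainStr)
  }
  gain <- suppressWarnings(as.numeric(gainStr))
  if (is.na(gain) || gain == 0) gain <- 200      # WFDB default gain
  adczero <- if (length(f) >= 5L)
    suppressWarnings(as.numeric(f[[5]])) else 0
  if (is.na(baseline)) baseline <- if (is.na(adczero)) 0 else adczero
  name <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else f[[1]]
  list(file = f[[1]], format = fmt, gain = gain, baseline = baseline,
       name = name)
}

#' Write a record as a WFDB header + format-16 signal pair
#'
#' Mainly fixture plumbing: quantizes to 16-bit ADC units with the given
#' gain and writes `<path>.hea` / `<path>.dat`.
#'
#' @param record an [ECGRecord-class].
#' @param path record path without extension.
#' @param adcGain ADC units per mV (default 200, the WFDB default).
#' @return `path`, invisibly.
#' @export
writeWFDBRecord <- function(record, path, adcGain = 200) {
  v <- voltages(record)
  mV <- v / 1e6
  adc <- round(mV * adcGain)
  if (any(abs(adc) > 32767))
    stop("record does not fit 16-bit ADC range at gain ", adcGain)
  rec <- basename(path)
  nsig <- ncol(v)
  hea <- c(paste(rec, nsig, samplingRate(record), nrow(v)),
           vapply(seq_len(nsig), function(j)
             paste(paste0(rec, ".dat"), 16, paste0(adcGain, "(0)/mV"),
                   16, 0, adc[1, j], 0, 0, colnames(v)[j]),
             character(1)))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(path)
}
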