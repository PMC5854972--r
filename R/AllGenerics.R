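#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor family: prefer these over direct slot access.
#'
#' @param x an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))
#' @rdname accessors
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))
#' @rdname accessors
#' @export
setGeneric("tMaxQRS", function(x) standardGeneric("tMaxQRS"))
#' @rdname accessors
#' @export
setGeneric("qrsIntervals", function(x) standardGeneric("qrsIntervals"))
#' @rdname accessors
#' @export
setGeneric("bandPower", function(x) standardGeneric("bandPower"))
#' @rdname accessors
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("timeMs", function(x) standardGeneric("timeMs"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' Extract one lead as a numeric vector
#'
#' @param x an [ECGRecord-class].
#' @param lead lead name (aliases L/R/F are accepted).
#' @return numeric vector of voltages in nV.
#' @export
setGeneric("getLead", function(x, lead) standardGeneric("getLead"))

setMethod("samplingRate", "ECGRecord", function(x) x@samplingRate)
setMethod("leadNames", "ECGRecord", function(x) colnames(x@voltages))
setMethod("nSamples", "ECGRecord", function(x) nrow(x@voltages))
setMethod("subjectId", "ECGRecord", function(x) x@subjectId)
setMethod("groupLabel", "ECGRecord", function(x) x@groupLabel)
setMethod("voltages", "ECGRecord", function(x) x@voltages)
setMethod("getLead", "ECGRecord", function(x, lead) {
  lead <- normalizeLeadNames(lead)
  if (!lead %in% colnames(x@voltages))
    stop("lead '", lead, "' not present in record (has: ",
         paste(colnames(x@voltages), collapse = ", "), ")")
  x@voltages[, lead]
})

setMethod("beatTimes", "BeatAnnotation", function(x) x@beats)
setMethod("nBeats", "BeatAnnotation", function(x) length(x@beats))

setMethod("tMaxQRS", "DetectionResult", function(x) x@tMax)
setMethod("qrsIntervals", "DetectionResult", function(x) x@intervals)
setMethod("nBeats", "DetectionResult", function(x) length(x@tMax))

setMethod("nBeats", "QRSWindowSet", function(x) dim(x@windows)[3])
setMethod("timeMs", "QRSWindowSet", function(x) x@timeMs)
setMethod("tMaxQRS", "QRSWindowSet", function(x) x@tMax)
setMethod("leadNames", "QRSWindowSet", function(x) dimnames(x@windows)[[2]])
setMethod("subjectId", "QRSWindowSet", function(x) x@subjectId)

#' @describeIn QRSWindowSet-class extract one window as a samples x leads
#'   matrix.
#' @param x a `QRSWindowSet`.
#' @param i window (beat) index.
#' @export
setMethod("[[", "QRSWindowSet", function(x, i) {
  x@windows[, , i, drop = TRUE]
})

setMethod("bandPower", "WaveletSpectrum", function(x) x@power)
setMethod("scales", "WaveletSpectrum", function(x) x@scales)
setMethod("frequencies", "WaveletSpectrum", function(x) x@frequencies)
setMethod("timeMs", "WaveletSpectrum", function(x) x@timeMs)

setMethod("seriesValues", "HFPowerSeries", function(x) x@values)
setMethod("timeMs", "HFPowerSeries", function(x) x@timeMs)
setMethod("seriesValues", "IntensitySeries", function(x) x@values)
setMethod("timeMs", "IntensitySeries", function(x) x@timeMs)

setMethod("nBeats", "LabeledCohort", function(x) length(x@records))

setMethod("show", "ECGRecord", function(object) {
  cat("ECGRecord:", ncol(object@voltages), "lead(s) x",
      nrow(object@voltages), "samples @", object@samplingRate, "Hz",
      sprintf("(%.1f s)\n", nrow(object@voltages) / object@samplingRate))
  cat("  leads:", paste(colnames(object@voltages), collapse = " "), "\n")
  if (nzchar(object@subjectId)) cat("  subject:", object@subjectId,
    if (!is.na(object@groupLabel)) paste0("[", object@groupLabel, "]"), "\n")
})

setMethod("show", "BeatAnnotation", function(object) {
  cat("BeatAnnotation:", length(object@beats), "beat(s)")
  if (nzchar(object@source)) cat(" from", object@source)
  cat("\n")
})

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult:", length(object@tMax), "QRS complex(es)",
      "detected on lead", object@detectionLead, "\n")
})

setMethod("show", "QRSWindowSet", function(object) {
  d <- dim(object@windows)
  cat("QRSWindowSet:", d[3], "window(s) of", d[1], "samples x", d[2],
      "lead(s); tMaxQRS at", object@timeMs[which(object@timeMs == 60)][1],
      "ms\n")
})

setMethod("show", "WaveletSpectrum", function(object) {
  cat("WaveletSpectrum:", nrow(object@power), "epochs x",
      ncol(object@power), "scales;",
      sprintf("%.1f-%.1f Hz\n", min(object@frequencies), max(object@frequencies)))
})

setMethod("show", "SynthesisConfig", function(object) {
  cat("SynthesisConfig:", object@nBeats, "beats @", object@heartRateBpm,
      "bpm,", object@fs, "Hz\n")
  cat(sprintf("  QRS %g nV (FWHM %g ms); HF burst %g nV @ %g Hz, %+g ms; noise %g nV RMS\n",
              object@qrsAmplitude, object@qrsWidthMs, object@hfAmplitude,
              object@hfFrequencyHz, object@hfOffsetMs, object@noiseRms))
})

setMethod("show", "LabeledCohort", function(object) {
  cat("LabeledCohort:", sum(object@labels == "control"), "control(s) +",
      sum(object@labels == "patient"), "patient(s)\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary (alpha =", object@alpha,
      if (object@varEqual) ", pooled t-test)\n" else ", Welch t-test)\n")
  print(formatCohortTable(object), row.names = FALSE)
})
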