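#' @import methods
NULL

## Canonical 12-lead names (augmented-limb leads may arrive as L/R/F).
.STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")
.LEAD_ALIASES <- c(L = "aVL", R = "aVR", F = "aVF")

#' Multi-lead ECG record
#'
#' Holds a multi-lead digital ECG as a samples x leads voltage matrix.
#' Voltages are stored internally in nanovolts (nV) so that spectral power
#' is naturally expressed in nV^2 Hz^-1 and reported tables only divide by
#' 10^3 for display.
#'
#' @slot voltages numeric matrix, one column per lead (colnames are lead
#'   names from the standard 12-lead set), in nV.
#' @slot samplingRate sampling rate in Hz; must exceed 260 Hz so the
#'   130 Hz band edge stays below Nyquist.
#' @slot subjectId subject identifier.
#' @slot groupLabel `"control"`, `"patient"`, or `NA` when unlabeled.
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(voltages = "matrix", samplingRate = "numeric",
                 subjectId = "character", groupLabel = "character"),
  prototype(subjectId = "", groupLabel = NA_character_))

setValidity("ECGRecord", function(object) {
  v <- object@voltages
  if (!is.numeric(v) || ncol(v) < 1L || nrow(v) < 1L)
    return("voltages must be a non-empty numeric matrix (samples x leads)")
  if (is.null(colnames(v)) || anyNA(colnames(v)) || any(colnames(v) == ""))
    return("every lead column must be named")
  bad <- setdiff(colnames(v), .STANDARD_LEADS)
  if (length(bad))
    return(paste0("unknown lead name(s): ", paste(bad, collapse = ", "),
                  " (expected the standard 12-lead set)"))
  if (anyDuplicated(colnames(v)))
    return("duplicated lead names")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 260)
    return("samplingRate must be a single value > 260 Hz (Nyquist above the 130 Hz band edge)")
  if (!is.na(object@groupLabel) &&
      !object@groupLabel %in% c("control", "patient"))
    return("groupLabel must be 'control', 'patient' or NA")
  TRUE
})

#' Reference or detected beat positions
#'
#' @slot beats strictly increasing 1-based sample indices of R peaks.
#' @slot source free-text provenance (e.g. file name or "synthetic truth").
#' @exportClass BeatAnnotation
setClass("BeatAnnotation",
  representation(beats = "integer", source = "character"),
  prototype(source = ""))

setValidity("BeatAnnotation", function(object) {
  b <- object@beats
  if (length(b) && (anyNA(b) || any(b < 1L)))
    return("beat indices must be positive")
  if (length(b) > 1L && any(diff(b) <= 0L))
    return("beat indices must be strictly increasing")
  TRUE
})

#' Typified (normalized) detection signal
#'
#' The squared first difference of one ECG lead, clipped at its empirical
#' 99.5th percentile and divided by that percentile so all values lie in
#' \[0, 1\].
#'
#' @slot values unitless series in \[0, 1\].
#' @slot p995 the normalization constant (on the nV^2 ms^-2 scale).
#' @slot sourceLead lead the detection signal was derived from.
#' @exportClass TypifiedSeries
setClass("TypifiedSeries",
  representation(values = "numeric", p995 = "numeric", sourceLead = "character"),
  prototype(sourceLead = ""))

setValidity("TypifiedSeries", function(object) {
  if (length(object@p995) != 1L || !is.finite(object@p995) || object@p995 <= 0)
    return("p995 must be a single positive value")
  v <- object@values
  if (anyNA(v) || any(v < 0) || any(v > 1 + 1e-12))
    return("typified values must lie in [0, 1]")
  TRUE
})

#' QRS detection result
#'
#' @slot intervals integer matrix with columns `start`, `end`: half-open
#'   1-based sample intervals where the typified detection signal exceeded
#'   the threshold (after merging and width filtering).
#' @slot tMax integer vector, one entry per retained interval: the sample
#'   index of the maximum positive V6 voltage near that interval (tMaxQRS).
#' @slot detectionLead lead used for the detection signal.
#' @exportClass DetectionResult
setClass("DetectionResult",
  representation(intervals = "matrix", tMax = "integer",
                 detectionLead = "character"),
  prototype(detectionLead = ""))

setValidity("DetectionResult", function(object) {
  iv <- object@intervals
  if (nrow(iv)) {
    if (ncol(iv) != 2L) return("intervals must have two columns (start, end)")
    if (any(iv[, 2] <= iv[, 1])) return("intervals must be non-empty half-open ranges")
    if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
      return("intervals must be sorted and disjoint")
  }
  if (length(object@tMax) != nrow(iv))
    return("one tMax per retained interval required")
  if (length(object@tMax) > 1L && any(diff(object@tMax) <= 0L))
    return("tMax indices must be strictly increasing")
  TRUE
})

#' Set of extracted QRS windows
#'
#' Each window spans 60 ms before to 85 ms after tMaxQRS (146 samples at
#' 1 kHz, a 145 ms span) across all leads of the source record.
#'
#' @slot windows numeric array samples x leads x beats (nV).
#' @slot timeMs time axis in ms (0 .. 145), tMaxQRS at 60 ms.
#' @slot tMax source-record sample index of each window's tMaxQRS.
#' @slot subjectId subject identifier inherited from the record.
#' @exportClass QRSWindowSet
setClass("QRSWindowSet",
  representation(windows = "array", timeMs = "numeric", tMax = "integer",
                 subjectId = "character"),
  prototype(subjectId = ""))

setValidity("QRSWindowSet", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L) return("windows must be a 3-d array (samples x leads x beats)")
  if (d[1] != length(object@timeMs)) return("time axis length mismatch")
  if (d[3] != length(object@tMax)) return("one tMax per window required")
  TRUE
})

#' Morlet wavelet transform parameters
#'
#' @slot omega0 central angular frequency of the mother wavelet (radians;
#'   default 6).
#' @slot dt sampling interval in seconds (default 0.001, i.e. 1 kHz).
#' @slot dj scale resolution in octaves between adjacent scales
#'   (default 1/125 suboctaves).
#' @slot fLow,fHigh analysis band edges in Hz (defaults 85 and 130).
#' @slot factorConvention scale-to-frequency conversion: `"response"`
#'   (2*pi/omega0; scale labels coincide with the frequency at which a pure
#'   tone's power spectrum peaks under this power normalization) or
#'   `"fourier"` (the traditional Morlet Fourier factor
#'   4*pi/(omega0 + sqrt(2 + omega0^2))).
#' @exportClass WaveletParams
setClass("WaveletParams",
  representation(omega0 = "numeric", dt = "numeric", dj = "numeric",
                 fLow = "numeric", fHigh = "numeric",
                 factorConvention = "character"),
  prototype(omega0 = 6, dt = 1e-3, dj = 1 / 125, fLow = 85, fHigh = 130,
            factorConvention = "response"))

setValidity("WaveletParams", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (object@dj <= 0) return("dj must be positive")
  if (object@omega0 <= 0) return("omega0 must be positive")
  if (object@fLow > object@fHigh) return("fLow must not exceed fHigh")
  if (object@fLow <= 0) return("band edges must be positive")
  if (!object@factorConvention %in% c("response", "fourier"))
    return("factorConvention must be 'response' or 'fourier'")
  TRUE
})

#' Time x scale wavelet power spectrum
#'
#' @slot power numeric matrix, time epochs x scales, in nV^2 Hz^-1
#'   (non-negative; possibly NA where masked by the cone of influence).
#' @slot scales wavelet scales (s), ascending.
#' @slot frequencies corresponding frequencies in Hz, descending.
#' @slot timeMs time axis in ms.
#' @slot coiPeriod per-epoch cone-of-influence period (s): periods longer
#'   than this are dominated by edge effects at that epoch.
#' @slot params the [WaveletParams-class] used.
#' @exportClass WaveletSpectrum
setClass("WaveletSpectrum",
  representation(power = "matrix", scales = "numeric", frequencies = "numeric",
                 timeMs = "numeric", coiPeriod = "numeric",
                 params = "WaveletParams"))

setValidity("WaveletSpectrum", function(object) {
  if (nrow(object@power) != length(object@timeMs))
    return("power rows must match the time axis")
  if (ncol(object@power) != length(object@scales))
    return("power columns must match the scale axis")
  if (length(object@frequencies) != length(object@scales))
    return("one frequency per scale required")
  if (any(object@power < 0, na.rm = TRUE))
    return("power must be non-negative")
  TRUE
})

#' Cumulative high-frequency power per time epoch
#'
#' The wavelet power summed over all in-band scales at each epoch of the
#' QRS window.
#'
#' @slot values band power per epoch (nV^2 Hz^-1), non-negative.
#' @slot timeMs time axis in ms.
#' @slot tmaxMs position of tMaxQRS on the time axis (60 ms).
#' @exportClass HFPowerSeries
setClass("HFPowerSeries",
  representation(values = "numeric", timeMs = "numeric", tmaxMs = "numeric"),
  prototype(tmaxMs = 60))

#' Intensity (running-mean power) series
#'
#' The running mean of the cumulative band-power series over elapsed
#' epochs: the instantaneous average of cumulative power.
#'
#' @slot values intensity per epoch (reported as nV^2 Hz^-1 s^-1).
#' @slot timeMs time axis in ms.
#' @exportClass IntensitySeries
setClass("IntensitySeries",
  representation(values = "numeric", timeMs = "numeric"))

.seriesValidity <- function(object) {
  if (length(object@values) != length(object@timeMs))
    return("values and time axis lengths differ")
  if (any(object@values < 0, na.rm = TRUE))
    return("values must be non-negative")
  TRUE
}
setValidity("HFPowerSeries", .seriesValidity)
setValidity("IntensitySeries", .seriesValidity)

#' Synthetic 12-lead ECG configuration
#'
#' Parameters of the sum-of-Gaussians beat model with an injectable
#' Gaussian-windowed high-frequency burst (the late-potential /
#' fragmentation surrogate) and band-limited additive noise.
#'
#' @slot nBeats number of beats.
#' @slot heartRateBpm heart rate (beats per minute); the implied inter-beat
#'   interval must exceed 300 ms.
#' @slot fs sampling rate in Hz (default 1000).
#' @slot qrsAmplitude R-wave peak amplitude in lead V6, in nV; other leads
#'   are scaled so V6 carries the largest positive R wave.
#' @slot qrsWidthMs full width at half maximum of the Gaussian R wave (ms).
#' @slot hfAmplitude peak amplitude (nV, in V6) of the high-frequency burst;
#'   0 disables it.
#' @slot hfFrequencyHz burst carrier frequency; must lie in \[85, 130\] when
#'   the burst is enabled.
#' @slot hfOffsetMs burst center relative to the R peak (ms; may be negative).
#' @slot hfWidthMs FWHM of the burst's Gaussian envelope (ms).
#' @slot noiseRms per-lead additive noise RMS (nV).
#' @slot noiseBandwidthHz low-pass cutoff of the noise (Hz); `Inf` gives
#'   unfiltered white noise.
#' @slot mainsAmplitude amplitude (nV) of an optional 50 Hz mains component.
#' @slot seed integer seed; records are bit-reproducible given the config.
#' @exportClass SynthesisConfig
setClass("SynthesisConfig",
  representation(nBeats = "integer", heartRateBpm = "numeric", fs = "numeric",
                 qrsAmplitude = "numeric", qrsWidthMs = "numeric",
                 hfAmplitude = "numeric", hfFrequencyHz = "numeric",
                 hfOffsetMs = "numeric", hfWidthMs = "numeric",
                 noiseRms = "numeric", noiseBandwidthHz = "numeric",
                 mainsAmplitude = "numeric", seed = "integer"))

setValidity("SynthesisConfig", function(object) {
  if (object@nBeats < 1L) return("nBeats must be >= 1")
  if (object@heartRateBpm <= 0) return("heartRateBpm must be positive")
  if (60000 / object@heartRateBpm <= 300)
    return("heart rate must yield an inter-beat interval > 300 ms")
  if (object@fs <= 260) return("fs must exceed 260 Hz")
  if (object@qrsAmplitude <= 0) return("qrsAmplitude must be positive")
  if (object@qrsWidthMs <= 0) return("qrsWidthMs must be positive")
  if (object@hfAmplitude < 0) return("hfAmplitude must be non-negative")
  if (object@hfAmplitude > 0 &&
      (object@hfFrequencyHz < 85 || object@hfFrequencyHz > 130))
    return("hfFrequencyHz must lie in [85, 130] when the burst is enabled")
  if (object@noiseRms < 0) return("noiseRms must be non-negative")
  TRUE
})

#' Labeled synthetic cohort
#'
#' @slot records list of [ECGRecord-class].
#' @slot annotations list of [BeatAnnotation-class] (generator truth).
#' @slot labels parallel character vector, `"control"` or `"patient"`.
#' @slot truth parallel list of per-record [SynthesisConfig-class].
#' @exportClass LabeledCohort
setClass("LabeledCohort",
  representation(records = "list", annotations = "list", labels = "character",
                 truth = "list"))

setValidity("LabeledCohort", function(object) {
  n <- length(object@records)
  if (n < 1L) return("cohort must be non-empty")
  if (length(object@labels) != n || length(object@truth) != n ||
      length(object@annotations) != n)
    return("records, annotations, labels and truth must be parallel")
  if (!all(object@labels %in% c("control", "patient")))
    return("labels must be 'control' or 'patient'")
  TRUE
})

#' Two-group cohort comparison summary
#'
#' @slot metricsTable data.frame with one row per metric: per-group mean,
#'   SD and n, the Welch (or pooled) t statistic, degrees of freedom and
#'   p-value, plus a `flag` column for degenerate contrasts.
#' @slot categoricalTable data.frame of chi-square contrasts (possibly
#'   zero rows).
#' @slot alpha significance threshold recorded with the analysis.
#' @slot varEqual whether the pooled-variance t-test was used.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(metricsTable = "data.frame", categoricalTable = "data.frame",
                 alpha = "numeric", varEqual = "logical"),
  prototype(alpha = 0.05, varEqual = FALSE))
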