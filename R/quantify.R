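## Collapse a band-restricted wavelet spectrum into the cumulative-power
## function and the intensity (running-mean power) function, and the
## headline per-beat metrics of both.

#' Cumulative band power per time epoch
#'
#' Sums the wavelet power over all in-band scales at each epoch.
#'
#' @param spectrum a [WaveletSpectrum-class] covering the analysis band.
#' @return an [HFPowerSeries-class].
#' @export
cumulativeBandPower <- function(spectrum) {
  p <- bandPower(spectrum)
  if (!ncol(p)) stop("spectrum has an empty scale axis")
  new("HFPowerSeries", values = rowSums(p), timeMs = timeMs(spectrum),
      tmaxMs = 60)
}

#' Power metrics of a cumulative band-power series
#'
#' Peak Power (maximum of the series), Time to Peak Power (epoch of the
#' first maximum, ms), Total Power (area under the curve, rectangle rule
#' at 1 ms epochs), the Initial (strictly before tMaxQRS) and Final (from
#' tMaxQRS on) High Frequency Contributions, and their ratio. The epoch
#' containing tMaxQRS belongs to the final contribution, the late-potential
#' region of interest; initial + final = total exactly.
#'
#' @param series an [HFPowerSeries-class].
#' @return named numeric vector: `peak_power`, `time_to_peak_power`,
#'   `total_power`, `initial_contribution`, `final_contribution`,
#'   `contribution_ratio` (NaN-flagged when the final part carries no
#'   power).
#' @export
hfMetrics <- function(series) {
  v <- seriesValues(series)
  t <- timeMs(series)
  peak <- max(v)
  initial <- sum(v[t < series@tmaxMs])
  final <- sum(v[t >= series@tmaxMs])
  c(peak_power = peak,
    time_to_peak_power = t[which.max(v)],
    total_power = initial + final,
    initial_contribution = initial,
    final_contribution = final,
    contribution_ratio = if (final > 0) initial / final else NaN)
}

#' Intensity function: running mean of the band power
#'
#' The instantaneous average of cumulative power: at each epoch the sum of
#' the band power over all elapsed epochs divided by their count.
#'
#' @param series an [HFPowerSeries-class].
#' @return an [IntensitySeries-class] of the same length.
#' @examples
#' s <- new("HFPowerSeries", values = c(1, 2, 3), timeMs = 0:2)
#' seriesValues(intensityFunction(s))  # 1.0 1.5 2.0
#' @export
intensityFunction <- function(series) {
  v <- seriesValues(series)
  new("IntensitySeries", values = cumsum(v) / seq_along(v),
      timeMs = timeMs(series))
}

#' Intensity metrics
#'
#' Peak Intensity, Time to Peak Intensity (first maximum, ms), Final
#' Intensity (value at the last epoch, which equals the mean of the whole
#' band-power series) and Total Intensity (area under the intensity
#' curve, rectangle rule).
#'
#' @param series an [IntensitySeries-class].
#' @return named numeric vector: `peak_intensity`,
#'   `time_to_peak_intensity`, `final_intensity`, `total_intensity`.
#' @export
intensityMetrics <- function(series) {
  v <- seriesValues(series)
  t <- timeMs(series)
  c(peak_intensity = max(v),
    time_to_peak_intensity = t[which.max(v)],
    final_intensity = v[length(v)],
    total_intensity = sum(v))
}

.METRIC_NAMES <- c("peak_power", "time_to_peak_power", "total_power",
                   "initial_contribution", "final_contribution",
                   "contribution_ratio", "peak_intensity",
                   "time_to_peak_intensity", "final_intensity",
                   "total_intensity")

#' Per-beat high-frequency metrics of a window set
#'
#' Runs the band-restricted Morlet transform on the analysis lead of
#' every extracted window and collapses each spectrum into the ten
#' power/intensity metrics.
#'
#' @param windowSet a [QRSWindowSet-class].
#' @param params a [WaveletParams-class].
#' @param lead analysis lead: a lead name (default `"V6"`, the alignment
#'   lead) or `"mean"` for the lead-averaged voltage.
#' @return data.frame with one row per beat: `subject_id`, `beat_index`,
#'   and the ten metrics (powers in nV^2 Hz^-1).
#' @export
analyzeWindows <- function(windowSet, params = waveletParams(),
                           lead = "V6") {
  nb <- nBeats(windowSet)
  if (!nb)
    return(cbind(data.frame(subject_id = character(), beat_index = integer()),
                 as.data.frame(matrix(numeric(), 0, length(.METRIC_NAMES),
                                      dimnames = list(NULL, .METRIC_NAMES)))))
  x <- if (identical(lead, "mean")) {
    apply(windowSet@windows, c(1, 3), mean)
  } else {
    lead <- normalizeLeadNames(lead)
    if (!lead %in% leadNames(windowSet))
      stop("lead '", lead, "' not present in the window set")
    windowSet@windows[, lead, , drop = TRUE]
  }
  x <- matrix(x, nrow = length(timeMs(windowSet)))
  P <- cwtPowerBatch(x, params)
  t <- timeMs(windowSet)
  rows <- vapply(seq_len(nb), function(i) {
    band <- new("HFPowerSeries",
                values = rowSums(matrix(P[, , i], nrow = length(t))),
                timeMs = t)
    c(hfMetrics(band), intensityMetrics(intensityFunction(band)))
  }, numeric(length(.METRIC_NAMES)))
  cbind(data.frame(subject_id = subjectId(windowSet),
                   beat_index = seq_len(nb)),
        as.data.frame(t(rows)))
}
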