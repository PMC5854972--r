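## Plotting hooks: scalogram, cumulative-power and intensity curves with
## their peak/final markers, and group mean curves. Base graphics.

#' Scalogram of a QRS window spectrum
#'
#' @param spectrum a [WaveletSpectrum-class].
#' @param main plot title.
#' @export
plotSpectrum <- function(spectrum, main = "QRS high-frequency power") {
  p <- bandPower(spectrum)
  graphics::image(x = timeMs(spectrum), y = rev(frequencies(spectrum)),
                  z = p[, rev(seq_len(ncol(p))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (ms)", ylab = "frequency (Hz)", main = main)
  graphics::abline(v = 60, lty = 3)
}

#' Cumulative band-power curve with peak markers
#'
#' @param series an [HFPowerSeries-class].
#' @param main plot title.
#' @export
plotPowerSeries <- function(series, main = "Cumulative HF power") {
  v <- seriesValues(series)
  t <- timeMs(series)
  graphics::plot(t, v, type = "l", xlab = "time (ms)",
                 ylab = "band power (nV^2/Hz)", main = main)
  graphics::abline(h = max(v), col = 2, lty = 2)
  graphics::abline(v = t[which.max(v)], col = 3, lty = 2)
  graphics::abline(v = 60, lty = 3)
}

#' Intensity curve with peak and final markers
#'
#' @param series an [IntensitySeries-class].
#' @param main plot title.
#' @export
plotIntensitySeries <- function(series, main = "HF intensity") {
  v <- seriesValues(series)
  t <- timeMs(series)
  graphics::plot(t, v, type = "l", xlab = "time (ms)",
                 ylab = "intensity (nV^2/Hz/s)", main = main)
  graphics::abline(h = max(v), col = 2, lty = 2)
  graphics::abline(v = t[which.max(v)], col = 3, lty = 2)
  graphics::abline(h = v[length(v)], col = 4, lty = 2)
}

#' Boxplots of a subject-level metric by group
#'
#' @param subjects data.frame from [aggregateSubjects()].
#' @param metric metric column name.
#' @export
plotMetricByGroup <- function(subjects, metric = "total_power") {
  graphics::boxplot(subjects[[metric]] ~ subjects$group_label,
                    xlab = "", ylab = metric)
}
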