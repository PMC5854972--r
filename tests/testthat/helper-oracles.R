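# Independent oracles and fixture builders used across the suite.

# Brute-force Morlet transform: evaluates the convolution sum term by
# term, independently of the package's FFT path.
directCWT <- function(x, params = waveletParams()) {
  sf <- scalesForBand(params)
  n <- length(x)
  P <- matrix(0, n, length(sf$scales))
  for (j in seq_along(sf$scales)) {
    s <- sf$scales[j]
    for (tau in seq_len(n)) {
      u <- ((seq_len(n) - tau) * params@dt) / s
      w <- sum(x * (1 / sqrt(s)) * pi^(-0.25) *
                 exp(-1i * params@omega0 * u - u^2 / 2))
      P[tau, j] <- Mod(w)^2 / s
    }
  }
  P
}

# Periodogram band-power fraction of a voltage segment (FFT oracle).
bandPowerFraction <- function(x, fs = 1000, fLow = 85, fHigh = 130) {
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_along(x) - 1) / length(x) * fs
  half <- f <= fs / 2
  sum(sp[half & f >= fLow & f <= fHigh]) / sum(sp[half])
}

# Band power of one noiseless beat's V6 window through the package CWT.
beatBandPower <- function(hfAmplitude, seed = 404, ...) {
  cfg <- synthConfig(nBeats = 3, noiseRms = 0, hfAmplitude = hfAmplitude,
                     seed = seed, ...)
  gen <- generateRecord(cfg)
  win <- extractWindows(gen$record, detectBeats(gen$record))
  sum(seriesValues(cumulativeBandPower(cwtPower(win[[2]][, "V6"]))))
}

# Time to Peak Power of the middle beat of a noiseless record.
beatTimeToPeak <- function(hfOffsetMs, seed = 405) {
  cfg <- synthConfig(nBeats = 3, noiseRms = 0, hfOffsetMs = hfOffsetMs,
                     seed = seed)
  gen <- generateRecord(cfg)
  win <- extractWindows(gen$record, detectBeats(gen$record))
  hfMetrics(cumulativeBandPower(cwtPower(win[[2]][, "V6"])))[["time_to_peak_power"]]
}
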