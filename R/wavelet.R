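## Morlet continuous wavelet transform of QRS windows, restricted to the
## 85-130 Hz band. The transform is the convolution of the series with
## daughter wavelets carrying a 1/sqrt(s) amplitude normalization; power is
## |Wave|^2/s. No additional dt or reconstruction-factor normalization is
## applied, so absolute power is convention-bound; every cross-group
## comparison is unaffected. The FFT path is exactly the direct convolution
## sum (zero-padded to a power of two that makes the circular convolution
## linear over the window support).

#' Morlet transform parameters
#'
#' @param omega0 central angular frequency of the mother wavelet
#'   (default 6).
#' @param dt sampling interval in seconds (default 0.001).
#' @param dj scale resolution in octaves (default 1/125 suboctaves).
#' @param fLow,fHigh band edges in Hz (defaults 85, 130).
#' @param factorConvention `"response"` (default) or `"fourier"`; see
#'   [WaveletParams-class] and the methods vignette for why the
#'   response-peak conversion is the default under this power
#'   normalization.
#' @return a [WaveletParams-class].
#' @export
waveletParams <- function(omega0 = 6, dt = 1e-3, dj = 1 / 125,
                          fLow = 85, fHigh = 130,
                          factorConvention = c("response", "fourier")) {
  new("WaveletParams", omega0 = omega0, dt = dt, dj = dj,
      fLow = fLow, fHigh = fHigh,
      factorConvention = match.arg(factorConvention))
}

#' Scale-to-frequency conversion factor
#'
#' Frequency = 1 / (factor * scale). `"response"` gives 2*pi/omega0, the
#' factor under which the labeled frequency of a scale coincides with the
#' frequency at which a pure tone's power (|Wave|^2/s) peaks across
#' scales. `"fourier"` gives the traditional Morlet factor
#' 4*pi/(omega0 + sqrt(2 + omega0^2)).
#'
#' @param params a [WaveletParams-class].
#' @return scalar conversion factor.
#' @export
fourierFactor <- function(params) {
  switch(params@factorConvention,
         response = 2 * pi / params@omega0,
         fourier = 4 * pi / (params@omega0 + sqrt(2 + params@omega0^2)))
}

#' Geometric scale ladder covering the analysis band
#'
#' Scales ascend from the `fHigh` edge in steps of 2^dj; the `fLow` edge
#' is appended exactly so both band-edge frequencies are included and all
#' labeled frequencies lie inside \[fLow, fHigh\].
#'
#' @param params a [WaveletParams-class].
#' @return list with `scales` (ascending) and `frequencies` (descending,
#'   Hz).
#' @export
scalesForBand <- function(params) {
  validObject(params)
  ff <- fourierFactor(params)
  k <- floor(log2(params@fHigh / params@fLow) / params@dj)
  freqs <- params@fHigh * 2^(-params@dj * (0:k))
  if (freqs[length(freqs)] / params@fLow > 1 + 1e-12)
    freqs <- c(freqs, params@fLow)
  if (!length(freqs)) stop("empty scale ladder for the requested band")
  list(scales = 1 / (ff * freqs), frequencies = freqs)
}

## FFT'd correlation kernels, cached per (params, padded length).
## Wave(tau, s) = sum_t x_t (1/sqrt(s)) psi*((t - tau) dt / s) is computed
## for all tau as IFFT(FFT(x) * K_s) with K_s(k) = sum_m g_s(m) e^{+2pi i k m/N},
## g_s(m) = (1/sqrt(s)) pi^(-1/4) exp(-i omega0 u) exp(-u^2/2), u = m dt / s.
.kernelCache <- new.env(parent = emptyenv())

.morletKernels <- function(params, n) {
  key <- paste(params@omega0, params@dt, params@dj, params@fLow,
               params@fHigh, params@factorConvention, n, sep = "|")
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  sf <- scalesForBand(params)
  ## pad so the circular convolution is linear over the window support:
  ## the widest kernel is < 4e-18 of its peak beyond 9 scales
  support <- ceiling(9 * max(sf$scales) / params@dt)
  N <- .nextPow2(n + support)
  m <- c(0:(N / 2 - 1), -(N / 2):-1)               # circular offsets
  K <- matrix(0 + 0i, N, length(sf$scales))
  for (j in seq_along(sf$scales)) {
    s <- sf$scales[j]
    u <- m * params@dt / s
    g <- (1 / sqrt(s)) * pi^(-0.25) * exp(-1i * params@omega0 * u -
                                            u^2 / 2)
    K[, j] <- stats::fft(g, inverse = TRUE)
  }
  out <- list(K = K, N = N, scales = sf$scales,
              frequencies = sf$frequencies)
  .kernelCache[[key]] <- out
  out
}

#' Batched wavelet power of many windows
#'
#' Computes the band-restricted Morlet power spectrum of every column of
#' `x` in one FFT pass. This is the workhorse behind [cwtPower()] and the
#' cohort pipeline.
#'
#' @param x numeric matrix, samples x windows (a single series is
#'   accepted).
#' @param params a [WaveletParams-class].
#' @return numeric array epochs x scales x windows of power values
#'   (nV^2 Hz^-1 when `x` is in nV).
#' @export
cwtPowerBatch <- function(x, params = waveletParams()) {
  x <- as.matrix(x)
  n <- nrow(x)
  ker <- .morletKernels(params, n)
  pad <- rbind(x, matrix(0, ker$N - n, ncol(x)))
  FX <- stats::mvfft(pad)
  nw <- ncol(x)
  ns <- length(ker$scales)
  P <- array(0, dim = c(n, ns, nw))
  ## scales are processed in chunks so one inverse mvfft covers many
  ## (scale, window) columns without exhausting memory
  chunk <- max(1L, min(ns, as.integer(4e6 / (ker$N * nw))))
  for (j0 in seq(1L, ns, by = chunk)) {
    js <- j0:min(ns, j0 + chunk - 1L)
    M <- FX[, rep(seq_len(nw), times = length(js)), drop = FALSE] *
      ker$K[, rep(js, each = nw), drop = FALSE]
    W <- stats::mvfft(M, inverse = TRUE) / ker$N
    W <- Mod(W[seq_len(n), , drop = FALSE])^2
    for (k in seq_along(js))
      P[, js[k], ] <- W[, (k - 1L) * nw + seq_len(nw)] / ker$scales[js[k]]
  }
  P
}

#' Morlet wavelet power spectrum of one QRS window lead
#'
#' @param x voltage series of one lead of a QRS window (nV; canonically
#'   146 samples at 1 kHz).
#' @param params a [WaveletParams-class].
#' @param maskCoi when `TRUE`, power at epochs whose cone-of-influence
#'   period is shorter than a scale's period is set to `NA`. Off by
#'   default: the headline metrics integrate the whole 145 ms window.
#' @return a [WaveletSpectrum-class].
#' @examples
#' w <- cos(2 * pi * 100 * (0:145) / 1000)
#' sp <- cwtPower(w)
#' frequencies(sp)[which.max(colMeans(bandPower(sp)))]
#' @export
cwtPower <- function(x, params = waveletParams(), maskCoi = FALSE) {
  stopifnot(is.numeric(x))
  n <- length(x)
  P <- cwtPowerBatch(matrix(x, ncol = 1), params)[, , 1, drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  ker <- .morletKernels(params, n)
  ff <- fourierFactor(params)
  edge <- pmin(seq_len(n) - 1L, n - seq_len(n))
  coi <- ff * edge * params@dt / sqrt(2)
  if (maskCoi) {
    periods <- 1 / ker$frequencies
    for (j in seq_along(periods)) P[periods[j] > coi, j] <- NA_real_
  }
  new("WaveletSpectrum", power = P, scales = ker$scales,
      frequencies = ker$frequencies, timeMs = (seq_len(n) - 1) * params@dt * 1000,
      coiPeriod = coi, params = params)
}

#' Write a wavelet spectrum as delimited text with axis metadata
#'
#' @param spectrum a [WaveletSpectrum-class].
#' @param path output file (tab-separated; `#`-prefixed axis headers).
#' @export
writeSpectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# frequencies_hz\t",
           paste(sprintf("%.10g", spectrum@frequencies), collapse = "\t")),
    paste0("# scales_s\t",
           paste(sprintf("%.10g", spectrum@scales), collapse = "\t")),
    paste0("# time_ms\t",
           paste(sprintf("%.10g", spectrum@timeMs), collapse = "\t"))), con)
  utils::write.table(spectrum@power, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
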