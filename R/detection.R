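## Modified Pan-Tompkins QRS detection: differentiation, squaring,
## 99.5th-percentile typification, fixed 0.6 threshold, V6 local-maximum
## correction, 145 ms window extraction, and the Se/PPV/Er evaluation
## harness. The original integration stage is deliberately absent: the
## percentile typification plus fixed threshold replaces the adaptive
## thresholding of the 1985 algorithm.

#' Differentiate and square a voltage series
#'
#' First-order forward difference followed by squaring; the first two
#' stages of the detector. Output length is `length(x) - 1`.
#'
#' @param x numeric voltage series (length >= 2).
#' @return non-negative numeric series of squared first differences.
#' @examples
#' differentiateAndSquare(c(0, 1, 3, 6))  # 1 4 9
#' @export
differentiateAndSquare <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples to differentiate")
  diff(x)^2
}

#' Typify a squared-derivative series over its 99.5th percentile
#'
#' Computes the empirical 99.5th percentile (linear-interpolation
#' definition), clips extreme values to it, and divides by it, so the
#' result lies in \[0, 1\]. Clipping (rather than deleting extremes)
#' preserves the time axis needed to place the QRS intervals.
#'
#' @param x squared-derivative series, length >= 200.
#' @param sourceLead lead name recorded for provenance.
#' @return a [TypifiedSeries-class].
#' @export
typify <- function(x, sourceLead = "") {
  if (length(x) < 200L)
    stop("typification needs at least 200 samples for a meaningful percentile")
  p995 <- stats::quantile(x, 0.995, type = 7, names = FALSE)
  if (!is.finite(p995) || p995 <= 0)
    stop("degenerate signal: 99.5th percentile is not positive")
  new("TypifiedSeries", values = pmin(x, p995) / p995, p995 = p995,
      sourceLead = sourceLead)
}

#' Threshold the typified signal into QRS intervals
#'
#' Maximal runs of samples strictly above the threshold; runs separated by
#' less than `mergeGapMs` are merged, and merged runs shorter than
#' `minWidthMs` are discarded. The defaults (0.6 threshold, 50 ms merge
#' gap, 5 ms minimum width) reflect physiologic bounds on QRS slopes.
#'
#' @param typified a [TypifiedSeries-class] (or numeric series in \[0,1\]).
#' @param threshold detection threshold in (0, 1); default 0.6.
#' @param mergeGapMs,minWidthMs run post-processing parameters (ms).
#' @param samplingRate Hz, used to convert ms to samples (default 1000).
#' @return integer matrix with columns `start`, `end`: sorted, disjoint,
#'   half-open 1-based sample intervals (possibly zero rows).
#' @export
detectQRSEpochs <- function(typified, threshold = 0.6, mergeGapMs = 50,
                            minWidthMs = 5, samplingRate = 1000) {
  stopifnot(threshold > 0, threshold < 1)
  v <- if (is(typified, "TypifiedSeries")) typified@values else typified
  r <- rle(v > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values] + 1L)
  if (!nrow(iv)) return(iv)
  gap <- as.integer(round(mergeGapMs * samplingRate / 1000))
  minW <- as.integer(round(minWidthMs * samplingRate / 1000))
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(merged)
    if (iv[i, 1] - merged[k, 2] < gap) merged[k, 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  merged[merged[, 2] - merged[, 1] >= minW, , drop = FALSE]
}

#' Locate tMaxQRS in lead V6 for each detected interval
#'
#' For every interval the tMaxQRS fiducial is the sample of maximum
#' positive V6 voltage within the interval dilated by `dilateMs` on both
#' sides (the squared-derivative interval need not contain the voltage
#' peak itself). Ties break to the earliest sample. Detections closer
#' than the refractory period keep the larger V6 peak.
#'
#' @param record an [ECGRecord-class] containing lead V6.
#' @param intervals interval matrix from [detectQRSEpochs()].
#' @param dilateMs search dilation around each interval (ms; default 25).
#' @param refractoryMs minimum distance between beats (ms; default 200).
#' @param detectionLead recorded for provenance.
#' @return a [DetectionResult-class].
#' @export
locateTMax <- function(record, intervals, dilateMs = 25, refractoryMs = 200,
                       detectionLead = "") {
  v6 <- getLead(record, "V6")    # errors when V6 is absent
  fs <- samplingRate(record)
  dil <- as.integer(round(dilateMs * fs / 1000))
  refr <- as.integer(round(refractoryMs * fs / 1000))
  tm <- integer(0); pk <- numeric(0); keep <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(1L, intervals[i, 1] - dil)
    hi <- min(length(v6), intervals[i, 2] - 1L + dil)
    j <- lo + which.max(v6[lo:hi]) - 1L   # which.max: earliest tie wins
    k <- length(tm)
    if (k && j - tm[k] < refr) {
      if (v6[j] > pk[k]) { tm[k] <- j; pk[k] <- v6[j]; keep[k] <- i }
    } else {
      tm <- c(tm, j); pk <- c(pk, v6[j]); keep <- c(keep, i)
    }
  }
  new("DetectionResult",
      intervals = intervals[keep, , drop = FALSE],
      tMax = tm, detectionLead = detectionLead)
}

#' Detect QRS complexes in a record
#'
#' Convenience chain: differentiation and squaring of the detection lead,
#' typification, thresholding, and V6 local-maximum correction.
#'
#' @param record an [ECGRecord-class] (1 kHz; use [resampleTo1kHz()] first
#'   if needed).
#' @param lead detection lead (default `"II"`, the largest R wave in
#'   standard limb orientation).
#' @param threshold,mergeGapMs,minWidthMs see [detectQRSEpochs()].
#' @param dilateMs,refractoryMs see [locateTMax()].
#' @return a [DetectionResult-class].
#' @examples
#' gen <- generateRecord(synthConfig(nBeats = 5, noiseRms = 0))
#' det <- detectBeats(gen$record)
#' all.equal(tMaxQRS(det), beatTimes(gen$annotation))
#' @export
detectBeats <- function(record, lead = "II", threshold = 0.6,
                        mergeGapMs = 50, minWidthMs = 5, dilateMs = 25,
                        refractoryMs = 200) {
  d2 <- differentiateAndSquare(getLead(record, lead))
  ty <- typify(d2, sourceLead = lead)
  iv <- detectQRSEpochs(ty, threshold = threshold, mergeGapMs = mergeGapMs,
                        minWidthMs = minWidthMs,
                        samplingRate = samplingRate(record))
  locateTMax(record, iv, dilateMs = dilateMs, refractoryMs = refractoryMs,
             detectionLead = lead)
}

#' Extract 145 ms analysis windows around each tMaxQRS
#'
#' Per beat, samples from 60 ms before to 85 ms after tMaxQRS (both
#' endpoints included: 146 samples spanning 145 ms at 1 kHz) across all
#' leads. Beats whose window would cross a record boundary are skipped
#' with a log entry.
#'
#' @param record an [ECGRecord-class] at 1 kHz.
#' @param detection a [DetectionResult-class] (or integer vector of
#'   tMaxQRS sample indices).
#' @param preMs,postMs window offsets in ms (defaults 60 and 85).
#' @return a [QRSWindowSet-class].
#' @export
extractWindows <- function(record, detection, preMs = 60, postMs = 85) {
  if (samplingRate(record) != 1000)
    stop("window extraction requires a 1 kHz record; resample first")
  tm <- if (is(detection, "DetectionResult")) tMaxQRS(detection)
        else as.integer(detection)
  v <- voltages(record)
  ok <- tm - preMs >= 1L & tm + postMs <= nrow(v)
  if (any(!ok))
    hfLog("info", sum(!ok), " beat(s) skipped at record bounds for '",
          subjectId(record), "'")
  tm <- tm[ok]
  len <- preMs + postMs + 1L
  w <- array(0, dim = c(len, ncol(v), length(tm)),
             dimnames = list(NULL, colnames(v), NULL))
  for (i in seq_along(tm))
    w[, , i] <- v[(tm[i] - preMs):(tm[i] + postMs), ]
  new("QRSWindowSet", windows = w, timeMs = seq(0, preMs + postMs),
      tMax = tm, subjectId = subjectId(record))
}

#' Score a detector against reference beats
#'
#' Greedy one-to-one nearest matching within the tolerance: candidate
#' (detected, reference) pairs are accepted in order of increasing time
#' difference, each beat matched at most once. TB (total beats) is the
#' number of reference beats (TP + FN).
#'
#' @param detected,reference [BeatAnnotation-class] objects (or sorted
#'   integer vectors of sample indices).
#' @param toleranceMs matching tolerance (ms; default 50).
#' @param samplingRate Hz (default 1000).
#' @return a `DetectionScore`: named numeric vector with elements
#'   `Se`, `PPV`, `Er` (percentages) and `TB`, `FP`, `FN`, `TP` (counts).
#' @examples
#' evaluateDetection(c(100, 500, 900), c(100, 500, 900))
#' @export
evaluateDetection <- function(detected, reference, toleranceMs = 50,
                              samplingRate = 1000) {
  d <- if (is(detected, "BeatAnnotation")) beatTimes(detected)
       else as.integer(detected)
  r <- if (is(reference, "BeatAnnotation")) beatTimes(reference)
       else as.integer(reference)
  if (is.unsorted(d, strictly = TRUE) || is.unsorted(r, strictly = TRUE))
    stop("detected and reference beat lists must be strictly increasing")
  tol <- toleranceMs * samplingRate / 1000
  TP <- 0L
  if (length(d) && length(r)) {
    dd <- abs(outer(d, r, "-"))
    cand <- which(dd <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dd[cand]), , drop = FALSE]
      usedD <- logical(length(d)); usedR <- logical(length(r))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!usedD[i] && !usedR[j]) { usedD[i] <- usedR[j] <- TRUE; TP <- TP + 1L }
      }
    }
  }
  scoreFromCounts(TB = length(r), FP = length(d) - TP, FN = length(r) - TP)
}

#' Build a detection score from raw counts
#'
#' Se = 100 TP/(TP+FN), PPV = 100 TP/(TP+FP), Er = 100 (FP+FN)/TB, with
#' TB = TP + FN.
#'
#' @param TB total (reference) beats.
#' @param FP,FN false positive / false negative counts.
#' @return named numeric vector (`Se`, `PPV`, `Er`, `TB`, `FP`, `FN`, `TP`).
#' @examples
#' scoreFromCounts(TB = 116137, FP = 507, FN = 277)[["Er"]]
#' @export
scoreFromCounts <- function(TB, FP, FN) {
  TP <- TB - FN
  c(Se = if (TB > 0) 100 * TP / TB else NaN,
    PPV = if (TP + FP > 0) 100 * TP / (TP + FP) else NaN,
    Er = if (TB > 0) 100 * (FP + FN) / TB else NaN,
    TB = TB, FP = FP, FN = FN, TP = TP)
}
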