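test_that("differentiation and squaring follow the forward difference", {
  expect_equal(differentiateAndSquare(c(5, 5, 5, 5)), c(0, 0, 0))
  expect_equal(differentiateAndSquare(c(0, 1, 3, 6)), c(1, 4, 9))
  set.seed(1)
  x <- rnorm(100)
  expect_true(all(differentiateAndSquare(x) >= 0))
  expect_length(differentiateAndSquare(x), 99L)
  expect_error(differentiateAndSquare(5), "2 samples")
})

test_that("typification clips at and divides by the 99.5th percentile", {
  ty <- typify(1:1000)
  expect_equal(ty@p995, 995.005)               # linear-interpolation percentile
  expect_equal(max(ty@values), 1)
  expect_equal(ty@values[1], 1 / 995.005)

  ty2 <- typify(rep(7, 300))
  expect_true(all(ty2@values == 1))

  expect_error(typify(rep(0, 300)), "degenerate")
  expect_error(typify(1:100), "200")
})

test_that("thresholding finds, merges and filters runs", {
  v <- rep(0, 1000)
  expect_identical(nrow(detectQRSEpochs(v)), 0L)

  v[100:120] <- 0.9                            # single rectangular pulse
  iv <- detectQRSEpochs(v)
  expect_equal(unname(iv[1, ]), c(100L, 121L))

  v2 <- rep(0, 1000)
  v2[100:110] <- 0.9
  v2[131:140] <- 0.9                           # 20 ms gap -> merged
  iv2 <- detectQRSEpochs(v2)
  expect_equal(nrow(iv2), 1L)
  expect_equal(unname(iv2[1, ]), c(100L, 141L))

  v3 <- rep(0, 1000)
  v3[500:502] <- 0.9                           # 3 ms run -> discarded
  expect_equal(nrow(detectQRSEpochs(v3)), 0L)
})

test_that("tMaxQRS is the earliest V6 maximum near the interval", {
  n <- 1000
  v6 <- exp(-((1:n - 500)^2) / (2 * 9^2)) * 1e6
  rec <- ecgRecord(cbind(II = v6 * 0.8, V6 = v6), 1000)
  iv <- cbind(start = 480L, end = 520L)
  det <- locateTMax(rec, iv)
  expect_equal(tMaxQRS(det), 500L)

  v6p <- v6; v6p[500:502] <- v6p[500]          # plateau -> earliest index
  recp <- ecgRecord(cbind(V6 = v6p), 1000)
  expect_equal(tMaxQRS(locateTMax(recp, iv)), 500L)

  # peak just outside the interval is still found via the +/-25 ms dilation
  ivOff <- cbind(start = 460L, end = 480L)
  expect_equal(tMaxQRS(locateTMax(rec, ivOff)), 500L)

  recNoV6 <- ecgRecord(cbind(II = v6), 1000)
  expect_error(locateTMax(recNoV6, iv), "V6")
})

test_that("refractory handling keeps the larger V6 peak", {
  n <- 1200
  v6 <- exp(-((1:n - 400)^2) / 162) * 8e5 + exp(-((1:n - 500)^2) / 162) * 1e6
  rec <- ecgRecord(cbind(V6 = v6), 1000)
  iv <- cbind(start = c(390L, 490L), end = c(410L, 510L))
  det <- locateTMax(rec, iv)                   # 100 ms apart < 200 ms refractory
  expect_equal(tMaxQRS(det), 500L)
  expect_equal(nrow(qrsIntervals(det)), 1L)
})

test_that("detection recovers noiseless synthetic beats exactly", {
  gen <- generateRecord(synthConfig(nBeats = 10, noiseRms = 0, seed = 4))
  det <- detectBeats(gen$record)
  expect_identical(tMaxQRS(det), beatTimes(gen$annotation))
})

test_that("detection is invariant to global voltage scaling", {
  gen <- generateRecord(synthConfig(nBeats = 8, noiseRms = 1e4, seed = 12))
  rec10 <- ecgRecord(voltages(gen$record) * 10, 1000)
  expect_identical(tMaxQRS(detectBeats(gen$record)),
                   tMaxQRS(detectBeats(rec10)))
})

test_that("windows span 145 ms with the V6 maximum at 60 ms", {
  gen <- generateRecord(synthConfig(nBeats = 12, noiseRms = 2e4, seed = 6))
  det <- detectBeats(gen$record)
  win <- extractWindows(gen$record, det)
  expect_equal(length(timeMs(win)), 146L)
  expect_equal(range(timeMs(win)), c(0, 145))
  for (i in seq_len(nBeats(win)))
    expect_equal(which.max(win[[i]][, "V6"]), 61L)  # t = 60 ms

  # explicit sample arithmetic: tMaxQRS = 1000 -> samples 940..1085
  w <- extractWindows(gen$record, 1000L)
  expect_equal(unname(w[[1]][, "V6"]),
               unname(getLead(gen$record, "V6")[940:1085]))
})

test_that("boundary beats are skipped with a log entry", {
  gen <- generateRecord(synthConfig(nBeats = 5, noiseRms = 0, seed = 8))
  expect_message(win <- extractWindows(gen$record, c(30L, 1300L)), "skipped")
  expect_equal(nBeats(win), 1L)
  # 12 s at 60 bpm: all 12 beats clear of the edges
  gen12 <- generateRecord(synthConfig(nBeats = 12, noiseRms = 0, seed = 8))
  win12 <- extractWindows(gen12$record, detectBeats(gen12$record))
  expect_equal(nBeats(win12), 12L)
})

test_that("detector scoring implements greedy one-to-one matching", {
  ref <- as.integer(seq(500, 9500, by = 1000))
  perfect <- evaluateDetection(ref, ref)
  expect_equal(unname(perfect[c("Se", "PPV", "Er")]), c(100, 100, 0))

  det <- sort(c(ref[-10], 9950L))              # 9 true + 1 spurious
  sc <- evaluateDetection(det, ref)
  expect_equal(unname(sc[c("Se", "PPV", "Er")]), c(90, 90, 20))
  expect_equal(unname(sc[c("TP", "FP", "FN", "TB")]), c(9, 1, 1, 10))

  expect_error(evaluateDetection(c(5L, 1L), ref), "increasing")

  # a detection can match at most one reference beat
  sc2 <- evaluateDetection(c(500L), c(490L, 530L))
  expect_equal(unname(sc2[["TP"]]), 1)
})

test_that("published detector counts reproduce their printed error rates", {
  pan <- scoreFromCounts(TB = 116137, FP = 507, FN = 277)
  expect_equal(round(pan[["Er"]], 3), 0.675)
  zid <- scoreFromCounts(TB = 109494, FP = 193, FN = 393)
  expect_equal(round(zid[["Er"]], 2), 0.54)
})
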