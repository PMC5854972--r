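test_that("noiseless beats land exactly on the configured grid", {
  cfg <- synthConfig(nBeats = 10, heartRateBpm = 60, noiseRms = 0,
                     hfAmplitude = 0)
  gen <- generateRecord(cfg)
  expect_equal(unique(diff(beatTimes(gen$annotation))), 1000)
  # R peaks of V6 sit on the annotated samples
  v6 <- getLead(gen$record, "V6")
  expect_true(all(vapply(beatTimes(gen$annotation),
                         function(b) v6[b] >= max(v6[(b - 5):(b + 5)]),
                         logical(1))))
})

test_that("the same seed reproduces a record bit for bit", {
  a <- generateRecord(synthConfig(seed = 77))
  b <- generateRecord(synthConfig(seed = 77))
  expect_identical(voltages(a$record), voltages(b$record))
  expect_identical(beatTimes(a$annotation), beatTimes(b$annotation))
  c <- generateRecord(synthConfig(seed = 78))
  expect_false(identical(voltages(a$record), voltages(c$record)))
})

test_that("V6 carries the largest positive R wave", {
  gen <- generateRecord(synthConfig(nBeats = 3, noiseRms = 0))
  peaks <- apply(voltages(gen$record), 2, max)
  expect_identical(names(which.max(peaks)), "V6")
})

test_that("the injected burst shows a spectral peak at its carrier", {
  for (f in c(90, 100, 120)) {
    cfg <- synthConfig(nBeats = 3, noiseRms = 0, hfAmplitude = 5e4,
                       hfFrequencyHz = f, seed = 11)
    gen <- generateRecord(cfg)
    base <- generateRecord(modifyConfig(cfg, hfAmplitude = 0))
    d <- getLead(gen$record, "V6") - getLead(base$record, "V6")
    b <- beatTimes(gen$annotation)[2]
    seg <- d[(b - 250):(b + 249)]              # 500 ms -> 2 Hz resolution
    sp <- Mod(stats::fft(seg))^2
    fr <- (seq_along(seg) - 1) / length(seg) * 1000
    peak <- fr[fr <= 500][which.max(sp[fr <= 500])]
    expect_lt(abs(peak - f), 5)
  }
})

test_that("a burst-free noiseless beat is effectively band-limited", {
  cfg <- synthConfig(nBeats = 3, noiseRms = 0, hfAmplitude = 0, seed = 5)
  gen <- generateRecord(cfg)
  b <- beatTimes(gen$annotation)[2]
  seg <- getLead(gen$record, "V6")[(b - 500):(b + 499)]
  expect_lt(bandPowerFraction(seg), 1e-6)
})

test_that("band power grows monotonically with the squared burst amplitude", {
  amps <- c(1e4, 3e4, 1e5)
  p <- vapply(amps, beatBandPower, numeric(1))
  expect_true(all(diff(p) > 0))
  # the burst-dominated regime scales ~ amplitude^2
  expect_gt(p[3] / p[2], 0.5 * (amps[3] / amps[2])^2)
})

test_that("noise is band-limited to the configured cutoff", {
  cfg <- synthConfig(nBeats = 3, qrsAmplitude = 1e6, hfAmplitude = 0,
                     noiseRms = 5e4, noiseBandwidthHz = 100, seed = 21)
  gen <- generateRecord(cfg)
  quiet <- getLead(gen$record, "V6")[1:200]    # before the first P wave
  sp <- Mod(stats::fft(quiet - mean(quiet)))^2
  f <- (0:199) / 200 * 1000
  inBand <- sum(sp[f > 0 & f <= 100])
  outBand <- sum(sp[f > 200 & f <= 500])
  expect_gt(inBand / outBand, 30)
  expect_equal(sd(quiet), 5e4, tolerance = 0.5)
})

test_that("the optional mains component is removed by the notch filter", {
  cfg <- synthConfig(nBeats = 3, noiseRms = 0, hfAmplitude = 0,
                     mainsAmplitude = 5e4, seed = 2)
  gen <- generateRecord(cfg)
  mainsPower <- function(rec) {
    x <- getLead(rec, "V6")[1:1000]
    sum((Mod(stats::fft(x - mean(x)))^2)[c(51, 951)])  # 50 Hz bins
  }
  before <- mainsPower(gen$record)
  after <- mainsPower(applyNotchFilter(gen$record))
  expect_lt(after / before, 1e-3)
})

test_that("cohorts are reproducible and differ only where configured", {
  ctrl <- synthConfig(noiseRms = 0, hfAmplitude = 2e4)
  pat <- modifyConfig(ctrl, hfAmplitude = 1e5, hfOffsetMs = 20)
  a <- generateCohort(3, 2, ctrl, pat, seed = 9)
  b <- generateCohort(3, 2, ctrl, pat, seed = 9)
  expect_identical(lapply(a@records, voltages), lapply(b@records, voltages))
  expect_identical(a@labels, c(rep("control", 3), rep("patient", 2)))
  # truth configs differ from the control template only in the burst fields
  for (i in which(a@labels == "patient")) {
    tr <- a@truth[[i]]
    expect_equal(tr@hfAmplitude, 1e5)
    expect_equal(tr@hfOffsetMs, 20)
    expect_equal(tr@qrsAmplitude, ctrl@qrsAmplitude)
    expect_equal(tr@noiseRms, ctrl@noiseRms)
  }
})

test_that("config invariants reject unphysiological settings", {
  expect_error(synthConfig(heartRateBpm = 250), "inter-beat")
  expect_error(synthConfig(hfAmplitude = 1e4, hfFrequencyHz = 60), "85")
  expect_silent(synthConfig(hfAmplitude = 0, hfFrequencyHz = 60))
  expect_error(modifyConfig(synthConfig(), bogus = 1), "bogus")
})

test_that("synthesis configs load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nBeats: 5", "heartRateBpm: 75", "noiseRms: 0"), path)
  cfg <- readSynthConfig(path)
  expect_equal(cfg@nBeats, 5L)
  expect_equal(cfg@heartRateBpm, 75)
  writeLines("nonsense: 1", path)
  expect_error(readSynthConfig(path), "nonsense")
})
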