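test_that("delimited records round-trip through read and write", {
  v <- cbind(II = c(-1.5, 0, 2.25, 7), V6 = c(3, 1, -2, 0.5)) * 1e6
  rec <- ecgRecord(v, 1000, subjectId = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeDelimitedRecord(rec, path)
  back <- readDelimitedRecord(path, samplingRate = 1000)
  expect_equal(voltages(back), voltages(rec))
  expect_identical(leadNames(back), c("II", "V6"))
})

test_that("delimited reader applies the unit scale and validates cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("II,V6", "0.5,1.0", "1.5,-2.0"), path)
  rec <- readDelimitedRecord(path, 1000, unitScale = 1e6)  # mV data
  expect_equal(getLead(rec, "V6"), c(1e6, -2e6))

  writeLines(c("II,V6", "0.5,1.0", "oops,-2.0"), path)
  expect_error(readDelimitedRecord(path, 1000), "row 2")

  writeLines(c("II,V6", "0.5,1.0", "1.5"), path)
  expect_error(readDelimitedRecord(path, 1000), "ragged")
})

test_that("a 12 s, 3-column CSV yields a 3-lead 12 s record", {
  m <- matrix(rnorm(12000 * 3), ncol = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(m, path, sep = ",", row.names = FALSE,
              col.names = c("I", "II", "V6"))
  rec <- readDelimitedRecord(path, 1000)
  expect_equal(nSamples(rec) / samplingRate(rec), 12)
  expect_length(leadNames(rec), 3)
})

test_that("lead aliases L/R/F normalize to the augmented names", {
  v <- cbind(L = 1:5, R = 1:5, F = 1:5, V6 = 1:5) * 1000
  rec <- ecgRecord(v, 1000)
  expect_identical(leadNames(rec), c("aVL", "aVR", "aVF", "V6"))
})

test_that("record invariants are enforced", {
  expect_error(ecgRecord(cbind(XX = 1:10), 1000), "lead")
  expect_error(ecgRecord(cbind(V6 = 1:10), 250), "260")
  expect_error(ecgRecord(cbind(V6 = 1:10), 1000, groupLabel = "case"),
               "groupLabel")
})

test_that("WFDB records round-trip and apply the stored gain", {
  v <- cbind(II = c(0.5, -0.25, 5), V6 = c(1, 2, -3)) * 1e6  # nV
  rec <- ecgRecord(v, 1000, subjectId = "w1")
  base <- file.path(withr::local_tempdir(), "w1")
  writeWFDBRecord(rec, base, adcGain = 200)
  back <- readWFDBRecord(base)
  expect_equal(voltages(back), voltages(rec))
  expect_equal(samplingRate(back), 1000)

  # hand conversion: adc value v at gain g is v/g mV = v/g * 1e6 nV
  adc <- c(100L, -50L, 1000L)
  hea <- file.path(withr::local_tempdir(), "h1.hea")
  writeLines(c("h1 1 500 3", "h1.dat 16 200(0)/mV 16 0 100 0 0 V6"), hea)
  writeBin(adc, sub("\\.hea$", ".dat", hea), size = 2L, endian = "little")
  rec2 <- readWFDBRecord(sub("\\.hea$", "", hea))
  expect_equal(unname(getLead(rec2, "V6")), adc / 200 * 1e6)
  expect_equal(samplingRate(rec2), 500)
})

test_that("WFDB reader fails cleanly on broken inputs", {
  d <- withr::local_tempdir()
  expect_error(readWFDBRecord(file.path(d, "nope")), "header")
  hea <- file.path(d, "orphan.hea")
  writeLines(c("orphan 1 1000 10", "orphan.dat 16 200/mV 16 0 0 0 0 V6"), hea)
  expect_error(readWFDBRecord(file.path(d, "orphan")), "missing")
  writeLines("zero 0 1000 10", file.path(d, "zero.hea"))
  expect_error(readWFDBRecord(file.path(d, "zero")), "zero")
})

test_that("WFDB and delimited readers agree on the same samples", {
  set.seed(31)
  v <- cbind(II = round(rnorm(400) * 200), V6 = round(rnorm(400) * 200))
  rec <- ecgRecord(v / 200 * 1e6, 1000)        # exact ADC-representable nV
  d <- withr::local_tempdir()
  writeWFDBRecord(rec, file.path(d, "r"), adcGain = 200)
  writeDelimitedRecord(rec, file.path(d, "r.csv"))
  a <- voltages(readWFDBRecord(file.path(d, "r")))
  b <- voltages(readDelimitedRecord(file.path(d, "r.csv"), 1000))
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-9)
})

test_that("metric tables round-trip at full precision", {
  rows <- data.frame(subject_id = c("a", "b"),
                     total_power = c(1.23456789012e8, 9.87e-3),
                     contribution_ratio = c(0.05347, 0.06912))
  path <- withr::local_tempfile(fileext = ".csv")
  writeMetricsTable(rows, path)
  expect_length(readLines(path), 3L)           # header + 2 subjects
  back <- readMetricsTable(path)
  expect_equal(signif(back$total_power, 12), signif(rows$total_power, 12))
  expect_equal(back$subject_id, rows$subject_id)

  writeMetricsTable(rows[0, ], path)           # empty -> header only
  expect_length(readLines(path), 1L)
})

test_that("beat annotations read and write as index-per-line text", {
  ann <- beatAnnotation(c(120L, 1120L, 2120L))
  path <- withr::local_tempfile(fileext = ".txt")
  writeBeatAnnotation(ann, path)
  expect_equal(beatTimes(readBeatAnnotation(path)), beatTimes(ann))
  expect_error(beatAnnotation(c(10L, 5L)), "increasing")
})

test_that("records at other rates resample to 1 kHz", {
  cfg <- synthConfig(nBeats = 4, fs = 500, noiseRms = 0, seed = 3)
  gen <- generateRecord(cfg)
  expect_message(rec <- resampleTo1kHz(gen$record), "resampling")
  expect_equal(samplingRate(rec), 1000)
  expect_equal(nSamples(rec), 2 * nSamples(gen$record))
  # R-peak positions double (1-based indexing shifts by at most 1 sample)
  det <- detectBeats(rec)
  expect_lt(max(abs(tMaxQRS(det) - (2 * beatTimes(gen$annotation) - 1))), 3)
})
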