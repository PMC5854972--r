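hfSeries <- function(v) new("HFPowerSeries", values = v,
                            timeMs = seq_along(v) - 1)

test_that("cumulative band power is the sum over scales at each epoch", {
  set.seed(20)
  m <- matrix(runif(146 * 77), 146, 77)
  sp <- new("WaveletSpectrum", power = m, scales = seq_len(77),
            frequencies = 77:1, timeMs = 0:145, coiPeriod = rep(1, 146),
            params = waveletParams())
  expect_equal(seriesValues(cumulativeBandPower(sp)),
               apply(m, 1, sum))               # independent column-sum oracle

  one <- m * 0; one[, 5] <- m[, 5]
  sp1 <- new("WaveletSpectrum", power = one, scales = seq_len(77),
             frequencies = 77:1, timeMs = 0:145, coiPeriod = rep(1, 146),
             params = waveletParams())
  expect_equal(seriesValues(cumulativeBandPower(sp1)), m[, 5])

  expect_equal(seriesValues(cumulativeBandPower(cwtPower(rep(0, 146)))),
               rep(0, 146))
})

test_that("power metrics follow the first-maximum and tMaxQRS split rules", {
  v <- c(0, 1, 3, 2, rep(0, 142))
  m <- hfMetrics(hfSeries(v))
  expect_equal(m[["peak_power"]], 3)
  expect_equal(m[["time_to_peak_power"]], 2)
  expect_equal(m[["total_power"]], 6)

  const <- hfMetrics(hfSeries(rep(2.5, 146)))
  expect_equal(const[["time_to_peak_power"]], 0)   # first maximum
  expect_equal(const[["initial_contribution"]] /
                 const[["final_contribution"]], 60 / 86)
  expect_equal(const[["contribution_ratio"]], 60 / 86)

  late <- c(rep(0, 60), rep(1, 86))                # nothing before 60 ms
  lm <- hfMetrics(hfSeries(late))
  expect_equal(lm[["initial_contribution"]], 0)
  expect_equal(lm[["contribution_ratio"]], 0)

  zm <- hfMetrics(hfSeries(rep(0, 146)))
  expect_true(is.nan(zm[["contribution_ratio"]]))
})

test_that("intensity is the running mean of the power series", {
  s <- new("HFPowerSeries", values = c(1, 2, 3), timeMs = 0:2)
  expect_equal(seriesValues(intensityFunction(s)), c(1, 1.5, 2))
  expect_equal(seriesValues(intensityFunction(hfSeries(rep(4, 146)))),
               rep(4, 146))
  expect_equal(seriesValues(intensityFunction(hfSeries(rep(0, 146)))),
               rep(0, 146))
})

test_that("intensity metrics report peak, final and area", {
  v <- c(1, 2, 3, rep(0, 143))
  im <- intensityMetrics(intensityFunction(hfSeries(v)))
  expect_equal(im[["peak_intensity"]], 2)          # running mean peaks at 2
  expect_equal(im[["time_to_peak_intensity"]], 2)
  expect_equal(im[["final_intensity"]], 6 / 146)
  expect_equal(im[["total_intensity"]],
               sum(cumsum(v) / seq_along(v)))

  mono <- intensityMetrics(intensityFunction(hfSeries(seq(0, 1, length = 146))))
  expect_equal(mono[["time_to_peak_intensity"]], 145)
  expect_equal(mono[["peak_intensity"]], mono[["final_intensity"]])

  zi <- intensityMetrics(intensityFunction(hfSeries(rep(0, 146))))
  expect_true(all(zi[c("peak_intensity", "final_intensity",
                       "total_intensity")] == 0))
})

test_that("intensity never exceeds the running power maximum and ends at the mean", {
  set.seed(33)
  for (i in 1:5) {
    v <- runif(146) * 10^runif(1, 0, 6)
    int <- seriesValues(intensityFunction(hfSeries(v)))
    expect_true(all(int <= cummax(v) + 1e-12))
    expect_equal(int[146], mean(v))
  }
})

test_that("metric identities hold on real pipeline output", {
  gen <- generateRecord(synthConfig(nBeats = 4, seed = 27))
  win <- extractWindows(gen$record, detectBeats(gen$record))
  for (i in seq_len(nBeats(win))) {
    band <- cumulativeBandPower(cwtPower(win[[i]][, "V6"]))
    m <- hfMetrics(band)
    expect_equal(m[["total_power"]],
                 m[["initial_contribution"]] + m[["final_contribution"]])
    expect_gte(m[["total_power"]], m[["peak_power"]])
    im <- intensityMetrics(intensityFunction(band))
    expect_equal(im[["final_intensity"]], mean(seriesValues(band)))
    expect_gte(im[["peak_intensity"]], im[["final_intensity"]])
  }
})

test_that("moving the burst later moves both time-to-peak metrics", {
  ttp <- vapply(c(0, 10, 20), beatTimeToPeak, numeric(1))
  expect_equal(diff(ttp), c(10, 10), tolerance = 0.21)  # +/- 2 ms on 10
  expect_true(all(diff(ttp) > 0))
})

test_that("per-window analysis returns one labeled row per beat", {
  gen <- generateRecord(synthConfig(nBeats = 5, seed = 30),
                        subjectId = "s9")
  win <- extractWindows(gen$record, detectBeats(gen$record))
  tab <- analyzeWindows(win)
  expect_equal(nrow(tab), 5L)
  expect_equal(unique(tab$subject_id), "s9")
  expect_true(all(c("peak_power", "total_intensity") %in% names(tab)))
  # lead-averaged mode runs and differs from single-lead V6
  tabM <- analyzeWindows(win, lead = "mean")
  expect_false(isTRUE(all.equal(tab$total_power, tabM$total_power)))
  expect_error(analyzeWindows(win, lead = "V9"), "V9")
})
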