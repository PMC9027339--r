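test_that("FSR divider conversion matches hand evaluation and is monotone", {
  expect_equal(fsrFromVoltage(2.5), 1e6)          # divider midpoint
  expect_equal(fsrFromVoltage(0), 0)
  expect_equal(fsrFromVoltage(4), 4e6)
  v <- seq(0, 4.99, by = 0.01)
  expect_true(all(diff(fsrFromVoltage(v)) > 0))
  expect_error(fsrFromVoltage(5), "saturated")
  expect_error(fsrFromVoltage(-0.1), "negative")
})

test_that("polarity inversion reverses order statistics", {
  expect_equal(fsrInvert(c(1, 3, 2)), c(2, 0, 1))
  expect_equal(fsrInvert(rep(4, 5)), rep(0, 5))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(fsrInvert(fsrInvert(x)), x - min(x))
  expect_equal(min(fsrInvert(x)), 0)
  expect_error(fsrInvert(numeric()), "empty")
})

test_that("block averaging frames, decimates and tracks the effective rate", {
  ba <- blockAverage(0:11, 8, 0.5, 100)
  expect_equal(ba$x, c(3.5, 7.5))
  expect_equal(ba$fsEffHz, 25)
  expect_equal(blockAverage(rep(3.3, 40), 8, 0.5, 100)$x, rep(3.3, 9))
  set.seed(2)
  x <- rnorm(64)
  nov <- blockAverage(x, 8, 0, 100)
  expect_equal(nov$x, blockAverageOracle(x, 8, 8))
  expect_equal(nov$fsEffHz, 100 / 8)
  ov <- blockAverage(x, 8, 0.5, 100)
  expect_equal(ov$x, blockAverageOracle(x, 8, 4))
  expect_error(blockAverage(1:5, 8), "shorter")
  expect_error(blockAverage(1:20, 8, 0.3), "hop")
})

test_that("Butterworth band-limiting has the designed gains", {
  expect_lt(max(abs(butterFilter(rep(2, 200), 25,
                                 filterSpec("highpass", 0.5)))), 2e-6)
  expect_lt(max(abs(butterFilter(rep(2, 200), 25,
                                 filterSpec("lowpass", 10)) - 2)), 1e-6)
  bf <- signal::butter(4, 10 / 12.5, type = "low")
  t <- (0:799) / 25
  core <- 200:600
  y2 <- butterFilter(sin(2 * pi * 2 * t), 25, filterSpec("lowpass", 10))
  g2 <- filterGain(bf$b, bf$a, 2, 25)^2  # squared: forward-backward pass
  expect_equal(max(abs(y2[core])), g2, tolerance = 0.02)
  y12 <- butterFilter(sin(2 * pi * 12 * t), 25, filterSpec("lowpass", 10))
  g12 <- filterGain(bf$b, bf$a, 12, 25)^2
  expect_lt(max(abs(y12[core])), g12 * 1.5 + 1e-9)
  expect_error(butterFilter(rnorm(100), 25, filterSpec("lowpass", 13)),
               "Nyquist")
  expect_error(butterFilter(rnorm(5), 25, filterSpec("lowpass", 5)),
               "too short")
})

test_that("each conditioning stage is linear", {
  set.seed(3)
  a <- rnorm(200); b <- rnorm(200)
  for (spec in list(filterSpec("highpass", 0.5), filterSpec("lowpass", 10))) {
    la <- butterFilter(a, 25, spec)
    lb <- butterFilter(b, 25, spec)
    lab <- butterFilter(2 * a - 5 * b, 25, spec)
    expect_lt(max(abs(lab - 2 * la + 5 * lb)) / max(abs(lab)), 1e-9)
  }
  ba <- blockAverage(a, 8, 0.5, 100)$x
  bb <- blockAverage(b, 8, 0.5, 100)$x
  bab <- blockAverage(2 * a - 5 * b, 8, 0.5, 100)$x
  expect_lt(max(abs(bab - 2 * ba + 5 * bb)), 1e-9)
})

test_that("EMG conditioning yields a zero-mean band-limited envelope", {
  z <- emgPipeline(rep(0, 400), 100)
  expect_equal(z$x, rep(0, length(z$x)))
  expect_equal(z$fsEffHz, 25)

  set.seed(4)
  raw <- 512 + rnorm(800, 0, 0.02)       # ADC-style DC offset
  raw[300:380] <- raw[300:380] + rnorm(81, 0, 1)
  out <- emgPipeline(raw, 100)
  expect_lt(abs(mean(out$x)), 1e-3 * 1)  # DC rejected relative to burst amp

  ## one 0.8 s activation burst -> one suprathreshold region (gaps < 0.2 s
  ## bridged, as in standard burst identification)
  raw2 <- rnorm(1000, 0, 0.02)
  raw2[400:480] <- raw2[400:480] + rnorm(81, 0, 1)
  env <- emgPipeline(raw2, 100)$x
  above <- env > 0.5 * max(env)
  r <- rle(above)
  inner <- which(!r$values & r$lengths < 8)  # gaps < 0.3 s at 25 Hz
  inner <- inner[inner > 1 & inner < length(r$values)]
  r$values[inner] <- TRUE
  merged <- rle(rep(r$values, r$lengths))
  expect_identical(sum(merged$values), 1L)
})

test_that("acceleration chain converts, band-limits and preserves tremor", {
  consts <- acquisitionConstants()
  scale <- consts$accelRangeG * 9.81 / 2^(consts$accelBits - 1)
  expect_equal(2^(consts$accelBits - 1) * scale, 2 * 9.81)  # full scale

  n <- 1200
  grav <- matrix(0, n, 3); grav[, 3] <- 9.81 / scale
  g <- accelPipeline(grav, 100)
  expect_lt(max(abs(g$xyz)), 1e-6)      # DC/gravity suppressed
  expect_equal(g$fsEffHz, 25)

  t <- (0:(n - 1)) / 100
  trem <- matrix(0, n, 3)
  trem[, 1] <- sin(2 * pi * 5 * t) / scale
  out <- accelPipeline(trem, 100)
  lp <- signal::butter(4, 30 / 50, type = "low")
  hp <- signal::butter(4, 0.5 / 12.5, type = "high")
  gain <- filterGain(lp$b, lp$a, 5, 100)^2 * boxcarGain(5, 100, 8) *
    filterGain(hp$b, hp$a, 5, 25)^2
  expect_equal(max(abs(out$xyz[60:240, 1])), gain, tolerance = 0.05)
  expect_error(accelPipeline(matrix(0, 100, 2), 100), "three axes")
})

test_that("MA and VA match their defining formulas", {
  expect_equal(magnitudeOfAcceleration(3, 4, 0), 5)
  expect_equal(magnitudeOfAcceleration(0, 0, 0), 0)
  expect_equal(magnitudeOfAcceleration(1, 2, 2), 3)
  expect_error(magnitudeOfAcceleration(1:3, 1:2, 1:3), "mismatch")

  expect_equal(variationOfAcceleration(c(7, 7, 7), c(1, 1, 1), c(0, 0, 0)),
               c(0, 0, 0))
  expect_equal(variationOfAcceleration(c(1, 3), c(0, 0), c(0, 0)), c(0, 2))

  set.seed(5)
  ax <- rnorm(1000); ay <- rnorm(1000); az <- rnorm(1000)
  expect_equal(variationOfAcceleration(ax, ay, az), vaOracle(ax, ay, az),
               tolerance = 1e-12)
})

test_that("the assembled signal space has the canonical layout", {
  fx <- fixturePhysio()
  sig <- signalMatrix(fx$space)
  expect_identical(colnames(sig), gaitSignalNames())
  expect_true(all(is.finite(sig)))
  expect_equal(effectiveRate(fx$space), 25)

  zero <- gaitRecording("z", "unknown", 100, fsrV = matrix(0, 200, 6),
                        emg = matrix(0, 200, 4), accel = matrix(0, 200, 3))
  zsp <- buildSignalSpace(zero)
  expect_equal(max(abs(signalMatrix(zsp))), 0)

  ## heel contact suprathreshold exactly in the generator windows
  nl <- fixtureNoiseless()
  heel <- signalMatrix(nl$space)[, "FSR2_left"]
  th <- min(heel) + 0.2 * (max(heel) - min(heel))
  tEff <- effectiveTimes(nl$space)
  tr <- nl$sim$truth[nl$sim$truth$side == "left", ]
  for (i in seq_len(nrow(tr))) {
    inside <- tEff > tr$onset_heel_s[i] + 0.08 &
      tEff < tr$start_s[i] + 0.6 * (tr$end_s[i] - tr$start_s[i])
    expect_true(all(heel[inside] > th))
  }
  outside <- rep(TRUE, length(tEff))
  for (i in seq_len(nrow(tr)))
    outside[tEff > tr$start_s[i] - 0.08 & tEff < tr$end_s[i] + 0.08] <- FALSE
  expect_true(all(heel[outside] < th))
})
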