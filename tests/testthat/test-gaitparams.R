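test_that("cadence counts single-foot stance initiations per minute", {
  st <- data.frame(side = rep(c("left", "right"), 5),
                   start_s = seq(0.5, 9.5, by = 1),
                   end_s = seq(1.0, 10, by = 1))
  expect_equal(cadence(st, 10, 0), 60)
  expect_warning(z <- cadence(st[0, ], 10, 0), "no step")
  expect_equal(z, 0)

  fx <- fixturePhysio()  # 2 s generator cycle: one step per second
  st2 <- rbind(fx$stancesL, fx$stancesR)
  expect_lt(abs(cadence(st2, 10, min(st2$start_s) - 0.5) - 60), 6 + 1e-9)
})

test_that("support fractions partition the window", {
  n <- 250  # 10 s at 25 Hz
  sig <- matrix(1, n, 12)
  colnames(sig) <- gaitSignalNames()
  sp <- methods::new("SignalSpace", signals = sig, fsEffHz = 25, t0S = 0)
  ml <- c(rep(TRUE, 150), rep(FALSE, 100))   # left 4 s alone + 2 s both
  mr <- c(rep(FALSE, 100), rep(TRUE, 150))
  sup <- supportFractions(sp, 10, 0, maskLeft = ml, maskRight = mr)
  expect_equal(unname(sup), c(40, 40, 20))
  both <- supportFractions(sp, 10, 0, maskLeft = rep(TRUE, n),
                           maskRight = rep(TRUE, n))
  expect_equal(unname(both), c(0, 0, 100))
  none <- supportFractions(sp, 10, 0, maskLeft = rep(FALSE, n),
                           maskRight = rep(FALSE, n))
  expect_equal(unname(none), c(0, 0, 0))
  expect_lte(sum(sup), 100)
})

test_that("support ratio reproduces the cohort-table values", {
  expect_equal(roundHalfUp(sdRatio(41.8, 14.9), 1), 2.8)
  expect_equal(roundHalfUp(sdRatio(48.5, 8.9), 1), 5.4)
  expect_equal(sdRatio(25, 25), 1)
  und <- sdRatio(30, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("stride-time variability is a sample coefficient of variation", {
  expect_equal(strideCov(c(1, 1, 1)), 0)
  expect_equal(strideCov(c(0.9, 1.0, 1.1)), 10)
  und <- strideCov(1.2)
  expect_true(is.na(und) && attr(und, "undefined"))

  sim <- simulateRecording(subjectParams(nCycles = 21, strideCovPct = 8,
                                         seed = 1))
  sp <- buildSignalSpace(sim$recording)
  stL <- detectStances(sp, "left")  # 20 left strides
  cm <- strideCov(strideDurations(stL))
  expect_lt(abs(cm - 8) / 8, 0.3)
})

test_that("temporal profile is deterministic and internally consistent", {
  fx <- fixturePhysio()
  st <- rbind(fx$stancesL, fx$stancesR)
  tp1 <- temporalProfile(fx$space, st)
  tp2 <- temporalProfile(fx$space, st)
  expect_identical(tp1, tp2)
  expect_lte(sum(tp1$single_support_pct) + tp1$double_support_pct, 100)
  expect_true(all(unlist(tp1[c("cadence_spm", "double_support_pct")]) >= 0))
  expect_equal(tp1$window_s, 10)
})

test_that("suppressed lift-off reduces the opposite single support", {
  base <- simulateRecording(subjectParams(nCycles = 10, seed = 5))
  heavy <- simulateRecording(subjectParams(
    nCycles = 10, liftoff = c(left = TRUE, right = FALSE),
    dragLevel = 0.5, seed = 5))
  spB <- buildSignalSpace(base$recording)
  spH <- buildSignalSpace(heavy$recording)
  supB <- supportFractions(spB, 10, 1)
  supH <- supportFractions(spH, 10, 1)
  expect_lt(supH["single_left"], supB["single_left"] - 10)
})

test_that("biomechanical profile matches the generator archetype", {
  fx <- fixturePhysio()
  bio <- biomechProfile(fx$space)
  expect_identical(bio$arm_balance, "present")
  expect_identical(as.character(bio$tremor), "absent")
  expect_identical(bio$strike$left[1], "heel_strike")
  expect_identical(bio$strike$right[1], "heel_strike")
  expect_gte(attr(bio$strike$left, "fraction"), 0.95)
  expect_identical(bio$liftoff$left, "present")
  expect_identical(bio$liftoff$right, "present")

  pd <- simulateRecording(subjectParams(
    "pd", strike = c(left = "flat", right = "flat"), armSwingAmp = 0.1,
    tremorAmp = 1, strideCovPct = 8, nCycles = 10, seed = 13))
  bioP <- biomechProfile(buildSignalSpace(pd$recording))
  expect_identical(bioP$strike$left[1], "flat_foot")
  expect_identical(bioP$strike$right[1], "flat_foot")
  expect_identical(as.character(bioP$tremor), "large")
  expect_identical(bioP$arm_balance, "absent")
})

test_that("group statistics use the sample (n-1) standard deviation", {
  gs <- groupStats(c(62, 27, 24, 56, 55))
  expect_equal(roundHalfUp(gs$mean, 1), 44.8)
  expect_equal(roundHalfUp(gs$sd, 1), 17.9)
  expect_identical(gs$n, 5L)
  gs2 <- groupStats(c(39, 44, 48, 32, 24))
  expect_equal(roundHalfUp(gs2$mean, 1), 37.4)
  expect_equal(roundHalfUp(gs2$sd, 1), 9.6)
  cc <- groupStats(c(4.4, 4.4, 4.4))
  expect_equal(cc$mean, 4.4)
  expect_equal(cc$sd, 0)
  one <- groupStats(7)
  expect_true(is.na(one$sd) && attr(one$sd, "undefined"))
  expect_identical(formatGroupStats(groupStats(c(14.9, 29.8, 23.4, 17.1, 19.7))),
                   "21 ± 5.9")
})

test_that("report rounding is half-away-from-zero at one decimal", {
  expect_equal(roundHalfUp(2.25, 1), 2.3)
  expect_equal(roundHalfUp(-2.25, 1), -2.3)
  expect_equal(roundHalfUp(20.96, 1), 21)
})
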