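makeSpace <- function(sig12, fsEff = 25) {
  colnames(sig12) <- gaitSignalNames()
  methods::new("SignalSpace", signals = sig12, fsEffHz = fsEff, t0S = 0)
}

test_that("stance segmentation recovers generator boundaries", {
  fx <- fixturePhysio()
  truth <- fx$sim$truth
  for (side in c("left", "right")) {
    st <- if (side == "left") fx$stancesL else fx$stancesR
    tr <- truth[truth$side == side, ]
    expect_identical(nrow(st), nrow(tr))
    expect_lt(max(abs(st$start_s - tr$start_s)), 1 / 25 + 1e-9)
    expect_lt(max(abs(st$end_s - tr$end_s)), 2 / 25 + 1e-9)
    expect_true(all(st$start_idx < st$end_idx))
    expect_true(all(diff(st$start_s) > 0))
    ## onsets lie within their segment
    expect_true(all(st$onset_heel_s >= st$start_s - 1e-9 &
                    st$onset_heel_s <= st$end_s + 1e-9))
  }
})

test_that("degenerate pressure inputs are handled", {
  n <- 100
  sig <- matrix(0, n, 12)
  sig[, 1] <- rnorm(n)  # keep MA non-flat
  w <- testthat::capture_warnings(st0 <- detectStances(makeSpace(sig), "left"))
  expect_true(any(grepl("flat.*FSR0_left", w)))
  expect_identical(nrow(st0), 0L)

  ## single rectangular pulse on the heel only
  sig2 <- matrix(0, n, 12)
  sig2[30:60, 7] <- 1  # FSR2_left
  suppressWarnings(st1 <- detectStances(makeSpace(sig2), "left"))
  expect_identical(nrow(st1), 1L)
  expect_identical(st1$start_idx, 30L)
  expect_identical(st1$end_idx, 61L)
  expect_identical(st1$strike_type, "indeterminate")
})

test_that("raising the threshold never lengthens a stance", {
  fx <- fixturePhysio()
  lo <- detectStances(fx$space, "left", eventConfig(thresholdFraction = 0.2))
  hi <- detectStances(fx$space, "left", eventConfig(thresholdFraction = 0.35))
  expect_identical(detectStances(fx$space, "left"), lo)  # idempotent
  for (i in seq_len(nrow(hi))) {
    j <- which(lo$start_idx <= hi$start_idx[i] & lo$end_idx >= hi$end_idx[i])
    expect_identical(length(j), 1L)  # each high-threshold stance nested
  }
})

test_that("MA peak detection finds prominent maxima", {
  tri <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  expect_identical(detectMaPeaks(tri), 11L)

  t <- (0:249) / 25
  s5 <- sin(2 * pi * 5 * t) + 2
  pk <- detectMaPeaks(s5)
  expect_true(abs(length(pk) / 10 - 5) <= 1)  # ~5 peaks per second

  fx <- fixturePhysio()
  pkT <- effectiveTimes(fx$space)[detectMaPeaks(signalMatrix(fx$space)[, "MA"])]
  bounds <- sort(c(fx$sim$truth$start_s, fx$sim$truth$end_s))
  inRange <- bounds[bounds > min(pkT) - 0.2 & bounds < max(pkT) + 0.2]
  d <- vapply(inRange, function(b) min(abs(pkT - b)), 0)
  ## sway reversals mark stance-boundary clusters: near-coincident
  ## boundaries share one reversal, so allow the cluster half-width
  expect_gte(mean(d <= 0.15), 0.75)
  expect_lte(median(d), 0.1)
})

test_that("strike classification follows the onset-order rules", {
  expect_identical(classifyStrike(0.00, 0.12, 0.25), "heel_strike")
  expect_identical(classifyStrike(0.00, 0.01, 0.03), "flat_foot")
  expect_identical(classifyStrike(0.20, 0.10, 0.00), "toe_first")
  expect_identical(classifyStrike(0.00, NA, 0.20), "heel_strike")
  expect_identical(classifyStrike(0.00, NA, NA), "indeterminate")
  ## boundary: exactly at tolerance stays flat-foot
  expect_identical(classifyStrike(0, 0.02, 0.05), "flat_foot")
})

test_that("lift-off and drag are distinguished", {
  fx <- fixturePhysio()
  stL <- fx$stancesL
  for (i in seq_len(nrow(stL) - 1)) {
    expect_true(detectLiftoff(fx$space, "left", stL[i, ], stL[i + 1, ]))
  }
  drag <- simulateRecording(subjectParams(
    nCycles = 8, liftoff = c(left = TRUE, right = FALSE), seed = 9))
  dsp <- buildSignalSpace(drag$recording)
  stR <- detectStances(dsp, "right")
  expect_gt(nrow(stR), 2)
  for (i in seq_len(nrow(stR) - 1)) {
    expect_false(detectLiftoff(dsp, "right", stR[i, ], stR[i + 1, ]))
  }
  z <- detectLiftoff(dsp, "right", stR[1, ], stR[1, ])
  expect_false(z)
  expect_true(attr(z, "degenerate"))
})

test_that("arm-balance presence reflects peak/boundary coincidence", {
  fx <- fixturePhysio()
  st <- rbind(fx$stancesL, fx$stancesR)
  pkT <- effectiveTimes(fx$space)[detectMaPeaks(signalMatrix(fx$space)[, "MA"])]
  expect_identical(assessArmBalance(pkT, st), "present")
  expect_identical(assessArmBalance(numeric(), st), "absent")
  expect_identical(assessArmBalance(pkT, st[1, ]), "indeterminate")

  noarm <- simulateRecording(subjectParams(
    "pd", armSwingAmp = 0.1, tremorAmp = 1, nCycles = 8, seed = 10))
  nsp <- buildSignalSpace(noarm$recording)
  nst <- rbind(detectStances(nsp, "left"), detectStances(nsp, "right"))
  npk <- effectiveTimes(nsp)[detectMaPeaks(signalMatrix(nsp)[, "MA"])]
  expect_identical(assessArmBalance(npk, nst), "absent")
})

test_that("tremor grading tracks the generator tremor amplitude", {
  fx <- fixturePhysio()
  sig <- signalMatrix(fx$space)
  expect_identical(as.character(gradeTremor(sig[, "MA"], sig[, "VA"], 25)),
                   "absent")

  grade <- function(tremorAmp, swing = 1.2, seed = 11) {
    s <- simulateRecording(subjectParams("pd", armSwingAmp = swing,
                                         tremorAmp = tremorAmp,
                                         nCycles = 8, seed = seed))
    sp <- buildSignalSpace(s$recording)
    m <- signalMatrix(sp)
    as.character(gradeTremor(m[, "MA"], m[, "VA"], effectiveRate(sp)))
  }
  expect_identical(grade(0), "absent")
  expect_identical(grade(0.35 * 1.2), "small")
  expect_identical(grade(1.2), "large")  # tremor equal to arm swing

  ## pure slow sway carries no tremor-band power
  t <- (0:499) / 25
  slow <- abs(sin(2 * pi * 0.5 * t)) + 0.2
  expect_identical(as.character(gradeTremor(slow, slow, 25)), "absent")
})
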