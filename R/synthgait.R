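## Synthetic gait generator: raw 100 Hz recordings with ground-truth event
## tables, emulating physiological gait (heel -> metatarsal -> toe pressure
## progression, phase-locked TA/GM bursts, arm-sway acceleration peaking at
## stance boundaries) and Parkinsonian gait (flat-foot or toe-led strike,
## 4-6 Hz tremor, suppressed arm balance, toe drag, elevated stride
## jitter).

#' Parameters of one simulated subject
#'
#' @param label `"physiological"` or `"pd"`.
#' @param cycleS nominal gait-cycle duration (s).
#' @param nCycles number of gait cycles.
#' @param strideCovPct stride-duration jitter, as a coefficient of
#'   variation in percent.
#' @param strike per-side strike type: `"heel"`, `"flat"` or
#'   `"toe_first"`.
#' @param liftoff per-side logical; `FALSE` keeps residual toe contact
#'   through the swing (foot drag).
#' @param armSwingAmp arm-sway acceleration amplitude (m/s^2).
#' @param tremorAmp tremor acceleration amplitude (m/s^2).
#' @param tremorHz tremor frequency (Hz), in the 4-6 Hz band.
#' @param stanceFraction stance share of the gait cycle.
#' @param siteOnsetLagsS heel->metatarsal and heel->toe onset lags (s)
#'   for a heel strike.
#' @param emgBurstAmp EMG burst amplitude (raw units).
#' @param fsrRestKohm unloaded FSR resistance (kilo-ohm).
#' @param fsrPressKohm fully loaded FSR resistance (kilo-ohm).
#' @param dragLevel residual toe pressure during drag, as a fraction of
#'   the inverted-resistance dynamic range; sits between the lift-off and
#'   contact detection thresholds.
#' @param noiseSd per-channel white-noise standard deviations: `fsrV`
#'   (V), `emg` (raw), `accelMs2` (m/s^2).
#' @param seed RNG seed; the simulation is deterministic given the seed.
#' @return A list of class `"SubjectParams"`.
#' @export
subjectParams <- function(label = c("physiological", "pd"), cycleS = 2,
                          nCycles = 12L, strideCovPct = 4,
                          strike = c(left = "heel", right = "heel"),
                          liftoff = c(left = TRUE, right = TRUE),
                          armSwingAmp = 1.5, tremorAmp = 0, tremorHz = 5,
                          stanceFraction = 0.6,
                          siteOnsetLagsS = c(0.1, 0.2), emgBurstAmp = 1,
                          fsrRestKohm = 2000, fsrPressKohm = 10,
                          dragLevel = 0.12,
                          noiseSd = list(fsrV = 0.005, emg = 0.05,
                                         accelMs2 = 0.05),
                          seed = 1L) {
  label <- match.arg(label)
  if (cycleS <= 0 || nCycles < 1L || stanceFraction <= 0 ||
      stanceFraction >= 1)
    stop("durations must be positive and fractions in (0, 1)")
  if (!all(strike %in% c("heel", "flat", "toe_first")))
    stop("strike must be heel, flat or toe_first")
  if (tremorAmp > 0 && (tremorHz < 4 || tremorHz > 6))
    stop("tremor frequency outside the 4-6 Hz tremor band")
  structure(list(label = label, cycleS = cycleS, nCycles = as.integer(nCycles),
                 strideCovPct = strideCovPct, strike = strike,
                 liftoff = liftoff, armSwingAmp = armSwingAmp,
                 tremorAmp = tremorAmp, tremorHz = tremorHz,
                 stanceFraction = stanceFraction,
                 siteOnsetLagsS = siteOnsetLagsS, emgBurstAmp = emgBurstAmp,
                 fsrRestKohm = fsrRestKohm, fsrPressKohm = fsrPressKohm,
                 dragLevel = dragLevel, noiseSd = noiseSd,
                 seed = as.integer(seed)), class = "SubjectParams")
}

## Smooth contact profile: half-cosine loading ramp, plateau, half-cosine
## release. The fast (40 ms) loading ramp keeps threshold crossings within
## one effective sample of the nominal onset.
.contactProfile <- function(t, on, off, rampUp = 0.04, rampDown = 0.08) {
  y <- numeric(length(t))
  up <- t >= on & t < on + rampUp
  y[up] <- 0.5 * (1 - cos(pi * (t[up] - on) / rampUp))
  mid <- t >= on + rampUp & t <= off - rampDown
  y[mid] <- 1
  dn <- t > off - rampDown & t <= off
  y[dn] <- 0.5 * (1 - cos(pi * (off - t[dn]) / rampDown))
  y
}

## Symmetric raised-cosine bump of half-width `hw` centered at `c0`.
.bump <- function(t, c0, hw) {
  y <- numeric(length(t))
  in_ <- abs(t - c0) < hw
  y[in_] <- 0.5 * (1 + cos(pi * (t[in_] - c0) / hw))
  y
}

#' Simulate one gait recording with ground truth
#'
#' Generates the raw 100 Hz telemetry of one subject walking
#' `params$nCycles` gait cycles, with per-cycle durations jittered at the
#' requested stride CoV, and returns both the [GaitRecording-class] and a
#' ground-truth event table listing every stance boundary, the per-site
#' plantar onsets, and the per-cycle strike and lift-off labels.
#'
#' @param params a [subjectParams()].
#' @param subjectId identifier stored in the recording.
#' @param fsHz acquisition rate (Hz).
#' @param consts acquisition constants.
#' @return List with `recording`, `truth` (data.frame: `side`, `cycle`,
#'   `start_s`, `end_s`, `strike`, `liftoff`, `onset_heel_s`,
#'   `onset_metatarsal_s`, `onset_toe_s`) and `params`.
#' @export
simulateRecording <- function(params, subjectId = "sim", fsHz = 100,
                              consts = acquisitionConstants()) {
  stopifnot(inherits(params, "SubjectParams"))
  .withSeed(params$seed, {
    pad <- 1
    jit <- stats::rnorm(params$nCycles, 0, params$strideCovPct / 100)
    jit <- pmin(pmax(jit, -0.3), 0.3)
    d <- params$cycleS * (1 + jit)
    leftStart <- pad + c(0, cumsum(d))[seq_len(params$nCycles)]
    totalT <- pad + sum(d) + pad
    n <- ceiling(totalT * fsHz)
    t <- (seq_len(n) - 1) / fsHz

    lag <- params$siteOnsetLagsS
    sitePlan <- function(strike, t0, sdur) {
      switch(strike,
        heel = list(on = c(heel = 0, metatarsal = lag[1], toe = lag[2]) + t0,
                    off = c(heel = 0.75, metatarsal = 0.9, toe = 1) * sdur + t0),
        flat = list(on = c(heel = 0, metatarsal = 0.005, toe = 0.01) + t0,
                    off = c(heel = 0.95, metatarsal = 0.97, toe = 1) * sdur + t0),
        toe_first = list(on = c(heel = lag[2], metatarsal = lag[1], toe = 0) + t0,
                         off = c(heel = 0.9, metatarsal = 0.95, toe = 1) *
                               sdur + t0))
    }

    press <- matrix(0, n, 6)  # contact fraction per plantar channel
    emg <- matrix(0, n, 4)
    truth <- list()
    events <- numeric()
    fsrCol <- function(side, site)
      3L * (side == "right") + c(toe = 1L, metatarsal = 2L, heel = 3L)[site]
    emgCol <- function(side, muscle)
      2L * (side == "right") + c(TA = 1L, GM = 2L)[muscle]

    for (side in c("left", "right")) {
      strike <- params$strike[[side]]
      lift <- params$liftoff[[side]]
      starts <- leftStart + if (side == "right") d / 2 else 0
      sdur <- params$stanceFraction * d
      for (k in seq_len(params$nCycles)) {
        plan <- sitePlan(strike, starts[k], sdur[k])
        for (site in c("toe", "metatarsal", "heel"))
          press[, fsrCol(side, site)] <- press[, fsrCol(side, site)] +
            .contactProfile(t, plan$on[[site]], plan$off[[site]])
        if (!lift && k < params$nCycles) {
          dragOn <- plan$off[["toe"]] - 0.05
          dragOff <- starts[k + 1] + 0.05
          press[, fsrCol(side, "toe")] <- press[, fsrCol(side, "toe")] +
            params$dragLevel * .contactProfile(t, dragOn, dragOff, 0.1, 0.1)
        }
        ## TA bursts at stance onset and during swing; GM from midstance
        ## to toe-off
        taEnv <- .bump(t, starts[k] + 0.1 * sdur[k], 0.18 * sdur[k]) +
          0.6 * .bump(t, starts[k] + sdur[k] + 0.5 * (d[k] - sdur[k]),
                      0.3 * (d[k] - sdur[k]))
        gmEnv <- .bump(t, starts[k] + 0.7 * sdur[k], 0.3 * sdur[k])
        emg[, emgCol(side, "TA")] <- emg[, emgCol(side, "TA")] +
          params$emgBurstAmp * taEnv * stats::rnorm(n)
        emg[, emgCol(side, "GM")] <- emg[, emgCol(side, "GM")] +
          params$emgBurstAmp * gmEnv * stats::rnorm(n)
        truth[[length(truth) + 1L]] <- data.frame(
          side = side, cycle = k, start_s = min(plan$on),
          end_s = max(plan$off),
          strike = c(heel = "heel_strike", flat = "flat_foot",
                     toe_first = "toe_first")[[strike]],
          liftoff = lift,
          onset_heel_s = plan$on[["heel"]],
          onset_metatarsal_s = plan$on[["metatarsal"]],
          onset_toe_s = plan$on[["toe"]])
        events <- c(events, min(plan$on), max(plan$off))
      }
    }
    ## Pressure fraction -> sensor resistance (linear in the inverted
    ## signal) -> divider voltage; measurement noise is added in volts.
    press <- pmin(press, 1)
    rK <- params$fsrRestKohm -
      press * (params$fsrRestKohm - params$fsrPressKohm)
    fsr <- consts$vDd * (rK * 1e3) / (rK * 1e3 + consts$rDiv)
    fsr <- fsr + matrix(stats::rnorm(n * 6, 0, params$noiseSd$fsrV), n, 6)
    fsr <- pmin(pmax(fsr, 0.01), consts$vDd * 0.998)
    emg <- emg + matrix(stats::rnorm(n * 4, 0, params$noiseSd$emg), n, 4)

    ## Arm sway: a smooth phase track advances by pi at every sway
    ## reversal (stance boundary events; near-coincident events merged),
    ## carried in quadrature on two axes so the acceleration magnitude
    ## peaks at the reversals and stays smooth in between. Tremor is a
    ## sinusoid on the second axis; gravity sits on z.
    ev <- sort(events)
    merged <- list()
    for (e in ev) {
      k <- length(merged)
      if (k > 0L && e - merged[[k]][length(merged[[k]])] < 0.3)
        merged[[k]] <- c(merged[[k]], e)
      else merged[[k + 1L]] <- e
    }
    evc <- vapply(merged, mean, 0)
    psi <- stats::approx(evc, seq_along(evc) * pi, xout = t, rule = 2)$y
    ax <- params$armSwingAmp * cos(psi)
    ay <- 0.3 * params$armSwingAmp * sin(psi) +
      params$tremorAmp * sin(2 * pi * params$tremorHz * t)
    az <- rep(9.81, n)
    acc <- cbind(ax, ay, az) +
      matrix(stats::rnorm(n * 3, 0, params$noiseSd$accelMs2), n, 3)
    scale <- consts$accelRangeG * 9.81 / 2^(consts$accelBits - 1)
    accRaw <- pmin(pmax(acc / scale, -2^(consts$accelBits - 1)),
                   2^(consts$accelBits - 1))

    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$side, truth$start_s), ]
    rownames(truth) <- NULL
    rec <- gaitRecording(subjectId, params$label, fsHz, fsrV = fsr,
                         emg = emg, accel = accRaw, consts = consts,
                         meta = list(generator = "pdgait-synthetic",
                                     seed = params$seed))
    list(recording = rec, truth = truth, params = params)
  })
}

#' Ground-truth contact masks on an effective time base
#'
#' Converts a generator truth table to per-foot boolean contact masks for
#' direct comparison with threshold-detected masks. By default the masks
#' carry the stance intervals only, matching the contact-threshold
#' semantics of the detector (a light drag below the contact threshold is
#' not support); with `dragCounts = TRUE` drag cycles extend contact
#' through the swing (heavy-drag regime).
#'
#' @param truth truth table from [simulateRecording()].
#' @param times effective-sample times, e.g. [effectiveTimes()].
#' @param dragCounts treat drag as ground contact.
#' @return List with logical `left` and `right` masks.
#' @export
truthMasks <- function(truth, times, dragCounts = FALSE) {
  maskFor <- function(side) {
    rows <- truth[truth$side == side, ]
    m <- rep(FALSE, length(times))
    for (i in seq_len(nrow(rows))) {
      end <- if (dragCounts && !rows$liftoff[i] && i < nrow(rows))
        rows$start_s[i + 1L] else rows$end_s[i]
      m <- m | (times >= rows$start_s[i] & times < end)
    }
    m
  }
  list(left = maskFor("left"), right = maskFor("right"))
}

## Parkinsonian archetypes for cohort simulation: flat-foot / toe-led
## strike mixes, tremor comparable to or exceeding the (possibly
## suppressed) arm swing, and one absent-lift-off (drag) case.
.pdArchetypes <- function() list(
  list(strike = c(left = "flat", right = "flat"),
       liftoff = c(left = TRUE, right = TRUE), arm = TRUE),
  list(strike = c(left = "flat", right = "flat"),
       liftoff = c(left = TRUE, right = TRUE), arm = FALSE),
  list(strike = c(left = "flat", right = "toe_first"),
       liftoff = c(left = TRUE, right = FALSE), arm = FALSE),
  list(strike = c(left = "toe_first", right = "flat"),
       liftoff = c(left = TRUE, right = TRUE), arm = TRUE),
  list(strike = c(left = "flat", right = "flat"),
       liftoff = c(left = TRUE, right = TRUE), arm = TRUE))

#' Simulate a two-class gait cohort
#'
#' Draws per-subject parameters from documented ranges - physiological:
#' bilateral heel strike and lift-off, full arm swing, no tremor, stride
#' CoV 3-6%; Parkinsonian: flat-foot / toe-led strike mixes with one
#' drag case, tremor comparable to or exceeding the (possibly suppressed)
#' arm swing, stride CoV 6-13% - and simulates each subject.
#'
#' @param nPerClass subjects per class.
#' @param seed cohort seed (per-subject seeds are derived from it).
#' @param nCycles gait cycles per subject.
#' @return List of per-subject results as returned by
#'   [simulateRecording()], physiological subjects first.
#' @export
simulateCohort <- function(nPerClass = 5L, seed = 1L, nCycles = 12L) {
  if (nPerClass < 1L) stop("need at least one subject per class")
  .withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * nPerClass)
    out <- vector("list", 2L * nPerClass)
    arch <- .pdArchetypes()
    for (i in seq_len(nPerClass)) {
      p <- subjectParams(
        label = "physiological",
        cycleS = stats::runif(1, 2.0, 2.8),
        nCycles = nCycles,
        strideCovPct = stats::runif(1, 3, 6),
        armSwingAmp = stats::runif(1, 1.2, 1.8),
        tremorAmp = 0, seed = seeds[i])
      out[[i]] <- simulateRecording(p, sprintf("ctrl%02d", i))
    }
    for (i in seq_len(nPerClass)) {
      a <- arch[[(i - 1L) %% length(arch) + 1L]]
      swing <- if (a$arm) stats::runif(1, 0.9, 1.4) else stats::runif(1, 0.05, 0.15)
      tremor <- stats::runif(1, 1.0, 1.4) * max(swing, 0.8)
      p <- subjectParams(
        label = "pd",
        cycleS = stats::runif(1, 2.2, 3.0),
        nCycles = nCycles,
        strideCovPct = stats::runif(1, 6, 13),
        strike = a$strike, liftoff = a$liftoff,
        armSwingAmp = swing, tremorAmp = tremor,
        tremorHz = stats::runif(1, 4.5, 5.5),
        seed = seeds[nPerClass + i])
      out[[nPerClass + i]] <- simulateRecording(p, sprintf("pd%02d", i))
    }
    out
  })
}
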