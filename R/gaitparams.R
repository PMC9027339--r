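## Temporal and biomechanical gait parameters: cadence, single/double
## support, support ratio, stride-time variability (coefficient of
## variation) and the qualitative per-subject profile, plus group summary
## statistics.

#' Round half away from zero
#'
#' Report-formatting convention: one decimal, half rounded away from zero,
#' with a trailing ".0" dropped when formatting.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

.fmt1 <- function(x) {
  r <- roundHalfUp(x, 1)
  ifelse(r == floor(r), format(floor(r)), format(r, nsmall = 1))
}

#' Cadence in steps per minute
#'
#' Counts step events - each single-foot stance initiation, both feet -
#' inside the analysis window and extrapolates to one minute. One gait
#' cycle therefore contributes two steps.
#'
#' @param stances combined stance table (both sides) from
#'   [detectStances()].
#' @param windowS analysis window length (s).
#' @param windowStartS window start time (s).
#' @return Steps per minute.
#' @export
#' @examples
#' cadence(data.frame(start_s = seq(0, 9), end_s = seq(0.5, 9.5)))  # 60
cadence <- function(stances, windowS = 10, windowStartS = 0) {
  inWin <- stances$start_s >= windowStartS &
    stances$start_s < windowStartS + windowS
  n <- sum(inWin)
  if (n == 0L) warning("no step events inside the analysis window")
  n * 60 / windowS
}

#' Single- and double-support fractions
#'
#' Per-effective-sample contact masks per foot over the analysis window:
#' single support of one side is the fraction of the window with that foot
#' in contact and the other not; double support has both feet in contact.
#'
#' @param space a [SignalSpace-class].
#' @param windowS analysis window length (s).
#' @param windowStartS window start time (s).
#' @param cfg an [eventConfig()].
#' @param maskLeft,maskRight optional precomputed contact masks (override
#'   threshold detection, e.g. for ground-truth evaluation).
#' @return Named numeric: `single_left`, `single_right`, `double`, in
#'   percent of the window.
#' @export
supportFractions <- function(space, windowS = 10, windowStartS = 0,
                             cfg = eventConfig(), maskLeft = NULL,
                             maskRight = NULL) {
  if (is.null(maskLeft)) maskLeft <- contactMask(space, "left", cfg)
  if (is.null(maskRight)) maskRight <- contactMask(space, "right", cfg)
  t <- effectiveTimes(space)
  w <- t >= windowStartS & t < windowStartS + windowS
  nW <- sum(w)
  if (nW == 0L) return(c(single_left = 0, single_right = 0, double = 0))
  c(single_left = 100 * sum(maskLeft[w] & !maskRight[w]) / nW,
    single_right = 100 * sum(maskRight[w] & !maskLeft[w]) / nW,
    double = 100 * sum(maskLeft[w] & maskRight[w]) / nW)
}

#' Single-to-double support ratio
#'
#' @param singlePct single-support percentage of one side.
#' @param doublePct double-support percentage.
#' @return The ratio (unitless); `NA` with attribute `undefined = TRUE`
#'   when double support is zero.
#' @export
#' @examples
#' roundHalfUp(sdRatio(41.8, 14.9), 1)  # 2.8
sdRatio <- function(singlePct, doublePct) {
  if (doublePct == 0) return(structure(NA_real_, undefined = TRUE))
  singlePct / doublePct
}

#' Stride-time variability as a coefficient of variation
#'
#' `100 * sd / mean` of the stride durations, with the sample (n - 1)
#' standard deviation. A stride is the interval between consecutive
#' same-side stance initiations.
#'
#' @param strideDurations stride durations (s), at least 2.
#' @return CoV in percent; `NA` flagged `undefined` with fewer than 2
#'   strides.
#' @export
#' @examples
#' strideCov(c(0.9, 1.0, 1.1))  # 10
strideCov <- function(strideDurations) {
  if (length(strideDurations) < 2L)
    return(structure(NA_real_, undefined = TRUE))
  100 * stats::sd(strideDurations) / mean(strideDurations)
}

#' Stride durations from a stance table
#'
#' @param stances combined stance table.
#' @param windowS,windowStartS analysis window; strides whose initiating
#'   stance starts inside the window are kept.
#' @return Numeric vector of stride durations (s), both sides pooled.
#' @export
strideDurations <- function(stances, windowS = Inf, windowStartS = 0) {
  out <- numeric()
  for (sd in split(stances, stances$side)) {
    st <- sort(sd$start_s)
    if (length(st) >= 2L) {
      d <- diff(st)
      keep <- st[-length(st)] >= windowStartS &
        st[-length(st)] < windowStartS + windowS
      out <- c(out, d[keep])
    }
  }
  out
}

#' Temporal gait profile over a steady-state window
#'
#' Assembles cadence, single/double support, support ratios and stride CoV
#' from one analysis window (default the first full 10 s starting at the
#' first complete gait cycle).
#'
#' @param space a [SignalSpace-class].
#' @param stances combined stance table (both sides).
#' @param cfg an [eventConfig()].
#' @param windowS analysis window length (s).
#' @param windowStartS window start; `NULL` uses the first stance
#'   initiation (start of steady state).
#' @return A list of class `"TemporalParameters"`.
#' @export
temporalProfile <- function(space, stances, cfg = eventConfig(),
                            windowS = 10, windowStartS = NULL) {
  dur <- nSamples(space) / effectiveRate(space)
  if (is.null(windowStartS))
    windowStartS <- if (nrow(stances)) min(stances$start_s) else 0
  if (windowStartS + windowS > dur + timeOffset(space)) {
    warning("signal shorter than the requested window; using full length")
    windowS <- dur + timeOffset(space) - windowStartS
  }
  sup <- supportFractions(space, windowS, windowStartS, cfg)
  strides <- strideDurations(stances, windowS, windowStartS)
  res <- list(cadence_spm = cadence(stances, windowS, windowStartS),
              single_support_pct = c(left = unname(sup["single_left"]),
                                     right = unname(sup["single_right"])),
              double_support_pct = unname(sup["double"]),
              sd_ratio = c(left = unname(sdRatio(sup["single_left"],
                                                 sup["double"])),
                           right = unname(sdRatio(sup["single_right"],
                                                  sup["double"]))),
              stride_cov_pct = strideCov(strides),
              n_strides = length(strides),
              window_s = windowS, window_start_s = windowStartS)
  class(res) <- "TemporalParameters"
  res
}

#' @export
print.TemporalParameters <- function(x, ...) {
  cat("Temporal gait parameters (window", .fmt1(x$window_s), "s)\n")
  cat("  cadence:       ", .fmt1(x$cadence_spm), "steps/min\n")
  cat("  single support: left", .fmt1(x$single_support_pct["left"]),
      "%, right", .fmt1(x$single_support_pct["right"]), "%\n")
  cat("  double support:", .fmt1(x$double_support_pct), "%\n")
  cat("  S/D ratio:      left", .fmt1(x$sd_ratio["left"]),
      ", right", .fmt1(x$sd_ratio["right"]), "\n")
  cat("  stride CoV:    ", .fmt1(x$stride_cov_pct), "% over",
      x$n_strides, "strides\n")
  invisible(x)
}

#' Qualitative biomechanical gait profile
#'
#' Majority vote over gait cycles for the strike type and lift-off of each
#' side, plus the arm-balance and tremor assessments: the profile mirrors a
#' clinical rating-scale row (arm balance, tremor, heel strike, lift-off).
#'
#' @param space a [SignalSpace-class].
#' @param cfg an [eventConfig()].
#' @return A list of class `"BiomechanicalProfile"` with elements
#'   `arm_balance`, `tremor`, per-side `strike` (majority type with the
#'   vote fraction as attribute) and per-side `liftoff`
#'   (`"present"`/`"absent"`, absent when any swing shows drag or contact
#'   never ceases).
#' @export
biomechProfile <- function(space, cfg = eventConfig()) {
  sig <- signalMatrix(space)
  stL <- detectStances(space, "left", cfg)
  stR <- detectStances(space, "right", cfg)
  stances <- rbind(stL, stR)
  peaks <- detectMaPeaks(sig[, "MA"], cfg)
  peakT <- effectiveTimes(space)[peaks]

  strikeOf <- function(st) {
    if (nrow(st) == 0L) return(structure("indeterminate", fraction = NA_real_))
    tab <- table(st$strike_type)
    win <- names(tab)[which.max(tab)]
    structure(win, fraction = unname(tab[win]) / nrow(st))
  }
  liftoffOf <- function(st, side) {
    if (nrow(st) < 2L) return("absent")  # contact never ceased
    ok <- vapply(seq_len(nrow(st) - 1L), function(i)
      isTRUE(detectLiftoff(space, side, st[i, ], st[i + 1L, ], cfg)), TRUE)
    if (all(ok)) "present" else "absent"
  }
  res <- list(
    arm_balance = assessArmBalance(peakT, stances, cfg),
    tremor = gradeTremor(sig[, "MA"], sig[, "VA"], effectiveRate(space), cfg),
    strike = list(left = strikeOf(stL), right = strikeOf(stR)),
    liftoff = list(left = liftoffOf(stL, "left"),
                   right = liftoffOf(stR, "right")),
    n_stances = c(left = nrow(stL), right = nrow(stR)))
  class(res) <- "BiomechanicalProfile"
  res
}

#' @export
print.BiomechanicalProfile <- function(x, ...) {
  hs <- function(s) switch(s, heel_strike = "present",
                           flat_foot = "absent (flat-foot strike)",
                           toe_first = "absent (toe-first)", s)
  cat("Biomechanical gait profile\n")
  cat("  arm balance:", x$arm_balance, "\n")
  cat("  tremor:     ", paste0(unclass(x$tremor)), "\n")
  cat("  heel strike: left", hs(x$strike$left[1]), "| right",
      hs(x$strike$right[1]), "\n")
  cat("  lift-off:    left", x$liftoff$left, "| right", x$liftoff$right, "\n")
  invisible(x)
}

#' Group summary statistics
#'
#' Mean and sample (n - 1) standard deviation of a per-subject parameter,
#' as used for group rows of a cohort report.
#'
#' @param values per-subject values, length at least 2 for the sd.
#' @return A list of class `"GroupStats"` with `mean`, `sd`, `n`.
#' @export
#' @examples
#' groupStats(c(62, 27, 24, 56, 55))  # mean 44.8, sd 17.9
groupStats <- function(values) {
  n <- length(values)
  res <- list(mean = mean(values),
              sd = if (n >= 2L) stats::sd(values)
                   else structure(NA_real_, undefined = TRUE),
              n = n)
  class(res) <- "GroupStats"
  res
}

#' @export
print.GroupStats <- function(x, ...) {
  cat(.fmt1(x$mean), "±", .fmt1(x$sd), sprintf("(n = %d)\n", x$n))
  invisible(x)
}

#' Format a group statistic like a cohort table row
#'
#' @param gs a [groupStats()] result.
#' @return Character string `"mean +/- sd"` at one decimal with trailing
#'   ".0" dropped.
#' @export
formatGroupStats <- function(gs) paste(.fmt1(gs$mean), "±", .fmt1(gs$sd))
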