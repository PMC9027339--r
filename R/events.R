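## Gait event detection: stance segmentation from plantar pressure
## thresholding, MA peak detection, strike-type / lift-off classification
## and tremor grading.

#' Event-detection configuration
#'
#' @param thresholdFraction per-sensor contact threshold, as a fraction of
#'   that sensor's dynamic range (threshold = min + fraction * range).
#' @param liftoffFraction near-zero pressure threshold used for lift-off
#'   ("complete removal of plantar pressure"), as a fraction of the dynamic
#'   range; deliberately lower than `thresholdFraction` so that light foot
#'   drag is distinguished from true lift-off.
#' @param simultaneityTolS onset-simultaneity tolerance (s) separating a
#'   heel/toe-led strike from a flat-foot strike.
#' @param minStanceS minimum stance duration (s); shorter segments are
#'   discarded.
#' @param minSwingS minimum swing duration (s); shorter inter-stance gaps
#'   are merged.
#' @param maPeakProminenceFraction peak prominence threshold for MA peak
#'   detection, as a fraction of the MA dynamic range.
#' @param armBalanceWindowS coincidence window (s) between MA peaks and
#'   stance boundaries.
#' @param armBalanceRate minimum fraction of stance boundaries with a
#'   coincident MA peak for arm balance to be called present.
#' @param peakExcessFactor arm balance is called absent outright when MA
#'   peaks outnumber stance boundaries by more than this factor (dense
#'   tremor-induced peaks make boundary coincidence meaningless).
#' @param tremorBandHz tremor frequency band (Hz).
#' @param tremorImageBandHz rectification image of the tremor band: the
#'   acceleration magnitude folds a tremor sinusoid to twice its
#'   frequency when arm swing is weak, so this band is pooled with the
#'   tremor band when estimating tremor amplitude.
#' @param gaitBandHz gait-related frequency band (Hz) used as the reference
#'   for tremor amplitude.
#' @param tremorFloor amplitude ratio below which tremor is absent.
#' @param tremorSmallLargeRatio amplitude ratio separating small from large
#'   tremor.
#' @param tremorMixingGain calibration divisor mapping the raw MA band
#'   ratio onto the tremor-to-arm-swing amplitude ratio: the magnitude
#'   operation mixes tremor into its band with roughly 2.4 times the gain
#'   of the slower sway components (see the package vignette).
#' @return A list of class `"EventConfig"`.
#' @export
eventConfig <- function(thresholdFraction = 0.2, liftoffFraction = 0.05,
                        simultaneityTolS = 0.05, minStanceS = 0.2,
                        minSwingS = 0.1, maPeakProminenceFraction = 0.1,
                        armBalanceWindowS = 0.15, armBalanceRate = 0.6,
                        peakExcessFactor = 2.5,
                        tremorBandHz = c(4, 6), tremorImageBandHz = c(8, 12),
                        gaitBandHz = c(0.5, 4),
                        tremorFloor = 0.15, tremorSmallLargeRatio = 0.5,
                        tremorMixingGain = 2.4) {
  fr <- c(thresholdFraction, liftoffFraction, maPeakProminenceFraction,
          armBalanceRate)
  if (any(fr <= 0 | fr >= 1)) stop("fractions must lie in (0, 1)")
  if (any(c(simultaneityTolS, minStanceS, minSwingS, armBalanceWindowS) <= 0))
    stop("tolerances must be positive")
  structure(list(thresholdFraction = thresholdFraction,
                 liftoffFraction = liftoffFraction,
                 simultaneityTolS = simultaneityTolS,
                 minStanceS = minStanceS, minSwingS = minSwingS,
                 maPeakProminenceFraction = maPeakProminenceFraction,
                 armBalanceWindowS = armBalanceWindowS,
                 armBalanceRate = armBalanceRate,
                 peakExcessFactor = peakExcessFactor,
                 tremorBandHz = tremorBandHz,
                 tremorImageBandHz = tremorImageBandHz,
                 gaitBandHz = gaitBandHz,
                 tremorFloor = tremorFloor,
                 tremorSmallLargeRatio = tremorSmallLargeRatio,
                 tremorMixingGain = tremorMixingGain),
            class = "EventConfig")
}

.sideSites <- function(side) {
  side <- match.arg(side, c("left", "right"))
  stats::setNames(paste0(c("FSR0_", "FSR1_", "FSR2_"), side),
                  c("toe", "metatarsal", "heel"))
}

## Per-sensor thresholds: min + fraction * (max - min). Flat (zero-range)
## channels carry no contact evidence; they are reported by name and
## excluded (threshold NA -> all-FALSE mask).
.fsrThresholds <- function(space, side, fraction) {
  sites <- .sideSites(side)
  sig <- signalMatrix(space)
  th <- vapply(sites, function(s) {
    v <- sig[, s]
    rng <- max(v) - min(v)
    if (rng <= 0) {
      warning("flat (zero-range) plantar channel excluded: ", s)
      return(NA_real_)
    }
    min(v) + fraction * rng
  }, 0)
  names(th) <- names(sites)
  th
}

## Boolean contact matrix (samples x sites) for one foot.
.contactMatrix <- function(space, side, fraction) {
  sites <- .sideSites(side)
  th <- .fsrThresholds(space, side, fraction)
  sig <- signalMatrix(space)
  m <- sapply(names(sites), function(k)
    if (is.na(th[k])) rep(FALSE, nrow(sig)) else sig[, sites[k]] > th[k])
  colnames(m) <- names(sites)
  m
}

#' Per-foot contact mask
#'
#' TRUE where at least one of the foot's three plantar sensors is above its
#' contact threshold.
#'
#' @param space a [SignalSpace-class].
#' @param side `"left"` or `"right"`.
#' @param cfg an [eventConfig()].
#' @return Logical vector over effective samples.
#' @export
contactMask <- function(space, side, cfg = eventConfig()) {
  rowSums(.contactMatrix(space, side, cfg$thresholdFraction)) > 0
}

.runsOfTrue <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values] + 1L)  # half-open
}

#' Detect stance phases from plantar pressure
#'
#' A stance spans the first to the last suprathreshold sample across the
#' foot's three plantar sensors, where each sensor is compared to an
#' empirical threshold computed as a fraction of its dynamic range. Gaps
#' shorter than `minSwingS` are merged and segments shorter than
#' `minStanceS` discarded. The per-site first-onset times within each
#' segment are reported for strike-type classification.
#'
#' @param space a [SignalSpace-class].
#' @param side `"left"` or `"right"`.
#' @param cfg an [eventConfig()].
#' @return A data.frame with one row per stance: `side`, `start_idx`,
#'   `end_idx` (half-open, effective samples), `start_s`, `end_s`, the
#'   per-site onset times `onset_heel_s`, `onset_metatarsal_s`,
#'   `onset_toe_s` (NA when a site never crosses threshold) and
#'   `strike_type` from [classifyStrike()].
#' @export
detectStances <- function(space, side, cfg = eventConfig()) {
  cm <- .contactMatrix(space, side, cfg$thresholdFraction)
  mask <- rowSums(cm) > 0
  fs <- effectiveRate(space)
  t <- effectiveTimes(space)
  empty <- data.frame(side = character(), start_idx = integer(),
                      end_idx = integer(), start_s = numeric(),
                      end_s = numeric(), onset_heel_s = numeric(),
                      onset_metatarsal_s = numeric(), onset_toe_s = numeric(),
                      strike_type = character())
  if (!any(mask)) return(empty)
  seg <- .runsOfTrue(mask)
  ## merge gaps shorter than the minimum swing
  if (nrow(seg) > 1L) {
    keep <- matrix(seg[1, ], 1)
    for (i in 2:nrow(seg)) {
      gap <- (seg[i, 1] - keep[nrow(keep), 2]) / fs
      if (gap < cfg$minSwingS) keep[nrow(keep), 2] <- seg[i, 2]
      else keep <- rbind(keep, seg[i, ])
    }
    seg <- keep
  }
  seg <- seg[(seg[, 2] - seg[, 1]) / fs >= cfg$minStanceS, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  onset <- function(i, site) {
    idx <- seg[i, 1]:(seg[i, 2] - 1L)
    hit <- idx[cm[idx, site]]
    if (length(hit)) t[hit[1]] else NA_real_
  }
  out <- data.frame(
    side = side,
    start_idx = as.integer(seg[, 1]), end_idx = as.integer(seg[, 2]),
    start_s = t[seg[, 1]], end_s = t[seg[, 2] - 1L] + 1 / fs,
    onset_heel_s = vapply(seq_len(nrow(seg)), onset, 0, site = "heel"),
    onset_metatarsal_s = vapply(seq_len(nrow(seg)), onset, 0,
                                site = "metatarsal"),
    onset_toe_s = vapply(seq_len(nrow(seg)), onset, 0, site = "toe"))
  out$strike_type <- vapply(seq_len(nrow(out)), function(i)
    classifyStrike(out$onset_heel_s[i], out$onset_metatarsal_s[i],
                   out$onset_toe_s[i], cfg), "")
  out
}

#' Detect arm-balance MA peaks
#'
#' Local maxima of the MA series with topographic prominence of at least
#' `maPeakProminenceFraction` of the series' dynamic range.
#'
#' @param ma MA series.
#' @param cfg an [eventConfig()].
#' @return Sorted integer indices of the peaks.
#' @export
detectMaPeaks <- function(ma, cfg = eventConfig()) {
  n <- length(ma)
  if (n == 0L) stop("empty MA series")
  rng <- max(ma) - min(ma)
  if (rng <= 0) return(integer())
  cand <- which(diff(sign(diff(ma))) < 0) + 1L
  if (!length(cand)) return(integer())
  ## prominence: height above the higher of the two valley minima that
  ## separate the peak from the nearest higher terrain (or series edge)
  prom <- vapply(cand, function(p) {
    h <- ma[p]
    left <- if (p > 1) ma[1:(p - 1)] else numeric()
    right <- if (p < n) ma[(p + 1):n] else numeric()
    lh <- which(left >= h)
    base.l <- min(ma[if (length(lh)) (max(lh)):(p) else 1:p])
    rh <- which(right >= h)
    base.r <- min(ma[if (length(rh)) p:(p + min(rh)) else p:n])
    h - max(base.l, base.r)
  }, 0)
  sort(cand[prom >= cfg$maPeakProminenceFraction * rng])
}

#' Classify the foot-strike type from plantar onset times
#'
#' Physiological gait shows a heel-to-metatarsal-to-toe pressure
#' progression; Parkinsonian gait typically shows a flat-foot strike
#' (simultaneous onsets) or, in more advanced stages, a toe-led
#' progression.
#'
#' @param onsetHeel,onsetMetatarsal,onsetToe per-site onset times (s); NA
#'   for a site that never crosses threshold (it is excluded).
#' @param cfg an [eventConfig()]; `simultaneityTolS` separates a led strike
#'   from a flat-foot strike.
#' @return One of `"heel_strike"`, `"flat_foot"`, `"toe_first"`, or
#'   `"indeterminate"` when fewer than two sites were ever active.
#' @export
#' @examples
#' classifyStrike(0, 0.12, 0.25)   # heel_strike
#' classifyStrike(0, 0.01, 0.03)   # flat_foot
classifyStrike <- function(onsetHeel, onsetMetatarsal, onsetToe,
                           cfg = eventConfig()) {
  on <- c(heel = onsetHeel, metatarsal = onsetMetatarsal, toe = onsetToe)
  on <- on[!is.na(on)]
  if (length(on) < 2L) return("indeterminate")
  tol <- cfg$simultaneityTolS
  if (max(on) - min(on) <= tol) return("flat_foot")
  lead <- names(on)[which.min(on)]
  others <- on[names(on) != lead]
  if (lead == "heel" && all(others - on["heel"] > tol)) return("heel_strike")
  if (lead == "toe" && all(others - on["toe"] > tol)) return("toe_first")
  ## mixed orderings: fall back on the heel-vs-toe relation
  if (all(c("heel", "toe") %in% names(on))) {
    if (on["heel"] <= on["toe"] - tol) return("heel_strike")
    if (on["toe"] <= on["heel"] - tol) return("toe_first")
  }
  "flat_foot"
}

#' Detect lift-off between two consecutive stances
#'
#' Lift-off means complete removal of plantar pressure during the swing:
#' TRUE iff some sub-interval of the inter-stance gap has all three sensors
#' below the near-zero `liftoffFraction` threshold. FALSE indicates foot
#' drag (residual contact throughout the swing).
#'
#' @param space a [SignalSpace-class].
#' @param side `"left"` or `"right"`.
#' @param seg1,seg2 two consecutive same-side rows of [detectStances()].
#' @param cfg an [eventConfig()].
#' @return Logical; a zero-length gap returns FALSE with attribute
#'   `degenerate = TRUE`.
#' @export
detectLiftoff <- function(space, side, seg1, seg2, cfg = eventConfig()) {
  gap <- seq.int(seg1$end_idx, seg2$start_idx - 1L)
  if (length(gap) == 0L || seg2$start_idx <= seg1$end_idx)
    return(structure(FALSE, degenerate = TRUE))
  cm <- .contactMatrix(space, side, cfg$liftoffFraction)
  any(rowSums(cm[gap, , drop = FALSE]) == 0)
}

#' Assess the presence of arm balance
#'
#' Physiological arm sway reverses direction at stance initiation and
#' termination, producing MA peaks coincident with stance boundaries. Arm
#' balance is called present when at least `armBalanceRate` of the stance
#' boundary times have an MA peak within `armBalanceWindowS`. When MA peaks
#' outnumber the boundaries by more than `peakExcessFactor` (dense
#' tremor-induced peaks), coincidence is uninformative and arm balance is
#' called absent.
#'
#' @param maPeakTimes MA peak times (s), e.g. from [detectMaPeaks()] mapped
#'   through [effectiveTimes()].
#' @param stances combined stance table (both sides).
#' @param cfg an [eventConfig()].
#' @return `"present"` or `"absent"`; `"indeterminate"` with fewer than 3
#'   stance boundaries.
#' @export
assessArmBalance <- function(maPeakTimes, stances, cfg = eventConfig()) {
  bounds <- sort(c(stances$start_s, stances$end_s))
  if (length(bounds) < 3L) return("indeterminate")
  if (length(maPeakTimes) == 0L) return("absent")
  if (length(maPeakTimes) > cfg$peakExcessFactor * length(bounds))
    return("absent")
  hit <- vapply(bounds, function(b)
    min(abs(maPeakTimes - b)) <= cfg$armBalanceWindowS, TRUE)
  if (mean(hit) >= cfg$armBalanceRate) "present" else "absent"
}

## Band amplitude estimate from the periodogram: sqrt of twice the power in
## the band (equals the amplitude for a pure sinusoid).
.bandAmplitude <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > band[1] & f <= band[2] & f <= fs / 2
  sqrt(2 * 2 * sum(p[keep]))  # x2 for the mirrored half-spectrum
}

#' Grade tremor from the arm-balance signals
#'
#' Compares the amplitude of the MA spectrum in the tremor band (4-6 Hz,
#' pooled with its 8-12 Hz rectification image: the magnitude operation
#' folds a tremor sinusoid to twice its frequency when arm swing is weak)
#' to the amplitude in the gait-related band (0.5-4 Hz). The amplitude
#' ratio is graded against two thresholds: below `tremorFloor` tremor is
#' absent; between the floor and `tremorSmallLargeRatio` it is small;
#' above, large. The grading is a quantitative operationalization of the
#' qualitative small/large tremor classes.
#'
#' @param ma,va MA and VA series (the ratio is computed on MA; VA is
#'   accepted for interface completeness).
#' @param fsEff effective sampling rate (Hz).
#' @param cfg an [eventConfig()].
#' @return `"absent"`, `"small"` or `"large"`, with the measured amplitude
#'   ratio in attribute `ratio`.
#' @export
gradeTremor <- function(ma, va, fsEff, cfg = eventConfig()) {
  if (length(ma) == 0L) stop("empty MA series")
  tremor <- sqrt(.bandAmplitude(ma, fsEff, cfg$tremorBandHz)^2 +
                 .bandAmplitude(ma, fsEff, cfg$tremorImageBandHz)^2)
  gait <- .bandAmplitude(ma, fsEff, cfg$gaitBandHz)
  ratio <- if (gait > 0) tremor / gait / cfg$tremorMixingGain
           else if (tremor > 0) Inf else 0
  grade <- if (ratio < cfg$tremorFloor) "absent"
           else if (ratio < cfg$tremorSmallLargeRatio) "small"
           else "large"
  structure(grade, ratio = ratio)
}

#' Export stance segments as tabular text
#'
#' BED-like tab-separated table (side, start_s, end_s, strike type) for
#' quick inspection.
#'
#' @param stances a stance table from [detectStances()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
exportStanceTable <- function(stances, path) {
  utils::write.table(stances, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
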