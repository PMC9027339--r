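## Signal conditioning: FSR divider inversion, decimating block averaging,
## zero-phase Butterworth band-limiting, acceleration conversion and the
## MA/VA arm-balance metrics, assembled into the 12-signal space.

#' Convert FSR divider voltage to sensor resistance
#'
#' The plantar pressure sensors are force-sense resistors read through a
#' resistive divider with supply `vDd` and series resistance `rDiv`, so the
#' sensor resistance is `v / (vDd - v) * rDiv` - strictly increasing in the
#' measured voltage.
#'
#' @param vFsr voltage drop(s) across the sensor, in `[0, vDd)`.
#' @param consts acquisition constants ([acquisitionConstants()]).
#' @return Resistance in ohms, same length as `vFsr`.
#' @export
#' @examples
#' fsrFromVoltage(2.5)  # divider midpoint: equals rDiv (1e6 ohm)
fsrFromVoltage <- function(vFsr, consts = acquisitionConstants()) {
  if (any(!is.finite(vFsr))) stop("non-finite FSR voltage")
  if (any(vFsr < 0)) stop("negative FSR voltage outside divider domain")
  if (any(vFsr >= consts$vDd))
    stop("FSR voltage at or above the supply: divider saturated")
  vFsr / (consts$vDd - vFsr) * consts$rDiv
}

#' Invert the polarity of a resistance series
#'
#' Returns `max(series) - series`, so that pressure (low sensor resistance)
#' maps to a HIGH signal level and absence of pressure to LOW.
#'
#' @param series finite, nonempty resistance series.
#' @return Series with reversed order statistics; its minimum is 0.
#' @export
#' @examples
#' fsrInvert(c(1, 3, 2))
fsrInvert <- function(series) {
  if (length(series) == 0L) stop("empty series")
  if (any(!is.finite(series))) stop("non-finite values in series")
  max(series) - series
}

#' Decimating block average
#'
#' Averages the input over rectangular frames of `window` samples whose
#' starts are `window * (1 - overlapFraction)` samples apart. The output is
#' one mean per frame, i.e. the series is decimated to an effective rate of
#' `fsHz / hop` (25 Hz for the default 8-sample window with 50% overlap at
#' 100 Hz).
#'
#' @param series input at the acquisition rate.
#' @param window frame length in samples.
#' @param overlapFraction fraction of frame overlap in `[0, 1)`.
#' @param fsHz input sampling rate (Hz).
#' @return List with `x` (frame means) and `fsEffHz`.
#' @export
#' @examples
#' blockAverage(0:11, window = 8, overlapFraction = 0.5, fsHz = 100)$x
blockAverage <- function(series, window = 8L, overlapFraction = 0.5,
                         fsHz = 100) {
  hop <- window * (1 - overlapFraction)
  if (abs(hop - round(hop)) > 1e-9 || hop < 1)
    stop("window * (1 - overlapFraction) must be a positive integer hop")
  hop <- as.integer(round(hop))
  n <- length(series)
  if (n < window) stop("series shorter than one averaging window")
  nFrames <- (n - window) %/% hop + 1L
  starts <- (seq_len(nFrames) - 1L) * hop
  cs <- c(0, cumsum(series))
  x <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
  list(x = x, fsEffHz = fsHz / hop, hop = hop, window = as.integer(window))
}

#' Butterworth filter specification
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param fcHz cutoff frequency in Hz.
#' @param order filter order.
#' @param zeroPhase apply forward-backward (zero-phase) by default; set
#'   `FALSE` for causal single-pass filtering.
#' @return A list of class `"FilterSpec"`.
#' @export
filterSpec <- function(kind = c("highpass", "lowpass"), fcHz, order = 4L,
                       zeroPhase = TRUE) {
  kind <- match.arg(kind)
  if (order < 1L) stop("filter order must be >= 1")
  if (!is.finite(fcHz) || fcHz <= 0) stop("cutoff must be positive")
  structure(list(kind = kind, fcHz = fcHz, order = as.integer(order),
                 zeroPhase = isTRUE(zeroPhase)), class = "FilterSpec")
}

## Minimum input length for stable zero-phase application.
.filterMinLength <- function(order) 3L * (order + 1L)

## Direct-form II transposed filtering with explicit initial state.
.df2t <- function(b, a, x, zi) {
  m <- length(a) - 1L
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (m > 1L)
      for (j in seq_len(m - 1L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
    z[m] <- b[m + 1L] * x[i] - a[m + 1L] * y[i]
    z
  }
  list(y = y)
}

## Steady-state initial filter state for a unit step (lfilter_zi).
.stepState <- function(b, a) {
  m <- length(a) - 1L
  comp <- rbind(-a[2:(m + 1L)],
                cbind(diag(1, m - 1L), rep(0, m - 1L)))
  B <- b[2:(m + 1L)] - a[2:(m + 1L)] * b[1]
  solve(diag(m) - t(comp), B)
}

## Zero-phase (forward-backward) filtering with reflection padding and
## steady-state initial conditions, so constant inputs pass (or are
## rejected) without edge transients.
.filtfilt <- function(b, a, x) {
  n <- length(x)
  nfact <- 3L * (length(a) - 1L)
  if (n <= nfact) stop("input too short for zero-phase filtering")
  zi <- .stepState(b, a)
  ext <- c(2 * x[1] - x[(nfact + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- .df2t(b, a, ext, zi * ext[1])$y
  y <- rev(.df2t(b, a, rev(y), zi * y[length(y)])$y)
  y[(nfact + 1L):(nfact + n)]
}

#' Apply a Butterworth filter
#'
#' Designs a digital Butterworth filter of the given specification and
#' applies it, by default forward-backward (zero phase) so that event
#' timing is preserved across channels. Input length must be at least
#' `3 * (order + 1)` samples (filter warm-up).
#'
#' @param series input series.
#' @param fsHz sampling rate of `series` (Hz).
#' @param spec a [filterSpec()].
#' @return Filtered series, same length as the input.
#' @export
butterFilter <- function(series, fsHz, spec) {
  stopifnot(inherits(spec, "FilterSpec"))
  if (spec$fcHz >= fsHz / 2)
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$fcHz, fsHz / 2))
  if (length(series) < .filterMinLength(spec$order))
    stop(sprintf("input too short for order-%d filtering (need >= %d samples)",
                 spec$order, .filterMinLength(spec$order)))
  type <- if (spec$kind == "highpass") "high" else "low"
  bf <- signal::butter(spec$order, spec$fcHz / (fsHz / 2), type = type)
  if (spec$zeroPhase) .filtfilt(bf$b, bf$a, series)
  else as.numeric(signal::filter(bf, series))
}

#' EMG conditioning chain
#'
#' Extracts a band-limited activation envelope from raw EMG: the signal is
#' rectified about its mean (envelope detection), block-averaged to the
#' effective rate, high-passed at 0.5 Hz to suppress the DC component, and
#' low-passed at 10 Hz. The 10 Hz band reflects that muscular activity is
#' identified, not evaluated at motor-unit level.
#'
#' @param rawEmg raw EMG at the acquisition rate.
#' @param fsHz acquisition rate (Hz).
#' @param window,overlapFraction block-averaging parameters.
#' @param fcLowHz,fcHighHz high-pass / low-pass cutoffs (Hz).
#' @param rectify rectify about the mean before averaging (default);
#'   `FALSE` band-limits the raw signal instead.
#' @param zeroPhase zero-phase filtering flag.
#' @return List with `x` (conditioned series) and `fsEffHz`.
#' @export
emgPipeline <- function(rawEmg, fsHz = 100, window = 8L,
                        overlapFraction = 0.5, fcLowHz = 0.5, fcHighHz = 10,
                        rectify = TRUE, zeroPhase = TRUE) {
  x <- if (rectify) abs(rawEmg - mean(rawEmg)) else rawEmg
  ba <- blockAverage(x, window, overlapFraction, fsHz)
  y <- butterFilter(ba$x, ba$fsEffHz,
                    filterSpec("highpass", fcLowHz, zeroPhase = zeroPhase))
  y <- butterFilter(y, ba$fsEffHz,
                    filterSpec("lowpass", fcHighHz, zeroPhase = zeroPhase))
  list(x = y, fsEffHz = ba$fsEffHz)
}

#' Acceleration conditioning chain
#'
#' Converts raw accelerometer codes to m/s^2 by full-scale conversion
#' (`accelRangeG` g over signed `accelBits`-bit codes), low-passes at 30 Hz
#' at the acquisition rate (applied before decimation so the cutoff stays
#' below Nyquist), block-averages to the effective rate, and high-passes at
#' 0.5 Hz to remove the gravity/DC component.
#'
#' @param rawXyz N x 3 matrix of raw axis codes.
#' @param fsHz acquisition rate (Hz).
#' @param consts acquisition constants.
#' @param window,overlapFraction block-averaging parameters.
#' @param fcLowHz,fcHighHz high-pass / low-pass cutoffs (Hz).
#' @param zeroPhase zero-phase filtering flag.
#' @return List with `xyz` (N_eff x 3 matrix, m/s^2) and `fsEffHz`.
#' @export
accelPipeline <- function(rawXyz, fsHz = 100, consts = acquisitionConstants(),
                          window = 8L, overlapFraction = 0.5, fcLowHz = 0.5,
                          fcHighHz = 30, zeroPhase = TRUE) {
  rawXyz <- as.matrix(rawXyz)
  if (ncol(rawXyz) != 3L) stop("rawXyz must have three axes")
  scale <- consts$accelRangeG * 9.81 / 2^(consts$accelBits - 1)
  out <- NULL
  fsEff <- NA_real_
  for (j in 1:3) {
    a <- rawXyz[, j] * scale
    a <- butterFilter(a, fsHz, filterSpec("lowpass", fcHighHz,
                                          zeroPhase = zeroPhase))
    ba <- blockAverage(a, window, overlapFraction, fsHz)
    y <- butterFilter(ba$x, ba$fsEffHz,
                      filterSpec("highpass", fcLowHz, zeroPhase = zeroPhase))
    if (is.null(out)) out <- matrix(0, length(y), 3,
                                    dimnames = list(NULL, c("x", "y", "z")))
    out[, j] <- y
    fsEff <- ba$fsEffHz
  }
  list(xyz = out, fsEffHz = fsEff)
}

#' Magnitude of acceleration (MA)
#'
#' Euclidean norm of the three dynamic acceleration axes (Pythagorean
#' theorem), the arm-balance magnitude descriptor.
#'
#' @param ax,ay,az equal-length axis series (m/s^2).
#' @return Nonnegative MA series.
#' @export
#' @examples
#' magnitudeOfAcceleration(3, 4, 0)  # 5
magnitudeOfAcceleration <- function(ax, ay, az) {
  if (length(ay) != length(ax) || length(az) != length(ax))
    stop("axis length mismatch")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Variation of acceleration (VA)
#'
#' For each sample k >= 2, the Euclidean distance of the current axis
#' readings from the running mean of all strictly past readings:
#' `VA(k) = sqrt(sum_axis (v(k) - mean(v[1..k-1]))^2)`. `VA(1)` is defined
#' as 0 (the mean over zero past samples is undefined; 0 is the neutral
#' convention).
#'
#' @param ax,ay,az equal-length axis series (m/s^2).
#' @return Nonnegative VA series of the same length.
#' @export
#' @examples
#' variationOfAcceleration(c(1, 3), c(0, 0), c(0, 0))  # c(0, 2)
variationOfAcceleration <- function(ax, ay, az) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) stop("axis length mismatch")
  if (n == 0L) return(numeric())
  pastMean <- function(v) {
    if (n == 1L) return(0)
    c(0, cumsum(v)[-n] / seq_len(n - 1L))
  }
  va <- sqrt((ax - pastMean(ax))^2 + (ay - pastMean(ay))^2 +
             (az - pastMean(az))^2)
  va[1] <- 0
  va
}

#' Assemble the conditioned 12-signal space
#'
#' Runs the full conditioning front end on a raw recording: the six FSR
#' voltages are converted to resistance (kilo-ohm), polarity-inverted and
#' block-averaged; the four EMG channels go through [emgPipeline()]; the
#' acceleration axes go through [accelPipeline()] and yield the MA and VA
#' arm-balance metrics. The result is the canonical ordered signal space at
#' the effective rate (see [gaitSignalNames()]).
#'
#' @param rec a [GaitRecording-class].
#' @param consts acquisition constants.
#' @param window,overlapFraction block-averaging parameters.
#' @param zeroPhase zero-phase filtering flag.
#' @return A [SignalSpace-class].
#' @export
buildSignalSpace <- function(rec, consts = acquisitionConstants(),
                             window = 8L, overlapFraction = 0.5,
                             zeroPhase = TRUE) {
  stopifnot(methods::is(rec, "GaitRecording"))
  fs <- rec@fsHz

  fsrCond <- function(v) {
    r <- fsrFromVoltage(pmin(v, consts$vDd * (1 - 1e-9)), consts) / 1e3
    blockAverage(fsrInvert(r), window, overlapFraction, fs)$x
  }
  fsrIdx <- c(toe = 1L, metatarsal = 2L, heel = 3L)
  fsrL <- lapply(fsrIdx, function(j) fsrCond(rec@fsrV[, j]))
  fsrR <- lapply(fsrIdx, function(j) fsrCond(rec@fsrV[, j + 3L]))

  emgC <- lapply(1:4, function(j)
    emgPipeline(rec@emg[, j], fs, window, overlapFraction,
                zeroPhase = zeroPhase)$x)

  acc <- accelPipeline(rec@accel, fs, consts, window, overlapFraction,
                       zeroPhase = zeroPhase)
  ma <- magnitudeOfAcceleration(acc$xyz[, 1], acc$xyz[, 2], acc$xyz[, 3])
  va <- variationOfAcceleration(acc$xyz[, 1], acc$xyz[, 2], acc$xyz[, 3])

  sig <- cbind(ma, va, emgC[[1]], emgC[[2]],
               fsrL$toe, fsrL$metatarsal, fsrL$heel,
               emgC[[3]], emgC[[4]],
               fsrR$toe, fsrR$metatarsal, fsrR$heel)
  colnames(sig) <- .SIGNAL_ORDER
  hop <- window * (1 - overlapFraction)
  methods::new("SignalSpace", signals = sig, fsEffHz = fs / hop,
               t0S = (window - 1) / (2 * fs))
}

#' Time stamps of the effective samples of a signal space
#'
#' @param space a [SignalSpace-class].
#' @return Seconds on the raw acquisition clock (frame centers).
#' @export
effectiveTimes <- function(space) {
  timeOffset(space) + (seq_len(nSamples(space)) - 1L) / effectiveRate(space)
}
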