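## Central S4 containers: raw telemetry, the conditioned 12-signal space,
## and the 120 x 120 shifted-signal correlation coefficient matrix.

.FSR_CHANNELS <- c("left.toe", "left.metatarsal", "left.heel",
                   "right.toe", "right.metatarsal", "right.heel")
.EMG_CHANNELS <- c("left.TA", "left.GM", "right.TA", "right.GM")
.ACCEL_AXES   <- c("x", "y", "z")

## Conditioned signal order: arm-balance magnitude (MA) and variation (VA)
## of acceleration, then per side TA/GM envelopes and the three plantar
## sensors (FSR0 toe, FSR1 metatarsal arch, FSR2 heel).
.SIGNAL_ORDER <- c("MA", "VA",
                   "TA_left", "GM_left", "FSR0_left", "FSR1_left", "FSR2_left",
                   "TA_right", "GM_right", "FSR0_right", "FSR1_right",
                   "FSR2_right")

.GAIT_LABELS <- c("physiological", "pd", "unknown")

#' Signal names of the conditioned gait signal space
#'
#' Returns the canonical ordering of the 12 conditioned signals: arm-balance
#' MA and VA, then Tibialis anterior / Gastrocnemius medialis envelopes and
#' the toe (FSR0), metatarsal-arch (FSR1) and heel (FSR2) plantar sensors,
#' left side before right.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' gaitSignalNames()
gaitSignalNames <- function() .SIGNAL_ORDER

#' Acquisition constants of the wearable physiograph
#'
#' Electrical and scaling constants of the acquisition front end: the
#' plantar pressure sensors are force-sense resistors (FSR) read through a
#' resistive divider, and the wrist accelerometer is a +/- `accelRangeG` g
#' device whose raw codes are signed `accelBits`-bit integers.
#'
#' @param vDd divider supply voltage in volts.
#' @param rDiv divider resistance in ohms.
#' @param accelRangeG accelerometer full scale in g.
#' @param adcBits resolution of the pressure/EMG ADC.
#' @param accelBits resolution of the accelerometer raw codes.
#' @return A list of class `"AcquisitionConstants"`.
#' @export
#' @examples
#' acquisitionConstants()
acquisitionConstants <- function(vDd = 5, rDiv = 1e6, accelRangeG = 2,
                                 adcBits = 10, accelBits = 16) {
  vals <- c(vDd = vDd, rDiv = rDiv, accelRangeG = accelRangeG,
            adcBits = adcBits, accelBits = accelBits)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition constants must be finite and strictly positive")
  structure(as.list(vals), class = "AcquisitionConstants")
}

#' GaitRecording: raw synchronized multichannel gait telemetry
#'
#' Holds one subject's raw telemetry sampled synchronously at `fsHz`
#' (nominally 100 Hz): six plantar-pressure voltages (three per foot: toe,
#' metatarsal arch, heel), four raw EMG channels (Tibialis anterior and
#' Gastrocnemius medialis, both legs) and the three wrist acceleration axes
#' in raw device codes.
#'
#' @slot subjectId opaque subject identifier.
#' @slot label `"physiological"`, `"pd"` or `"unknown"`.
#' @slot fsHz sampling frequency in Hz.
#' @slot time sample timestamps in seconds (uniform, spacing `1/fsHz`).
#' @slot fsrV N x 6 matrix of FSR voltages (V), columns
#'   `left.toe`, `left.metatarsal`, `left.heel`, then the right side.
#' @slot emg N x 4 matrix of raw EMG (`left.TA`, `left.GM`, `right.TA`,
#'   `right.GM`).
#' @slot accel N x 3 matrix of raw acceleration codes (`x`, `y`, `z`).
#' @slot meta free-form key/value annotations.
#' @export
setClass("GaitRecording",
         representation(subjectId = "character", label = "character",
                        fsHz = "numeric", time = "numeric",
                        fsrV = "matrix", emg = "matrix", accel = "matrix",
                        meta = "list"))

setValidity("GaitRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(object@label) != 1L || !object@label %in% .GAIT_LABELS)
    msg <- c(msg, "label must be one of physiological/pd/unknown")
  if (length(object@fsHz) != 1L || !is.finite(object@fsHz) || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  n <- length(object@time)
  if (n < 1L) msg <- c(msg, "recording must contain at least one sample")
  if (ncol(object@fsrV) != 6L || !identical(colnames(object@fsrV), .FSR_CHANNELS))
    msg <- c(msg, "fsrV must have the 6 canonical plantar channels")
  if (ncol(object@emg) != 4L || !identical(colnames(object@emg), .EMG_CHANNELS))
    msg <- c(msg, "emg must have the 4 canonical EMG channels")
  if (ncol(object@accel) != 3L || !identical(colnames(object@accel), .ACCEL_AXES))
    msg <- c(msg, "accel must have the x/y/z axes")
  if (nrow(object@fsrV) != n || nrow(object@emg) != n || nrow(object@accel) != n)
    msg <- c(msg, "all channels must share the time-base length")
  if (length(msg)) msg else TRUE
})

#' Construct a GaitRecording
#'
#' Builds and (optionally) validates a [GaitRecording-class]. Timestamps are
#' regenerated from `fsHz` when absent, reflecting the synchronous-sampling
#' acquisition of the device.
#'
#' @param subjectId subject identifier.
#' @param label gait label (`"physiological"`, `"pd"`, `"unknown"`).
#' @param fsHz sampling frequency (Hz).
#' @param fsrV,emg,accel channel matrices (see [GaitRecording-class]).
#' @param time optional timestamp vector; defaults to `(0:(N-1))/fsHz`.
#' @param meta list of free-form annotations.
#' @param consts acquisition constants used for range validation.
#' @param validate if `TRUE` (default) reject recordings violating any
#'   invariant; set `FALSE` to construct deliberately broken fixtures for
#'   [validateRecording()].
#' @return A [GaitRecording-class].
#' @export
#' @examples
#' rec <- gaitRecording("s1", "physiological", 100,
#'                      fsrV = matrix(0, 10, 6), emg = matrix(0, 10, 4),
#'                      accel = matrix(0, 10, 3))
#' nSamples(rec)
gaitRecording <- function(subjectId, label = "unknown", fsHz = 100,
                          fsrV, emg, accel, time = NULL, meta = list(),
                          consts = acquisitionConstants(), validate = TRUE) {
  fsrV <- as.matrix(fsrV); emg <- as.matrix(emg); accel <- as.matrix(accel)
  colnames(fsrV) <- .FSR_CHANNELS
  colnames(emg) <- .EMG_CHANNELS
  colnames(accel) <- .ACCEL_AXES
  if (is.null(time)) time <- (seq_len(nrow(fsrV)) - 1) / fsHz
  obj <- methods::new("GaitRecording", subjectId = as.character(subjectId),
                      label = label, fsHz = fsHz, time = as.numeric(time),
                      fsrV = fsrV, emg = emg, accel = accel, meta = meta)
  if (validate) {
    rep <- validateRecording(obj, consts)
    if (nrow(rep) > 0L)
      stop("invalid recording: ", paste(rep$message, collapse = "; "))
  }
  obj
}

#' SignalSpace: the 12 conditioned gait signals on a common time base
#'
#' The conditioned signal space produced by [buildSignalSpace()]: arm-balance
#' MA and VA in m/s^2, four EMG envelopes, and six polarity-inverted plantar
#' resistances in kilo-ohms, all at the effective rate left after block
#' averaging.
#'
#' @slot signals N x 12 matrix, columns ordered as [gaitSignalNames()].
#' @slot fsEffHz effective sampling rate in Hz.
#' @slot t0S time (s) of the first effective sample on the raw clock.
#' @export
setClass("SignalSpace",
         representation(signals = "matrix", fsEffHz = "numeric",
                        t0S = "numeric"))

setValidity("SignalSpace", function(object) {
  msg <- character()
  if (!identical(colnames(object@signals), .SIGNAL_ORDER))
    msg <- c(msg, "signals must hold the 12 canonical series in order")
  if (!all(is.finite(object@signals)))
    msg <- c(msg, "all conditioned samples must be finite")
  if (length(object@fsEffHz) != 1L || object@fsEffHz <= 0)
    msg <- c(msg, "fsEffHz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: shifted-signal Pearson coefficients of one gait frame
#'
#' Pairwise Pearson coefficients over the 12 conditioned signals and their
#' `nShifts` delayed versions (120 series in total), computed on one signal
#' frame (typically a stance phase). Row/column `10 * (i - 1) + s + 1`
#' corresponds to signal `i` delayed by `s` shift steps.
#'
#' @slot m 120 x 120 coefficient matrix in `[-1, 1]` (NA where a shifted
#'   series had zero variance within the frame).
#' @slot signalOrder the 12 signal names.
#' @slot nShifts number of shifted versions per signal (10).
#' @slot shiftStep effective samples per shift.
#' @slot fsEffHz effective rate of the source frame (Hz).
#' @slot frame integer `c(start, end)` of the half-open source frame.
#' @slot side frame context (`"left"`, `"right"` or `""`).
#' @export
setClass("CorrelationMatrix",
         representation(m = "matrix", signalOrder = "character",
                        nShifts = "integer", shiftStep = "integer",
                        fsEffHz = "numeric", frame = "integer",
                        side = "character"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  d <- length(object@signalOrder) * object@nShifts
  if (!all(dim(object@m) == c(d, d)))
    msg <- c(msg, sprintf("matrix must be %d x %d", d, d))
  ok <- is.finite(object@m)
  if (any(abs(object@m[ok]) > 1 + 1e-9))
    msg <- c(msg, "coefficients must lie in [-1, 1]")
  if (max(abs(object@m - t(object@m)), na.rm = TRUE) > 1e-9)
    msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname pdgait-accessors
#' @export
setMethod("subjectId", "GaitRecording", function(object) object@subjectId)

#' @rdname pdgait-accessors
#' @export
setMethod("gaitLabel", "GaitRecording", function(object) object@label)

#' @rdname pdgait-accessors
#' @export
setMethod("samplingRate", "GaitRecording", function(object) object@fsHz)

#' @rdname pdgait-accessors
#' @export
setMethod("nSamples", "GaitRecording", function(object) length(object@time))

#' @rdname pdgait-accessors
#' @export
setMethod("fsrVolts", "GaitRecording", function(object) object@fsrV)

#' @rdname pdgait-accessors
#' @export
setMethod("emgRaw", "GaitRecording", function(object) object@emg)

#' @rdname pdgait-accessors
#' @export
setMethod("accelRaw", "GaitRecording", function(object) object@accel)

#' @rdname pdgait-accessors
#' @export
setMethod("signalMatrix", "SignalSpace", function(object) object@signals)

#' @rdname pdgait-accessors
#' @export
setMethod("effectiveRate", "SignalSpace", function(object) object@fsEffHz)

#' @rdname pdgait-accessors
#' @export
setMethod("timeOffset", "SignalSpace", function(object) object@t0S)

#' @rdname pdgait-accessors
#' @export
setMethod("nSamples", "SignalSpace", function(object) nrow(object@signals))

#' @rdname pdgait-accessors
#' @export
setMethod("corrValues", "CorrelationMatrix", function(object) object@m)

#' @rdname pdgait-accessors
#' @export
setMethod("signalOrder", "CorrelationMatrix", function(object) object@signalOrder)

#' @rdname pdgait-accessors
#' @export
setMethod("shiftStep", "CorrelationMatrix", function(object) object@shiftStep)

#' @rdname pdgait-accessors
#' @export
setMethod("effectiveRate", "CorrelationMatrix", function(object) object@fsEffHz)

## ---- show methods ----

setMethod("show", "GaitRecording", function(object) {
  cat(sprintf("GaitRecording '%s' (%s)\n", object@subjectId, object@label))
  cat(sprintf("  %d samples at %g Hz (%.2f s)\n", length(object@time),
              object@fsHz, length(object@time) / object@fsHz))
  cat("  channels: 6 FSR (V), 4 EMG, 3 accel axes\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SignalSpace", function(object) {
  cat(sprintf("SignalSpace: %d effective samples at %g Hz (t0 = %.3f s)\n",
              nrow(object@signals), object@fsEffHz, object@t0S))
  cat("  signals:", paste(colnames(object@signals), collapse = ", "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  d <- nrow(object@m)
  cat(sprintf("CorrelationMatrix %d x %d (%d signals x %d shifts, step %d)\n",
              d, d, length(object@signalOrder), object@nShifts,
              object@shiftStep))
  cat(sprintf("  frame [%d, %d) at %g Hz%s; %d flagged entries\n",
              object@frame[1], object@frame[2], object@fsEffHz,
              if (nzchar(object@side)) paste0(", side ", object@side) else "",
              sum(!is.finite(object@m))))
})
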