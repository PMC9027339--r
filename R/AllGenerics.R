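#' @include AllClasses.R
NULL

#' Accessors for gait telemetry containers
#'
#' `subjectId()`, `gaitLabel()`, `samplingRate()` and `nSamples()` access the
#' metadata of a [GaitRecording-class]; `fsrVolts()`, `emgRaw()` and
#' `accelRaw()` return the raw channel matrices. `signalMatrix()`,
#' `effectiveRate()` and `timeOffset()` access the conditioned
#' [SignalSpace-class]; `corrValues()`, `signalOrder()` and `shiftStep()`
#' access a [CorrelationMatrix-class].
#'
#' @param object a pdgait S4 object.
#' @return The slot value (see the class documentation for units).
#' @name pdgait-accessors
#' @aliases subjectId gaitLabel samplingRate nSamples fsrVolts emgRaw
#'   accelRaw signalMatrix effectiveRate timeOffset corrValues signalOrder
#'   shiftStep
#' @examples
#' rec <- simulateRecording(subjectParams(nCycles = 3, seed = 1))$recording
#' subjectId(rec)
#' samplingRate(rec)
NULL

#' @rdname pdgait-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname pdgait-accessors
#' @export
setGeneric("gaitLabel", function(object) standardGeneric("gaitLabel"))

#' @rdname pdgait-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname pdgait-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname pdgait-accessors
#' @export
setGeneric("fsrVolts", function(object) standardGeneric("fsrVolts"))

#' @rdname pdgait-accessors
#' @export
setGeneric("emgRaw", function(object) standardGeneric("emgRaw"))

#' @rdname pdgait-accessors
#' @export
setGeneric("accelRaw", function(object) standardGeneric("accelRaw"))

#' @rdname pdgait-accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname pdgait-accessors
#' @export
setGeneric("effectiveRate", function(object) standardGeneric("effectiveRate"))

#' @rdname pdgait-accessors
#' @export
setGeneric("timeOffset", function(object) standardGeneric("timeOffset"))

#' @rdname pdgait-accessors
#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))

#' @rdname pdgait-accessors
#' @export
setGeneric("signalOrder", function(object) standardGeneric("signalOrder"))

#' @rdname pdgait-accessors
#' @export
setGeneric("shiftStep", function(object) standardGeneric("shiftStep"))

#' Validate a gait recording against its invariants
#'
#' @param object a [GaitRecording-class] (or a raw list parsed from a
#'   telemetry file).
#' @param consts acquisition constants from [acquisitionConstants()].
#' @return A data.frame report with one row per violated invariant
#'   (`channel`, `index`, `message`); zero rows when the recording is valid.
#' @export
setGeneric("validateRecording",
           function(object, consts = acquisitionConstants())
             standardGeneric("validateRecording"))
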