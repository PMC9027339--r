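## Telemetry at-rest format. The acquisition device streams records to a
## mobile terminal which stores them as JSON; only that at-rest format is
## implemented here, as a versioned schema with explicit keys:
##
##   {"schema_version": 1, "subject": "...", "label": "...", "fs_hz": 100,
##    "n": <samples>, "channels": {"fsr": {"left": {"toe": [...], ...}, ...},
##    "emg": {"left": {"TA": [...], ...}, ...},
##    "accel": {"x": [...], ...}}, "meta": {...}}
##
## Channel arrays are stored column-wise under named keys (compact,
## streamable); timestamps are regenerated from fs_hz on read because the
## acquisition is synchronous-sampled.

.SCHEMA_VERSION <- 1L

.chanPaths <- function() {
  list(fsr = list(left = c("toe", "metatarsal", "heel"),
                  right = c("toe", "metatarsal", "heel")),
       emg = list(left = c("TA", "GM"), right = c("TA", "GM")),
       accel = c("x", "y", "z"))
}

#' Read a gait telemetry record
#'
#' Parses a JSON telemetry file (schema version 1, see the package vignette
#' for the full schema) into a validated [GaitRecording-class]. All 13
#' channels must be present with a common length; timestamps are regenerated
#' from `fs_hz`.
#'
#' @param path file to read.
#' @param consts acquisition constants used for validation.
#' @return A [GaitRecording-class].
#' @seealso [writeGaitRecording()], [validateRecording()]
#' @export
readGaitRecording <- function(path, consts = acquisitionConstants()) {
  if (!file.exists(path)) stop("no such telemetry file: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse telemetry file '",
                                           path, "': ", conditionMessage(e)))
  for (key in c("schema_version", "subject", "fs_hz", "channels"))
    if (is.null(doc[[key]]))
      stop("malformed telemetry record: missing key '", key, "'")
  if (!identical(as.integer(doc$schema_version), .SCHEMA_VERSION))
    stop("unsupported telemetry schema version: ", doc$schema_version,
         " (this reader supports version ", .SCHEMA_VERSION, ")")

  getChan <- function(...) {
    keys <- c(...)
    x <- doc$channels
    for (k in keys) {
      x <- x[[k]]
      if (is.null(x))
        stop("malformed telemetry record: missing channel key 'channels.",
             paste(keys, collapse = "."), "'")
    }
    as.numeric(x)
  }
  chans <- list(
    left.toe = getChan("fsr", "left", "toe"),
    left.metatarsal = getChan("fsr", "left", "metatarsal"),
    left.heel = getChan("fsr", "left", "heel"),
    right.toe = getChan("fsr", "right", "toe"),
    right.metatarsal = getChan("fsr", "right", "metatarsal"),
    right.heel = getChan("fsr", "right", "heel"),
    left.TA = getChan("emg", "left", "TA"),
    left.GM = getChan("emg", "left", "GM"),
    right.TA = getChan("emg", "right", "TA"),
    right.GM = getChan("emg", "right", "GM"),
    x = getChan("accel", "x"), y = getChan("accel", "y"),
    z = getChan("accel", "z"))
  lens <- vapply(chans, length, 0L)
  n <- if (!is.null(doc$n)) as.integer(doc$n) else lens[1]
  if (any(lens != n))
    stop("channel length mismatch in telemetry record: ",
         paste(sprintf("%s (%d of %d)", names(lens)[lens != n],
                       lens[lens != n], n), collapse = ", "))
  label <- if (is.null(doc$label)) "unknown" else doc$label
  meta <- if (is.null(doc$meta)) list() else as.list(doc$meta)
  gaitRecording(subjectId = doc$subject, label = label,
                fsHz = as.numeric(doc$fs_hz),
                fsrV = do.call(cbind, chans[1:6]),
                emg = do.call(cbind, chans[7:10]),
                accel = do.call(cbind, chans[11:13]),
                meta = meta, consts = consts)
}

#' Write a gait telemetry record
#'
#' Serializes a valid [GaitRecording-class] to the versioned JSON at-rest
#' format. Serialization is deterministic (two writes of the same recording
#' are byte-identical) and keeps at least 10 significant digits, so
#' `readGaitRecording(writeGaitRecording(rec))` round-trips within
#' floating-point serialization precision.
#'
#' @param rec a valid [GaitRecording-class]; recordings with non-finite
#'   samples are rejected before writing.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeGaitRecording <- function(rec, path) {
  stopifnot(methods::is(rec, "GaitRecording"))
  if (!all(is.finite(rec@fsrV)) || !all(is.finite(rec@emg)) ||
      !all(is.finite(rec@accel)))
    stop("recording contains non-finite samples; refusing to write")
  col <- function(m, j) unname(m[, j])
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    subject = rec@subjectId,
    label = rec@label,
    fs_hz = rec@fsHz,
    n = length(rec@time),
    channels = list(
      fsr = list(left = list(toe = col(rec@fsrV, 1),
                             metatarsal = col(rec@fsrV, 2),
                             heel = col(rec@fsrV, 3)),
                 right = list(toe = col(rec@fsrV, 4),
                              metatarsal = col(rec@fsrV, 5),
                              heel = col(rec@fsrV, 6))),
      emg = list(left = list(TA = col(rec@emg, 1), GM = col(rec@emg, 2)),
                 right = list(TA = col(rec@emg, 3), GM = col(rec@emg, 4))),
      accel = list(x = col(rec@accel, 1), y = col(rec@accel, 2),
                   z = col(rec@accel, 3))),
    meta = rec@meta)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(10))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write telemetry file '",
                                           path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' @describeIn validateRecording report every violated recording invariant,
#'   with the channel name and first offending sample index.
#' @export
setMethod("validateRecording", "GaitRecording", function(object, consts) {
  bad <- list()
  note <- function(channel, index, message)
    bad[[length(bad) + 1L]] <<- data.frame(channel = channel, index = index,
                                           message = message)
  n <- length(object@time)
  if (n < 1L) note("time", NA_integer_, "recording has no samples")
  if (!is.finite(object@fsHz) || object@fsHz <= 0)
    note("fs_hz", NA_integer_, "sampling frequency must be positive")
  if (n > 1L && is.finite(object@fsHz) && object@fsHz > 0) {
    dt <- diff(object@time)
    off <- which(abs(dt - 1 / object@fsHz) > 1e-6)
    if (length(off))
      note("time", off[1] + 1L,
           sprintf("timestamps not uniform at 1/fs (first offence at sample %d)",
                   off[1] + 1L))
    if (any(dt <= 0))
      note("time", which(dt <= 0)[1] + 1L, "timestamps not strictly increasing")
  }
  checkFinite <- function(m, what) {
    for (j in seq_len(ncol(m))) {
      i <- which(!is.finite(m[, j]))
      if (length(i))
        note(colnames(m)[j], i[1],
             sprintf("%s channel %s has non-finite sample at index %d",
                     what, colnames(m)[j], i[1]))
    }
  }
  checkFinite(object@fsrV, "FSR"); checkFinite(object@emg, "EMG")
  checkFinite(object@accel, "accel")
  for (j in seq_len(6)) {
    v <- object@fsrV[, j]
    i <- which(is.finite(v) & (v < 0 | v > consts$vDd))
    if (length(i))
      note(colnames(object@fsrV)[j], i[1],
           sprintf("FSR voltage outside [0, %g] V at index %d", consts$vDd, i[1]))
  }
  full <- 2^(consts$accelBits - 1)
  for (j in seq_len(3)) {
    v <- object@accel[, j]
    i <- which(is.finite(v) & abs(v) > full)
    if (length(i))
      note(colnames(object@accel)[j], i[1],
           sprintf("accel raw code outside +/-%g at index %d", full, i[1]))
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(channel = character(), index = integer(),
                  message = character())
})

#' Export a recording as CSV for spreadsheet inspection
#'
#' One column per channel plus the timestamp, with a header row.
#'
#' @param rec a [GaitRecording-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
exportRecordingCSV <- function(rec, path) {
  stopifnot(methods::is(rec, "GaitRecording"))
  df <- data.frame(t = rec@time,
                   stats::setNames(as.data.frame(rec@fsrV),
                                   paste0("fsr.", colnames(rec@fsrV))),
                   stats::setNames(as.data.frame(rec@emg),
                                   paste0("emg.", colnames(rec@emg))),
                   stats::setNames(as.data.frame(rec@accel),
                                   paste0("accel.", colnames(rec@accel))),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
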