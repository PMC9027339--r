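## Cross-correlation and the shifted-signal Pearson correlation coefficient
## matrix: lag analysis of biosignal pairs, assembly of the 120 x 120
## matrix over the 12-signal space and its 10 delayed versions per signal,
## and deterministic rendering as a blue-to-yellow color image.

#' Raw cross-correlation of two signal frames
#'
#' `R(m) = sum_n sig1(n + m) * sig2(n)` for lags `m = -(N-1) .. N-1`, with
#' negative lags by the standard relation `R12(-m) = R21(m)`. A maximum at
#' the origin indicates direct interdependency; a displaced maximum
#' measures the lag between the signals.
#'
#' @param sig1,sig2 equal-length finite series, N >= 2.
#' @return A list with `lag` (integer lags) and `r` (correlation values),
#'   length `2N - 1`.
#' @export
#' @examples
#' xcorr(c(0, 1, 0), c(0, 1, 0))$r  # impulse autocorrelation
xcorr <- function(sig1, sig2) {
  n <- length(sig1)
  if (length(sig2) != n) stop("signal length mismatch")
  if (n < 2L) stop("frames must have at least 2 samples")
  if (any(!is.finite(sig1)) || any(!is.finite(sig2)))
    stop("non-finite values in signal frame")
  ## stats::convolve(x, y, type = "open") computes conv(x, rev(y)), which
  ## is exactly the cross-correlation sum; index k = m + N is lag m
  r <- stats::convolve(sig1, sig2, type = "open")
  list(lag = -(n - 1L):(n - 1L), r = as.numeric(r))
}

#' Lag of the cross-correlation peak, in milliseconds
#'
#' @param R result of [xcorr()] (list with `lag` and `r`).
#' @param fsEff effective sampling rate (Hz) of the correlated frames.
#' @param tiePrefer for symmetric ties at the same `|lag|`, report the
#'   negative or the positive lag (the result is then flagged
#'   `ambiguous`).
#' @return Lag in ms (positive lag means `sig1` must be delayed to match
#'   `sig2`); `NA` flagged `undefined` for an all-zero correlation.
#' @export
xcorrPeakLag <- function(R, fsEff, tiePrefer = c("negative", "positive")) {
  tiePrefer <- match.arg(tiePrefer)
  if (length(R$r) == 0L) stop("empty cross-correlation")
  if (all(R$r == 0)) return(structure(NA_real_, undefined = TRUE))
  mx <- max(R$r)
  cand <- R$lag[R$r >= mx - 1e-12 * max(1, abs(mx))]
  best <- cand[order(abs(cand), if (tiePrefer == "negative") cand else -cand)][1]
  ambiguous <- sum(abs(cand) == abs(best)) > 1L
  structure(best * 1000 / fsEff, lag_samples = best, ambiguous = ambiguous)
}

#' Pearson correlation coefficient with degenerate-input guard
#'
#' Sample Pearson coefficient (1/(N-1) normalization with sample mean and
#' sd). A zero-variance input makes the coefficient undefined; it is
#' flagged rather than forced to 0.
#'
#' @param x,y equal-length series, N >= 2.
#' @return Coefficient in `[-1, 1]`, or `NA` with attribute
#'   `undefined = TRUE` for zero-variance input.
#' @export
pearsonCoef <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y)
}

#' Bank of delayed versions of a signal frame
#'
#' Version `s` (s = 0 .. nShifts-1) is the frame delayed by `s * step`
#' effective samples. All versions are truncated to their common overlap
#' (no circular wrap or zero padding), so each column has length
#' `N - (nShifts - 1) * step`.
#'
#' @param sig signal frame.
#' @param nShifts number of versions.
#' @param step delay step in effective samples.
#' @return Matrix with `nShifts` columns (shift 0 first).
#' @export
shiftBank <- function(sig, nShifts = 10L, step = 1L) {
  n <- length(sig)
  maxOff <- (nShifts - 1L) * step
  L <- n - maxOff
  if (L < 2L) stop("frame too short for the requested shift bank")
  out <- vapply(0:(nShifts - 1L), function(s)
    sig[(maxOff - s * step + 1L):(maxOff - s * step + L)], numeric(L))
  colnames(out) <- paste0("shift", 0:(nShifts - 1L))
  out
}

#' Shifted-signal correlation coefficient matrix of a gait frame
#'
#' Builds the 120-series bank (12 conditioned signals x `nShifts` delayed
#' versions, signal-major order: row `nShifts * (i - 1) + s + 1` is signal
#' `i` at shift `s`) over one signal frame - typically a stance phase -
#' and computes all pairwise Pearson coefficients. Within each
#' `nShifts x nShifts` section, the location of the largest coefficient
#' measures the lag between the two signals.
#'
#' @param space a [SignalSpace-class].
#' @param frame integer `c(start, end)` half-open effective-sample window,
#'   or a single stance row from [detectStances()].
#' @param nShifts shifted versions per signal.
#' @param step shift step in effective samples.
#' @return A [CorrelationMatrix-class]. Entries involving a zero-variance
#'   series within the frame are `NA` (flagged) and the corresponding
#'   diagonal stays 1.
#' @export
corrMatrix <- function(space, frame, nShifts = 10L, step = 1L) {
  side <- ""
  if (is.data.frame(frame)) {
    stopifnot(nrow(frame) == 1L)
    side <- as.character(frame$side)
    frame <- c(frame$start_idx, frame$end_idx)
  }
  frame <- as.integer(frame)
  if (frame[1] < 1L || frame[2] > nSamples(space) + 1L ||
      frame[2] <= frame[1])
    stop("frame outside signal bounds")
  sig <- signalMatrix(space)[frame[1]:(frame[2] - 1L), , drop = FALSE]
  banks <- lapply(seq_len(ncol(sig)), function(j)
    shiftBank(sig[, j], nShifts, step))
  bank <- do.call(cbind, banks)
  sds <- apply(bank, 2, stats::sd)
  m <- suppressWarnings(stats::cor(bank))
  m[, sds == 0] <- NA_real_
  m[sds == 0, ] <- NA_real_
  diag(m) <- 1
  m[!is.na(m)] <- pmin(1, pmax(-1, m[!is.na(m)]))
  dimnames(m) <- NULL
  methods::new("CorrelationMatrix", m = m, signalOrder = gaitSignalNames(),
               nShifts = as.integer(nShifts), shiftStep = as.integer(step),
               fsEffHz = effectiveRate(space), frame = frame, side = side)
}

#' Lag between two signals from their matrix section
#'
#' Finds the largest coefficient within the `nShifts x nShifts` section of
#' signals `i` (rows) and `j` (columns); the displacement
#' `col_shift - row_shift` at that maximum, converted through the shift
#' step and effective rate, is the lag in ms. The sign convention agrees
#' with [xcorrPeakLag()] applied to the same (i, j) pair.
#'
#' @param mat a [CorrelationMatrix-class].
#' @param i,j signal indices (1-12), `i != j`.
#' @return List with `shift` (displacement in shift steps) and `lag_ms`;
#'   `NA`s flagged `undefined` when the whole section is flagged. Ties are
#'   broken toward the smallest `|shift|`.
#' @export
sectionLag <- function(mat, i, j) {
  stopifnot(i != j)
  ns <- mat@nShifts
  rows <- (i - 1L) * ns + seq_len(ns)
  cols <- (j - 1L) * ns + seq_len(ns)
  sec <- mat@m[rows, cols, drop = FALSE]
  if (all(is.na(sec)))
    return(structure(list(shift = NA_integer_, lag_ms = NA_real_),
                     undefined = TRUE))
  mx <- max(sec, na.rm = TRUE)
  idx <- which(sec >= mx - 1e-12, arr.ind = TRUE)
  disp <- unname(idx[, "col"] - idx[, "row"])
  best <- disp[order(abs(disp), disp)][1]
  list(shift = as.integer(best),
       lag_ms = best * mat@shiftStep * 1000 / mat@fsEffHz)
}

## Fixed colormap anchors so that rendering is bit-reproducible:
## low coefficients map to deep blue, high coefficients to yellow.
.CMAP_LOW  <- c(0.00, 0.00, 0.55)
.CMAP_HIGH <- c(1.00, 1.00, 0.00)
.CMAP_FLAG <- c(0.50, 0.50, 0.50)

#' Render a correlation matrix as a color image
#'
#' Maps coefficients linearly from `[-1, 1]` onto a fixed blue-to-yellow
#' colormap (low to high) and resamples the 120 x 120 grid to 160 x 160
#' pixels by nearest neighbor - the input dimension of the gait
#' classifier. Flagged (NA) entries render in a reserved neutral gray.
#' Rendering is a pure deterministic function of the matrix.
#'
#' @param mat a [CorrelationMatrix-class].
#' @param size output image side length in pixels.
#' @return A `size x size x 3` numeric array in `[0, 1]` (RGB).
#' @export
renderMatrixImage <- function(mat, size = 160L) {
  m <- mat@m
  d <- nrow(m)
  t01 <- (m + 1) / 2
  idx <- floor((seq_len(size) - 1L) * d / size) + 1L
  t01 <- t01[idx, idx]
  px <- array(0, dim = c(size, size, 3))
  flag <- is.na(t01)
  for (k in 1:3) {
    plane <- .CMAP_LOW[k] + (.CMAP_HIGH[k] - .CMAP_LOW[k]) * t01
    plane[flag] <- .CMAP_FLAG[k]
    px[, , k] <- plane
  }
  attr(px, "colormap") <- "blueyellow"
  px
}

#' Write a rendered matrix image to disk
#'
#' PNG (lossless) is the default and the format used for classifier
#' datasets; JPEG export is available when the EBImage package is
#' installed.
#'
#' @param pixels array from [renderMatrixImage()].
#' @param path destination file.
#' @param format `"png"` or `"jpeg"`.
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
writeMatrixImage <- function(pixels, path, format = c("png", "jpeg"),
                             quality = 90) {
  format <- match.arg(format)
  if (format == "png") {
    png::writePNG(pixels, path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG export requires the EBImage package")
    EBImage::writeImage(EBImage::Image(aperm(pixels, c(2, 1, 3)),
                                       colormode = "Color"),
                        path, quality = quality)
  }
  invisible(path)
}

#' Export correlation coefficients as plain text
#'
#' @param mat a [CorrelationMatrix-class].
#' @param path destination file (tab-separated matrix).
#' @return `path`, invisibly.
#' @export
exportMatrixText <- function(mat, path) {
  utils::write.table(mat@m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
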