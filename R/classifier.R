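## Dataset construction from correlation matrices, stratified
## (subject-disjoint) splitting, photometric augmentation and the
## confusion-matrix performance metrics.

#' Build a labeled image dataset from recordings
#'
#' Runs the front end on each labeled recording (conditioning, stance
#' segmentation, one correlation matrix per stance frame, rendering) and
#' collects the rendered images with a provenance manifest. Sources with
#' label `"unknown"` are excluded with a warning.
#'
#' @param recordings list of [GaitRecording-class] objects.
#' @param consts acquisition constants.
#' @param cfg an [eventConfig()].
#' @param nShifts,step shift-bank parameters of [corrMatrix()].
#' @param minFrame minimum frame length in effective samples (shorter
#'   stances are skipped).
#' @param size rendered image side length.
#' @return A list of class `"gaitDataset"`: `images` (`size x size x 3 x N`
#'   array) and `manifest` (data.frame: `subject`, `label`, `side`,
#'   `frame_start`, `frame_end`).
#' @export
makeDataset <- function(recordings, consts = acquisitionConstants(),
                        cfg = eventConfig(), nShifts = 10L, step = 1L,
                        minFrame = 15L, size = 160L) {
  imgs <- list()
  rows <- list()
  for (rec in recordings) {
    if (gaitLabel(rec) == "unknown") {
      warning("excluding unlabeled recording ", subjectId(rec))
      next
    }
    space <- buildSignalSpace(rec, consts)
    for (side in c("left", "right")) {
      st <- detectStances(space, side, cfg)
      for (i in seq_len(nrow(st))) {
        if (st$end_idx[i] - st$start_idx[i] < minFrame) next
        mat <- corrMatrix(space, st[i, ], nShifts, step)
        imgs[[length(imgs) + 1L]] <- renderMatrixImage(mat, size)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjectId(rec), label = gaitLabel(rec), side = side,
          frame_start = st$start_idx[i], frame_end = st$end_idx[i])
      }
    }
  }
  n <- length(imgs)
  arr <- array(0, dim = c(size, size, 3L, n))
  for (i in seq_len(n)) arr[, , , i] <- imgs[[i]]
  structure(list(images = arr,
                 manifest = if (n) do.call(rbind, rows)
                            else data.frame(subject = character(),
                                            label = character(),
                                            side = character(),
                                            frame_start = integer(),
                                            frame_end = integer())),
            class = "gaitDataset")
}

#' @export
print.gaitDataset <- function(x, ...) {
  cat(sprintf("gaitDataset: %d images (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$label)),
                            table(x$manifest$label)), collapse = ", ")))
  invisible(x)
}

.subsetDataset <- function(ds, idx) {
  structure(list(images = ds$images[, , , idx, drop = FALSE],
                 manifest = ds$manifest[idx, , drop = FALSE]),
            class = "gaitDataset")
}

#' Split a dataset into train/validation/test partitions
#'
#' Stratified by class and deterministic under the config seed. With
#' `subjectDisjoint` (default) whole subjects are assigned greedily per
#' class so that no subject's frames span two partitions - a stricter
#' policy than per-image splitting, avoiding leakage between frames of one
#' subject.
#'
#' @param ds a `"gaitDataset"`.
#' @param cfg a [trainConfig()] (uses `split`, `seed`, `subjectDisjoint`).
#' @return List with elements `train`, `val`, `test` (each a
#'   `"gaitDataset"` whose manifest gains a `partition` column).
#' @export
splitDataset <- function(ds, cfg = trainConfig()) {
  man <- ds$manifest
  if (nrow(man) < 10L) stop("need at least 10 images to split")
  if (length(unique(man$label)) < 2L)
    stop("both classes must be present to split")
  parts <- names(cfg$split)
  assign <- character(nrow(man))
  rng <- .withSeed(cfg$seed, {
    for (cl in unique(man$label)) {
      inCl <- which(man$label == cl)
      if (cfg$subjectDisjoint) {
        counts <- table(man$subject[inCl])
        subj <- sample(names(counts))  # seed-deterministic tie order
        subj <- subj[order(-counts[subj])]
        target <- cfg$split * sum(counts)
        got <- stats::setNames(numeric(length(parts)), parts)
        for (s in subj) {
          deficit <- target - got
          p <- parts[which.max(deficit / pmax(target, 1e-9))]
          assign[inCl[man$subject[inCl] == s]] <- p
          got[p] <- got[p] + counts[s]
        }
      } else {
        idx <- sample(inCl)
        nTr <- round(cfg$split["train"] * length(idx))
        nVa <- round(cfg$split["val"] * length(idx))
        assign[idx[seq_len(nTr)]] <- "train"
        assign[idx[nTr + seq_len(min(nVa, length(idx) - nTr))]] <- "val"
        assign[idx[assign[idx] == ""]] <- "test"
      }
    }
  })
  out <- lapply(stats::setNames(parts, parts), function(p) {
    sub <- .subsetDataset(ds, which(assign == p))
    sub$manifest$partition <- rep(p, nrow(sub$manifest))
    sub
  })
  out
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  eval.parent(substitute(expr))
}

#' Photometric augmentation of an image dataset
#'
#' Enlarges the dataset by `factor` with brightness/contrast jitter within
#' +/- 10% and integer translations of at most 2 px (edge replication).
#' No flips or rotations are applied: matrix row/column positions encode
#' signal identity, so geometric flips would change the semantics of the
#' image. Originals are retained.
#'
#' @param ds a `"gaitDataset"`.
#' @param factor enlargement factor (1 returns the input unchanged).
#' @param jitter brightness/contrast jitter bound.
#' @param maxShiftPx maximum translation in pixels.
#' @param seed RNG seed.
#' @return Enlarged `"gaitDataset"`.
#' @export
augmentDataset <- function(ds, factor = 2L, jitter = 0.1, maxShiftPx = 2L,
                           seed = 1L) {
  if (factor <= 1L) return(ds)
  if (nrow(ds$manifest) == 0L) stop("empty dataset")
  n <- nrow(ds$manifest)
  d <- dim(ds$images)
  out <- array(0, dim = c(d[1:3], n * factor))
  out[, , , seq_len(n)] <- ds$images
  man <- ds$manifest[rep(seq_len(n), factor), , drop = FALSE]
  man$augmented <- rep(c(FALSE, rep(TRUE, factor - 1L)), each = n)
  .withSeed(seed, {
    for (k in seq_len((factor - 1L) * n)) {
      src <- ds$images[, , , (k - 1L) %% n + 1L]
      contrast <- stats::runif(1, 1 - jitter, 1 + jitter)
      bright <- stats::runif(1, -jitter, jitter)
      img <- 0.5 + (src - 0.5) * contrast + bright
      sh <- if (maxShiftPx > 0)
        sample(seq.int(-maxShiftPx, maxShiftPx), 2, replace = TRUE)
      else c(0L, 0L)
      ri <- pmin(pmax(seq_len(d[1]) - sh[1], 1L), d[1])
      ci <- pmin(pmax(seq_len(d[2]) - sh[2], 1L), d[2])
      out[, , , n + k] <- pmin(pmax(img[ri, ci, ], 0), 1)
    }
  })
  structure(list(images = out, manifest = man), class = "gaitDataset")
}

#' Confusion-matrix performance metrics
#'
#' Counts true/false positives and negatives with the Parkinsonian class
#' as positive, and derives accuracy, sensitivity, specificity and
#' precision (positive predictive value). Ratios with a zero denominator
#' are `NA` flagged `undefined` rather than NaN.
#'
#' @param truth,predicted equal-length label vectors
#'   (`"physiological"`/`"pd"`).
#' @param losses optional per-sample test losses; their mean is reported
#'   as the model error.
#' @return A list of class `"EvalMetrics"`: counts `tp`, `fp`, `tn`,
#'   `fn` and metrics `acc`, `se`, `sp`, `ppv`, `error`.
#' @export
#' @examples
#' evaluateMetrics(rep(c("pd", "physiological"), c(10, 25)),
#'                 rep(c("pd", "physiological", "pd", "physiological"),
#'                     c(9, 1, 1, 24)))
evaluateMetrics <- function(truth, predicted, losses = NULL) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  pos <- "pd"
  tp <- sum(truth == pos & predicted == pos)
  fp <- sum(truth != pos & predicted == pos)
  tn <- sum(truth != pos & predicted != pos)
  fn <- sum(truth == pos & predicted != pos)
  ratio <- function(num, den) if (den == 0)
    structure(NA_real_, undefined = TRUE) else num / den
  res <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              acc = ratio(tn + tp, tp + tn + fp + fn),
              se = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp),
              error = if (is.null(losses)) NA_real_ else mean(losses))
  if (length(unique(truth)) < 2L)
    attr(res, "degenerate") <- "only one class present in truth"
  class(res) <- "EvalMetrics"
  res
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf("counts: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("Acc %.3f  Se %.3f  Sp %.3f  PPV %.3f  error %.3f\n",
              x$acc, x$se, x$sp, x$ppv, x$error))
  if (!is.null(attr(x, "degenerate")))
    cat("flag:", attr(x, "degenerate"), "\n")
  invisible(x)
}

#' Write a dataset manifest (and optionally images) to disk
#'
#' @param ds a `"gaitDataset"`.
#' @param dir output directory (created if needed).
#' @param writeImages also write each image as PNG.
#' @return The manifest path, invisibly.
#' @export
writeDatasetManifest <- function(ds, dir, writeImages = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds$manifest
  man$path <- sprintf("img_%04d.png", seq_len(nrow(man)))
  if (writeImages)
    for (i in seq_len(nrow(man)))
      png::writePNG(ds$images[, , , i], file.path(dir, man$path[i]))
  p <- file.path(dir, "manifest.csv")
  utils::write.csv(man, p, row.names = FALSE)
  invisible(p)
}
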