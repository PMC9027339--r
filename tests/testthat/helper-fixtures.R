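# Shared simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixturePhysio <- function() {
  if (is.null(.fixtures$physio)) {
    sim <- simulateRecording(subjectParams(nCycles = 10, seed = 7))
    space <- buildSignalSpace(sim$recording)
    .fixtures$physio <- list(
      sim = sim, space = space,
      stancesL = detectStances(space, "left"),
      stancesR = detectStances(space, "right"))
  }
  .fixtures$physio
}

fixtureNoiseless <- function() {
  if (is.null(.fixtures$noiseless)) {
    p <- subjectParams(nCycles = 8, seed = 2,
                       noiseSd = list(fsrV = 0, emg = 0.05, accelMs2 = 0.05))
    sim <- simulateRecording(p)
    .fixtures$noiseless <- list(sim = sim,
                                space = buildSignalSpace(sim$recording))
  }
  .fixtures$noiseless
}

# A tiny valid recording for io tests.
tinyRecording <- function(n = 120, seed = 1) {
  set.seed(seed)
  gaitRecording("tiny", "physiological", 100,
                fsrV = matrix(runif(n * 6, 0, 4.5), n, 6),
                emg = matrix(rnorm(n * 4), n, 4),
                accel = matrix(rnorm(n * 3, 0, 100), n, 3))
}

# Linearly separable two-blob images for classifier sanity checks.
blobDataset <- function(n = 40, side = 32L, seed = 1) {
  set.seed(seed)
  x <- array(0, c(side, side, 3, n))
  y <- character(n)
  for (i in seq_len(n)) {
    img <- array(runif(side * side * 3, 0, 0.2), c(side, side, 3))
    if (i %% 2 == 1) {
      img[5:12, 5:12, ] <- img[5:12, 5:12, ] + 0.7
      y[i] <- "pd"
    } else {
      img[(side - 11):(side - 4), (side - 11):(side - 4), ] <-
        img[(side - 11):(side - 4), (side - 11):(side - 4), ] + 0.7
      y[i] <- "physiological"
    }
    x[, , , i] <- pmin(img, 1)
  }
  structure(list(images = x,
                 manifest = data.frame(subject = sprintf("b%02d", seq_len(n)),
                                       label = y)),
            class = "gaitDataset")
}
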