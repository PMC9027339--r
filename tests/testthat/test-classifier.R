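test_that("dataset construction labels one image per stance frame", {
  sims <- list(simulateRecording(subjectParams(nCycles = 4, seed = 30), "a"),
               simulateRecording(subjectParams("pd",
                                               strike = c(left = "flat",
                                                          right = "flat"),
                                               nCycles = 4, seed = 31), "b"))
  ds <- makeDataset(lapply(sims, `[[`, "recording"))
  expect_s3_class(ds, "gaitDataset")
  expect_identical(dim(ds$images)[1:3], c(160L, 160L, 3L))
  expect_identical(dim(ds$images)[4], nrow(ds$manifest))
  expect_setequal(unique(ds$manifest$label), c("physiological", "pd"))
  expect_true(all(ds$manifest$frame_end > ds$manifest$frame_start))

  expect_identical(nrow(makeDataset(list())$manifest), 0L)

  unl <- simulateRecording(subjectParams(nCycles = 4, seed = 32), "u")$recording
  unl@label <- "unknown"
  expect_warning(ds2 <- makeDataset(list(unl)), "unlabeled")
  expect_identical(nrow(ds2$manifest), 0L)
})

test_that("splitting is stratified, seeded and optionally subject-disjoint", {
  ds <- blobDataset(100)
  cfg <- trainConfig(seed = 5, subjectDisjoint = FALSE)
  sp <- splitDataset(ds, cfg)
  expect_lte(abs(nrow(sp$train$manifest) - 70), 1)
  expect_lte(abs(nrow(sp$val$manifest) - 10), 1)
  expect_lte(abs(nrow(sp$test$manifest) - 20), 1)
  for (p in sp) {
    tab <- table(p$manifest$label)
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  sp2 <- splitDataset(ds, cfg)
  expect_identical(sp$train$manifest, sp2$train$manifest)

  ## subject-disjoint: frames of one subject stay in one partition
  cohort <- simulateCohort(2, seed = 33, nCycles = 5)
  dsc <- makeDataset(lapply(cohort, `[[`, "recording"))
  spc <- splitDataset(dsc, trainConfig(seed = 1, subjectDisjoint = TRUE))
  subj <- lapply(spc, function(p) unique(p$manifest$subject))
  expect_identical(length(Reduce(intersect, subj[lengths(subj) > 0])), 0L)

  oneClass <- ds
  oneClass$manifest$label <- "pd"
  expect_error(splitDataset(oneClass, cfg), "both classes")
})

test_that("augmentation enlarges the set with bounded photometric jitter", {
  ds <- blobDataset(12)
  aug <- augmentDataset(ds, factor = 2L, seed = 3)
  expect_identical(dim(aug$images)[4], 24L)
  expect_identical(aug$images[, , , 1:12], ds$images)
  expect_false(any(aug$manifest$augmented[1:12]))
  expect_true(all(aug$manifest$augmented[13:24]))
  for (k in 13:24)
    expect_gt(max(abs(aug$images[, , , k] - ds$images[, , , k - 12])), 0)
  expect_true(all(aug$images >= 0 & aug$images <= 1))
  expect_identical(augmentDataset(ds, factor = 1L), ds)

  ## photometric-only copies differ by at most the jitter bound
  ph <- augmentDataset(ds, factor = 2L, maxShiftPx = 0L, seed = 4)
  for (k in 13:24) {
    delta <- abs(ph$images[, , , k] - ds$images[, , , k - 12])
    expect_lte(max(delta), 0.5 * 0.1 + 0.1 + 1e-9)
  }
})

test_that("confusion metrics follow their defining ratios", {
  allc <- evaluateMetrics(c("pd", "physiological"), c("pd", "physiological"))
  expect_equal(c(allc$acc, allc$se, allc$sp, allc$ppv), rep(1, 4))

  truth <- rep(c("pd", "physiological"), c(10, 25))
  pred <- c(rep("pd", 9), "physiological", "pd", rep("physiological", 24))
  m <- evaluateMetrics(truth, pred, losses = rep(0.2, 35))
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(9L, 1L, 1L, 24L))
  expect_equal(m$se, 0.9)
  expect_equal(m$sp, 0.96)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$acc, 33 / 35)
  expect_equal(m$error, 0.2)
  ## exact integer identity
  expect_identical(m$acc * (m$tp + m$tn + m$fp + m$fn), as.numeric(m$tp + m$tn))

  noPos <- evaluateMetrics(rep("physiological", 5), rep("physiological", 5))
  expect_true(is.na(noPos$se) && attr(noPos$se, "undefined"))
  expect_identical(attr(noPos, "degenerate"),
                   "only one class present in truth")
})

test_that("the compact CNN separates trivially separable images", {
  ds <- blobDataset(40)
  cfg <- trainConfig(imageDim = c(32L, 32L, 3L), epochs = 10, seed = 1)
  m <- trainClassifier(ds, NULL, cfg)
  expect_gte(tail(m$history$acc, 1), 0.99)
  expect_true(all(is.finite(m$history$loss)))

  p <- predictClassifier(m, ds)
  expect_equal(rowSums(as.matrix(p[, 1:2])), rep(1, 40), tolerance = 1e-6)
  expect_identical(predictClassifier(m, ds), p)  # inference deterministic

  expect_error(predictClassifier(m, array(0, c(16, 16, 3, 2))), "dimensions")
})

test_that("training is reproducible under a fixed seed", {
  ds <- blobDataset(24)
  cfg <- trainConfig(imageDim = c(32L, 32L, 3L), epochs = 4, seed = 7)
  m1 <- trainClassifier(ds, NULL, cfg)
  m2 <- trainClassifier(ds, NULL, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("label noise degrades expected accuracy", {
  accAt <- function(noise, seed) {
    ds <- blobDataset(60, seed = 100 + seed)
    man <- ds$manifest
    if (noise > 0) {
      set.seed(200 + seed)
      flip <- sample(60, round(noise * 60))
      man$label[flip] <- ifelse(man$label[flip] == "pd", "physiological", "pd")
    }
    dsn <- structure(list(images = ds$images, manifest = man),
                     class = "gaitDataset")
    cfg <- trainConfig(imageDim = c(32L, 32L, 3L), epochs = 6, seed = seed,
                       subjectDisjoint = FALSE)
    sp <- splitDataset(dsn, cfg)
    m <- trainClassifier(sp$train, NULL, cfg)
    pred <- predictClassifier(m, sp$test)
    ## evaluate against the clean labels
    clean <- blobDataset(60, seed = 100 + seed)$manifest$label
    idx <- as.integer(rownames(sp$test$manifest))
    mean(pred$label == clean[idx])
  }
  a0 <- mean(vapply(1:3, function(s) accAt(0, s), 0))
  a30 <- mean(vapply(1:3, function(s) accAt(0.3, s), 0))
  expect_gt(a0, a30)
})
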