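randomSpace <- function(n, seed, inject = NULL) {
  set.seed(seed)
  sig <- matrix(rnorm(n * 12), n, 12)
  if (!is.null(inject)) for (j in names(inject)) sig[, as.integer(j)] <- inject[[j]]
  colnames(sig) <- gaitSignalNames()
  methods::new("SignalSpace", signals = sig, fsEffHz = 25, t0S = 0)
}

test_that("cross-correlation matches the exhaustive double-loop oracle", {
  expect_equal(xcorr(c(0, 1, 0), c(0, 1, 0))$r, c(0, 0, 1, 0, 0))
  set.seed(20)
  for (i in 1:100) {
    n <- sample(2:32, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- xcorr(a, b)
    expect_equal(r$lag, -(n - 1):(n - 1))
    expect_lt(max(abs(r$r - xcorrOracle(a, b))), 1e-10)
  }
  ## orthogonal sinusoids over integer periods
  t <- (0:99) / 100
  r0 <- xcorr(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t))
  expect_lt(abs(r0$r[r0$lag == 0]), 1e-10)
  expect_error(xcorr(1:4, 1:5), "mismatch")
})

test_that("cross-correlation peak lag converts to milliseconds", {
  n <- 40
  set.seed(21)
  a <- as.numeric(stats::filter(rnorm(n + 10), rep(0.5, 3), sides = 1))
  a[is.na(a)] <- 0
  r <- xcorr(a[6:(5 + 30)], a[6:(5 + 30)])
  expect_equal(unclass(xcorrPeakLag(r, 25)), 0, ignore_attr = TRUE)

  b <- a[6:(5 + 30) - 2]  # delayed by 2 samples
  pk <- xcorrPeakLag(xcorr(a[6:(5 + 30)], b), 25)
  expect_identical(attr(pk, "lag_samples"), -2L)
  expect_equal(abs(as.numeric(pk)), 80)  # 2 / 25 Hz in ms

  tie <- xcorrPeakLag(list(lag = -3:3, r = c(1, 0, 0, 0.5, 0, 0, 1)), 25)
  expect_true(attr(tie, "ambiguous"))
  expect_equal(attr(tie, "lag_samples"), -3)
  tiePos <- xcorrPeakLag(list(lag = -3:3, r = c(1, 0, 0, 0.5, 0, 0, 1)), 25,
                         tiePrefer = "positive")
  expect_equal(attr(tiePos, "lag_samples"), 3)

  und <- xcorrPeakLag(list(lag = -1:1, r = c(0, 0, 0)), 25)
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("Pearson coefficient matches its defining formula", {
  set.seed(22)
  x <- rnorm(30)
  expect_equal(pearsonCoef(x, x), 1)
  expect_equal(pearsonCoef(x, -x), -1)
  expect_equal(pearsonCoef(c(1, 2, 3), c(1, 2, 4)),
               pearsonOracle(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(pearsonCoef(a, b), pearsonOracle(a, b), tolerance = 1e-12)
  }
  und <- pearsonCoef(rep(2, 10), rnorm(10))
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("the shift bank delays by whole steps over a common overlap", {
  sig <- numeric(30); sig[5] <- 1
  bank <- shiftBank(sig, 10, 1)
  expect_identical(dim(bank), c(21L, 10L))
  expect_equal(bank[, 1], sig[10:30])  # shift 0: identity tail
  ## the impulse at raw index 5 sits at delayed index 5 + s, i.e. at
  ## column position 5 + s - 9 once inside the common window
  for (s in 0:9) {
    idx <- which(bank[, s + 1] == 1)
    p <- 5 + s - 9
    if (p >= 1) expect_equal(idx, p) else expect_length(idx, 0)
  }
  expect_error(shiftBank(1:10, 10, 1), "too short")
})

test_that("the correlation matrix has the documented structure", {
  fx <- fixturePhysio()
  mat <- corrMatrix(fx$space, fx$stancesL[3, ])
  m <- corrValues(mat)
  expect_identical(dim(m), c(120L, 120L))
  expect_equal(diag(m), rep(1, 120))
  expect_lt(max(abs(m - t(m)), na.rm = TRUE), 1e-9)
  expect_true(all(abs(m[is.finite(m)]) <= 1 + 1e-9))
  expect_identical(signalOrder(mat), gaitSignalNames())

  ## known delayed pair: argmax of the (3, 4) section on the d-offset
  ## off-diagonal
  set.seed(23)
  base <- as.numeric(stats::filter(rnorm(80), rep(1 / 3, 3), sides = 1))
  base[is.na(base)] <- 0
  d <- 4
  inj <- list("3" = base[21:80], "4" = base[21:80 - d])
  sp <- randomSpace(60, 24, inj)
  mm <- corrMatrix(sp, c(1, 61))
  sec <- corrValues(mm)[21:30, 31:40]
  arg <- which(sec == max(sec), arr.ind = TRUE)
  expect_equal(unname(arg[1, "col"] - arg[1, "row"]), -d)
})

test_that("zero-variance series are flagged, not fabricated", {
  sp <- randomSpace(40, 25, list("5" = rep(2, 40)))
  expect_warning(mm <- corrMatrix(sp, c(1, 41)), NA)
  m <- corrValues(mm)
  block <- 41:50  # rows of signal 5
  expect_true(all(is.na(m[block, setdiff(1:120, block)])))
  expect_equal(diag(m)[block], rep(1, 10))
  sl <- sectionLag(mm, 5, 6)
  expect_true(is.na(sl$shift))
})

test_that("section lag and cross-correlation peak lag agree", {
  mkPair <- function(d, seed) {
    set.seed(seed)
    b <- as.numeric(stats::filter(rnorm(100), rep(1 / 4, 4), sides = 1))
    b[is.na(b)] <- 0
    list(s1 = b[21:90], s2 = b[21:90 - d])
  }
  ## identical signals -> zero displacement
  sp0 <- randomSpace(50, 26, list("3" = sin(1:50), "4" = sin(1:50)))
  expect_identical(sectionLag(corrMatrix(sp0, c(1, 51)), 3, 4)$shift, 0L)

  set.seed(27)
  for (trial in 1:50) {
    d <- sample(0:9, 1)
    p <- mkPair(d, 1000 + trial)
    sig <- matrix(rnorm(70 * 12), 70, 12)
    sig[, 3] <- p$s1; sig[, 4] <- p$s2
    colnames(sig) <- gaitSignalNames()
    sp <- methods::new("SignalSpace", signals = sig, fsEffHz = 25, t0S = 0)
    sl <- sectionLag(corrMatrix(sp, c(1, 71)), 3, 4)
    pk <- xcorrPeakLag(xcorr(p$s1 - mean(p$s1), p$s2 - mean(p$s2)), 25)
    expect_identical(sl$shift, -d)
    expect_lte(abs(attr(pk, "lag_samples") - sl$shift), 1)
    expect_equal(sl$lag_ms, sl$shift * 40)
  }
})

test_that("matrix rendering is deterministic with the fixed colormap", {
  fx <- fixturePhysio()
  mat <- corrMatrix(fx$space, fx$stancesL[2, ])
  img <- renderMatrixImage(mat)
  expect_identical(dim(img), c(160L, 160L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, renderMatrixImage(mat))

  ## constant +1 matrix renders uniform brightest yellow
  ones <- mat
  ones@m[] <- 1
  imgY <- renderMatrixImage(ones)
  expect_equal(unique(as.vector(imgY[, , 1])), 1)
  expect_equal(unique(as.vector(imgY[, , 2])), 1)
  expect_equal(unique(as.vector(imgY[, , 3])), 0)

  ## identity-style matrix: yellow diagonal on a blue field
  eye <- mat
  eye@m[] <- -1; diag(eye@m) <- 1
  imgE <- renderMatrixImage(eye)
  expect_equal(imgE[1, 1, ], c(1, 1, 0))          # diagonal pixel
  expect_equal(imgE[1, 80, ], c(0, 0, 0.55))      # off-diagonal pixel

  ## flagged entries use the reserved neutral color
  flg <- mat
  flg@m[1, 5] <- NA; flg@m[5, 1] <- NA
  imgF <- renderMatrixImage(flg)
  px <- imgF[1, 7, ]  # matrix col 5 maps to pixels 6-7 at 160/120
  expect_equal(px, c(0.5, 0.5, 0.5))
})

test_that("images and matrices export to disk deterministically", {
  fx <- fixturePhysio()
  mat <- corrMatrix(fx$space, fx$stancesL[1, ])
  img <- renderMatrixImage(mat)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  writeMatrixImage(img, f1)
  writeMatrixImage(img, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- png::readPNG(f1)
  expect_lt(max(abs(back - img)), 1 / 255)

  ft <- withr::local_tempfile(fileext = ".tsv")
  exportMatrixText(mat, ft)
  m2 <- as.matrix(utils::read.table(ft, sep = "\t"))
  expect_equal(unname(m2), unname(corrValues(mat)), tolerance = 1e-6)
})
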