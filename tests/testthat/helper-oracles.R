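# Independent brute-force oracles used across test files. These are kept
# deliberately naive (explicit loops, direct formula transcription) so
# they stay independent of the vectorized implementation paths.

xcorrOracle <- function(s1, s2) {
  n <- length(s1)
  sapply(-(n - 1):(n - 1), function(m) {
    s <- 0
    for (k in 1:n) {
      j <- k + m
      if (j >= 1 && j <= n) s <- s + s1[j] * s2[k]
    }
    s
  })
}

vaOracle <- function(ax, ay, az) {
  n <- length(ax)
  va <- numeric(n)
  for (k in seq_len(n)) {
    if (k == 1) { va[k] <- 0; next }
    xm <- sum(ax[1:(k - 1)]) / (k - 1)
    ym <- sum(ay[1:(k - 1)]) / (k - 1)
    zm <- sum(az[1:(k - 1)]) / (k - 1)
    va[k] <- sqrt((ax[k] - xm)^2 + (ay[k] - ym)^2 + (az[k] - zm)^2)
  }
  va
}

pearsonOracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  s <- 0
  for (k in 1:n) s <- s + ((x[k] - mx) / sx) * ((y[k] - my) / sy)
  s / (n - 1)
}

blockAverageOracle <- function(x, window, hop) {
  starts <- seq(1, length(x) - window + 1, by = hop)
  sapply(starts, function(s) mean(x[s:(s + window - 1)]))
}

# Magnitude response of a digital filter b/a at frequency f (Hz).
filterGain <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * z)
  den <- sum(a * exp(-1i * w * (seq_along(a) - 1)))
  Mod(num / den)
}

# Gain of the decimating rectangular block average at frequency f.
boxcarGain <- function(f, fs, window) {
  if (f == 0) return(1)
  abs(sin(pi * f * window / fs) / (window * sin(pi * f / fs)))
}
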