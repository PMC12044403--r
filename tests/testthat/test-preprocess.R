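mkrec <- function(d, fs = 250, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(d)))
  EEGRecording(d, labels, fs)
}

sine <- function(f, fs, dur, phase = 0) {
  sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs + phase)
}

fitAmpPhase <- function(x, f, fs) {
  tt <- (seq_along(x) - 1) / fs
  fit <- lm(x ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt) - 1)
  a <- coef(fit)
  list(amp = sqrt(sum(a^2)), phase = atan2(-a[2], a[1]))
}

test_that("bandpass preserves passband tones and suppresses stopband tones", {
  fs <- 1000
  x10 <- sine(10, fs, 10)
  x80 <- sine(80, fs, 10)
  rec <- mkrec(rbind(x10, x80), fs)
  out <- bandpassFilter(rec, 0.5, 40)
  core <- 2001:8000      # interior, away from filter edge transients
  f10 <- fitAmpPhase(out@data[1, core], 10, fs)
  expect_equal(f10$amp, 1, tolerance = 0.02)
  expect_lt(abs(f10$phase), 0.01)                      # zero net phase
  expect_lt(sd(out@data[2, core]), 0.01 * sd(x80[core]))  # >= 40 dB down
})

test_that("bandpass removes DC and errors on too-short input", {
  fs <- 500
  rec <- mkrec(matrix(5 + sine(10, fs, 12), 1), fs)
  out <- bandpassFilter(rec, 0.5, 40)
  expect_lt(abs(mean(out@data[1, 2000:4000])), 0.05)
  short <- mkrec(matrix(rnorm(100), 1), fs)
  expect_error(bandpassFilter(short, 0.5, 40), "too short")
})

test_that("filtering and referencing are linear operations", {
  fs <- 500
  set.seed(1)
  x <- matrix(rnorm(2 * fs * 12), 2)
  y <- matrix(rnorm(2 * fs * 12), 2)
  lhs <- bandpassFilter(mkrec(2 * x + 3 * y, fs), 1, 30)@data
  rhs <- 2 * bandpassFilter(mkrec(x, fs), 1, 30)@data +
    3 * bandpassFilter(mkrec(y, fs), 1, 30)@data
  expect_equal(lhs, rhs, tolerance = 1e-10)
  lhs2 <- averageReference(mkrec(2 * x + 3 * y, fs))@data
  rhs2 <- 2 * averageReference(mkrec(x, fs))@data +
    3 * averageReference(mkrec(y, fs))@data
  expect_equal(lhs2, rhs2, tolerance = 1e-12)
})

test_that("line-noise regression removes 50 Hz and spares neighbors", {
  fs <- 500
  x <- 2 * sine(50, fs, 10) + sine(10, fs, 10, phase = 0.3)
  out <- removeLineNoise(mkrec(matrix(x, 1), fs), 50, 2)
  core <- 501:4500
  f50 <- fitAmpPhase(out@data[1, core], 50, fs)
  f10 <- fitAmpPhase(out@data[1, core], 10, fs)
  expect_lt(f50$amp, 2 * 10^(-20 / 20))   # >= 20 dB reduction
  expect_equal(f10$amp, 1, tolerance = 0.05)

  # pure 50 Hz tone: essentially gone
  tone <- mkrec(matrix(sine(50, fs, 10), 1), fs)
  cleaned <- removeLineNoise(tone, 50, 2)
  expect_lt(sd(cleaned@data[1, core]), 0.1 * sd(tone@data[1, core]))

  # no line content: output ~ input
  set.seed(2)
  broad <- sine(10, fs, 10) + 0.5 * sine(23, fs, 10, 1)
  out2 <- removeLineNoise(mkrec(matrix(broad, 1), fs), 50, 2)
  rel <- sqrt(mean((out2@data[1, core] - broad[core])^2)) /
    sqrt(mean(broad[core]^2))
  expect_lt(rel, 0.01)
})

test_that("average reference zeroes column sums and is idempotent", {
  set.seed(3)
  rec <- mkrec(matrix(rnorm(4 * 100, mean = 7), 4), 100)
  out <- averageReference(rec)
  expect_lt(max(abs(colSums(out@data))), 1e-10)
  out2 <- averageReference(out)
  expect_equal(out@data, out2@data, tolerance = 1e-12)
  pm <- mkrec(rbind(sine(5, 100, 1), -sine(5, 100, 1)), 100)
  expect_equal(averageReference(pm)@data, pm@data, tolerance = 1e-12)
})

test_that("flatline and low-correlation channels are flagged", {
  fs <- 250
  spec <- CouplingSpec(
    data.frame(i = c("A", "C"), j = c("B", "D"), freq = 10, lag = 0,
               strength = 1), noiseSd = 0.1)
  for (s in 1:5) {
    rec <- generateCoupledRecording(spec, c("A", "B", "C", "D"), fs, 10,
                                    seed = s)
    # clean, strongly coupled channels: empty report
    rep0 <- detectBadChannels(rec, flatlineS = 5, corrThreshold = 0.8)
    expect_length(rep0@flatline, 0)
    expect_length(rep0@lowCorrelation, 0)

    # pure independent noise channel among coupled ones: low correlation
    noisy <- rec@data
    noisy <- rbind(noisy, rnorm(ncol(noisy)))
    rec2 <- EEGRecording(noisy, c("A", "B", "C", "D", "E"), fs)
    rep2 <- detectBadChannels(rec2)
    expect_true("E" %in% rep2@lowCorrelation)
    expect_false("A" %in% rep2@lowCorrelation)
  }

  # 6-s flat run in a 10-s recording trips the 5-s criterion
  rec3 <- generateCoupledRecording(spec, c("A", "B", "C", "D"), fs, 10, 9)
  rec3@data[2, 1:(6 * fs)] <- 0
  rep3 <- detectBadChannels(rec3, flatlineS = 5)
  expect_true("B" %in% rep3@flatline)
  rep4 <- detectBadChannels(rec3, flatlineS = 7)
  expect_false("B" %in% rep4@flatline)
})

test_that("spherical-spline interpolation reconstructs held-out channels", {
  labs32 <- c("Fp1", "Fp2", "Fz", "F3", "F7", "F4", "F8", "FT9", "FT10",
              "T7", "T8", "TP9", "TP10", "Cz", "C3", "C4", "FC1", "FC2",
              "FC5", "FC6", "CP1", "CP5", "CP2", "CP6", "Pz", "P3", "P7",
              "P4", "P8", "Oz", "O1", "O2")
  pos <- standardPositions(labs32)
  # smooth scalp field: low-order harmonics of position, time-modulated
  tt <- seq(0, 1, length.out = 200)
  field <- function(p) 30 * p[3] + 20 * p[1] * p[2] + 10 * p[2]
  base <- apply(pos, 1, field)
  d <- outer(base, sin(2 * pi * 3 * tt)) + outer(base * 0.3, cos(2 * pi * tt))
  rec <- EEGRecording(d, labs32, 200, positions = pos)

  # leave one out, reconstruct, compare
  for (held in c("Cz", "P3", "F4")) {
    corrupted <- rec
    i <- match(held, labs32)
    corrupted@data[i, ] <- 0
    fixed <- interpolateChannels(corrupted, held)
    err <- sqrt(mean((fixed@data[i, ] - rec@data[i, ])^2)) /
      sqrt(mean(rec@data[i, ]^2))
    expect_lt(err, 0.10)
    # good channels untouched
    expect_identical(fixed@data[-i, ], corrupted@data[-i, ])
  }
})

test_that("interpolation handles identity, constants and missing positions", {
  labs <- c("Fz", "Cz", "Pz", "C3", "C4")
  rec <- EEGRecording(matrix(rnorm(5 * 50), 5), labs, 100)
  expect_identical(interpolateChannels(rec, character(0)), rec)

  # all good channels carry the same signal -> spline reproduces it
  v <- sine(4, 100, 0.5)
  recc <- EEGRecording(rbind(v, v, v, v, 0 * v), labs, 100)
  fixed <- interpolateChannels(recc, "C4")
  expect_lt(max(abs(fixed@data[5, ] - v)) / max(abs(v)), 0.01)

  nopos <- new("EEGRecording", channelLabels = c("A1", "B2", "C3x", "D4"),
               sfreq = 100, data = matrix(rnorm(400), 4), positions = NULL,
               meta = list())
  expect_error(interpolateChannels(nopos, "A1"), "positions")
  expect_error(interpolateChannels(rec, "Qz"), "unknown channel")
})

test_that("epoch segmentation slices exact lengths and checks bounds", {
  fs <- 100
  rec <- mkrec(matrix(rnorm(2 * 200 * fs), 2), fs, c("C3", "C4"))
  b <- data.frame(start = c(0, 60, 120),
                  segment = c("elevator", "plank_start", "plank_end"),
                  condition = "neutral")
  eps <- segmentEpochs(rec, b, subjectId = "S9", epochLength = 60)
  expect_length(eps, 3L)
  for (e in eps) expect_equal(ncol(e@recording@data), 60 * fs)
  expect_equal(vapply(eps, function(e) e@task, ""),
               c("elevator", "plank", "plank"))
  expect_equal(eps[[2]]@recording@data[1, 1], rec@data[1, 60 * fs + 1])

  # overlap is legal
  b2 <- data.frame(start = c(0, 30), segment = c("elevator", "plank_end"),
                   condition = "negative")
  expect_length(segmentEpochs(rec, b2, epochLength = 60), 2L)

  # beyond the end: error naming the segment
  b3 <- data.frame(start = 150, segment = "plank_end", condition = "neutral")
  expect_error(segmentEpochs(rec, b3, epochLength = 60), "plank_end")
})
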