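test_that("default region map matches the fixed 32-electrode parcellation", {
  map <- defaultRegionMap()
  expect_setequal(regionNames(map),
                  c("frontal", "temporal", "central", "parietal", "occipital"))
  counts <- vapply(regionNames(map),
                   function(r) length(regionElectrodes(map, r)), 1L)
  expect_equal(unname(counts[c("frontal", "temporal", "central",
                               "parietal", "occipital")]),
               c(9L, 4L, 11L, 5L, 3L))
  expect_equal(sum(counts), 32L)
  expect_equal(regionLookup("Oz", map), "occipital")
  expect_equal(regionLookup("Cz", map), "central")
  expect_equal(regionLookup("FT10", map), "frontal")
  # case-insensitive: vendor headers spell Fp1/FP1 interchangeably
  expect_equal(regionLookup("fp1", map), "frontal")
  expect_true(is.na(regionLookup("FCz", map)))
})

test_that("restricting the region map keeps only present electrodes", {
  map <- restrictRegionMap(defaultRegionMap(), reducedMontage())
  expect_equal(length(unlist(map@map)), 16L)
  expect_equal(length(regionElectrodes(map, "temporal")), 2L)
})

test_that("EDF files round-trip labels, rate and data within quantization", {
  set.seed(42)
  rec <- EEGRecording(matrix(rnorm(2 * 100, sd = 20), 2, 100),
                      c("C3", "C4"), sfreq = 100)
  path <- tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readRecording(path)
  expect_equal(channelLabels(back), c("C3", "C4"))
  expect_equal(sfreq(back), 100)
  # 16-bit quantization: span / 65535 per channel
  tol <- max(apply(rec@data, 1, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back@data - rec@data)), 2 * tol)
})

test_that("EDF with non-integer-second length still round-trips", {
  rec <- EEGRecording(matrix(sin(1:150), 3, 50), c("A", "B", "C"), 32)
  path <- tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readRecording(path, format = "edf")
  expect_equal(sfreq(back), 32, tolerance = 1e-6)
  expect_equal(dim(back@data), c(3L, 50L))
})

test_that("BrainVision round-trips in all four binary layouts", {
  set.seed(7)
  rec <- EEGRecording(matrix(rnorm(3 * 64, sd = 15), 3, 64),
                      c("Fz", "Cz", "Pz"), sfreq = 250)
  for (fmt in c("IEEE_FLOAT_32", "INT_16")) {
    for (ori in c("MULTIPLEXED", "VECTORIZED")) {
      path <- tempfile(fileext = ".vhdr")
      writeBrainVision(rec, path, binaryFormat = fmt, orientation = ori)
      back <- readRecording(path)
      expect_equal(channelLabels(back), channelLabels(rec))
      expect_equal(sfreq(back), 250)
      tol <- if (fmt == "INT_16") max(abs(rec@data)) / 16000 else 1e-4
      expect_lt(max(abs(back@data - rec@data)), tol)
    }
  }
})

test_that("missing companion files and mismatched payloads are errors", {
  rec <- EEGRecording(matrix(rnorm(2 * 50), 2, 50), c("A", "B"), 100)
  path <- tempfile(fileext = ".vhdr")
  writeBrainVision(rec, path)
  eeg <- sub("\\.vhdr$", ".eeg", path)

  # payload with a sample's worth of bytes missing -> channel mismatch
  raw <- readBin(eeg, "raw", n = file.size(eeg))
  writeBin(raw[1:(length(raw) - 2)], eeg)
  expect_error(readRecording(path), "mismatched|not a whole number")

  file.remove(eeg)
  expect_error(readRecording(path), "missing.*data file")

  expect_error(readRecording(tempfile(fileext = ".edf")), "not found")
})

test_that("written EDF and BrainVision files are readable by an independent reader", {
  py <- Sys.which("python")
  has_mne <- nzchar(py) &&
    system2(py, c("-c", shQuote("import mne")), stdout = FALSE,
            stderr = FALSE) == 0
  expect_true(has_mne, info = "python+mne oracle unavailable")
  set.seed(11)
  rec <- EEGRecording(matrix(rnorm(2 * 200, sd = 30), 2, 200),
                      c("C3", "C4"), sfreq = 100)
  edf <- tempfile(fileext = ".edf")
  vhdr <- tempfile(fileext = ".vhdr")
  writeEDF(rec, edf)
  writeBrainVision(rec, vhdr, binaryFormat = "INT_16")
  script <- tempfile(fileext = ".py")
  out_csv <- tempfile(fileext = ".csv")
  writeLines(sprintf("
import mne, numpy as np
r1 = mne.io.read_raw_edf('%s', verbose='ERROR')
r2 = mne.io.read_raw_brainvision('%s', verbose='ERROR')
d1 = r1.get_data() * 1e6
d2 = r2.get_data() * 1e6
np.savetxt('%s', np.array([d1.shape[0], d1.shape[1],
           np.abs(d1).max(), np.abs(d2 - d1).max()]))
", edf, vhdr, out_csv), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  vals <- scan(out_csv, quiet = TRUE)
  expect_equal(vals[1], 2)
  expect_equal(vals[2], 200)
  expect_gt(vals[3], 1)          # microvolt scale preserved
  expect_lt(vals[4], 0.1)        # both writers agree within quantization
})

test_that("metrics tables round-trip and are written in sorted order", {
  tb <- data.frame(
    subject = c("S2", "S1", "S1"),
    condition = c("neutral", "negative", "neutral"),
    task = c("plank", "elevator", "elevator"),
    scope = "frontal", metric = "efficiency",
    value = c(1 / 3, exp(1), pi))
  path <- tempfile(fileext = ".csv")
  writeMetricsTable(tb, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4L)
  expect_equal(lines[1], "subject,condition,task,scope,metric,value")
  back <- readMetricsTable(path)
  expect_equal(back$subject, c("S1", "S1", "S2"))
  expect_equal(back$value, c(exp(1), pi, 1 / 3), tolerance = 1e-15)

  tb2 <- data.frame(subject = "S1", condition = "neutral",
                    task = c("plank", "elevator"), scope = "global",
                    metric = "q", value = c(2, 1))
  writeMetricsTable(tb2, path)
  back2 <- readMetricsTable(path)
  expect_equal(back2$task, c("elevator", "plank"))  # elevator sorts first
  expect_equal(back2$value, c(1, 2))

  expect_error(writeMetricsTable(tb[c(1, 1), ], path), "duplicate")
})

test_that("standard montage positions are unit vectors with sane geometry", {
  pos <- standardPositions(c("Cz", "Oz", "FP1", "T7", "T8"))
  expect_equal(unname(sqrt(rowSums(pos^2))), rep(1, 5), tolerance = 1e-5)
  expect_gt(pos["Cz", "z"], 0.9)        # vertex on top
  expect_lt(pos["Oz", "y"], -0.9)       # occiput at the back
  expect_lt(pos["T7", "x"], -0.9)       # left temporal on the left
  expect_error(standardPositions("XX9"), "unknown electrode")
})

test_that("recording invariants are enforced", {
  expect_error(EEGRecording(matrix(0, 2, 10), c("A", "B", "C"), 100),
               "labels")
  expect_error(EEGRecording(matrix(0, 2, 10), c("A", "a"), 100), "unique")
  expect_error(EEGRecording(matrix(0, 2, 10), c("A", "B"), -1), "sfreq")
  expect_error(EEGEpoch(EEGRecording(matrix(0, 2, 10), c("A", "B"), 10),
                        "S1", "bad_condition", "elevator"), "condition")
})
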