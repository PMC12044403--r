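# Standard 10-20/10-10 electrode coordinates (unit sphere, head-centred:
# +x right, +y anterior, +z superior). Public montage reference data.
.STANDARD_POSITIONS <- local({
  v <- c(
    "Fp1", -0.288927, 0.954856, -0.069079,
    "Fp2", 0.275680, 0.958731, -0.069541,
    "Fz", -0.005183, 0.747957, 0.663727,
    "F3", -0.533663, 0.723260, 0.438291,
    "F7", -0.765630, 0.630892, -0.125640,
    "F4", 0.531632, 0.733883, 0.422828,
    "F8", 0.759997, 0.637019, -0.128883,
    "FT9", -0.820129, 0.296292, -0.489489,
    "FT10", 0.814953, 0.298172, -0.496936,
    "T7", -0.993691, 0.001031, -0.112150,
    "T8", 0.993307, 0.012811, -0.114789,
    "TP9", -0.843263, -0.296613, -0.448251,
    "TP10", 0.838173, -0.303792, -0.452964,
    "Cz", -0.004274, 0.069233, 0.997591,
    "C3", -0.717434, 0.048508, 0.694935,
    "C4", 0.721875, 0.056699, 0.689697,
    "FC1", -0.360838, 0.435576, 0.824663,
    "FC2", 0.355262, 0.445137, 0.821975,
    "FC5", -0.878913, 0.391347, 0.272689,
    "FC6", 0.875647, 0.400999, 0.269151,
    "CP1", -0.353209, -0.303084, 0.885089,
    "CP5", -0.880774, -0.333420, 0.336256,
    "CP2", 0.365621, -0.301479, 0.880586,
    "CP6", 0.886290, -0.322257, 0.332628,
    "Pz", -0.004809, -0.619521, 0.784966,
    "P3", -0.540286, -0.629044, 0.558923,
    "P7", -0.787118, -0.616103, -0.029365,
    "P4", 0.546223, -0.622084, 0.560939,
    "P8", 0.784837, -0.618962, -0.030276,
    "Oz", -0.007229, -0.989501, 0.144348,
    "O1", -0.298421, -0.950660, 0.084790,
    "O2", 0.288118, -0.953820, 0.084944,
    "FCz", -0.004599, 0.441403, 0.897297,
    "Fpz", -0.006870, 0.999800, -0.018771
  )
  m <- matrix(as.numeric(v[seq_along(v) %% 4 != 1]), ncol = 3, byrow = TRUE)
  rownames(m) <- v[seq(1, length(v), by = 4)]
  colnames(m) <- c("x", "y", "z")
  m
})

#' Standard montage positions for 10-20 electrode labels
#'
#' Returns unit-sphere coordinates (head-centred: +x right, +y anterior,
#' +z superior) for the given electrode labels. Matching is
#' case-insensitive, so vendor spellings such as "FP1" and "Fp1" resolve to
#' the same electrode.
#'
#' @param labels character vector of electrode names.
#' @return labels x 3 numeric matrix of unit vectors.
#' @export
standardPositions <- function(labels) {
  idx <- match(tolower(labels), tolower(rownames(.STANDARD_POSITIONS)))
  if (anyNA(idx))
    stop("unknown electrode label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  m <- .STANDARD_POSITIONS[idx, , drop = FALSE]
  rownames(m) <- labels
  m
}

#' The fixed cortical parcellation of the 32-channel montage
#'
#' Five pairwise-disjoint electrode sets covering the 32 analyzed scalp
#' channels: 9 frontal, 4 temporal, 11 central, 5 parietal, 3 occipital.
#'
#' @return a \code{\link{RegionMap}}.
#' @examples
#' map <- defaultRegionMap()
#' regionLookup("Oz", map)   # "occipital"
#' @export
defaultRegionMap <- function() {
  new("RegionMap", map = list(
    frontal   = c("FP1", "FP2", "Fz", "F3", "F7", "F4", "F8", "FT9", "FT10"),
    temporal  = c("T8", "T7", "TP9", "TP10"),
    central   = c("Cz", "C3", "C4", "FC1", "FC2", "FC5", "FC6",
                  "CP1", "CP5", "CP2", "CP6"),
    parietal  = c("Pz", "P3", "P7", "P4", "P8"),
    occipital = c("Oz", "O1", "O2")
  ))
}

#' Find the region of an electrode
#'
#' Case-insensitive lookup of an electrode label in a region map.
#'
#' @param label electrode name.
#' @param map a \code{RegionMap} (default: \code{defaultRegionMap()}).
#' @return region name, or \code{NA_character_} if the electrode is not in
#'   any region (such channels are excluded from regional metrics but kept
#'   for global ones).
#' @export
regionLookup <- function(label, map = defaultRegionMap()) {
  for (r in names(map@map))
    if (tolower(label) %in% tolower(map@map[[r]])) return(r)
  NA_character_
}

#' Restrict a region map to the electrodes present in a recording
#'
#' Drops from each region the electrodes that are absent from
#' \code{labels}; regions left empty are removed. Used when analysing
#' reduced montages with the standard parcellation.
#'
#' @param map a \code{RegionMap}.
#' @param labels electrode labels actually present.
#' @return a \code{RegionMap} whose electrode spellings follow \code{labels}.
#' @export
restrictRegionMap <- function(map, labels) {
  m <- lapply(map@map, function(els) {
    labels[tolower(labels) %in% tolower(els)]
  })
  m <- m[vapply(m, length, 1L) > 0]
  new("RegionMap", map = m)
}

## ---------------------------------------------------------------- EDF I/O

.pad <- function(x, width) formatC(as.character(x), width = -width)

#' Write a recording as EDF
#'
#' European Data Format writer: 16-bit samples, physical dimension in
#' microvolts, per-channel physical scaling from the data range. Records are
#' 1 s long when the sample count divides evenly by the sampling rate,
#' otherwise a single record covering the whole signal is written.
#'
#' @param rec an \code{EEGRecording}.
#' @param path output file path (conventionally .edf).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  d <- rec@data
  n_ch <- nrow(d)
  n <- ncol(d)
  fs <- rec@sfreq
  if (n %% fs == 0 && fs == round(fs)) {
    n_rec <- n %/% fs
    spr <- as.integer(fs)
    dur <- "1"
  } else {
    n_rec <- 1L
    spr <- n
    dur <- format(n / fs, digits = 7)
  }
  phys_min <- apply(d, 1, min)
  phys_max <- apply(d, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1     # avoid zero scaling span
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L + 256L * n_ch, 8); wr("", 44)
  wr(n_rec, 8); wr(dur, 8); wr(n_ch, 4)
  for (l in rec@channelLabels) wr(l, 16)
  for (i in seq_len(n_ch)) wr("", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (v in phys_min) wr(format(v, digits = 7), 8)
  for (v in phys_max) wr(format(v, digits = 7), 8)
  for (i in seq_len(n_ch)) wr(dig_min, 8)
  for (i in seq_len(n_ch)) wr(dig_max, 8)
  for (i in seq_len(n_ch)) wr("", 80)
  for (i in seq_len(n_ch)) wr(spr, 8)
  for (i in seq_len(n_ch)) wr("", 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(n_ch)) {
      dig <- round((d[i, cols] - phys_min[i]) / scale[i] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  if (grepl("BDF", reserved, ignore.case = TRUE))
    stop("unsupported EDF dialect: ", reserved)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)                  # transducer
  phys_dim <- vapply(seq_len(n_ch), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(80)                  # prefiltering
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(32)
  if (header_bytes != 256L + 256L * n_ch)
    stop("EDF header length field inconsistent with channel count")
  if (length(unique(spr)) != 1)
    stop("unsupported EDF dialect: per-channel sampling rates differ")

  payload <- file.size(path) - header_bytes
  expected <- as.numeric(n_rec) * sum(spr) * 2
  if (payload != expected)
    stop(sprintf("EDF payload size (%d bytes) does not match header (%d records x %d channels): corrupt or mismatched channel count",
                 payload, n_rec, n_ch))

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  d <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      d[i, cols] <- (dig - dig_min[i]) * scale[i] + phys_min[i]
    }
  }
  # convert to microvolts; EEG convention: bare/unknown dimension is uV
  mult <- ifelse(tolower(phys_dim) %in% c("mv"), 1000,
                 ifelse(tolower(phys_dim) %in% c("v"), 1e6, 1))
  d <- d * mult
  keep <- labels != "EDF Annotations"
  EEGRecording(d[keep, , drop = FALSE], labels[keep], spr[1] / dur)
}

## -------------------------------------------------------- BrainVision I/O

#' Write a recording in BrainVision format
#'
#' Emits the .vhdr/.vmrk/.eeg triplet. Both binary layouts of the format
#' are supported: IEEE_FLOAT_32 (resolution 1) and INT_16 (per-channel
#' resolution chosen from the data range), in MULTIPLEXED or VECTORIZED
#' sample orientation.
#'
#' @param rec an \code{EEGRecording}.
#' @param path output header path (.vhdr); companion .eeg/.vmrk are written
#'   next to it.
#' @param binaryFormat "IEEE_FLOAT_32" or "INT_16".
#' @param orientation "MULTIPLEXED" (sample-major) or "VECTORIZED"
#'   (channel-major).
#' @return \code{path}, invisibly.
#' @export
writeBrainVision <- function(rec, path, binaryFormat = c("IEEE_FLOAT_32", "INT_16"),
                             orientation = c("MULTIPLEXED", "VECTORIZED")) {
  binaryFormat <- match.arg(binaryFormat)
  orientation <- match.arg(orientation)
  stub <- sub("\\.vhdr$", "", path)
  eeg_path <- paste0(stub, ".eeg")
  vmrk_path <- paste0(stub, ".vmrk")
  d <- rec@data
  n_ch <- nrow(d)

  if (binaryFormat == "INT_16") {
    res <- pmax(apply(abs(d), 1, max), 1e-12) / 32000
  } else {
    res <- rep(1, n_ch)
  }

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg_path)),
    paste0("MarkerFile=", basename(vmrk_path)),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec@sfreq, digits = 12)),
    "[Binary Infos]",
    paste0("BinaryFormat=", binaryFormat),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), rec@channelLabels,
            format(res, digits = 12))
  )
  writeLines(hdr, path, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", basename(eeg_path)),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,00000000000000000000"), vmrk_path)

  con <- file(eeg_path, "wb")
  on.exit(close(con))
  if (orientation == "MULTIPLEXED") {
    vals <- d / res            # recycles res down columns (channels)
    vec <- as.vector(vals)     # column-major = sample-major interleave
  } else {
    vals <- d / res
    vec <- as.vector(t(vals))  # channel blocks
  }
  if (binaryFormat == "INT_16") {
    writeBin(as.integer(round(vec)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = 4, endian = "little")
  }
  invisible(path)
}

.parseVhdr <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  section <- ""
  kv <- list()
  channels <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    m <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(m) != 2) next
    key <- trimws(m[1]); val <- trimws(m[2])
    if (section == "channel infos" && grepl("^Ch[0-9]+$", key)) {
      channels[[key]] <- strsplit(val, ",")[[1]]
    } else if (section %in% c("common infos", "binary infos")) {
      kv[[tolower(key)]] <- val
    }
  }
  list(kv = kv, channels = channels)
}

.readBrainVision <- function(path) {
  if (!file.exists(path)) stop("missing BrainVision header file: ", path)
  h <- .parseVhdr(path)
  kv <- h$kv
  if (!is.null(kv$dataformat) && toupper(kv$dataformat) != "BINARY")
    stop("unsupported BrainVision dialect: DataFormat=", kv$dataformat)
  data_file <- file.path(dirname(path), kv$datafile)
  if (!file.exists(data_file))
    stop("missing BrainVision data file referenced by header: ", kv$datafile)
  if (!is.null(kv$markerfile)) {
    marker_file <- file.path(dirname(path), kv$markerfile)
    if (!file.exists(marker_file))
      stop("missing BrainVision marker file referenced by header: ",
           kv$markerfile)
  }
  n_ch <- as.integer(kv$numberofchannels)
  sfreq <- 1e6 / as.numeric(kv$samplinginterval)
  orientation <- toupper(kv$dataorientation %||% "MULTIPLEXED")
  fmt <- toupper(kv$binaryformat %||% "INT_16")
  if (!fmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop("unsupported BrainVision binary layout: ", fmt)

  labels <- character(n_ch); res <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    ch <- h$channels[[paste0("Ch", i)]]
    if (is.null(ch)) stop("header missing Channel Infos entry Ch", i)
    labels[i] <- ch[1]
    if (length(ch) >= 3 && nzchar(ch[3])) res[i] <- as.numeric(ch[3])
  }

  bytes <- if (fmt == "INT_16") 2 else 4
  sz <- file.size(data_file)
  if (sz %% (bytes * n_ch) != 0)
    stop(sprintf("BrainVision payload (%d bytes) is not a whole number of %d-channel samples: mismatched channel count or truncated file",
                 sz, n_ch))
  n <- sz %/% (bytes * n_ch)
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw <- if (fmt == "INT_16") {
    readBin(con, "integer", n = n * n_ch, size = 2, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "numeric", n = n * n_ch, size = 4, endian = "little")
  }
  d <- if (orientation == "MULTIPLEXED") {
    matrix(raw, nrow = n_ch)            # channels vary fastest
  } else if (orientation == "VECTORIZED") {
    t(matrix(raw, nrow = n))
  } else {
    stop("unsupported BrainVision dialect: DataOrientation=", orientation)
  }
  d <- d * res
  EEGRecording(d, labels, sfreq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EEG recording from disk
#'
#' Reads BrainVision (.vhdr + .eeg/.vmrk) or EDF files into an
#' \code{\link{EEGRecording}} with data in microvolts. With
#' \code{format = "auto"} the format is chosen from the file extension.
#'
#' @param path path to the .vhdr or .edf file.
#' @param format "brainvision", "edf" or "auto".
#' @return an \code{EEGRecording}.
#' @export
readRecording <- function(path, format = c("auto", "brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, brainvision = .readBrainVision(path), edf = .readEDF(path))
}

## ------------------------------------------------------------ metrics CSV

.METRIC_COLS <- c("subject", "condition", "task", "scope", "metric", "value")

#' Write a metrics table as CSV
#'
#' Long-format per-cell metric values, one row per
#' (subject, condition, task, scope, metric). Rows are sorted by all key
#' columns so output is deterministic; values keep full double precision;
#' '.' decimal separator, UTF-8.
#'
#' @param table data.frame with columns subject, condition, task, scope,
#'   metric, value.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsTable <- function(table, path) {
  stopifnot(nrow(table) > 0, all(.METRIC_COLS %in% names(table)))
  table <- table[, .METRIC_COLS]
  key <- do.call(order, table[, setdiff(.METRIC_COLS, "value")])
  table <- table[key, ]
  if (anyDuplicated(table[, setdiff(.METRIC_COLS, "value")]))
    stop("duplicate (subject, condition, task, scope, metric) rows")
  table$value <- format(table$value, digits = 17, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(table, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a metrics table written by \code{writeMetricsTable}
#' @param path CSV path.
#' @return data.frame with the canonical six columns.
#' @export
readMetricsTable <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  stopifnot(all(.METRIC_COLS %in% names(tb)))
  tb[, .METRIC_COLS]
}
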