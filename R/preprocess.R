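#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR bandpass applied forward with
#' group-delay compensation, giving zero net phase. The transition width is
#' \code{min(max(0.25*low, 2 Hz), high/4)}; the -6 dB cutoffs sit half a
#' transition width outside the band edges (the low cutoff is clamped to
#' \code{low/2} when that would go nonpositive), so the passband interior
#' is unity gain within ripple and attenuation reaches the Hamming stopband
#' (about 53 dB) one transition width beyond the edges.
#'
#' @param rec an \code{EEGRecording}.
#' @param low high-pass edge (Hz), default 0.5.
#' @param high low-pass edge (Hz), default 40.
#' @return the filtered \code{EEGRecording}.
#' @export
bandpassFilter <- function(rec, low = 0.5, high = 40) {
  fs <- rec@sfreq
  if (!(0 < low && low < high && high < fs / 2))
    stop("need 0 < low < high < sfreq/2")
  tw <- min(max(0.25 * low, 2), high / 4)
  ord <- ceiling(3.3 * fs / tw / 2) * 2       # even order, Hamming main lobe
  lowc <- max(low - tw / 2, low / 2)
  highc <- min(high + tw / 2, fs / 2 * 0.999)
  # high-pass by spectral inversion of a unity-DC low-pass: exact zero at
  # DC regardless of how the transition band sits against 0 Hz; cascade
  # with the anti-aliasing low-pass for the band's upper edge
  bl_low <- signal::fir1(ord, lowc / (fs / 2), type = "low")
  bh <- -bl_low / sum(bl_low)
  bh[ord / 2 + 1] <- bh[ord / 2 + 1] + 1
  bl <- signal::fir1(ord, highc / (fs / 2), type = "low")
  b <- stats::convolve(bh, rev(bl), type = "open")
  n <- ncol(rec@data)
  if (n < 3 * length(b))
    stop(sprintf("signal too short for filter: %d samples < 3 x %d taps",
                 n, length(b)))
  delay <- ord                                # two cascaded ord/2 delays
  out <- rec@data
  for (i in seq_len(nrow(out))) {
    padded <- c(rec@data[i, ], numeric(delay))
    y <- signal::fftfilt(b, padded)
    out[i, ] <- y[(delay + 1):(delay + n)]
  }
  initialize(rec, data = out)
}

#' Sliding-window line-noise removal
#'
#' Within overlapping Hann-weighted windows, sine and cosine components at
#' the line frequency and at every window-grid frequency within
#' \code{bandwidth/2} of it are fit by least squares and subtracted;
#' windows are recombined by overlap-add. Broadband content away from the
#' line band is preserved.
#'
#' @param rec an \code{EEGRecording}.
#' @param lineFreq line frequency (Hz), default 50.
#' @param bandwidth width of the removal band (Hz), default 2.
#' @param windowS window length (s), default 4.
#' @return the cleaned \code{EEGRecording}.
#' @export
removeLineNoise <- function(rec, lineFreq = 50, bandwidth = 2, windowS = 4) {
  fs <- rec@sfreq
  if (lineFreq >= fs / 2) stop("lineFreq must be below the Nyquist frequency")
  n <- ncol(rec@data)
  nper <- min(round(windowS * fs), n)
  hop <- max(1, nper %/% 2)
  starts <- unique(c(seq(1, max(1, n - nper + 1), by = hop),
                     max(1, n - nper + 1)))
  # removal frequencies: the window's grid within +-bandwidth/2, plus the
  # line frequency itself
  grid <- (0:(nper %/% 2)) * fs / nper
  freqs <- unique(c(lineFreq,
                    grid[grid >= lineFreq - bandwidth / 2 &
                         grid <= lineFreq + bandwidth / 2]))
  tt <- (0:(nper - 1)) / fs
  X <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
  qrX <- qr(X)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))  # Hann
  out <- matrix(0, nrow(rec@data), n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:(s + nper - 1)
    seg <- rec@data[, idx, drop = FALSE]
    fitted <- t(qr.fitted(qrX, t(seg)))
    cleaned <- seg - fitted
    out[, idx] <- out[, idx] + sweep(cleaned, 2, w, `*`)
    wsum[idx] <- wsum[idx] + w
  }
  wsum[wsum < 1e-12] <- 1
  out <- sweep(out, 2, wsum, `/`)
  # window edges get zero weight under Hann; take them from the raw
  # regression of the first/last window instead
  for (idx0 in c(1, n)) {
    if (abs(wsum[idx0]) <= 1e-12 || wsum[idx0] == 1) {
      s <- if (idx0 == 1) 1 else max(1, n - nper + 1)
      seg <- rec@data[, s:(s + nper - 1), drop = FALSE]
      cleaned <- seg - t(qr.fitted(qrX, t(seg)))
      out[, idx0] <- cleaned[, idx0 - s + 1]
    }
  }
  initialize(rec, data = out)
}

#' Average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each output sample sums to zero across channels. Idempotent.
#'
#' @param rec an \code{EEGRecording} with at least 2 channels.
#' @return the re-referenced \code{EEGRecording}.
#' @export
averageReference <- function(rec) {
  if (nrow(rec@data) < 2) stop("average reference needs at least 2 channels")
  initialize(rec, data = sweep(rec@data, 2, colMeans(rec@data), `-`))
}

#' Detect flatline and low-correlation channels
#'
#' Flatline: a channel with a run of at least \code{flatlineS} seconds in
#' which the absolute sample-to-sample change stays below 1e-8 microvolts.
#' Low correlation: a channel whose best absolute Pearson correlation with
#' any other channel — computed in 1-s windows and aggregated as the median
#' across windows — falls below \code{corrThreshold}.
#'
#' @param rec an \code{EEGRecording}.
#' @param flatlineS flatline criterion in seconds (default 5).
#' @param corrThreshold correlation criterion (default 0.8).
#' @return a \code{\link{BadChannelReport}}.
#' @export
detectBadChannels <- function(rec, flatlineS = 5, corrThreshold = 0.8) {
  d <- rec@data
  fs <- rec@sfreq
  n <- ncol(d)
  run_len <- round(flatlineS * fs)

  flat <- vapply(seq_len(nrow(d)), function(i) {
    still <- abs(diff(d[i, ])) < 1e-8
    r <- rle(still)
    any(r$values & r$lengths >= run_len - 1)
  }, logical(1))

  win <- round(fs)
  nwin <- n %/% win
  low_corr <- rep(FALSE, nrow(d))
  if (nwin >= 1 && nrow(d) >= 2) {
    best <- matrix(NA_real_, nrow(d), nwin)
    for (w in seq_len(nwin)) {
      seg <- d[, ((w - 1) * win + 1):(w * win), drop = FALSE]
      sds <- apply(seg, 1, stats::sd)
      C <- suppressWarnings(abs(stats::cor(t(seg))))
      C[!is.finite(C)] <- 0
      diag(C) <- 0
      best[, w] <- apply(C, 1, max)
      best[sds == 0, w] <- 0
    }
    low_corr <- apply(best, 1, stats::median) < corrThreshold
  }
  new("BadChannelReport",
      flatline = rec@channelLabels[flat],
      lowCorrelation = rec@channelLabels[low_corr],
      thresholds = list(flatline_s = flatlineS,
                        corr_threshold = corrThreshold))
}

# Perrin-style spherical spline kernel: Legendre series over cos(angle),
# order m = 4, 7 terms.
.gKernel <- function(cosang, m = 4, nterms = 7) {
  g <- matrix(0, nrow(cosang), ncol(cosang))
  Pprev <- matrix(1, nrow(cosang), ncol(cosang))   # P_0
  Pcur <- cosang                                    # P_1
  for (deg in 1:nterms) {
    g <- g + (2 * deg + 1) / (deg^m * (deg + 1)^m) * Pcur
    Pnext <- ((2 * deg + 1) * cosang * Pcur - deg * Pprev) / (deg + 1)
    Pprev <- Pcur; Pcur <- Pnext
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the listed channels from the remaining good channels by
#' spherical-spline interpolation on the unit sphere (Legendre series of
#' order m = 4 with 7 terms, ridge regularization 1e-5). Good channels are
#' returned untouched.
#'
#' @param rec an \code{EEGRecording} with positions for all channels.
#' @param bad character vector of channel labels to reconstruct.
#' @return the \code{EEGRecording} with bad channels replaced.
#' @export
interpolateChannels <- function(rec, bad) {
  if (length(bad) == 0) return(rec)
  if (is.null(rec@positions))
    stop("channel positions are required for spherical-spline ",
         "interpolation; attach a montage (see standardPositions)")
  labs <- rec@channelLabels
  bad_idx <- match(tolower(bad), tolower(labs))
  if (anyNA(bad_idx))
    stop("unknown channel label(s): ", paste(bad[is.na(bad_idx)], collapse = ", "))
  good_idx <- setdiff(seq_along(labs), bad_idx)
  if (length(good_idx) < 4)
    stop("spherical-spline interpolation needs at least 4 good channels")

  P <- rec@positions / sqrt(rowSums(rec@positions^2))
  Pg <- P[good_idx, , drop = FALSE]
  Pb <- P[bad_idx, , drop = FALSE]
  G <- .gKernel(pmin(pmax(Pg %*% t(Pg), -1), 1))
  ng <- length(good_idx)
  A <- rbind(cbind(G + diag(1e-5, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(rec@data[good_idx, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  Gb <- .gKernel(pmin(pmax(Pb %*% t(Pg), -1), 1))
  interp <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad_idx), ncol(rec@data), byrow = TRUE)
  out <- rec@data
  out[bad_idx, ] <- interp
  initialize(rec, data = out)
}

#' Cut labeled fixed-length epochs out of a recording
#'
#' @param rec an \code{EEGRecording}.
#' @param boundaries data.frame with columns \code{start} (seconds),
#'   \code{segment} (one of elevator, plank_start, plank_end) and
#'   \code{condition} (neutral or negative).
#' @param subjectId subject identifier attached to every epoch.
#' @param epochLength epoch length in seconds (default 60). Every epoch has
#'   exactly \code{epochLength * sfreq} samples; overlapping boundaries are
#'   legal.
#' @return list of \code{EEGEpoch}.
#' @export
segmentEpochs <- function(rec, boundaries, subjectId = "S001",
                          epochLength = 60) {
  n <- ncol(rec@data)
  len <- round(epochLength * rec@sfreq)
  lapply(seq_len(nrow(boundaries)), function(r) {
    start <- round(boundaries$start[r] * rec@sfreq) + 1
    stop_ <- start + len - 1
    if (stop_ > n)
      stop(sprintf("segment '%s' starting at %g s extends beyond the end of the recording (%g s)",
                   boundaries$segment[r], boundaries$start[r], n / rec@sfreq))
    slice <- initialize(rec, data = rec@data[, start:stop_, drop = FALSE])
    EEGEpoch(slice, subjectId, boundaries$condition[r],
             boundaries$segment[r])
  })
}
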