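.epochData <- function(x) {
  if (is(x, "EEGEpoch")) list(d = x@recording@data, fs = x@recording@sfreq,
                              labels = x@recording@channelLabels)
  else if (is(x, "EEGRecording")) list(d = x@data, fs = x@sfreq,
                                       labels = x@channelLabels)
  else stop("expected an EEGEpoch or EEGRecording")
}

#' Pearson-correlation connectivity
#'
#' Absolute sample Pearson correlation between every channel pair over the
#' epoch. Correlations are rectified (absolute value) so that the
#' reciprocal distance transform downstream is well defined; the diagonal
#' is fixed at 0. A zero-variance channel gets a zero row/column with a
#' warning rather than an error.
#'
#' @param epoch an \code{EEGEpoch} or \code{EEGRecording}.
#' @return a \code{ConnectivityMatrix} with method "pearson".
#' @export
pearsonConnectivity <- function(epoch) {
  x <- .epochData(epoch)
  if (ncol(x$d) < 2) stop("need at least 2 samples")
  sds <- apply(x$d, 1, stats::sd)
  W <- suppressWarnings(abs(stats::cor(t(x$d))))
  if (any(sds == 0)) {
    warning("zero-variance channel(s) set to zero connectivity: ",
            paste(x$labels[sds == 0], collapse = ", "))
    W[sds == 0, ] <- 0
    W[, sds == 0] <- 0
  }
  ConnectivityMatrix(W, x$labels, "pearson")
}

#' wPLI accumulation kernel
#'
#' Given the imaginary parts of an ensemble of cross-spectra (windows x
#' frequency bins), returns the per-bin weighted Phase Lag Index
#' \code{|sum_k Im S_k| / sum_k |Im S_k|} and the band-pooled index in
#' which both sums also run over bins. Bins whose denominator is zero give
#' 0 by convention.
#'
#' @param imS numeric matrix, windows x bins, of Im(S_ij).
#' @return list(perBin = numeric vector, pooled = scalar).
#' @export
wpliKernel <- function(imS) {
  imS <- as.matrix(imS)
  num <- abs(colSums(imS))
  den <- colSums(abs(imS))
  perBin <- ifelse(den > 0, num / den, 0)
  tot_den <- sum(den)
  pooled <- if (tot_den > 0) abs(sum(imS)) / tot_den else 0
  list(perBin = perBin, pooled = pooled)
}

#' Weighted Phase Lag Index connectivity
#'
#' Welch-style estimator: the epoch is cut into Hann-tapered windows with
#' the given overlap, cross-spectra are computed per window by FFT, and for
#' every channel pair the index
#' \code{|sum Im S| / sum |Im S|} is formed with the sums running over the
#' window ensemble and the frequency bins inside \code{band} (band-pooled;
#' see the methods vignette for why bins are pooled rather than averaged).
#' Imaginary parts below 1e-12 of the cross-spectral magnitude are floored
#' to zero, so numerically-real cross-spectra (zero-lag coupling) yield 0.
#'
#' @param epoch an \code{EEGEpoch} or \code{EEGRecording}.
#' @param band frequency band c(low, high) in Hz, default c(1, 40).
#' @param windowS window length in seconds, default 2.
#' @param overlap fractional window overlap, default 0.5.
#' @return a \code{ConnectivityMatrix} with method "wpli", entries in [0,1].
#' @export
wpliConnectivity <- function(epoch, band = c(1, 40), windowS = 2,
                             overlap = 0.5) {
  x <- .epochData(epoch)
  fs <- x$fs
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie within (0, sfreq/2)")
  n <- ncol(x$d)
  nper <- round(windowS * fs)
  hop <- max(1, round(nper * (1 - overlap)))
  if (n < nper + hop)
    stop("epoch too short: need at least 2 windows of ", windowS, " s")
  starts <- seq(1, n - nper + 1, by = hop)
  n_ch <- length(x$labels)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  freqs <- (0:(nper - 1)) * fs / nper
  sel <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)

  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  num <- numeric(nrow(pairs))
  den <- numeric(nrow(pairs))
  for (s in starts) {
    seg <- t(x$d[, s:(s + nper - 1), drop = FALSE]) * taper
    F <- stats::mvfft(seg)[sel, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      S <- F[, i] * Conj(F[, j])
      imS <- Im(S)
      imS[abs(imS) < 1e-12 * Mod(S)] <- 0
      num[p] <- num[p] + sum(imS)
      den[p] <- den[p] + sum(abs(imS))
    }
  }
  W <- matrix(0, n_ch, n_ch)
  vals <- ifelse(den > 0, abs(num) / den, 0)
  W[pairs] <- vals
  W[pairs[, c(2, 1), drop = FALSE]] <- vals
  ConnectivityMatrix(W, x$labels, "wpli", band = band)
}

#' Connectivity-to-distance transform
#'
#' Distances are the reciprocals of connectivity weights
#' (\code{D = 1/W}); weights at or below \code{weightFloor} give an
#' infinite distance (disconnected pair). The diagonal is 0. Negative
#' Pearson weights must be rectified before this transform (the Pearson
#' estimator already returns absolute values).
#'
#' @param conn a \code{ConnectivityMatrix}.
#' @param weightFloor weights at or below this are disconnected
#'   (default 1e-6).
#' @return a \code{DistanceMatrix}.
#' @export
connectivityToDistance <- function(conn, weightFloor = 1e-6) {
  W <- conn@W
  D <- ifelse(W > weightFloor, 1 / W, Inf)
  diag(D) <- 0
  new("DistanceMatrix", labels = conn@labels, D = D,
      provenance = conn@method)
}

#' Proportional thresholding and binarization
#'
#' Keeps the strongest \code{ceiling(keep * n(n-1)/2)} of the upper-triangle
#' weights as edges of weight 1 and sets the rest to 0. Ties at the cut are
#' resolved deterministically: candidates are ranked by descending weight,
#' then by lexicographic (label_i, label_j) pair order, and the quota is
#' filled in that ranking.
#'
#' @param conn a \code{ConnectivityMatrix}.
#' @param keep fraction of edges to retain, in (0, 1]; default 0.75.
#' @return a binary \code{ConnectivityMatrix} (method "binary").
#' @export
proportionalThreshold <- function(conn, keep = 0.75) {
  stopifnot(keep > 0, keep <= 1)
  n <- length(conn@labels)
  ut <- which(upper.tri(conn@W), arr.ind = TRUE)
  w <- conn@W[ut]
  quota <- ceiling(keep * nrow(ut))
  ord <- order(-w, conn@labels[ut[, 1]], conn@labels[ut[, 2]])
  kept <- ord[seq_len(quota)]
  B <- matrix(0, n, n)
  B[ut[kept, , drop = FALSE]] <- 1
  B[ut[kept, c(2, 1), drop = FALSE]] <- 1
  ConnectivityMatrix(B, conn@labels, "binary", band = conn@band)
}

#' Export a connectivity matrix as square CSV
#'
#' @param conn a \code{ConnectivityMatrix} or \code{DistanceMatrix}.
#' @param path output path; the label set forms the header row and first
#'   column.
#' @return \code{path}, invisibly.
#' @export
writeConnectivityCSV <- function(conn, path) {
  W <- weightMatrix(conn)
  utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  invisible(path)
}
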