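#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' EEGRecording: a labeled multichannel time series
#'
#' Container for a continuous multichannel recording: a channels x samples
#' matrix in microvolts, ordered channel labels, the sampling frequency, and
#' (optionally) per-channel unit-sphere electrode coordinates used by
#' spherical-spline interpolation.
#'
#' @slot channelLabels character vector, one label per data row, unique.
#' @slot sfreq sampling frequency in Hz (> 0).
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot positions optional numeric matrix (channels x 3) of unit-sphere
#'   electrode coordinates, or NULL.
#' @slot meta free-form annotation list.
#' @export
setClass("EEGRecording",
  representation(
    channelLabels = "character",
    sfreq = "numeric",
    data = "matrix",
    positions = "matrixOrNULL",
    meta = "list"
  ),
  prototype(positions = NULL, meta = list())
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "number of channel labels must equal number of data rows")
  if (anyDuplicated(tolower(object@channelLabels)))
    msg <- c(msg, "channel labels must be unique (case-insensitive)")
  if (length(object@sfreq) != 1 || !is.finite(object@sfreq) || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (!is.null(object@positions)) {
    if (nrow(object@positions) != nrow(object@data) || ncol(object@positions) != 3)
      msg <- c(msg, "positions must be a channels x 3 matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param channelLabels character vector of channel names.
#' @param sfreq sampling frequency (Hz).
#' @param positions optional channels x 3 matrix of unit-sphere coordinates;
#'   if NULL, standard montage positions are attached when all labels are
#'   known 10-20 names.
#' @param meta free-form list of annotations.
#' @return an \code{EEGRecording}.
#' @export
EEGRecording <- function(data, channelLabels, sfreq, positions = NULL,
                         meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(positions)) {
    std <- tryCatch(standardPositions(channelLabels), error = function(e) NULL)
    positions <- std
  }
  new("EEGRecording", channelLabels = as.character(channelLabels),
      sfreq = as.numeric(sfreq), data = data, positions = positions,
      meta = meta)
}

#' @describeIn EEGRecording-class number of channels
#' @param x,object an \code{EEGRecording}
#' @export
setMethod("nrow", "EEGRecording", function(x) nrow(x@data))

#' Accessors for EEGRecording
#'
#' \code{channelLabels}, \code{sfreq}, \code{eegData}, \code{channelPositions}
#' return the respective slots; \code{nSamples} the number of samples.
#'
#' @param object an \code{EEGRecording} (or \code{EEGEpoch} where noted).
#' @return the slot value.
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)

#' @rdname channelLabels
#' @export
setGeneric("sfreq", function(object) standardGeneric("sfreq"))
#' @rdname channelLabels
#' @export
setMethod("sfreq", "EEGRecording", function(object) object@sfreq)

#' @rdname channelLabels
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname channelLabels
#' @export
setMethod("eegData", "EEGRecording", function(object) {
  d <- object@data
  rownames(d) <- object@channelLabels
  d
})

#' @rdname channelLabels
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))
#' @rdname channelLabels
#' @export
setMethod("channelPositions", "EEGRecording", function(object) object@positions)

#' @rdname channelLabels
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname channelLabels
#' @export
setMethod("nSamples", "EEGRecording", function(object) ncol(object@data))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sfreq,
              ncol(object@data) / object@sfreq))
  cat("  channels:", paste(utils::head(object@channelLabels, 8), collapse = ", "),
      if (length(object@channelLabels) > 8) "..." else "", "\n")
  cat("  positions:", if (is.null(object@positions)) "none" else "unit sphere", "\n")
})

.CONDITIONS <- c("neutral", "negative")
.TASKS <- c("elevator", "plank")
.SEGMENTS <- c("elevator", "plank_start", "plank_end")

#' EEGEpoch: a fixed-length labeled slice of a recording
#'
#' An epoch carries the sliced \code{EEGRecording} plus the within-subject
#' factorial labels used by the repeated-measures design: subject, condition
#' (neutral / negative), task (elevator / plank) and the recording segment
#' it was cut from (elevator / plank_start / plank_end).
#'
#' @slot recording the sliced \code{EEGRecording}.
#' @slot subjectId subject identifier.
#' @slot condition one of "neutral", "negative".
#' @slot task one of "elevator", "plank".
#' @slot segment one of "elevator", "plank_start", "plank_end".
#' @export
setClass("EEGEpoch",
  representation(
    recording = "EEGRecording",
    subjectId = "character",
    condition = "character",
    task = "character",
    segment = "character"
  )
)

setValidity("EEGEpoch", function(object) {
  msg <- character()
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of: %s",
                          paste(.CONDITIONS, collapse = ", ")))
  if (!object@task %in% .TASKS)
    msg <- c(msg, sprintf("task must be one of: %s",
                          paste(.TASKS, collapse = ", ")))
  if (!object@segment %in% .SEGMENTS)
    msg <- c(msg, sprintf("segment must be one of: %s",
                          paste(.SEGMENTS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpoch
#'
#' @param recording the sliced \code{EEGRecording}.
#' @param subjectId subject identifier (string).
#' @param condition "neutral" or "negative".
#' @param task "elevator" or "plank"; if missing, derived from
#'   \code{segment} (elevator stays elevator, plank_* become plank).
#' @param segment "elevator", "plank_start" or "plank_end".
#' @return an \code{EEGEpoch}.
#' @export
EEGEpoch <- function(recording, subjectId, condition, segment,
                     task = if (segment == "elevator") "elevator" else "plank") {
  new("EEGEpoch", recording = recording, subjectId = as.character(subjectId),
      condition = condition, task = task, segment = segment)
}

#' @rdname channelLabels
#' @export
setMethod("eegData", "EEGEpoch", function(object) eegData(object@recording))
#' @rdname channelLabels
#' @export
setMethod("sfreq", "EEGEpoch", function(object) object@recording@sfreq)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EEGEpoch", function(object) object@recording@channelLabels)

setMethod("show", "EEGEpoch", function(object) {
  cat(sprintf("EEGEpoch: subject %s | %s | %s (%s) | %.1f s @ %g Hz\n",
              object@subjectId, object@condition, object@task, object@segment,
              ncol(object@recording@data) / object@recording@sfreq,
              object@recording@sfreq))
})

#' ConnectivityMatrix: symmetric channel-pair coupling strengths
#'
#' A symmetric channels x channels matrix of functional-connectivity weights
#' tagged with the estimator that produced it. By convention the diagonal is
#' fixed at zero. Pearson matrices hold absolute correlations in [0, 1]
#' (rectified; see \code{\link{pearsonConnectivity}}); wPLI matrices hold
#' values in [0, 1]; binary matrices hold 0/1 after proportional
#' thresholding.
#'
#' @slot labels ordered channel labels.
#' @slot W the weight matrix.
#' @slot method one of "pearson", "wpli", "binary".
#' @slot band analysis frequency band (low, high) in Hz, or c(NA, NA).
#' @export
setClass("ConnectivityMatrix",
  representation(
    labels = "character",
    W = "matrix",
    method = "character",
    band = "numeric"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  W <- object@W
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  if (length(object@labels) != nrow(W))
    msg <- c(msg, "labels length must match W dimension")
  if (!isSymmetric(unname(W), tol = 1e-10)) msg <- c(msg, "W must be symmetric")
  if (any(abs(diag(W)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (!object@method %in% c("pearson", "wpli", "binary"))
    msg <- c(msg, "method must be 'pearson', 'wpli' or 'binary'")
  if (object@method %in% c("wpli", "binary") &&
      any(W < -1e-12 | W > 1 + 1e-12))
    msg <- c(msg, sprintf("%s entries must lie in [0,1]", object@method))
  if (object@method == "pearson" && any(abs(W) > 1 + 1e-12))
    msg <- c(msg, "pearson entries must lie in [-1,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param W square symmetric weight matrix (diagonal forced to 0).
#' @param labels channel labels.
#' @param method "pearson", "wpli" or "binary".
#' @param band frequency band (low, high) Hz; NA for broadband/time-domain.
#' @return a \code{ConnectivityMatrix}.
#' @export
ConnectivityMatrix <- function(W, labels, method, band = c(NA_real_, NA_real_)) {
  W <- as.matrix(W)
  diag(W) <- 0
  dimnames(W) <- list(labels, labels)
  new("ConnectivityMatrix", labels = as.character(labels), W = W,
      method = method, band = as.numeric(band))
}

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "ConnectivityMatrix", function(object) object@labels)

#' Extract the weight matrix
#'
#' @param object a \code{ConnectivityMatrix} or \code{DistanceMatrix}.
#' @return the numeric matrix with label dimnames.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))
#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "ConnectivityMatrix", function(object) {
  W <- object@W
  dimnames(W) <- list(object@labels, object@labels)
  W
})

setMethod("show", "ConnectivityMatrix", function(object) {
  bd <- if (all(is.na(object@band))) "broadband" else
    sprintf("%g-%g Hz", object@band[1], object@band[2])
  cat(sprintf("ConnectivityMatrix (%s, %s): %d channels, weights in [%.3g, %.3g]\n",
              object@method, bd, length(object@labels),
              min(object@W), max(object@W)))
})

#' DistanceMatrix: graph distances derived from connectivity
#'
#' Pairwise edge lengths where distance is the reciprocal of connectivity
#' weight; weights at or below the floor become infinite (disconnected).
#'
#' @slot labels channel labels.
#' @slot D distance matrix (nonnegative, possibly Inf; zero diagonal).
#' @slot provenance method tag of the source connectivity matrix.
#' @export
setClass("DistanceMatrix",
  representation(labels = "character", D = "matrix", provenance = "character")
)

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  D <- object@D
  if (nrow(D) != ncol(D)) msg <- c(msg, "D must be square")
  if (length(object@labels) != nrow(D))
    msg <- c(msg, "labels length must match D dimension")
  if (any(diag(D) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(D < 0)) msg <- c(msg, "distances must be nonnegative")
  if (!isSymmetric(unname(ifelse(is.infinite(D), .Machine$double.xmax, D)),
                   tol = 1e-10))
    msg <- c(msg, "D must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "DistanceMatrix", function(object) {
  D <- object@D
  dimnames(D) <- list(object@labels, object@labels)
  D
})
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "DistanceMatrix", function(object) object@labels)

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (from %s): %d nodes, %d disconnected pairs\n",
              object@provenance, length(object@labels),
              sum(is.infinite(object@D)) / 2))
})

#' GraphPartition: a community assignment with its modularity
#'
#' @slot labels node labels.
#' @slot membership integer community id per node (1-based, contiguous).
#' @slot Q Newman modularity of the partition.
#' @export
setClass("GraphPartition",
  representation(labels = "character", membership = "integer", Q = "numeric")
)

setValidity("GraphPartition", function(object) {
  msg <- character()
  if (length(object@membership) != length(object@labels))
    msg <- c(msg, "one community id per node required")
  if (length(object@Q) != 1 || object@Q < -0.5 - 1e-9 || object@Q > 1 + 1e-9)
    msg <- c(msg, "Q must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GraphPartition", function(object) {
  cat(sprintf("GraphPartition: %d nodes in %d communities, Q = %.4f\n",
              length(object@labels), length(unique(object@membership)),
              object@Q))
})

#' CentralityVector: per-node eigenvector centrality
#'
#' Nonnegative leading-eigenvector entries of the adjacency matrix,
#' normalized to unit Euclidean norm.
#'
#' @slot labels node labels.
#' @slot values nonnegative centrality per node, sum of squares = 1.
#' @export
setClass("CentralityVector",
  representation(labels = "character", values = "numeric")
)

setValidity("CentralityVector", function(object) {
  msg <- character()
  if (length(object@values) != length(object@labels))
    msg <- c(msg, "one value per node required")
  if (any(object@values < -1e-12)) msg <- c(msg, "entries must be nonnegative")
  if (abs(sum(object@values^2) - 1) > 1e-8)
    msg <- c(msg, "values must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "CentralityVector", function(object) object@labels)

#' Extract centrality values
#' @param object a \code{CentralityVector}.
#' @return named numeric vector.
#' @export
setGeneric("centralityValues", function(object) standardGeneric("centralityValues"))
#' @rdname centralityValues
#' @export
setMethod("centralityValues", "CentralityVector", function(object)
  stats::setNames(object@values, object@labels))

setMethod("show", "CentralityVector", function(object) {
  top <- order(object@values, decreasing = TRUE)[1:min(3, length(object@values))]
  cat(sprintf("CentralityVector: %d nodes; top: %s\n", length(object@labels),
              paste(sprintf("%s=%.3f", object@labels[top], object@values[top]),
                    collapse = ", ")))
})

#' BadChannelReport: channels flagged by automated detection
#'
#' @slot flatline labels with a flatline run at least flatline_s seconds long.
#' @slot lowCorrelation labels whose best windowed correlation with any other
#'   channel falls below the threshold.
#' @slot thresholds list(flatline_s=, corr_threshold=) actually used.
#' @export
setClass("BadChannelReport",
  representation(flatline = "character", lowCorrelation = "character",
                 thresholds = "list")
)

setMethod("show", "BadChannelReport", function(object) {
  cat(sprintf("BadChannelReport (flatline >= %g s, corr < %g):\n",
              object@thresholds$flatline_s, object@thresholds$corr_threshold))
  cat("  flatline:       ",
      if (length(object@flatline)) paste(object@flatline, collapse = ", ")
      else "none", "\n")
  cat("  low correlation:",
      if (length(object@lowCorrelation)) paste(object@lowCorrelation, collapse = ", ")
      else "none", "\n")
})

#' RegionMap: cortical region to electrode-set mapping
#'
#' Maps the five cortical region names (frontal, temporal, central, parietal,
#' occipital) to pairwise-disjoint electrode label sets.
#'
#' @slot map named list of character vectors, one per region.
#' @export
setClass("RegionMap", representation(map = "list"))

.REGIONS <- c("frontal", "temporal", "central", "parietal", "occipital")

setValidity("RegionMap", function(object) {
  msg <- character()
  if (!all(names(object@map) %in% .REGIONS))
    msg <- c(msg, sprintf("region names must be among: %s",
                          paste(.REGIONS, collapse = ", ")))
  all_labels <- tolower(unlist(object@map, use.names = FALSE))
  if (anyDuplicated(all_labels))
    msg <- c(msg, "region electrode sets must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' Region names of a RegionMap
#' @param object a \code{RegionMap}.
#' @return character vector of region names.
#' @export
setGeneric("regionNames", function(object) standardGeneric("regionNames"))
#' @rdname regionNames
#' @export
setMethod("regionNames", "RegionMap", function(object) names(object@map))

#' Electrodes of one region
#' @param object a \code{RegionMap}.
#' @param region region name.
#' @return character vector of electrode labels.
#' @export
setGeneric("regionElectrodes", function(object, region)
  standardGeneric("regionElectrodes"))
#' @rdname regionElectrodes
#' @export
setMethod("regionElectrodes", "RegionMap", function(object, region) {
  if (!region %in% names(object@map))
    stop("unknown region: ", region)
  object@map[[region]]
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap:\n")
  for (r in names(object@map))
    cat(sprintf("  %-9s (%2d): %s\n", r, length(object@map[[r]]),
                paste(object@map[[r]], collapse = ", ")))
})
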