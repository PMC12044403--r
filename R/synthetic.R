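#' CouplingSpec: planted cross-channel couplings for synthetic EEG
#'
#' Describes a set of pairwise sinusoidal couplings: for each edge
#' (i, j, frequency, lag, strength) both channels receive the same
#' sinusoid with a fresh random base phase per realization; channel j's copy
#' is shifted by the planted phase lag. Each channel additionally receives
#' independent white Gaussian noise. Ground-truth lags and strengths are
#' therefore analytically known, which is what estimator validation needs.
#'
#' @slot edges data.frame with columns i, j (channel labels), freq (Hz),
#'   lag (radians, in (-pi, pi]), strength (in [0, 1]).
#' @slot noiseSd per-channel white-noise standard deviation (microvolts).
#' @slot amplitude sinusoid amplitude scale (microvolts).
#' @slot pinkNoise logical; if TRUE the additive noise is 1/f-shaped
#'   instead of white.
#' @export
setClass("CouplingSpec",
  representation(edges = "data.frame", noiseSd = "numeric",
                 amplitude = "numeric", pinkNoise = "logical"),
  prototype(pinkNoise = FALSE)
)

setValidity("CouplingSpec", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("i", "j", "freq", "lag", "strength")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("edges needs columns:", paste(need, collapse = ", ")))
  else {
    if (any(e$strength < 0 | e$strength > 1))
      msg <- c(msg, "coupling strength must lie in [0,1]")
    if (any(e$lag <= -pi | e$lag > pi))
      msg <- c(msg, "phase lag must lie in (-pi, pi]")
    if (any(e$freq <= 0)) msg <- c(msg, "frequencies must be positive")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a CouplingSpec
#'
#' @param edges data.frame(i, j, freq, lag, strength); see
#'   \code{\linkS4class{CouplingSpec}}.
#' @param noiseSd white-noise SD in microvolts (default 1).
#' @param amplitude sinusoid amplitude in microvolts (default 1).
#' @param pinkNoise use 1/f-shaped instead of white noise (default FALSE).
#' @return a \code{CouplingSpec}.
#' @export
CouplingSpec <- function(edges, noiseSd = 1, amplitude = 1, pinkNoise = FALSE) {
  edges$i <- as.character(edges$i); edges$j <- as.character(edges$j)
  new("CouplingSpec", edges = edges, noiseSd = noiseSd,
      amplitude = amplitude, pinkNoise = pinkNoise)
}

# Evaluate a function under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from a base seed and string identifiers,
# independent of iteration order (stable polynomial string hash).
deriveSeed <- function(seed, ...) {
  ids <- paste(c(...), collapse = "\x1f")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(ids)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

.pinkNoise <- function(n) {
  # 1/f amplitude shaping in the frequency domain, unit variance
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  k <- c(1, seq_len(n - 1))
  shaped <- Re(stats::fft(f / sqrt(pmin(k, n - k + 1)), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Generate a recording with planted sinusoidal couplings
#'
#' Each channel is the sum, over the coupling edges it participates in, of
#' \code{amplitude * strength * sin(2 pi f t + phi_base [+ lag])} plus
#' independent Gaussian noise. \code{phi_base} is drawn uniformly per edge
#' per realization, which makes the coupling genuine (not phase-locked to
#' the clock) while the pairwise lag stays exact. Output is deterministic
#' given \code{seed}.
#'
#' @param spec a \code{CouplingSpec}.
#' @param labels channel labels of the output recording.
#' @param sfreq sampling frequency (Hz).
#' @param duration length in seconds.
#' @param seed integer seed.
#' @return an \code{EEGRecording}.
#' @export
generateCoupledRecording <- function(spec, labels, sfreq, duration, seed) {
  n <- round(duration * sfreq)
  if (n < 2) stop("duration*sfreq must be at least 2 samples")
  e <- spec@edges
  unknown <- setdiff(unique(c(e$i, e$j)), labels)
  if (length(unknown))
    stop("coupling edges name unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  if (any(e$freq >= sfreq / 2))
    stop("coupling frequencies must be below the Nyquist frequency")
  n_ch <- length(labels)
  withSeed(seed, {
    d <- if (spec@noiseSd > 0) {
      if (spec@pinkNoise) {
        spec@noiseSd * t(vapply(seq_len(n_ch), function(i) .pinkNoise(n),
                                numeric(n)))
      } else {
        matrix(stats::rnorm(n_ch * n, sd = spec@noiseSd), n_ch, n)
      }
    } else matrix(0, n_ch, n)
    if (nrow(e)) {
      t_s <- (seq_len(n) - 1) / sfreq
      for (k in seq_len(nrow(e))) {
        phi <- stats::runif(1, 0, 2 * pi)
        a <- spec@amplitude * e$strength[k]
        arg <- 2 * pi * e$freq[k] * t_s + phi
        ii <- match(e$i[k], labels); jj <- match(e$j[k], labels)
        d[ii, ] <- d[ii, ] + a * sin(arg)
        d[jj, ] <- d[jj, ] + a * sin(arg + e$lag[k])
      }
    }
    EEGRecording(d, labels, sfreq,
                 positions = tryCatch(standardPositions(labels),
                                      error = function(e) NULL))
  })
}

#' Two channels sharing one lagged sinusoidal source
#'
#' Fixture generator for phase-lag estimator validation: channels "A" and
#' "B" carry the same unit-amplitude sinusoid, B shifted by \code{lag},
#' plus independent Gaussian noise with amplitude ratio
#' signal / noise = \code{snr} (use \code{Inf} for a noiseless pair).
#'
#' @param frequency source frequency (Hz).
#' @param lag planted phase lag (radians).
#' @param snr signal-to-noise amplitude ratio (>= 0; Inf for no noise).
#' @param duration seconds.
#' @param sfreq sampling frequency (Hz).
#' @param seed integer seed.
#' @return a 2-channel \code{EEGRecording}.
#' @export
plantLagPair <- function(frequency, lag, snr, duration, sfreq, seed = 1) {
  stopifnot(snr >= 0)
  noise_sd <- if (is.infinite(snr)) 0 else if (snr == 0) 1 else 1 / snr
  spec <- CouplingSpec(
    data.frame(i = "A", j = "B", freq = frequency, lag = lag,
               strength = if (snr == 0) 0 else 1),
    noiseSd = noise_sd, amplitude = 1
  )
  generateCoupledRecording(spec, c("A", "B"), sfreq, duration, seed)
}

#' Instantaneous phase via the analytic signal
#'
#' FFT-based Hilbert transform; returns the unwrapped-free instantaneous
#' phase (radians) of each sample. Used to verify planted lags.
#'
#' @param x numeric vector (one channel).
#' @return numeric vector of phases in (-pi, pi].
#' @export
instantaneousPhase <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(f * h, inverse = TRUE) / n
  Arg(z)
}

#' StudyDesign: a 2x2 fully within-subject synthetic study
#'
#' Specifies a factorial study: every subject contributes one epoch to each
#' of the four (condition x task) cells. Each cell has its own base
#' \code{CouplingSpec}; per-region additive coupling-strength deltas plant
#' condition/task effects; a per-subject random intercept on coupling
#' strength creates the within-subject correlation a repeated-measures
#' design assumes.
#'
#' @slot nSubjects number of subjects (>= 2).
#' @slot epochLength epoch length in seconds.
#' @slot sfreq sampling frequency (Hz).
#' @slot channelLabels montage labels.
#' @slot baseCoupling named list of 4 \code{CouplingSpec}s, names
#'   "neutral.elevator", "neutral.plank", "negative.elevator",
#'   "negative.plank".
#' @slot effectMap data.frame(region, condition, task, delta): additive
#'   strength delta applied to every edge whose both endpoints lie in the
#'   region, in the matching cells.
#' @slot subjectSd SD of the per-subject random intercept on strength.
#' @slot seed integer base seed.
#' @export
setClass("StudyDesign",
  representation(nSubjects = "integer", epochLength = "numeric",
                 sfreq = "numeric", channelLabels = "character",
                 baseCoupling = "list", effectMap = "data.frame",
                 subjectSd = "numeric", seed = "integer")
)

.CELLS <- c("neutral.elevator", "neutral.plank",
            "negative.elevator", "negative.plank")

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
  if (!setequal(names(object@baseCoupling), .CELLS))
    msg <- c(msg, paste("baseCoupling must name all four cells:",
                        paste(.CELLS, collapse = ", ")))
  if (nrow(object@effectMap) &&
      !all(c("region", "condition", "task", "delta") %in% names(object@effectMap)))
    msg <- c(msg, "effectMap needs columns region, condition, task, delta")
  if (length(msg)) msg else TRUE
})

#' The default reduced-scale montage (16 channels)
#'
#' A 16-electrode subset of the standard montage covering all five regions
#' (5 frontal, 2 temporal, 3 central, 3 parietal, 3 occipital), used as the
#' default synthetic scale.
#'
#' @return character vector of 16 labels.
#' @export
reducedMontage <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4",
    "T7", "T8",
    "Cz", "C3", "C4",
    "Pz", "P3", "P4",
    "Oz", "O1", "O2")
}

# Carrier frequency per region (Hz). Distinct carriers keep cross-region
# pairs incoherent, so planted within-region coupling is identifiable: with
# a single shared frequency, every channel pair would hold a constant
# relative phase over the epoch and look coupled to both estimators.
.REGION_FREQS <- c(frontal = 6, temporal = 14, central = 10,
                   parietal = 19, occipital = 24)

#' Default carrier frequency of a region
#' @param region region name.
#' @return frequency in Hz.
#' @export
regionCarrierFreq <- function(region) {
  if (!region %in% names(.REGION_FREQS)) stop("unknown region: ", region)
  unname(.REGION_FREQS[region])
}

# All within-region electrode pairs for the given labels and map, each
# region on its own carrier frequency.
.withinRegionEdges <- function(labels, map, lag = pi / 4, strength = 0.4) {
  out <- list()
  for (r in regionNames(map)) {
    els <- intersect(labels, regionElectrodes(map, r))
    if (length(els) < 2) next
    cmb <- utils::combn(els, 2)
    out[[r]] <- data.frame(i = cmb[1, ], j = cmb[2, ],
                           freq = .REGION_FREQS[[r]],
                           lag = lag, strength = strength)
  }
  do.call(rbind, out)
}

#' Cross-region coupling edges for planting network integration
#'
#' Builds coupling edges between every electrode pair spanning the two
#' named regions, at the first region's carrier frequency (so the added
#' coupling also dilutes that region's internal phase consistency, the way
#' increased between-network integration reduces segregation).
#'
#' @param regionA,regionB region names.
#' @param labels montage labels.
#' @param map a \code{RegionMap}.
#' @param strength coupling strength (default 0.5).
#' @param lag phase lag (default pi/3).
#' @return edge data.frame suitable for \code{CouplingSpec}.
#' @export
crossRegionEdges <- function(regionA, regionB, labels = reducedMontage(),
                             map = restrictRegionMap(defaultRegionMap(),
                                                     labels),
                             strength = 0.5, lag = pi / 3) {
  a <- intersect(labels, regionElectrodes(map, regionA))
  b <- intersect(labels, regionElectrodes(map, regionB))
  e <- expand.grid(i = a, j = b, stringsAsFactors = FALSE)
  e$freq <- regionCarrierFreq(regionA)
  e$lag <- lag
  e$strength <- strength
  e
}

#' Anterior/posterior two-module base coupling
#'
#' A base \code{CouplingSpec} in which the montage forms two coupled
#' super-communities: every electrode pair within the anterior module
#' (frontal + temporal + central) is coupled on the 6 Hz carrier and every
#' pair within the posterior module (parietal + occipital) on the 19 Hz
#' carrier. This mimics large-scale anterior-posterior network
#' segregation and gives the thresholded wPLI network a clearly modular
#' baseline, so that planted integration effects on modularity are
#' identifiable.
#'
#' @param labels montage labels (default \code{reducedMontage()}).
#' @param map region map used to assign electrodes to modules.
#' @param strength within-module coupling strength (default 0.6).
#' @param noiseSd additive white-noise SD (default 1).
#' @return a \code{CouplingSpec}.
#' @export
anteriorPosteriorCoupling <- function(labels = reducedMontage(),
                                      map = restrictRegionMap(
                                        defaultRegionMap(), labels),
                                      strength = 0.6, noiseSd = 1) {
  region_of <- vapply(labels, regionLookup, "", map = map)
  ant <- labels[region_of %in% c("frontal", "temporal", "central")]
  post <- labels[region_of %in% c("parietal", "occipital")]
  mod_edges <- function(g, f) {
    cmb <- utils::combn(g, 2)
    data.frame(i = cmb[1, ], j = cmb[2, ], freq = f, lag = pi / 4,
               strength = strength)
  }
  CouplingSpec(rbind(mod_edges(ant, 6), mod_edges(post, 19)),
               noiseSd = noiseSd)
}

#' Anterior-posterior integration edges
#'
#' Coupling edges between every anterior-module and posterior-module
#' electrode pair, on their own 12 Hz carrier. Added to the negative cells
#' of a study built on \code{\link{anteriorPosteriorCoupling}}, they model
#' threat-induced network integration: the added cross-module coupling
#' displaces within-module edges from the proportionally thresholded
#' network and lowers its Louvain modularity.
#'
#' @param labels montage labels (default \code{reducedMontage()}).
#' @param map region map used to assign electrodes to modules.
#' @param strength cross-module coupling strength (default 0.85).
#' @param lag planted phase lag (default pi/3).
#' @return edge data.frame suitable for \code{CouplingSpec}.
#' @export
integrationEdges <- function(labels = reducedMontage(),
                             map = restrictRegionMap(defaultRegionMap(),
                                                     labels),
                             strength = 0.85, lag = pi / 3) {
  region_of <- vapply(labels, regionLookup, "", map = map)
  ant <- labels[region_of %in% c("frontal", "temporal", "central")]
  post <- labels[region_of %in% c("parietal", "occipital")]
  e <- expand.grid(i = ant, j = post, stringsAsFactors = FALSE)
  e$freq <- 12
  e$lag <- lag
  e$strength <- strength
  e
}

#' Construct a StudyDesign
#'
#' With no arguments this returns the default synthetic study: 20 subjects,
#' 16 channels, 250 Hz, 10-s epochs, within-region 10 Hz couplings
#' (strength 0.4, lag pi/4) identical in all four cells (a null study), and
#' a subject random intercept SD of 0.05 on coupling strength.
#'
#' @param nSubjects subjects (default 20).
#' @param epochLength seconds (default 10).
#' @param sfreq Hz (default 250).
#' @param channelLabels montage (default \code{reducedMontage()}).
#' @param baseCoupling named list of 4 CouplingSpecs, or a single
#'   \code{CouplingSpec} replicated to all cells, or NULL for the default
#'   within-region coupling.
#' @param effectMap data.frame(region, condition, task, delta); empty by
#'   default (null study). \code{task} or \code{condition} may be NA to
#'   apply the delta across that factor's levels.
#' @param subjectSd random-intercept SD on strength (default 0.05).
#' @param seed base seed (default 1).
#' @return a \code{StudyDesign}.
#' @export
StudyDesign <- function(nSubjects = 20, epochLength = 10, sfreq = 250,
                        channelLabels = reducedMontage(),
                        baseCoupling = NULL,
                        effectMap = data.frame(region = character(),
                                               condition = character(),
                                               task = character(),
                                               delta = numeric()),
                        subjectSd = 0.05, seed = 1) {
  if (is.null(baseCoupling)) {
    map <- restrictRegionMap(defaultRegionMap(), channelLabels)
    baseCoupling <- CouplingSpec(.withinRegionEdges(channelLabels, map),
                                 noiseSd = 1, amplitude = 1)
  }
  if (is(baseCoupling, "CouplingSpec"))
    baseCoupling <- stats::setNames(rep(list(baseCoupling), 4), .CELLS)
  new("StudyDesign", nSubjects = as.integer(nSubjects),
      epochLength = epochLength, sfreq = sfreq,
      channelLabels = channelLabels, baseCoupling = baseCoupling,
      effectMap = effectMap, subjectSd = subjectSd, seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d subjects x 4 cells | %d ch @ %g Hz, %g-s epochs | %d planted effect(s)\n",
              object@nSubjects, length(object@channelLabels), object@sfreq,
              object@epochLength, nrow(object@effectMap)))
})

#' Generate a full factorial synthetic study
#'
#' Emits \code{nSubjects x 4} epochs (one per condition x task cell per
#' subject). Per subject, a random intercept (SD \code{subjectSd}) is added
#' to every edge's coupling strength in every cell; the effect-map deltas
#' are added to edges whose both endpoints lie in the named region, in the
#' matching cells. Strengths are clipped to [0, 1]; the number of clipped
#' edges is recorded in the returned attribute \code{"clipWarnings"} (and
#' a warning is raised if any clipping occurred). Reproducible from the
#' design seed.
#'
#' @param design a \code{StudyDesign}.
#' @param map region map used to resolve effect regions (default: standard
#'   map restricted to the design's montage).
#' @return list of \code{EEGEpoch}, with attribute "clipWarnings".
#' @export
generateStudy <- function(design,
                          map = restrictRegionMap(defaultRegionMap(),
                                                  design@channelLabels)) {
  cells <- expand.grid(condition = .CONDITIONS, task = .TASKS,
                       stringsAsFactors = FALSE)
  region_of <- vapply(design@channelLabels, regionLookup, "", map = map)
  clip_count <- 0L
  epochs <- vector("list", design@nSubjects * 4L)
  k <- 0L
  for (s in seq_len(design@nSubjects)) {
    sid <- sprintf("S%03d", s)
    intercept <- withSeed(deriveSeed(design@seed, "intercept", sid),
                          stats::rnorm(1, 0, design@subjectSd))
    for (ci in seq_len(nrow(cells))) {
      cond <- cells$condition[ci]; task <- cells$task[ci]
      spec <- design@baseCoupling[[paste(cond, task, sep = ".")]]
      e <- spec@edges
      e$strength <- e$strength + intercept
      em <- design@effectMap
      if (nrow(em)) {
        for (r in seq_len(nrow(em))) {
          if (!is.na(em$condition[r]) && em$condition[r] != cond) next
          if (!is.na(em$task[r]) && em$task[r] != task) next
          hit <- region_of[e$i] %in% em$region[r] &
                 region_of[e$j] %in% em$region[r]
          e$strength[hit] <- e$strength[hit] + em$delta[r]
        }
      }
      out_of_range <- e$strength < 0 | e$strength > 1
      clip_count <- clip_count + sum(out_of_range)
      e$strength <- pmin(pmax(e$strength, 0), 1)
      cell_spec <- CouplingSpec(e, noiseSd = spec@noiseSd,
                                amplitude = spec@amplitude,
                                pinkNoise = spec@pinkNoise)
      rec <- generateCoupledRecording(
        cell_spec, design@channelLabels, design@sfreq, design@epochLength,
        seed = deriveSeed(design@seed, "epoch", sid, cond, task))
      segment <- if (task == "elevator") "elevator" else "plank_end"
      k <- k + 1L
      epochs[[k]] <- EEGEpoch(rec, sid, cond, segment, task)
    }
  }
  if (clip_count > 0)
    warning(clip_count, " edge strength value(s) clipped to [0,1]")
  attr(epochs, "clipWarnings") <- clip_count
  epochs
}
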