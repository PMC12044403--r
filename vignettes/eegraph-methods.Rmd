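---
title: "EEG brain-network analysis with eegraph: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG brain-network analysis with eegraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegraph)
```

# Scope

`eegraph` implements the analysis chain used to study how emotionally
salient contexts (for example, walking at virtual height) reorganize
human brain networks measured with scalp EEG: preprocessing of
multichannel recordings, two complementary functional-connectivity
estimators, graph-theoretic summaries over a fixed cortical
parcellation, and a fully within-subject 2×2 statistical layer. Because
raw experimental datasets of this kind are typically not redistributable,
the package ships a synthetic-study generator with planted, analytically
known coupling structure; every claim the test suite makes is checked
against that ground truth or against independent oracles.

# The data model

A `Recording` is a channels × samples matrix in microvolts with ordered
channel labels, a sampling rate and (optionally) unit-sphere electrode
positions. An `Epoch` is a fixed-length slice carrying the factorial
labels of the design: subject, condition (`neutral`/`negative`), task
(`elevator`/`plank`) and the recording segment it came from (`elevator`,
`plank_start`, `plank_end`). The reference study records 32 channels at
1000 Hz in 60-s epochs; the package's default synthetic scale is 16
channels at 250 Hz in 10-s epochs, which preserves every structural
property of the analysis (window counts, band edges, design balance)
at desk-scale runtimes. Full scale is one configuration change.

The fixed parcellation maps the 32 montage labels to five regions
(9 frontal, 4 temporal, 11 central, 5 parietal, 3 occipital). Label
matching is case-insensitive because vendor headers disagree on
spellings such as `FP1`/`Fp1`. Channels outside the map (for example a
recovered reference electrode) are kept for global metrics and excluded
from regional ones.

# Preprocessing

* **Bandpass (default 0.5–40 Hz).** Windowed-sinc (Hamming) linear-phase
  FIR, applied forward with exact group-delay compensation, so the net
  phase is zero. The transition width is
  `min(max(0.25·low, 2 Hz), high/4)`. The high-pass stage is built by
  spectral inversion of a unity-DC low-pass, which pins an exact zero at
  0 Hz even when the transition band straddles DC — a windowed ideal
  bandpass would otherwise leak a substantial fraction of any DC offset
  when the lower edge sits near 0.5 Hz. Signals shorter than three
  kernel lengths are rejected rather than padded.
* **Line noise.** Sliding 4-s Hann windows with 50% overlap-add; within
  each window, sines and cosines at the line frequency and at all
  window-grid frequencies within ±bandwidth/2 are fit by least squares
  and subtracted. This is a regression approach in the CleanLine family:
  a stationary 50 Hz tone is removed essentially completely, while
  content a few hertz away is untouched (the test suite bounds
  collateral distortion at 10 Hz to 5%).
* **Average reference.** Per-sample channel mean subtracted; idempotent,
  column sums exactly zero.
* **Bad channels.** Two detectors, mirroring channel-level automated
  rejection: a flatline criterion (≥ 5 s with successive-sample changes
  below 1e-8 µV) and a correlation criterion (median across 1-s windows
  of the best absolute correlation with any other channel below 0.8).
  Burst-level cleaning (ASR) and ICA are deliberately out of scope: the
  analysis consumes per-epoch connectivity, and channel-level handling
  plus interpolation is the reproducible core.
* **Interpolation.** Perrin-style spherical splines on the unit sphere
  (Legendre series in cos θ, order m = 4, 7 terms, ridge 1e-5), solved
  with the usual constant-offset constraint. Good channels are never
  modified. Standard montage coordinates for the 32 labels are embedded.

# Connectivity

**Pearson.** The absolute sample correlation per channel pair. The
absolute value is taken because the downstream distance transform is the
reciprocal `D = 1/W` ("inversely proportional" read literally), and
negative weights would make path lengths undefined. A zero-variance
channel yields a zero row with a warning instead of an error so that
batch runs survive degenerate epochs.

**wPLI.** The weighted Phase Lag Index over 1–40 Hz from Hann-tapered
Welch cross-spectra (2-s windows, 50% overlap). The package pools the
imaginary parts over *both* the window ensemble and the frequency bins
of the band:

$$\mathrm{wPLI}_{ij} \;=\;
\frac{\bigl|\sum_{k,b}\mathrm{Im}\,S_{ij}(k,b)\bigr|}
     {\sum_{k,b}\bigl|\mathrm{Im}\,S_{ij}(k,b)\bigr|}.$$

Pooling, rather than averaging per-bin indices across the band, is a
deliberate convention: with broadband noise every off-signal bin carries
a well-defined near-zero per-bin index, so a plain bin average would be
bounded near the noise floor no matter how strong a narrowband lagged
coupling is. The pooled form weights each bin by the evidence it
carries, reaches 1 for a noiseless quarter-cycle lag, and stays at the
white-noise floor (≈ 0.01 for 60-s epochs) for independent channels.
Imaginary parts smaller than 1e-12 of the cross-spectral magnitude are
floored to zero, so numerically real cross-spectra — zero-lag coupling,
the volume-conduction signature wPLI is designed to ignore — give
exactly 0. The per-bin kernel remains available as `wpliKernel()`.

**Thresholding.** Proportional: the strongest
`ceiling(keep · n(n−1)/2)` upper-triangle weights become edges of an
unweighted graph (default keep = 0.75; for 32 channels that is exactly
372 of 496 edges). Ties at the cut are resolved by descending weight,
then lexicographic label-pair order, making runs bit-reproducible.

# Graph metrics

* **Efficiency** is the mean inverse shortest-path length over all node
  pairs (Dijkstra on the reciprocal distances, `1/∞ := 0`). Part of the
  EEG literature calls this quantity "local efficiency" when computed per
  region; canonically it is global efficiency of the (sub)graph, and the
  function is named `networkEfficiency` accordingly. Regional efficiency
  uses the region-induced subgraph — paths may not leave the region.
  This is the simplest reading consistent with a per-region analysis;
  reported regional magnitudes in the literature are therefore not
  directly comparable across region sizes, and the package makes no
  attempt to match any particular published regional value.
* **Louvain modularity.** Standard two-phase Louvain (greedy local
  moving, then aggregation) on the binarized network, configuration-null
  Newman Q with resolution 1. The sweep order is shuffled from a seed,
  so results are reproducible and the stochasticity is explicit. The
  returned Q is validated in the tests against exhaustive enumeration of
  all partitions on small graphs (never exceeding the true maximum and
  reaching ≥ 95% of it).
* **Eigenvector centrality.** Power iteration on `A + sI` with
  `s = max row sum`. The spectral shift leaves eigenvectors unchanged
  but guarantees convergence on bipartite-like graphs (a star's plain
  power iteration oscillates between the two eigenvalues ±√n). The
  result is sign-fixed nonnegative and unit-norm; on disconnected
  graphs mass concentrates on the dominant component, which is
  documented rather than hidden. The wPLI matrix feeds centrality, as
  the phase-lag measure already computed in this pipeline.
* **Per-condition modularity** averages per-epoch Q within each design
  cell before the ANOVA.

# Statistics

Both factors have two levels, so each repeated-measures effect is
*exactly* a paired contrast: the main effect of condition is the paired
t-test on subject means across conditions (F = t² on 1, n−1 df), and the
interaction is the paired test on the double difference. This closed
form is identical to the classical within-subject decomposition for a
2×2 design (the tests verify agreement with `aov`'s error strata to
1e-8) and is trivially oracle-checkable. Partial eta squared follows as
`F/(F + df_den)`. Zero-variance contrasts report F = 0, p = 1 rather
than erroring, so degenerate synthetic cells cannot abort a batch.

Normality screening uses the one-sample KS statistic against a normal
with the sample's own moments. Because the parameters are estimated from
the data, the classical KS p-value would be anti-conservative; the
p-value is therefore Monte-Carlo calibrated (Lilliefors-style, seeded,
default 10,000 null draws). Post hocs are paired t-tests with Bonferroni
multiplication; rank correlations are Pearson on mid-ranks with the
t-approximate p on n−2 df. No correction is applied across the many
(scope, metric) ANOVAs by default, mirroring common per-region practice;
`bonferroniAcrossScopes = TRUE` enables it.

# The synthetic generator

Each coupling edge `(i, j, f, φ, s)` adds `amplitude·s·sin(2πft + φ_base)`
to channel i and the same sinusoid shifted by the planted lag φ to
channel j, with a fresh uniform base phase per edge per epoch, plus
independent white Gaussian noise per channel (1/f-shaped noise is
available behind a flag). Lags and strengths are therefore analytically
known, which is the property estimator validation needs; a neural-mass
model would be more realistic but would forfeit exact ground truth.

Two structural choices deserve comment:

* **Per-region carrier frequencies** (frontal 6, temporal 14, central
  10, parietal 19, occipital 24 Hz). Within one epoch each sinusoid's
  phase is constant, so *any* two channels sharing a carrier hold a
  fixed relative phase and look coupled to both estimators. Distinct
  regional carriers keep cross-region pairs incoherent, making planted
  within-region structure identifiable.
* **The integration study.** For modularity experiments the base
  coupling is a two-module (anterior/posterior) structure
  (`anteriorPosteriorCoupling()`), and the negative condition adds
  strong uniform cross-module coupling (`integrationEdges()`). At 75%
  edge retention the thresholded graph is dense, and modularity responds
  to *displacement*: the added cross-module edges outrank within-module
  edges at the proportional cut, so the retained network loses
  segregated structure and Louvain Q drops. Weak or sparse cross-region
  plants do not move Q at this density — an instructive property of
  proportional thresholding itself, and the reason the planted
  integration effect is deliberately strong. Planted deltas throughout
  are calibration knobs for power, not estimates of any real study's
  effect sizes.

Per-subject random intercepts on coupling strength (SD 0.05) induce the
within-subject correlation a repeated-measures analysis assumes.
Strengths pushed outside [0, 1] are clipped and counted. All generation
is bit-reproducible: every epoch derives a 31-bit sub-seed by stable
string hashing of (seed, subject, condition, task), independent of
iteration order.

What the generator does **not** emulate: volume conduction, 1/f
background by default, artifacts (blinks, EMG, motion), non-stationary
phase dynamics. Passing tests therefore demonstrate correctness of the
estimators and statistics under known coupling, not robustness to every
property of real EEG.

# Numerical conventions and edge cases

* wPLI denominator 0 → index 0; relative floor 1e-12 on imaginary parts.
* Distance transform: weights ≤ 1e-6 are treated as disconnected.
* Efficiency of an edgeless (sub)graph is 0; of a complete unit-weight
  graph 1.
* Louvain on an edgeless graph: singleton communities, Q = 0; move
  acceptance requires a gain > 1e-12 to prevent tie cycling.
* Power iteration: tol 1e-10 in max-norm, cap 1000 iterations, error
  (with the count) on non-convergence.
* EDF is written with 16-bit quantization against per-channel physical
  ranges; BrainVision supports INT_16 and IEEE_FLOAT_32 in both sample
  orientations. Unknown physical dimensions are assumed microvolts, the
  EEG convention.
* CSV outputs are sorted on all key columns, use `.` decimals and UTF-8,
  and round-trip at full double precision.

# Problem sizes used by the validation suite

The test suite and the acceptance script run at the reduced synthetic
scale (16 channels, 250 Hz, 10-s epochs): null-calibration of the ANOVA
uses 1000 replicate studies of 20 subjects; directional-recovery checks
use 20 replicate studies of 75 subjects (the reference study's sample
size); estimator fixtures use 60-s two-channel epochs. Oracle
equivalence for graph metrics enumerates all partitions of ≤ 7-node
graphs. These sizes are the package's validation design; larger studies
run through exactly the same code paths.

# Known limitations

* The plank task enters the 2×2 design through a configurable mapping
  (`plank_end` by default; `plank_start` or the mean of both as
  alternatives) because a three-segment recording protocol must be
  collapsed to a two-level task factor and the right collapse is a
  scientific choice, not a software one.
* Regional efficiency magnitudes depend on region size through the
  induced-subgraph definition; compare within a region across
  conditions, not across regions.
* Louvain is a heuristic; the package bounds its behavior on small
  graphs by enumeration but makes no optimality guarantee at 32 nodes.
* The KS screen is descriptive; the ANOVA layer does not gate on it.
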