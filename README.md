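# eegraph

Graph-theoretic analysis of EEG functional connectivity, built for
within-subject factorial designs such as walking under virtual height
threat: does a negative, threatening context reorganize brain networks —
more frontal coupling, less global segregation, shifted network hubs —
relative to a neutral one, across task phases?

The package carries a multichannel EEG study end to end:

1. **I/O** — BrainVision (`.vhdr`/`.vmrk`/`.eeg`, INT_16 and
   IEEE_FLOAT_32, multiplexed and vectorized) and EDF readers/writers;
   a fixed 32-electrode cortical parcellation (frontal, temporal,
   central, parietal, occipital).
2. **Preprocessing** — zero-phase windowed-sinc FIR bandpass (0.5–40 Hz
   default), sliding-window line-noise regression, average reference,
   flatline/low-correlation bad-channel detection, spherical-spline
   interpolation, 60-s epoch segmentation.
3. **Connectivity** — absolute Pearson correlation, and the weighted
   Phase Lag Index over 1–40 Hz from Hann-tapered Welch cross-spectra:

   wPLI_ij = |Σ Im S_ij| / Σ |Im S_ij|,

   with the sums pooled over windows and band bins; reciprocal distance
   transform (D = 1/W); proportional thresholding + binarization
   (top 75% of edges, deterministic tie rule).
4. **Graph metrics** — efficiency E = mean of 1/d_ij over node pairs
   (global and per region-induced subgraph), Louvain community detection
   with Newman modularity Q, eigenvector centrality by shifted power
   iteration, regional aggregation.
5. **Statistics** — 2 (condition: neutral × negative) × 2 (task:
   elevator × plank) fully within-subject ANOVA via exact paired
   contrasts (F = t², df = 1, n−1), partial eta squared
   η²p = F/(F + df_err), Lilliefors-corrected KS normality screening,
   Bonferroni post hocs, Spearman correlations against covariates.
6. **Synthetic studies** — a generator that plants cross-channel
   phase-lag couplings, regional effects and cross-module integration
   with known ground truth, so every stage is testable without access
   to restricted clinical data.

## Worked example

```r
library(eegraph)

# A planted quarter-cycle phase lag at 10 Hz, signal-to-noise 5,
# is recovered by the wPLI estimator:
pair <- plantLagPair(frequency = 10, lag = pi/2, snr = 5,
                     duration = 60, sfreq = 250, seed = 42)
w <- wpliConnectivity(pair)
weightMatrix(w)["A", "B"]
#> 0.988

# A full synthetic null study (12 subjects, 2x2 within-subject design),
# through connectivity, graph metrics and the ANOVA layer:
cfg <- defaultPipelineConfig(
  design = list(nSubjects = 12, epochLength = 10, sfreq = 250),
  seed = 7)
res <- runPipeline(cfg)
subset(res$anova, scope == "frontal" & metric == "efficiency")
#>          effect     F df_num df_den     p eta_p_sq
#>       condition 0.288      1     11 0.602   0.0255
#>            task 2.227      1     11 0.164   0.1684
#>  condition:task 2.010      1     11 0.184   0.1545
```

The frontal-efficiency F ratios are small with p ≫ 0.05, as they should
be for a null study: no condition or task effect was planted, and the
effect sizes (η²p ≈ 0.03–0.17 at n = 12) are what sampling noise alone
produces. `res$metrics` holds the long-format per-cell metric table
(subject × condition × task × scope × metric), `res$normality` the KS
screen (here p = 0.542 for global efficiency — no deviation from
normality), and `res$posthoc` Bonferroni-adjusted simple effects for
significant interactions. With `cfg$outDir` set, all tables are written
as deterministic CSVs plus a JSON run manifest; identical config + seed
gives byte-identical outputs.

A shell entry point wrapping the same function lives at
`inst/scripts/eegraph-pipeline.R`
(`Rscript eegraph-pipeline.R run --config cfg.yaml --out results/`);
`inst/extdata/example_config.yaml` documents the config schema.

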