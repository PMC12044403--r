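# Example eegraph pipeline configuration.
# Synthetic mode: generate a 2 (condition) x 2 (task) within-subject study
# and run the full connectivity -> graph-metric -> ANOVA pipeline on it.
input: synthetic
design:
  nSubjects: 20
  epochLength: 10     # seconds
  sfreq: 250          # Hz
manifest: ~           # for input: files, path to a manifest CSV
preprocess:
  bandpass: ~         # e.g. [0.5, 40] to enable
  lineFreq: ~         # e.g. 50
  averageReference: no
  detectBad: no
connectivity:
  band: [1.0, 40.0]   # wPLI band, Hz
  windowS: 2.0        # Welch window, s
  overlap: 0.5
  keep: 0.75          # proportional threshold
  weightFloor: 1.0e-06
plankMapping: plank_end   # plank_end | plank_start | mean_of_both
bonferroniAcrossScopes: no
covariates: ~         # CSV with column 'subject' + numeric covariates
seed: 1
outDir: ~
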