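# eegms — resting-state EEG microstate analysis and classification

Resting-state EEG decomposes into a sequence of *microstates*: scalp
potential topographies that stay quasi-stable for ~80–120 ms and then
switch abruptly. Their temporal statistics are altered in Alzheimer's
disease (AD), which makes microstate parameters candidate classification
markers. `eegms` is for researchers who want a tested, reproducible R
implementation of that analysis chain:

* **Segmentation.** Global field power
  `GFP_t = sqrt(mean_i (u_i - u_bar)^2)` locates moments of high
  topographic signal-to-noise; the topographies at smoothed-GFP peaks are
  clustered with a polarity-invariant **modified K-means** (assignment by
  squared spatial correlation; template update = dominant eigenvector of
  the assigned maps' outer-product sum), two-level (subject → group), with
  the global explained variance
  `GEV = Σ_t GFP_t² r_t² / Σ_t GFP_t²` as objective and model-quality
  index. Templates are labelled A–D against canonical reference maps and
  **backfitted** sample-by-sample with temporal smoothing.
* **Feature sets.** A 36-dimensional microstate feature vector per epoch
  (duration, occurrence, coverage, mean spatial correlation and GEV share
  per state, plus the 4×4 run-wise transition matrix; the identity
  `duration × occurrence = coverage` holds by construction) and a
  16-dimensional conventional vector (moments, Welch PSD summaries,
  Hjorth parameters, Petrosian fractal dimension, Lempel–Ziv complexity,
  approximate/sample/fuzzy entropy — the `O(N²)` entropy kernels in C++).
* **Classification harness.** SVM (RBF), KNN, random forest and logistic
  regression on either feature set with a stratified 70/30 split,
  accuracy/sensitivity/specificity and rank-based AUC (positive class =
  AD), a five-band (delta–gamma) band-selection experiment, and a paired
  microstate-vs-conventional comparison.
* **Synthetic EEG generator** with planted microstate structure
  (semi-Markov state sequences, configurable transition matrix and SNR,
  polarity flips, planted AD/HC contrast), so every stage is verifiable
  without any external recording. Readers for EDF and a plain CSV
  channel-matrix dialect handle real data.

## Worked example

```r
library(eegms)

# synthetic dataset: 3 subjects per group, 6 five-second epochs each
cfg <- sim_config(n_subjects_per_group = 3, n_epochs_per_subject = 6,
                  seed = 42)
ds  <- simulate_dataset(cfg)
epochs <- unlist(lapply(ds$subjects, `[[`, "epochs"), recursive = FALSE)
subj   <- unlist(lapply(ds$subjects, function(s) rep(s$id, length(s$epochs))))
grp    <- unlist(lapply(ds$subjects, function(s) rep(s$group, length(s$epochs))))

fit <- microstates(epochs, k = 4, fs = 250, subjects = subj, seed = 1)
summary(fit)
#> Microstate model: 4 classes (ABCD), 21 channels
#>   fitted on 36 epochs / 6 subject(s), 144 GFP-peak maps
#>   GEV of peak maps: 0.996; mean backfit GEV: 0.959
#>
#> Temporal dynamics (pooled over training epochs):
#>  state duration_ms occurrence_hz coverage
#>      A         117          2.26    0.264
#>      B         108          2.08    0.224
#>      C         119          2.13    0.254
#>      D         131          1.97    0.258
#>
#> Run-wise transition probabilities:
#>       A     B     C     D
#> A 0.000 0.322 0.353 0.325
#> B 0.373 0.000 0.353 0.274
#> C 0.386 0.293 0.000 0.322
#> D 0.335 0.367 0.298 0.000
```

The GEV line says 99.6% of the GFP-weighted topographic variance at the
peak maps is explained by the four templates, and 95.9% across all
samples after backfitting. The dynamics table recovers the planted
conditions (100 ms mean duration, near-uniform transitions — the pooled
estimates sit a few percent high because sub-12 ms runs are absorbed by
temporal smoothing).

```r
segs  <- predict(fit, epochs)                    # backfit every epoch
feats <- microstate_features(segs, 250, subject_id = subj, group = grp)
round(feats[1:3, c("duration_A", "occurrence_A", "coverage_A",
                   "gev_A", "p_AB")], 3)
#>       duration_A occurrence_A coverage_A gev_A  p_AB
#> HC011      0.069          2.4      0.166 0.150 0.417
#> HC012      0.095          3.0      0.286 0.295 0.400
#> HC013      0.129          1.6      0.206 0.178 0.375
```

From here, `conventional_features()` builds the 16-feature table for the
same epochs, `split_table()` makes the stratified 70/30 split (use
`mode = "subject"` to avoid leakage), and `feature_set_comparison()` runs
the four classifiers on both tables with one shared split.

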