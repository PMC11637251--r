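---
title: "EEG microstate analysis and feature-based classification with eegms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis and feature-based classification with eegms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Resting-state EEG does not wander continuously through topography space:
the scalp potential field stays quasi-stable for roughly 80–120 ms and then
switches abruptly to another configuration. These quasi-stable periods —
*microstates* — are conventionally summarised by four template maps labelled
A–D, and their temporal statistics (how long each state lasts, how often it
occurs, which state follows which) change in neurological disease,
including Alzheimer's disease (AD). `eegms` implements the full analysis
chain: segmentation of multichannel EEG into microstates, extraction of a
36-dimensional microstate feature set and a 16-dimensional conventional
signal-feature set per epoch, and a classifier harness that compares the
two feature sets on the same data.

Segmentation follows the standard two-stage scheme.

1. **Template estimation.** Global field power,
   `GFP_t = sqrt(mean((u_i - mean(u))^2))` over the `N` electrodes, indexes
   the topographic signal-to-noise at each sample. The GFP series is
   smoothed with a Gaussian moving average and the topographies at its
   local maxima are clustered with a *polarity-invariant modified K-means*:
   a map is assigned to the template with the largest squared spatial
   correlation, and each template is updated to the dominant eigenvector of
   the outer-product sum of its assigned maps (the first right singular
   vector of the stacked maps). The objective is the global explained
   variance, `GEV = sum(GFP_t^2 r_t^2) / sum(GFP_t^2)`, which ascends
   monotonically; iteration stops when its relative change falls below a
   tolerance, and the best of several random restarts is kept. With epochs
   from several subjects the clustering is run per subject first and the
   pooled subject templates are clustered again (two-level clustering).

2. **Backfitting.** Every sample of every epoch is assigned to the template
   with the highest absolute spatial correlation — polarity carries no
   information in this framework, because the dipolar generators reverse
   sign within a state. Runs shorter than a minimum duration are treated as
   noise and relabelled sample-by-sample to the better-correlating
   neighbouring state (temporal smoothing).

The estimator is exposed in the classic R modelling idiom: `microstates()`
returns a fitted object with `print`, `summary`, `coef` (the K×N template
matrix), `predict` (backfitting new epochs), `plot` (template
topographies on the 10–20 layout) and `simulate` (a parametric bootstrap
from the fitted templates and dynamics) methods.

```{r}
library(eegms)
cfg <- sim_config(n_subjects_per_group = 4, n_epochs_per_subject = 10)
ds <- simulate_dataset(cfg)
epochs <- unlist(lapply(ds$subjects, `[[`, "epochs"), recursive = FALSE)
subj <- unlist(lapply(ds$subjects, function(s) rep(s$id, length(s$epochs))))
fit <- microstates(epochs, k = 4, fs = 250, subjects = subj, seed = 1)
summary(fit)
```

## Feature sets

**Microstate features (36).** For each of the four states:
mean run duration (s), occurrence (runs/s), coverage (fraction of
samples), mean absolute spatial correlation over the state's samples, and
the state's share of GEV — 20 scalars — plus the full 4×4 run-wise
transition-probability matrix (16 entries, diagonal structurally 0 because
run encoding forbids self-transitions). The three temporal quantities are
linked by the identity `duration × occurrence = coverage`, which the test
suite verifies on every epoch. The 5-scalars-×-4-states + 16-transitions
composition is the only combination of the named parameters that reaches
36 columns; since no column inventory is published for the set, this
composition is an interpretation and is documented as such. Transition
probabilities are computed on run sequences rather than sample-wise:
sample-wise matrices are dominated by diagonal self-loops and the
literature convention is run-wise. A state absent from an epoch reports
zeros (not `NA`) to keep classifier input dense. Boundary runs truncated
by the epoch edges are included in duration averages.

**Conventional features (16).** Per channel, then averaged over channels:
mean, median, RMS, sample SD and variance (the variance doubles as Hjorth
activity, which is why the list has 16 entries rather than 17), mean Welch
power spectral density over 0–Nyquist, spectral flatness
(geometric/arithmetic PSD mean), Hjorth mobility and complexity, skewness
and kurtosis (standardised moments, kurtosis not excess), Petrosian
fractal dimension, Lempel–Ziv complexity (median binarisation, LZ76
exhaustive parsing, normalised by `n/log2(n)`), and approximate, sample
and fuzzy entropy. The entropy kernels are `O(N²)` and implemented in C++;
the test suite checks them to `1e-10` against independent brute-force R
implementations of the defining formulas.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 4 | number of microstate classes; the canonical A–D set. A data-driven K sweep is out of scope. |
| `peak_window` | 50 samples | Gaussian GFP-smoothing width; sigma = window/6. An even width has no centre sample, so the kernel length is rounded up to odd to avoid half-sample peak shifts. |
| `n_init` / `max_iter` / `tol` | 50 / 300 / 1e-6 | modified K-means restarts, iteration cap, relative-GEV stopping threshold. None are dictated by the method; these reach the exhaustive-search optimum on all tested small instances. |
| `min_duration` | 3 samples (12 ms at 250 Hz) | temporal smoothing threshold for backfitting. |
| `m`, `r`, `fuzz_n` | 2, 0.2·SD, 2 | embedding dimension, tolerance and fuzzy exponent for the entropies — the field-standard defaults. ApEn uses the standard `<= r` match test (a strict mode exists as a flag). The published SampEn variant with an unused `q` argument and garbled `B^m` indexing is not guessable; the standard Richman–Moorman definition is implemented. |
| Welch PSD | 1-s Hann segments, 50% overlap | spectral flatness and mean PSD are computed from the same PSD. |
| classifier hyperparameters | SVM-RBF C=1, gamma=1/(p·var); KNN k=5; RF 100 trees; LR ridge lambda=1/n | recorded in every report; none are tuned. Features are z-scored with training statistics only. The positive class is AD. |

Tie-breaking is uniform everywhere: when correlations tie, the lowest
label index wins.

Two ambiguities in the published pipeline are resolved explicitly. The
"Gaussian-weighted" smoothing at 50 points is read as a Gaussian moving
average over the GFP series; a second, independent smoothing stage (the
`min_duration` relabelling) acts on the label sequence, so both readings
of "temporal smoothing" are present with independent parameters. Backfit
correlations are computed on average-referenced raw samples; correlation
is scale-invariant, so GFP-normalising the samples first would change
nothing.

## The synthetic-data generator

Real recordings from the public datasets this method targets cannot ship
with a package, so every stage is validated against synthetic EEG with
*planted* microstate structure. `sim_config()` defaults define the
emulated conditions: 21 channels (standard 10–20 names), 250 Hz, 5-s
epochs, four zero-mean unit-norm template maps, and a semi-Markov label
sequence with geometric run lengths of mean 100 ms — the midpoint of the
classic 80–120 ms range. The geometric (memoryless) law is the simplest
run-length distribution with a controllable mean, which is exactly what
recovery tests need. The sampling rate of the source data is not
published; 250 Hz is an assumption and a config field.

Each sample is `a_t · s_t · template[state_t] + noise`: `a_t > 0` is a
smooth sinusoidal GFP envelope, `s_t` a ±1 square wave (period 0.5 s) that
exists purely so the tests genuinely exercise polarity invariance, and the
noise is spatially white Gaussian (a pink 1/f option exists but is off by
default — nothing in the emulated pipeline depends on noise colour),
scaled to a configured RMS signal-to-noise ratio and average-referenced.
The disease contrast plants a +30% mean duration and a perturbed
transition row by default, mirroring reported AD microstate alterations.
An optional `carrier_band` confines the clean switching signal to one
frequency band, which is how the band-selection experiment constructs data
whose group contrast lives only in the alpha band.

What the generator does **not** emulate: volume conduction from realistic
sources, electrode geometry beyond template labelling, artifacts (ocular,
muscle), non-stationarity across the recording, and 1/f background by
default. Passing tests therefore demonstrate that the algorithms recover
planted structure under controlled noise — not that the pipeline is robust
to everything real EEG contains. Artifact rejection in the ingest module
is correspondingly minimal: the published pipeline removed
artifact-containing segments without stating a criterion, and an optional
peak-to-peak threshold is the package's stand-in.

## Numerical and design choices

* **Filtering** is zero-phase: a 4th-order Butterworth band-pass applied
  forward and backward (8th-order magnitude response) with odd-reflection
  edge padding, so microstate timing is not delayed and 5-s epochs keep
  their in-band amplitude within 5%. Band edges follow the standard
  delta (0.5–4), theta (4–8), alpha (8–13), beta (13–30), gamma
  (30–45 Hz) bank.
* **Degenerate inputs.** A zero-variance sample has no defined spatial
  correlation; it inherits the previous label (leading samples take the
  first valid label). All-flat epochs and all-zero map sets are errors.
  Empty clusters during K-means are re-seeded with the worst-explained
  map. A constant signal returns 0 for the three entropies, Hjorth
  mobility/complexity (with a warning), and `c(n) = 1` for LZ complexity
  by convention.
* **Canonical labelling.** Fitted templates are matched to built-in
  idealised A–D reference maps (two diagonal gradients, an
  occipital–frontal gradient, a fronto-central focal map on the 10–20
  layout) by a hand-written Hungarian assignment maximising total
  absolute correlation; users can supply their own reference. The
  reference only fixes order and sign — it never influences the fit.
* **Splits.** The 70/30 split is stratified by group. Epoch mode
  replicates the published design and is flagged loudly: epochs of one
  subject can land in both train and test, which inflates accuracy.
  Subject mode keeps subjects intact and is the recommended design; both
  are first-class.
* **Group sizes.** The shipped participants table lists 36 disease and 22
  control rows while the accompanying text reports 29/29;
  `summarize_participants()` reports the counts as found and corrects
  nothing silently.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which the statistical checks
are meaningful: template/dynamics recovery uses 10 subjects × 10 five-second
epochs at SNR 5; run-length and transition convergence checks use 200
epochs (>5,000 runs); the feature-set comparison uses 8 subjects × 10
epochs per seed over three seeds, with the group contrast confined to
transition structure (identical run-length law in both groups) so that the
single-channel amplitude statistics the conventional features measure are
matched between groups — under that construction the microstate feature
set dominates the conventional set for all four classifiers, reproducing
the published pattern structurally. Published headline accuracies were
computed on an external clinical dataset and are dataset-dependent; they
are not reproduced numerically here.

## Limitations

* K is fixed by the user; GEV/GMD-curve selection of K is not implemented.
* No source localisation or physiological interpretation of the template
  maps.
* The EDF reader supports the plain 16-bit continuous-recording subset of
  the format (one sampling rate, no annotations, EDF+ extensions ignored).
* Microstate syntax analyses beyond first-order transitions (entropy of
  label sequences, Markov tests, Hurst exponents) are out of scope.
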