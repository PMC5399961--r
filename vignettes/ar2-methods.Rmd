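---
title: "Methods: automatic EMG artifact reduction for ictal scalp EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic EMG artifact reduction for ictal scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ar2eeg)
```

## The problem and the model

Seizure activity above ~16 Hz (beta–gamma ictal rhythms) and scalp-muscle
EMG occupy the same frequency range, so frequency filtering alone cannot
separate them. What does distinguish them is spatial structure: a cortical
generator is seen, through volume conduction, by many electrodes at once
with a smoothly varying amplitude, while a muscle generator projects almost
entirely onto the one or two electrodes over the active muscle. The pipeline
operationalizes exactly that contrast. The signal below 16 Hz is never
touched: it is split off, held aside, and added back at the end, so the
method can only ever change the high band.

The processing chain, with every tunable written as its `ar2_config()` name:

1. **Band-pass 16–70 Hz** (`band_low_hz`, `band_high_hz`, `fir_order = 500`).
   Even-order Hamming windowed-sinc FIR, applied zero-phase by compensating
   the `order/2` group delay with reflection padding. Zero-phase matters
   because step 6 adds bands back together; misaligned bands would smear the
   very transients a reader inspects. When `fs < 156` Hz the upper edge is
   clipped to `0.45 * fs` to keep the design inside Nyquist.
2. **Composite envelope** (`smooth_window_s = 0.5` s). Per channel the
   Hilbert envelope of the band-passed signal is z-scored over the whole
   record — the z-score makes channels with different gains commensurate —
   then averaged across channels and smoothed with a centered moving
   average. A per-channel z-score was chosen over a single global
   normalization because a single hot channel should not dominate the
   composite; the window length is not dictated by the method description
   and 0.5 s is long enough to bridge individual EMG motor-unit bursts while
   staying much shorter than a seizure discharge run.
3. **Artifact epoch** (`envelope_threshold_sd = 1`). The longest run of
   composite samples *strictly* greater than 1 SD; ties break to the
   earliest run, so results are deterministic at boundaries.
4. **Channel screening** (`mi_bins = 16`, `mi_inclusion_threshold = 0.2`).
   Normalized mutual information `I(X;Y)/sqrt(H(X)H(Y))` from equal-width
   joint histograms, computed pairwise over the artifact epoch. Equal-width
   binning over each series' own range makes the estimate invariant to
   affine rescaling, i.e. to electrode gain. A channel is kept iff its
   maximum pairwise NMI is ≥ the threshold (inclusive, again for
   deterministic boundaries). The threshold value is an operating point of
   the screening stage, not a published constant; 0.2 sits well above the
   histogram-estimator bias floor for epochs of a few hundred samples
   (~0.04 at 1,000 samples with 16 bins) and well below the values coherent
   scalp channels produce (≥ 0.4 in simulated scenes). If there is no epoch,
   the epoch is too short for a 16-bin histogram (< `4 * mi_bins` samples),
   or screening would exclude everything, the pipeline falls back to
   processing all channels — a record without a detectable artifact epoch is
   precisely a record where exclusion has no basis.
5. **Trials and ICA** (`trial_s = 120`, `ica_seed`, `ica_tol = 1e-6`,
   `ica_max_iter = 512`, `extended_infomax = FALSE`). The high band of the
   included channels is segmented into consecutive 120-s trials (24,000
   samples at 200 Hz). A final remainder shorter than half a trial is merged
   into the last full trial — a sliver of a few seconds cannot support its
   own decomposition — otherwise it stands alone. Each trial is
   mean-centered, whitened by principal components (directions below 1e-9 of
   total variance are dropped with a warning; exact collinearity therefore
   reduces the component count rather than crashing the run), and rotated by
   natural-gradient Infomax with the logistic nonlinearity: blockwise
   updates `W <- W + lr (block I + (1-2g(U))U') W`, annealing the learning
   rate by 0.98 whenever successive updates turn by more than 60°, stopping
   when the weight-change norm drops below `ica_tol`. Non-convergence at
   `ica_max_iter` is a warning, not an error: the rotation is still a valid
   decomposition, just short of the tolerance, and the flag is recorded
   per-trial in the run report. The sample permutations come from a
   Mersenne-Twister generator seeded with `ica_seed + trial − 1`, so a run
   is bit-reproducible from its report. Extended Infomax (kurtosis-sign
   switching, for sub-Gaussian sources) is available but off by default,
   matching the classic Infomax configuration.
6. **Focality classification** (`focality_threshold_sd = 2`,
   `classify_mode`). Every mixing-matrix column (a component's scalp
   topography) is z-scored across electrodes with the population-SD
   convention (divide by n; fixed so documented closed-form values like the
   one-hot z of 4.243 at 19 electrodes are exact). Focality is the maximum
   **absolute** z — ICA determines columns only up to sign, so a muscle
   component whose column happens to come out negative-peaked must classify
   identically. Two modes:
   * `per_component` (default): each component is tested on its own.
     Chosen as default because it never discards a non-focal component.
   * `variance_prefix`: every component up to and including the *last*
     focal one (in explained-variance order) is discarded, formalizing the
     assumption that myogenic components outrank neurogenic ones in
     variance, with a single boundary between the last myogenic and first
     neurogenic component.
7. **Prune, back-project, reconstitute.** `cleaned = A[, keep] S[keep, ]`
   (plus the removed trial means when anything is kept; pruning everything
   returns exact zeros). Output = low band + cleaned high band for included
   channels; excluded channels pass through as low + original high —
   clinical reviewers expect all traces present, and an excluded channel is
   flagged, not silenced. Trials are concatenated without cross-fade, so
   discontinuities on the order of the removed artifact are possible at
   trial boundaries.

## The synthetic scene and what it does (not) establish

`simulate_scene()` builds scenes that are exact sums of four matrices
(neurogenic + EMG + bad-channel noise + background), so every stage can be
scored against ground truth. The defaults are the package's study
conditions: 19-channel 10–20 montage, 200 Hz, 300 s; a 22 Hz rhythm, 50 µV
peak, over F3 from t = 120 s, with a Gaussian spatial spread of σ = 1.3
head-radius units (max topography z ≈ 1.5 — genuinely distributed); EMG as
20–95 Hz noise bursts, 60 µV, on F7/T3 with weights 1/0.6 (max topography
z ≈ 3.6 — genuinely focal), bursting every 25 s during the seizure, as
seizure-associated muscle activity does; and 8 µV RMS of 1/f background.

Two generator choices deserve emphasis because the method's behavior depends
on them being physiologically right:

* **The rhythm waxes and wanes** (5-s runs at 60% duty). A strictly
  stationary sinusoid is sub-Gaussian and classic Infomax would leave it
  smeared across the Gaussian background subspace; discharge runs make the
  source super-Gaussian (normalized fourth moment ≈ 2.92/duty ≈ 4.9) and
  cleanly separable — which is also what ictal recruiting rhythms actually
  look like.
* **The background is spatially smoothed** (Gaussian kernel, σ = 0.6, rows
  L2-normalized). Fully independent per-channel noise would hand ICA
  nineteen one-hot — maximally focal — components and the pruning rule would
  gut the record; volume conduction makes real background shared between
  neighbors, and the smoothed generator reproduces that.

On the default scene (seed 0) the pipeline prunes the EMG component(s) and
keeps the rhythm: onset-channel retention 0.90, mean EMG-electrode
suppression 11.2 dB (93% of pooled >16 Hz artifact power removed). The
retention ceiling is set by the background the cleaner legitimately keeps:
with a 16.8 µV RMS rhythm over 8 µV RMS background at F3, the attainable
correlation is ≈ 0.90 even for oracle cleaning of the artifact.

What passing these tests does **not** show: the generator has no forward
head model (topographies are parametric, not conducted), no ocular or ECG
artifacts, no electrode drift or salt-bridge artifacts, and EMG is modeled
as band-limited noise under burst envelopes rather than motor-unit trains.
Clinical performance therefore rests on the spatial-contrast assumption
holding in real recordings, not on these tests.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open `[start, end)` throughout; all boundary
  comparisons are documented as strict (envelope threshold) or inclusive
  (channel inclusion, focality), so reruns are exactly reproducible.
* The high band is the exact complement `x − lowpass(x)` rather than an
  independently designed high-pass: reconstitution is then an identity when
  nothing is pruned (verified to ≤ 1e-6 µV end-to-end). The two designs
  differ only inside the filter transition band.
* EDF export uses a symmetric per-channel physical range padded ≥ 1% and
  rounded up to 4 significant digits (so the 8-character ASCII header field
  represents it exactly), with the symmetric digital range ±32767 so 0 µV is
  exactly representable. Round-trip error is ≤ half a quantization step.
  A zero-amplitude channel is written at ±1 µV with a warning.
* Dead channels (zero envelope variance) are dropped from the composite
  envelope with a warning; constant series are a hard error in the MI
  estimator (zero entropy), and the pipeline's screening stage is the caller
  responsible for never feeding it one.
* Sub-trial-length recordings decompose as a single short trial with a
  warning when shorter than the 20·channels² samples Infomax prefers.

## Problem sizes used in the shipped checks

The test suite and acceptance script size their simulations to desk scale:
the full 300-s/19-channel scene for the end-to-end, identity and
determinism checks; 60-s scenes (same generator, same physics) for the
100-repeat channel-screening study; 3×24,000-sample Laplacian mixtures over
10 seeds for ICA recovery; 1,000 random envelopes for the epoch-finder
oracle. These sizes are the package's chosen study conditions and are stated
here so they can be scaled up knowingly.

## Known limitations

Single-reference montage only (no re-referencing is performed); no notch
filtering, resampling, or IIR options; no BDF (24-bit) support; no attempt
to separate ocular or cardiac artifact classes; trial-boundary
discontinuities as noted above. The variance-prefix classification mode is
provided for completeness but the per-component mode is the default
precisely because it is the conservative reading of the focality rule.
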