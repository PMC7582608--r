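---
title: "Methods: HRV and heartprint indices with a paired-CV RBF-SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV and heartprint indices with a paired-CV RBF-SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with an implantable cardioverter-defibrillator (ICD) produce
beat-annotated RR-interval recordings: a sequence of inter-beat intervals in
seconds, each labeled `N` when the terminating beat is of sinus origin or
`V` when it is a premature ventricular complex (PVC). Some recordings end
immediately before a spontaneous ventricular tachycardia or fibrillation
episode ("pre-event"); others are follow-up controls from the same patients.
The question is whether short recordings (~1000 beats, about 15 minutes)
carry enough information to flag an imminent episode.

hrvprint implements the full analysis pipeline: preprocessing, 16 indices
(11 heart-rate-variability indices computed on the sinus-only tachogram and
5 "heartprint" indices describing the PVC pattern), min-max feature scaling,
and a radial-basis-function support vector machine whose index combination
and hyperparameters are chosen by a patient-paired 10-fold cross-validation
with greedy forward selection.

## Preprocessing

* **Truncation.** Every recording is reduced to its final 1000 beats
  (`truncate_last_n()`), so pre-event and control recordings cover
  comparable spans ending at the moment of interest.
* **PVC-free tail.** Recordings whose last beats contain PVCs are suspect:
  those beats may already be the onset of the arrhythmia. `pvc_free_tail()`
  checks the final 10 beats; 10 is a package default — the requirement is
  qualitative ("no PVCs at the end") and the window is configurable.
  Recordings failing the check should be excluded rather than edited.
* **NN-series estimation.** HRV is defined on normal-to-normal (NN)
  intervals only. A PVC contaminates two intervals: the V-labeled coupling
  interval and the interval that ends the compensatory pause.
  `estimate_nn_series()` replaces both with values linearly interpolated
  between the nearest uncontaminated intervals. Linear interpolation is the
  standard simple surrogate for tachogram editing: it is deterministic,
  preserves series length and the local trend, and converges to the
  identity as the PVC rate goes to zero. More elaborate adaptive filters
  exist; they matter mostly at high ectopy rates, where excluding the
  recording is usually the better remedy.

## The 16 indices

Time-domain, from the NN series in ms: `meanNN`, `SDNN` (sample SD),
`RMSSD` (root-mean-square of successive differences), `pNN50` (% of
successive differences strictly greater than 50 ms — the strict inequality
follows the index's definition "differences greater than 50 ms").
`meanNN_lm` and `SDNN_lm` repeat mean and SD on the final 60 s of the
recording (the maximal suffix of intervals fitting in the window), because
autonomic changes immediately before an episode are expected to be most
visible at the end.

Frequency-domain: the NN tachogram is cubic-spline interpolated to a
uniform 3 Hz grid, split into consecutive non-overlapping 5-minute
segments, linearly detrended per segment, and analysed with Welch's
periodogram (Hann window of 300 samples, 50% overlap). `LF` and `HF` are
the one-sided power-density integrals over 0.04–0.15 Hz and 0.15–0.4 Hz in
ms²; `LFnu = 100·LF/(LF+HF)`, `HFnu = 100·HF/(LF+HF)` (so `LFnu+HFnu = 100`
by construction, the usual normalized-unit convention when only the two
bands are retained) and `LF_HF = LF/HF`. Per-recording values are
across-segment means. Design choices a user should know about:

* the segment grid is anchored at the recording *end*, so the most recent
  5-minute blocks are always analysed and any partial segment is dropped at
  the start;
* the boundary bin at 0.15 Hz belongs to HF (the bands share that edge);
* a segment with zero HF power cannot contribute a ratio and is excluded
  from the averages with a warning; if no segment remains (a constant
  tachogram), the spectral indices are `NA`;
* all SDs use the sample (n−1) denominator.

Heartprint, from the annotated series: `PVCs_hour` (count of V beats per
hour of recording), `meanCI`/`SDCI` (mean/SD of coupling intervals — the
duration of each V-labeled interval whose preceding beat is sinus; a V
directly following another V has no defined coupling interval and is
excluded), `NIBmax` (the most frequent number of intervening sinus beats
between consecutive PVCs, ties broken toward the smaller value) and `sNIB`
(the number of times that modal NIB value occurs). Both the modal value and
its count are exposed because the two summaries answer different questions
(what the repeating pattern is vs how dominant it is). With fewer than two
PVCs these pattern statistics are undefined and carried as `NA` — never as
a silent zero — and are imputed with training-set medians before modeling.

## Scaling and the classifier

Each index is mapped to `(x − min)/(max − min)` with minima and ranges
learned from **training rows only** (`fit_minmax()`), so training columns
span exactly [0, 1]. The identical transformation is applied to test data,
which may therefore legitimately fall outside [0, 1]; values are never
clipped, matching how an online detector would behave on unseen extremes.

The classifier is a soft-margin SVM with RBF kernel
`K(x_i, x_j) = exp(−γ‖x_i − x_j‖²)`, `γ > 0`, trained by libsvm (via
e1071). The package treats the cost `C` in its conventional soft-margin
role. Recordings are *ranked* by the signed decision margin — the canonical
ranking score for an SVM — and classified at margin 0, which is the natural
threshold when every fold is balanced by construction.

### Patient-paired folds

One pre-event and one control recording are selected per eligible patient
(uniformly at random when several exist), and patients — never individual
recordings — are distributed across 10 folds. Both recordings of a patient
share a fold, so no patient contributes to both training and validation of
the same split, and every fold has exactly 50% pre-event prevalence.
Imputation medians and the min-max scaler are refit inside every split from
the 9 training folds, so no test-fold information leaks into preprocessing.

### Greedy forward search with grid re-optimization

All C(16,2) = 120 index pairs are scored over the full hyperparameter grid
(cost 0.5–10 in steps of 0.5; γ = 2^e for e = −15, −14.5, …, 3); the best
pair by mean cross-validated AUC is fixed and single indices are added
greedily, re-optimizing (C, γ) at every size. Ties in mean AUC are broken
toward smaller C, then smaller γ (the simplest model), and ties in the
final size selection toward fewer indices. `select_final()` reports both
the size with the best mean AUC and the one with the best mean accuracy.
The final model (`train_final()`) is then fit on *all* recordings, not only
the selected pairs, and evaluated on held-out data with a Hanley–McNeil 95%
CI for AUC and a Wilson 95% CI for accuracy (standard closed-form choices).

## The synthetic cohort generator

Real ICD recordings are not redistributable, so the package ships a
generator that emulates their testable structure:

* sinus tachogram `NN(t) = mean_nn + lf_amp·sin(2π·0.10·t + φ₁) +
  hf_amp·sin(2π·0.30·t + φ₂) + ε`, `ε ~ N(0, sd_noise²)`, with seeded
  random phases — the minimal model with controllable LF/HF content
  (autoregressive or integral-pulse-frequency-modulation models add realism
  the extraction contracts do not need);
* PVCs inserted as a run of events separated by NIB gaps drawn from a
  categorical `nib_weights` distribution, the count set by
  `pvc_rate × duration`; each PVC replaces a scheduled beat with a coupling
  interval from a truncated normal (`ci_mean`, `ci_sd`, bounds
  0.2–0.95 × `mean_nn` to exclude non-physical values) followed by a fully
  compensatory pause `2·NN − CI`, the textbook PVC timing, which also keeps
  total duration — and hence `meanNN` — unbiased;
* the last 10 beats are kept PVC-free so generated recordings always pass
  the tail check.

The paired templates `preset_pre_event()` / `preset_control()` encode the
expected contrasts: pre-event recordings have shorter `mean_nn` (676 vs
787 ms), more PVCs (159 vs 71 per hour), shorter `ci_mean` (520 vs 575 ms)
and a larger LF/HF (amplitudes 25/12 vs 20/15 ms, chosen so the extracted
ratios land near 3 vs 1.5); noise SDs of 13/14 ms put RMSSD in the high
teens of ms, typical for this population. `generate_cohort()` applies one
shared log-normal multiplier set (SD 0.1) per patient to both templates, so
between-patient variability is larger than the within-patient effect noise
and the pairing is informative.

What the generator does **not** emulate: circadian and posture
nonstationarity, respiratory sinus arrhythmia coupled to a variable
breathing rate, multiform PVCs, atrial ectopy or artefact labels, and any
genuine pre-arrhythmic dynamics. Passing tests therefore demonstrate that
the pipeline recovers *planted* structure and stays at chance when none is
planted — not that classifier performance transfers to real
device data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant tachograms yield `NA`
spectral indices; constant training columns scale to 0 with a warning;
recordings shorter than one 5-minute segment, or with fewer than 2 sinus
intervals, raise errors rather than silently degrade. All randomized steps
(generator, pair selection, fold shuffling) take explicit seeds and restore
the caller's RNG state.

The test and acceptance workloads use cohorts of 20 patients (40
recordings of 1000 beats), a reduced 5 × 7 hyperparameter grid for the
end-to-end searches, 20-seed replications for parameter-recovery and
null-calibration checks, and 1000-case fuzz loops for the brute-force
oracle comparisons — sizes at which the full pipeline, including the
combinatorial pair stage of the greedy search, runs in a few minutes while
keeping the statistical checks well-powered. The full default grid (20
costs × 37 gammas) remains the default for `greedy_search()`.

## Known limitations

* AUC on 4-recording validation folds is granular (steps of 0.25), so
  across-fold SDs are large by construction; interpret them as spread, not
  as standard errors.
* The NN-replacement estimator is intentionally simple; at very high PVC
  burdens (>20% of beats) interpolated segments dominate the tachogram and
  the spectral indices mostly reflect the interpolant.
* `sNIB` and `NIBmax` are deterministic summaries of a possibly flat NIB
  histogram; with few PVCs both are noisy, which is why sparse-PVC
  recordings are imputed rather than scored.
* Min-max scaling is sensitive to single extreme training values; that is
  inherent to the min-max design, which the package keeps rather
  than improves.
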