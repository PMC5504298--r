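---
title: "Personalized detection of pedaling intent from EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized detection of pedaling intent from EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedalbci)
```

## The problem

A brain–computer interface (BCI) for lower-limb rehabilitation must notice
that a person *intends* to start pedaling before (or just as) the movement
begins, from scalp EEG alone, and must do so causally — using only samples
already recorded. The physiological handle is event-related
desynchronization/synchronization (ERD/ERS): band power in the mu (8–12 Hz)
and beta (13–30 Hz) rhythms over sensorimotor cortex drops roughly 2 s before
a self-initiated movement and rebounds about 2 s after onset. Which channels
and which band carry that signature varies markedly between people, which is
why this package treats the *choice* of feature algorithm and electrode
subset as part of the model and selects both per subject.

`pedalbci` implements the full pipeline: a documented session format with a
synthetic-session generator, IMU-based movement-onset labelling, per-epoch
preprocessing, five spectral feature algorithms, an RBF-kernel SVM classifier
evaluated offline and pseudo-online, the weighted-discriminator (WD) metric,
and the WD-driven selection procedures.

## The session protocol and data model

A session is 16 trials of 5 pedaling cycles. Each cycle is about 10 s of
rest, a verbal cue, a volitional wait of at least 3 s (cycles violating the
wait are discarded), then roughly 5 s of pedaling. EEG is 32 channels
(10-10 system) at 500 Hz in µV; movement ground truth comes from two
gyroscopes per leg (20 Hz, deg/s). The "real start" of a cycle is the first
IMU sample at or after the cue where the rectified two-sensor average of
*both* legs exceeds a threshold (default 10 deg/s — the threshold is a free
parameter of the original procedure; 10 deg/s sits well above our simulated
rest noise of ~1 deg/s and well below pedaling amplitudes of ~50 deg/s).
Onset resolution is deliberately limited to the 20 Hz IMU grid.

All times are seconds from session start and every interval is half-open
`[t0, t1)`, so epoch counting has no boundary ambiguity. Sessions are stored
as a directory of TSV files plus `meta.json`; EDF import is provided as a
convenience (`read_edf_eeg()`).

## Class windows, epochs

Around each onset two labelled windows are built: with **4 s** processing
windows the *start* class spans `[onset − 2, onset + 2)` and with **2 s**
windows `[onset − 2, onset)`; the *rest* window has the same duration and
precedes the start window with a 0.5 s gap. Windows and continuous test
streams are cut into 1 s epochs stepped by 200 ms, giving 16 epochs per 4 s
window and 6 per 2 s window. Epoch boundaries snap to the 2 ms sample grid,
rounding down, so counts follow `floor((L − 1)/0.2) + 1` exactly.

## Preprocessing

Each epoch is processed independently: a 50 Hz notch, a 4th-order Butterworth
high-pass at 0.2 Hz (DC/drift removal), then a common average reference
(CAR) subtracting the instantaneous 32-channel mean. Both IIR filters are
applied forward–backward (zero phase) so the ERD timing is not shifted; the
implementation extends the epoch by an odd-symmetric reflection with
steady-state initial conditions, which makes constant inputs transient-free.

Numerical choices worth stating:

* The notch is an RBJ-cookbook biquad. Its quality factor defaults to
  **Q = 10** rather than a sharper Q = 30: a Q = 30 notch rings at 50 Hz for
  ~0.4 s, and within a single 1 s epoch that ringing caps the measurable
  suppression near 18 dB. Q = 10 achieves ≥ 25 dB worst-case within the
  epoch while leaving 30 Hz (the top of the beta band) at gain 0.991.
* CAR always uses all 32 recorded channels, regardless of the electrode
  configuration selected later; channel selection follows preprocessing.
* Internally, batched evaluation applies CAR *before* filtering and then
  filters only the channels the evaluation grid needs. Because CAR is a
  fixed channel-mixing matrix and the per-channel filters are identical and
  linear, the two orders are numerically equivalent (a regression test
  asserts this); it merely avoids filtering channels that are never used.

## Feature algorithms

All features are per-electrode functions of the epoch spectrum, estimated by
the periodogram of the 1 s epoch (native 1 Hz resolution); algorithm D uses
a 0.5 Hz grid obtained by zero-padding the epoch to 2 s:

* **A** — mean power spectral density over 18–28 Hz (1/electrode);
* **B** — Euclidean norm of the 0–50 Hz amplitude spectrum (51 bins at 1 Hz;
  the 0 Hz bin is retained — it is ~0 after the high-pass) (1/electrode);
* **C** — mean PSD of 1–4, 8–12 and 13–28 Hz (3/electrode);
* **D** — mean PSD within ±1 Hz of the electrode's *optimal frequency*
  (1/electrode). At training time the class-mean PSDs on the 8–28 Hz, 0.5 Hz
  grid (41 candidates) are normalised to unit sum per class and the
  frequency with the largest absolute difference is kept, ties resolving to
  the lowest frequency. The normalisation is applied to the class-*mean*
  spectrum (the description "separated and normalized" is ambiguous; the
  class-mean reading is the stabler estimator). The optimal frequencies are
  part of the trained model and are refit inside every cross-validation
  fold;
* **E** — summed 1 Hz amplitude spectrum over mu [8, 12], low beta (12, 24]
  and high beta (24, 30] (3/electrode; shared edges are assigned to the
  lower band).

## Electrode configurations

Eight channel subsets over sensorimotor cortex are studied (full
motor+premotor, motor only, premotor only, left / right variants with and
without medial extensions, and a reduced five-electrode set). The exact
memberships ship as an editable `montages.tsv`; the defaults have sizes
9, 5, 4, 4, 6, 4, 6, 5 and laterality consistent with every selection
outcome in the bundled reference tables. Users with their own layouts can
substitute the file.

## Classification and evaluation

Features are z-scored with training-set statistics and fed to an RBF-kernel
SVM (`e1071`, cost 1, `gamma = 1/(n_features × var)` of the standardised
matrix — hyperparameters the original procedure leaves open; these are the
common library defaults and are stored in the model).

**Offline**: leave-one-trial-out cross-validation (15 train / 1 test,
16 folds). Held-out epoch predictions are grouped per class window and
reduced by majority vote, ties voting 0 (rest). A start window voted 1 is a
true detection; a rest window voted 1 a false detection. TPR, FP/min and Acc
are computed per fold and averaged; offline rest time is the summed duration
of rest-window decisions, which makes the offline FPR the fraction of rest
windows misclassified.

**Pseudo-online**: the first 10 trials train, the last 6 test. Every 200 ms
epoch of each test cycle is classified in temporal order; a detection fires
after 5 consecutive positive predictions (1 s at the 200 ms shift),
timestamped at the end of the fifth epoch. The queue then disarms until a
negative prediction rearms it, so one sustained activation produces exactly
one detection (the original description does not say whether the queue
rearms; disarming prevents a single long activation from inflating the
detection count). A detection inside the cycle's start
class window is true (counted once per window); all others are false
positives. Rest time is the test duration minus the start windows. Metrics
are per test trial and averaged.

## The weighted discriminator and model selection

WD = 0.4·TPR + 0.6·Acc − FPR, with TPR and Acc as fractions and
FPR = (FP/min) × (duration of one false positive in minutes): the window
length (2 or 4 s) offline, 1 s pseudo-online. WD lives in [−1, 1]. Acc with
zero total detections is defined as 0 (the ratio is 0/0 there; the
conservative convention penalises silent models).

Per-subject selection: (1) keep the two algorithms with the highest
configuration-averaged WD; (2) preselect the maximum WD among their 16 cells
together with every cell within 0.01 of it (on unrounded values); (3) pick
the fewest-electrode preselected cell, break ties by WD, and remaining ties
uniformly at random with an explicitly seeded generator recorded in the
audit trail. Uniform (subject-independent) selection averages WD across
subjects — first per algorithm (after configuration-averaging), then per
configuration given the chosen algorithm.

Paired comparisons of per-trial WD samples use the two-sided Wilcoxon
signed-rank test: zero differences dropped, the exact null distribution (a
convolution over signed midranks, valid under ties) up to n = 25, a
tie-corrected normal approximation above, and p = 1 when no differences
remain.

## The synthetic cohort

No recordings are distributed with the original study, so the generator is a
first-class module. Each synthetic subject is: 1/f-like background noise
(a Kellet-style pinking cascade, σ = 10 µV), per-channel mu (10 Hz) and beta
(20 Hz) oscillators (10 µV) with random phase and a slowly varying envelope
(AR(1), ~1 s autocorrelation, ±30 %), a common 50 Hz line component (2 µV),
and the subject's ERD/ERS signature: on the affected channels the oscillator
in the affected band is scaled by `1 − erd_depth` from 2 s before onset to
onset and by `1 + ers_gain` for 2 s after onset. Waits are drawn uniformly
from [3, 4.5] s (the protocol only bounds them below) and pedaling bouts
from [4.5, 5.5] s ("about 5 s"). IMU traces are ~1 deg/s noise at rest and
50 deg/s, 1 Hz oscillations while pedaling. A single master seed drives
everything; cohorts rotate through archetypes (left/right motor × mu/beta,
plus midline) so that different montages are genuinely optimal for
different subjects.

Default `erd_depth` is 0.5 — a moderate, realistic single-trial attenuation;
the study the package mirrors does not quantify its subjects' ERD depths, so
this is a free parameter, not a calibrated one. What the generator does
*not* model: volume conduction, ocular/muscle artifacts, electrode drift,
the Bereitschaftspotential, or non-stationary rhythm frequency. Passing the
synthetic recovery tests therefore demonstrates that the pipeline's
machinery is correct and sensitive, not that real-EEG performance would
match.

## Problem sizes used by the test-suite

The stochastic checks run at sizes chosen to keep a full suite run
desk-scale: unit tests use 4-trial × 2-cycle sessions with the protocol's
timing intact; the high-SNR recovery check runs 5 seeds of a full 16-trial
subject (`erd_depth` 0.7, matched montage, algorithm D, 2 s windows — the
generator's ERD is strictly pre-onset, which is exactly what the 2 s window
isolates); the personalization check runs 10 cohort seeds × 5 subjects ×
full 16-trial sessions over an A/D × {1, 2, 4, 6} grid, comparing
personalized against uniform-algorithm+configuration models on 30 paired
per-trial WD values per seed. With 4 s windows the synthetic start class is
bimodal (deep ERD followed by strong ERS), which the RBF-SVM separates less
cleanly; both window types remain available throughout the API.

## Known limitations

* The synthetic generator's simplifications above; in particular the
  perfectly common 50 Hz line component is removed exactly by CAR, which is
  kinder than real line noise with channel-dependent amplitude.
* Per-epoch zero-phase filtering accepts edge transients within each epoch
  rather than filtering continuously across a cycle.
* The bundled montage memberships are a documented reconstruction consistent
  with the reference tables' selection outcomes, not a measured cap layout.
* Offline and pseudo-online WD values are not comparable with each other
  (their FPR definitions differ); comparisons are only meaningful within an
  analysis mode.
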