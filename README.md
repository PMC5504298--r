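# pedalbci

Personalized brain–computer-interface (BCI) models for detecting
self-initiated **pedaling intent** from multichannel EEG.

Movement intention shows up in scalp EEG as event-related
desynchronization/synchronization (ERD/ERS): mu (8–12 Hz) and beta
(13–30 Hz) band power over sensorimotor cortex drops ~2 s before a
self-paced movement and rebounds ~2 s after onset. Where (which electrodes)
and in which band this happens is strongly subject-dependent. `pedalbci`
therefore treats the feature-extraction algorithm and the electrode subset
as part of the model and selects both per subject, using a composite metric,
the **weighted discriminator**

```
WD = 0.4·TPR + 0.6·Acc − FPR,     FPR = (FP/min) × (duration of one FP in minutes)
```

with TPR and Acc as fractions, so WD ∈ [−1, 1]. The FP duration is the
processing-window length (2 or 4 s) for offline analysis and 1 s for
pseudo-online analysis.

The package implements the complete pipeline for a cue-paced pedaling
protocol (16 trials × 5 cycles; ~10 s rest, cue, ≥3 s volitional wait, ~5 s
pedaling):

* **Session data model and IO** — TSV directory format, EDF import,
  validation (`bci_session()`, `read_session()`, `read_edf_eeg()`);
* **Synthetic sessions** — protocol-faithful EEG/IMU generator with
  per-subject ERD/ERS heterogeneity (`generate_session()`,
  `generate_cohort()`);
* **Movement-onset detection** from per-leg averaged gyroscope traces
  (`detect_real_starts()`);
* **Windowing and preprocessing** — rest/start class windows, 1 s epochs at
  200 ms shift; 50 Hz notch, 0.2 Hz Butterworth high-pass, common average
  reference, all zero-phase per epoch (`build_class_windows()`,
  `slice_epochs()`, `preprocess_epoch()`);
* **Five spectral feature algorithms** A–E, including algorithm D's
  per-electrode optimal-frequency fit (`extract_features()`,
  `fit_optimal_frequencies()`);
* **Classification** — RBF-kernel SVM; offline leave-one-trial-out CV with
  per-window majority voting, and pseudo-online causal evaluation with a
  5-consecutive-detections voting queue (`evaluate_offline()`,
  `evaluate_pseudo_online()`, `evaluate_grid()`);
* **Metrics and model selection** — TPR, FP/min, Acc, FPR, WD; personalized
  and uniform selection procedures and the paired Wilcoxon signed-rank
  comparison (`compute_wd()`, `select_personalized()`,
  `compare_paired_wd()`).

A reference five-subject study's result tables (WD grids and best-model
metrics) ship as plain-text data (`reference_wd_offline()`,
`reference_best_models()`, …) and serve as fixed inputs for the WD
arithmetic and the selection procedures.

## Worked example

Simulate a high-SNR subject (left-motor mu ERD, depth 0.7), label onsets
from the IMU, and evaluate algorithm D on the matching left electrode
configuration pseudo-online with 2 s windows:

```r
library(pedalbci)

params <- synth_params(subject_profile(erd_depth = 0.7),
                       protocol = default_protocol(n_trials = 4,
                                                   cycles_per_trial = 2),
                       seed = 42)
ses <- generate_session(params)
ses$events <- detect_real_starts(ses$imu, ses$events)

r <- evaluate_pseudo_online(ses, "D", 4, "2s", train_trials = 1:3)
as_result_row(r$result)
#>   tpr_pct fp_per_min acc_pct fpr wd
#> 1     100          0     100   0  1
```

Every pedaling intention in the held-out trial is detected (TPR 100%), with
no false alarms during rest (FP/min 0, Acc 100%), giving the maximal WD
of 1.

Model selection on a bundled reference WD grid (subject 1, offline, 4 s
windows) reproduces the study's published choice:

```r
select_personalized(reference_wd_offline("4s")[["1"]])
#> <selection_result> algorithm D, configuration 4 (WD 0.68)
```

A full synthetic study (simulate → detect onsets → evaluate a grid → select
→ report) is one call, `run_full_study(out_dir)`, or one shell command via
the bundled CLI (`inst/cli/pedalbci`), with subcommands `simulate`,
`detect-onsets`, `evaluate`, `select`, `compare` and `run-study`.

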