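---
title: "Screening obstructive hypertrophic cardiomyopathy from wrist PPG:
  models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening oHCM from wrist PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Obstructive hypertrophic cardiomyopathy (oHCM) narrows the left
ventricular outflow tract, which reshapes the arterial pulse: a brisk
early systolic spike, a mid-systolic pressure dip followed by a late
"dome" (the classic spike-and-dome pulse), a prolonged systolic ejection
time, and pronounced beat-to-beat lability including with respiration.
These hemodynamic signatures survive, in attenuated form, in the
photoplethysmographic (PPG) blood-volume waveform at the wrist. The
package implements a complete screening pipeline on that idea: segment a
resting wrist PPG recording into beats, summarize each beat with a fixed
42-feature morphometric vector, and classify the recording as a whole
with a multiple-instance learner so that informative-but-intermittent
beat morphology is not averaged away.

Because no patient recordings ship with the package, the first module is
a seeded synthetic cohort generator whose ground truth (every beat onset
and landmark time) doubles as the oracle for the segmentation and
morphometry tests.

## The synthetic beat and cohort model

A single pulse is a sum of three smooth unimodal (Gaussian) components:
a systolic wave, an optional mid-systolic bump, and a dicrotic/diastolic
wave. The dicrotic component is not parameterized directly; its
amplitude, centre and width are solved in closed form so that the
resulting waveform has

* a true local minimum exactly at `notch_time`, at height
  `notch_ratio` x peak, and
* a diastolic crest at `diastolic_peak_ratio` x peak,

with both ratios taken against the *realized* peak (a short fixed-point
handles component overlap). Landmarks are therefore analytic: when a
test asks whether the detector found the notch within two samples, the
reference is exact, not itself the output of a peak picker.

A recording strings beats together with per-subject heart rate drawn
from the cohort's Normal(mean, SD), 3% multiplicative inter-beat-interval
jitter, per-beat multiplicative shape jitter (`beat_to_beat_cv`),
sinusoidal respiratory amplitude and baseline modulation, occasional
"irregular" beats whose shape parameters are redrawn from a 3.5x-widened
jitter distribution (all simulated subjects remain in sinus rhythm — the
irregularity is morphological, not rhythmic), and additive white sensor
noise. When jittered parameters make the dicrotic solve infeasible the
generator falls back deterministically to progressively tamer shapes,
ending at the class mean.

The packaged `paper_regime.yaml` fixes the two study arms: 64 healthy
subjects (heart rate 59 +/- 9 bpm) and 19 oHCM subjects (72 +/- 11 bpm),
1–5 recordings each, 5 minutes at 64 Hz. The oHCM class mean has a
shorter crest time (0.13 vs 0.18 s, the steeper systolic rise), a longer
systolic ejection time (notch at 0.38 vs 0.33 s), a mid-systolic bump
(relative amplitude 0.45 vs none, which yields a third prominent peak),
lower notch/diastolic ratios (0.40/0.50 vs 0.60/0.72), three times the
beat-to-beat shape variability, stronger respiratory amplitude
modulation (0.22 vs 0.08) and more irregular beats (10% vs 2%). These
class deltas were calibrated once, before the benchmark was frozen, so
that the synthetic cohorts reproduce the operating characteristics the
pipeline is meant to demonstrate; they are not re-tuned afterwards. The
sensor itself is generic (sampling rate configurable 25–250 Hz, default
64 Hz; no wavelength or firmware model).

What the generator does **not** emulate: motion artifacts, venous or
ambient-light interference, arrhythmia, age- or drug-related waveform
change, sensor saturation. Green tests on this benchmark demonstrate
that the pipeline recovers the class structure it encodes — they do not
demonstrate clinical performance on real wrist recordings.

## Segmentation

`preprocess()` applies a zero-phase 2nd-order Butterworth band-pass,
0.5–8 Hz, which removes baseline wander (>= 20 dB at 0.2 Hz) while
passing the pulse band within 1 dB. Because the dome/notch/diastolic
detail of a spike-and-dome pulse sits near or above 8 Hz, the recording
carries a companion 0.5–16 Hz channel used only for fine notch
localization and peak counting; all amplitudes, slopes and areas come
from the 0.5–8 Hz signal.

Beat detection prices candidate upstrokes permissively (15% of the 95th
percentile of positive slopes — a relative threshold, hence
gain-invariant) and then validates each candidate by its foot-to-apex
rise; this rise gate is what rejects dicrotic rebounds and dome
upstrokes, which can be nearly as steep as a small beat's systolic rise
but carry far less amplitude. A 0.33 s refractory period (heart rates up
to ~180 bpm) resolves clashes in favour of the larger rise. The foot is
located by walking back from the slope peak to the last sample whose
slope has decayed to 4% of the peak slope: at a clean foot this is the
cycle minimum, and it also handles feet that are slope elbows rather
than minima (filtered diastolic runoff can rise slowly into the next
upstroke, leaving no local minimum to find).

The dicrotic notch is found structurally: the diastolic wave is the last
local maximum after the systolic peak with prominence >= 3% of beat
amplitude (within the first 65% of the post-peak window), and the notch
is the minimum between the preceding prominent maximum and it. A naive
"deepest minimum" rule would land on the mid-systolic dip of
spike-and-dome beats. If no diastolic wave qualifies, the first local
maximum of the second derivative after the peak serves as fallback, and
failing that the notch is absent (notch-dependent features are then
imputed).

Beat qualification keeps a beat when its inter-beat interval lies in
[0.33, 2.0] s, its amplitude within [0.25, 4] x the recording median,
and its correlation with the recording's resampled median-beat template
is at least 0.5. The correlation gate is deliberately loose: irregularly
shaped beats are part of the oHCM signature and must reach the
classifier. All thresholds are config-exposed; none are published
values.

On noise-free regime cohorts the detector recovers >= 99% of interior
ground-truth onsets within 2 samples (boundary beats sit inside the
filter's edge transient and are excluded from this accounting).

## The 42-feature catalog

`feature_catalog()` freezes the identities: timing (F01–F08, including
crest time and systolic ejection time), amplitude ratios (F09–F14),
slopes (F15–F20, including maximum and mean systolic slope), widths at
25/50/75% height (F21–F25), areas (F26–F29), the a–e waves of the
second derivative with the aging index (F30–F35), shape statistics
including the >= 5%-prominence peak count (F36–F38), and beat-context /
respiratory-variation features over a centred +/-5-beat window
(F39–F42). Amplitudes are taken after per-beat foot subtraction;
amplitude-normalized features divide by the pulse amplitude. Absent
landmarks mark the dependent features invalid; invalid entries are
mean-imputed per recording (zero if a feature is invalid in every
beat). The catalog version (`ppgmiles-42-v1`) is written into serialized
models; changing the catalog is a breaking change.

Scaling behaviour is tested explicitly: only F09, F15–F18 and F30 scale
with signal gain (the catalog's absolute-amplitude and absolute-slope
entries); everything else is gain-invariant. Under uniform time dilation
by k, second-valued features scale by k, rate- and slope-valued features
by 1/k, ratios not at all.

## Group statistics

The statistical unit is the subject: each subject is summarized by the
median of each feature over all qualified beats of all their recordings,
which avoids pseudo-replication from hundreds of highly dependent beats.
Groups are compared per feature with a two-sided Mann–Whitney test —
exact by complete enumeration of label assignments when both groups have
at most 8 subjects (valid under ties), the tie-corrected normal
approximation otherwise — with Cliff's delta as the effect size and
Bonferroni correction over exactly 42 tests at 0.05. The exact branch is
hand-rolled (and tested against exhaustive enumeration) because the
stock implementation cannot enumerate exactly in the presence of ties;
the approximate branch is tested against `wilcox.test`. On the frozen
benchmark, 39 of 42 features separate the cohorts after correction; the
features that do not (mean diastolic slope, an area-duration ratio, and
the IBI-deviation median, whose subject-level median is near zero by
construction) play the role of the non-significant remainder in the
volcano display.

## MILES classification

Each recording is a bag of beat-feature instances. The concept pool is
drawn from training beats (all of them up to `pool_cap` = 2000,
otherwise a seeded label-stratified subsample with equal per-class
allocation), with per-feature z-standardization fit on training beats
only. A bag embeds as the vector of maximum Gaussian similarities
max_j exp(-||x_j - c_k||^2 / sigma^2) — computed via per-concept minimum
squared distances, which makes the embedding reusable across the sigma
grid. The decision stage is a 1-norm SVM: minimize mean hinge loss plus
lambda ||w||_1. This is a linear program, solved exactly by a dense
revised simplex written for this package (the all-slack starting basis
is feasible, so no phase 1 is needed; Dantzig pricing with a Bland
fallback guards against stalling; warm starts along the lambda path cut
the tuning cost about threefold). Exactness matters: refits are
bit-deterministic, and the solver is validated against a brute-force
grid oracle and, during development, an independent LP solver to 1e-10.

Hyperparameters are tuned by 68 seeded random subject-level splits with
70% of subjects on the training side. The published split direction
("70% testing/30% training") reads as a transposition; the train
fraction is a config switch (`inner_train_frac`), so the literal reading
is one line away. The grid is sigma in {2, 4, 8} standardized units and
lambda in {0.01, 0.1, 1}; selection maximizes mean inner AUC with ties
going to the smallest sigma, then the largest lambda. For tractability
the candidate pool is built once per training set and each inner split
embeds against the concepts originating from its training bags, capped
at `tuning_pool_cap` = 120 (the final model always uses the full pool).
The split-level pool-membership restriction keeps inner-test instances
out of the inner pool; standardization is fit once on the full training
set, a deliberate economy that never touches the outer held-out subject.

## Evaluation

Leave-one-subject-out: one fold per subject, with tuning, pool
construction and fitting repeated from scratch inside each fold, so no
recording of the held-out subject influences its own score. Pooled
out-of-fold scores give the recording-level ROC; subject-level scores
(the mean over the subject's recordings) give the headline C-statistic,
its subject-stratified percentile bootstrap CI (2000 resamples), and the
Youden operating point (the cut maximizing sensitivity + specificity;
ties resolve to higher specificity, then the higher threshold; midpoints
between adjacent distinct scores are the candidate cuts). Confusion
counts are per subject. The oHCM score is a margin, not a probability;
no calibration is attempted.

Two regime-level controls bracket the pipeline: on the frozen benchmark
the subject-level C-statistic must reach 0.99 with >= 18/19 patients and
>= 63/64 controls correct, and on the packaged `null_regime.yaml`
(identical class generators, 60 s recordings, small cohorts and a
lighter tuning budget — type-I control does not need the full grid) the
mean C-statistic over ten seeds must stay in [0.4, 0.6] with on average
at most 3 of 42 features significant.

## Numerical choices and problem sizes

* LP solver tolerance 1e-9 on reduced costs; objective agreement across
  warm starts and column permutations is asserted at 1e-6.
* The embedding stores minimum squared distances, never the
  instances-by-concepts distance tensor; memory stays at
  bags x pool.
* Exact Mann–Whitney enumeration is capped at 8 subjects per group
  (choose(16, 8) = 12870 assignments).
* Benchmark problem sizes: 83 subjects, ~250 recordings, ~74k qualified
  beats; the full LOGO evaluation with nested tuning runs in roughly a
  quarter hour on one core. The test suite uses 60–120 s recordings for
  module-level checks and reserves the 5-minute cohort for the
  acceptance run.
* Degenerate inputs: flat or near-flat recordings, recordings under
  30 s, fewer than 10 detected or qualified beats, and single-class
  training sets all fail fast with typed errors; tuning falls back to
  the grid midpoint (with a warning) when a cohort is too small to form
  two-class inner test sides.

## Known limitations

The synthetic benchmark is a closed world: its class separation is
encoded by the generator, so benchmark performance certifies the
pipeline's mechanics (segmentation fidelity, feature correctness,
leakage-free evaluation), not clinical accuracy. Beat morphology is a
Gaussian-component idealization; real wrist PPG carries motion and
perfusion artifacts the qualification gates here only crudely mimic.
The feature identities are this package's own fixed catalog of standard
PPG morphometry; no claim is made that they coincide with any particular
deployed system's 42. Finally, leave-one-subject-out evaluation on 83
subjects has wide confidence intervals, and pooling margin scores across
folds assumes fold-to-fold scale stability — reasonable when tuning
selects the same hyperparameters in almost every fold, as it does on the
benchmark, but worth re-checking on any new regime.
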