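# Benchmark regime: two-class synthetic wrist-PPG cohort with class
# separation in the directions reported for obstructive HCM -- shorter
# crest time (steeper systolic rise), longer systolic ejection time,
# a mid-systolic bump producing multiple peaks of variable intensity,
# and larger beat-to-beat / respiratory variability. Frozen; changing any
# value changes the benchmark.
name: paper_regime
seed: 20260928
synth:
  healthy:
    n_subjects: 64
    hr_mean: 59
    hr_sd: 9
    recordings_per_subject: [1, 5]
    recording_duration: 300
    sampling_rate: 64
    beat_to_beat_cv: 0.04
    ibi_cv: 0.03
    resp_rate: 0.25
    resp_amplitude_mod: 0.08
    resp_baseline_mod: 0.03
    irregular_beat_prob: 0.02
    noise_sd: 0.02
    beat_shape:
      crest_time: 0.18
      notch_time: 0.33
      pulse_amplitude: 1.0
      notch_ratio: 0.60
      diastolic_peak_ratio: 0.72
      mid_systolic_bump_amplitude: 0.0
      component_widths: {systolic: 0.075, bump: 0.045}
      bump_position: 0.7
  ohcm:
    n_subjects: 19
    hr_mean: 72
    hr_sd: 11
    recordings_per_subject: [1, 5]
    recording_duration: 300
    sampling_rate: 64
    beat_to_beat_cv: 0.12
    ibi_cv: 0.03
    resp_rate: 0.25
    resp_amplitude_mod: 0.22
    resp_baseline_mod: 0.03
    irregular_beat_prob: 0.10
    noise_sd: 0.02
    beat_shape:
      crest_time: 0.13
      notch_time: 0.38
      pulse_amplitude: 1.0
      notch_ratio: 0.40
      diastolic_peak_ratio: 0.50
      mid_systolic_bump_amplitude: 0.45
      component_widths: {systolic: 0.05, bump: 0.045}
      bump_position: 0.7
segment:
  refractory_s: 0.33
  ibi_bounds_s: [0.33, 2.0]
  amplitude_bounds_rel: [0.25, 4.0]
  template_corr_min: 0.5
  min_beats: 10
cv:
  inner_splits: 68
  inner_train_frac: 0.7
  n_boot: 2000
  pool_cap: 2000
  tuning_pool_cap: 120
  sigma_grid: [2, 4, 8]
  lambda_grid: [0.01, 0.1, 1]
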