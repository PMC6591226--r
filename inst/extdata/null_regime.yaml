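# Null regime: both classes generated from the identical healthy-like
# process, for type-I error control of the statistics layer and the
# cross-validated classifier. Sized for quick repeated runs (60 s
# recordings, small cohorts, lighter tuning budget): the null properties
# being checked do not depend on cohort size.
name: null_regime
seed: 20260928
synth:
  healthy:
    n_subjects: 16
    hr_mean: 62
    hr_sd: 9
    recordings_per_subject: [1, 2]
    recording_duration: 60
    sampling_rate: 64
    beat_to_beat_cv: 0.05
    ibi_cv: 0.03
    resp_rate: 0.25
    resp_amplitude_mod: 0.10
    resp_baseline_mod: 0.03
    irregular_beat_prob: 0.03
    noise_sd: 0.02
    beat_shape:
      crest_time: 0.17
      notch_time: 0.32
      pulse_amplitude: 1.0
      notch_ratio: 0.55
      diastolic_peak_ratio: 0.68
      mid_systolic_bump_amplitude: 0.1
      component_widths: {systolic: 0.065, bump: 0.045}
      bump_position: 0.7
  ohcm:
    n_subjects: 10
    hr_mean: 62
    hr_sd: 9
    recordings_per_subject: [1, 2]
    recording_duration: 60
    sampling_rate: 64
    beat_to_beat_cv: 0.05
    ibi_cv: 0.03
    resp_rate: 0.25
    resp_amplitude_mod: 0.10
    resp_baseline_mod: 0.03
    irregular_beat_prob: 0.03
    noise_sd: 0.02
    beat_shape:
      crest_time: 0.17
      notch_time: 0.32
      pulse_amplitude: 1.0
      notch_ratio: 0.55
      diastolic_peak_ratio: 0.68
      mid_systolic_bump_amplitude: 0.1
      component_widths: {systolic: 0.065, bump: 0.045}
      bump_position: 0.7
segment:
  refractory_s: 0.33
  ibi_bounds_s: [0.33, 2.0]
  amplitude_bounds_rel: [0.25, 4.0]
  template_corr_min: 0.5
  min_beats: 10
cv:
  inner_splits: 12
  inner_train_frac: 0.7
  n_boot: 500
  pool_cap: 2000
  tuning_pool_cap: 120
  sigma_grid: [2, 8]
  lambda_grid: [0.1, 1]
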