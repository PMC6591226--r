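# Shared fixtures: small deterministic cohorts and parameter sets used
# across test files. Everything is generated in code at test time.

# Clean single-subject recording parameters: no noise, no modulation,
# fixed heart rate -- the setting where generator ground truth is an
# exact oracle.
clean_params <- function(hr = 72, duration = 60, ...) {
  defaults <- list(hr_mean = hr, hr_sd = 0, recording_duration = duration,
                   noise_sd = 0, resp_amplitude_mod = 0,
                   resp_baseline_mod = 0, irregular_beat_prob = 0,
                   beat_to_beat_cv = 0, ibi_cv = 0)
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}

# Small two-class cohort in the benchmark regimes but cheap to run.
small_cohort <- function(n_healthy = 6, n_ohcm = 5, duration = 60,
                         seed = 420) {
  cfg <- read_config("paper_regime")
  ph <- cfg$synth$healthy
  ph$n_subjects <- as.integer(n_healthy)
  ph$recording_duration <- duration
  ph$recordings_per_subject <- c(1L, 2L)
  po <- cfg$synth$ohcm
  po$n_subjects <- as.integer(n_ohcm)
  po$recording_duration <- duration
  po$recordings_per_subject <- c(1L, 2L)
  synth_cohort(ph, po, seed = seed)
}

# Random instance bags for classifier-level tests (no signal pipeline).
random_bags <- function(n_bags, beats_per_bag, d = 42, seed = 1,
                        shift = 0) {
  set.seed(seed)
  lapply(seq_len(n_bags), function(i) {
    matrix(rnorm(beats_per_bag * d, mean = shift), beats_per_bag, d,
           dimnames = list(NULL, sprintf("F%02d", seq_len(d))))
  })
}

expect_same_indices <- function(a, b) {
  expect_equal(a$onset_idx, b$onset_idx)
  expect_equal(a$peak_idx, b$peak_idx)
  expect_equal(a$notch_idx, b$notch_idx)
  expect_equal(a$end_idx, b$end_idx)
}
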