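test_that("single-beat waveform honours shape landmarks", {
  # Symmetric systolic component only: sample argmax falls on crest_time.
  sh <- beat_shape(crest_time = 0.2, notch_time = 0.4, notch_ratio = 0.5,
                   diastolic_peak_ratio = 0, mid_systolic_bump_amplitude = 0)
  y <- synth_beat_waveform(sh, 1, 64)
  expect_length(y, 64)
  expect_lt(abs((which.max(y) - 1) / 64 - 0.2), 1 / 64 + 1e-9)
  expect_true(is.na(attr(y, "landmarks")$notch_time))

  # Notch landmark is the parameter itself, exactly.
  sh2 <- beat_shape(notch_time = 0.33)
  y2 <- synth_beat_waveform(sh2, 1, 64)
  expect_identical(attr(y2, "landmarks")$notch_time, 0.33)
  # ... and it is a genuine local minimum of the sampled waveform.
  i <- round(0.33 * 64) + 1
  expect_true(y2[i] <= y2[i - 2] && y2[i] <= y2[i + 2])

  # Deterministic: repeated calls give identical samples.
  expect_identical(as.numeric(y2),
                   as.numeric(synth_beat_waveform(sh2, 1, 64)))

  # Realized height ratios match the shape parameters.
  t <- seq(0, 0.999, 1 / 512)
  comp <- ppgmiles:::solve_beat_components(sh2)
  yy <- ppgmiles:::eval_beat_components(comp, t)
  pk <- max(yy)
  expect_equal(ppgmiles:::eval_beat_components(comp, 0.33) / pk, 0.60,
               tolerance = 0.01)
  expect_equal(max(yy[t > 0.36]) / pk, 0.72, tolerance = 0.01)
})

test_that("waveform starts and ends at foot level and rejects bad shapes", {
  y <- synth_beat_waveform(beat_shape(), 1, 64)
  expect_lt(abs(y[1]), 1e-9)
  expect_error(beat_shape(crest_time = 0.4, notch_time = 0.3), "crest_time")
  expect_error(beat_shape(notch_ratio = 1.2), "notch_ratio")
  expect_error(beat_shape(notch_ratio = 0.7, diastolic_peak_ratio = 0.6),
               "diastolic_peak_ratio")
  expect_error(synth_beat_waveform(beat_shape(), period = 0.2, rate = 64),
               "period")
  expect_error(synth_beat_waveform(beat_shape(), period = 1, rate = 10),
               "rate")
})

test_that("interval model forces beat count and spacing", {
  # HR 60, no jitter, 10 s: exactly 10 beats with onsets 0..9 s.
  out <- synth_recording(clean_params(hr = 60, duration = 10), 42)
  expect_equal(out$truth$beat_onset_times, 0:9)
  expect_length(out$recording$samples, 640)
})

test_that("beat amplitude jitter reproduces the nominal CV", {
  p <- cohort_params(hr_mean = 60, hr_sd = 0, beat_to_beat_cv = 0.1,
                     resp_amplitude_mod = 0, resp_baseline_mod = 0,
                     irregular_beat_prob = 0, noise_sd = 0,
                     recording_duration = 1000)
  out <- synth_recording(p, 5)
  amps <- vapply(out$truth$shapes, function(s) s$pulse_amplitude, 1)
  expect_gt(length(amps), 900)
  cv <- sd(amps) / mean(amps)
  # Monte-Carlo tolerance for ~1000 normal draws: sd of the CV estimate
  # is about cv/sqrt(2n) ~ 0.0022; allow 3 of those.
  expect_lt(abs(cv - 0.1), 0.008)
})

test_that("recordings are reproducible and respiration modulates amplitude", {
  p <- cohort_params(recording_duration = 40)
  a <- synth_recording(p, 7)
  b <- synth_recording(p, 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$beat_onset_times, b$truth$beat_onset_times)

  pm <- cohort_params(recording_duration = 120, resp_amplitude_mod = 0.3,
                      beat_to_beat_cv = 0, noise_sd = 0,
                      irregular_beat_prob = 0, hr_sd = 0)
  out <- synth_recording(pm, 9)
  amps <- vapply(out$truth$shapes, function(s) s$pulse_amplitude, 1)
  cv <- sd(amps) / mean(amps)
  expect_gt(cv, 0.15)   # ~0.3/sqrt(2) expected from sinusoidal modulation
})

test_that("cohort generation is labeled, sized and seeded correctly", {
  co <- small_cohort(3, 2, duration = 30, seed = 11)
  expect_equal(nrow(co$subjects), 5)
  expect_equal(sum(co$subjects$label == "healthy"), 3)
  expect_equal(sum(co$subjects$label == "oHCM"), 2)
  expect_true(all(co$subjects$n_recordings >= 1 &
                    co$subjects$n_recordings <= 5))
  expect_equal(length(co$recordings), sum(co$subjects$n_recordings))

  co2 <- small_cohort(3, 2, duration = 30, seed = 11)
  expect_identical(lapply(co$recordings, `[[`, "samples"),
                   lapply(co2$recordings, `[[`, "samples"))

  ph <- clean_params(duration = 30); ph$n_subjects <- 0L
  po <- clean_params(duration = 30); po$n_subjects <- 2L
  expect_warning(synth_cohort(ph, po, seed = 1), "single-class")
})

test_that("realized per-class heart rates match the cohort model", {
  cfg <- read_config("paper_regime")
  ph <- cfg$synth$healthy; ph$recording_duration <- 30
  po <- cfg$synth$ohcm; po$recording_duration <- 30
  co <- synth_cohort(ph, po, seed = 2024)
  for (cls in c("healthy", "oHCM")) {
    par <- if (cls == "healthy") ph else po
    hrs <- co$subjects$heart_rate[co$subjects$label == cls]
    se <- par$hr_sd / sqrt(length(hrs))
    expect_lt(abs(mean(hrs) - par$hr_mean), 2 * se + 1e-9)
  }
})

test_that("ground truth is internally consistent", {
  co <- small_cohort(2, 2, duration = 45, seed = 77)
  for (rid in names(co$truths)) {
    tr <- co$truths[[rid]]
    dur <- length(co$recordings[[rid]]$samples) /
      co$recordings[[rid]]$sampling_rate
    expect_true(all(diff(tr$beat_onset_times) > 0))
    expect_true(all(tr$beat_onset_times >= 0 & tr$beat_onset_times < dur))
    expect_true(all(tr$peak_times > tr$beat_onset_times))
    ok <- !is.na(tr$notch_times)
    expect_true(all(tr$notch_times[ok] > tr$peak_times[ok] - 1e-9))
    expect_true(all(tr$notch_times[ok] < dur))
  }
})

test_that("paper-regime class means separate in the documented directions", {
  cfg <- read_config("paper_regime")
  h <- cfg$synth$healthy; o <- cfg$synth$ohcm
  expect_lt(o$beat_shape$crest_time, h$beat_shape$crest_time)   # steeper rise
  expect_gt(o$beat_shape$notch_time, h$beat_shape$notch_time)   # longer SET
  expect_gt(o$beat_to_beat_cv, h$beat_to_beat_cv)               # variability
  expect_gt(o$beat_shape$mid_systolic_bump_amplitude,
            h$beat_shape$mid_systolic_bump_amplitude)           # extra peaks
  expect_gt(o$irregular_beat_prob, h$irregular_beat_prob)
})
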