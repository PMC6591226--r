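#' Beat shape parameters
#'
#' Describes the morphology of a single synthetic PPG pulse as a sum of
#' smooth unimodal (Gaussian) components: a systolic wave, an optional
#' mid-systolic bump (the "dome" of the spike-and-dome pulse seen with
#' dynamic LVOT obstruction, producing multiple peaks of variable
#' intensity), and a dicrotic/diastolic wave. The dicrotic component's
#' amplitude, centre and width are solved in closed form so that the
#' waveform has a true local minimum exactly at `notch_time` with height
#' `notch_ratio * peak` and a diastolic crest of height
#' `diastolic_peak_ratio * peak`. Landmark times are therefore analytic,
#' which makes the generator usable as a ground-truth oracle for the
#' segmentation and morphometry code.
#'
#' @param crest_time Seconds from beat foot to systolic peak.
#' @param notch_time Seconds from beat foot to dicrotic notch. Must exceed
#'   `crest_time`.
#' @param pulse_amplitude Peak minus foot amplitude, arbitrary units.
#' @param notch_ratio Notch height over peak height, in (0, 1).
#' @param diastolic_peak_ratio Diastolic crest height over peak height, in
#'   \[0, 1). Must exceed `notch_ratio` when positive; `0` removes the
#'   dicrotic wave entirely (and with it the notch).
#' @param mid_systolic_bump_amplitude Relative amplitude (fraction of the
#'   systolic peak) of the mid-systolic bump; `0` removes it.
#' @param component_widths Named numeric vector with elements `systolic`
#'   and `bump`: Gaussian widths (standard deviations) in seconds. The
#'   dicrotic width is derived from the landmark constraints.
#' @param bump_position Position of the bump centre as a fraction of the
#'   crest-to-notch interval (default 0.7).
#' @return An object of class `beat_shape`.
#' @export
beat_shape <- function(crest_time = 0.18,
                       notch_time = 0.33,
                       pulse_amplitude = 1,
                       notch_ratio = 0.60,
                       diastolic_peak_ratio = 0.72,
                       mid_systolic_bump_amplitude = 0,
                       component_widths = c(systolic = 0.075, bump = 0.045),
                       bump_position = 0.7) {
  stopifnot(is_pos_num(crest_time), is_pos_num(notch_time),
            is_pos_num(pulse_amplitude))
  if (!(crest_time < notch_time)) {
    stop("beat_shape: crest_time must be smaller than notch_time")
  }
  if (!(notch_ratio > 0 && notch_ratio < 1)) {
    stop("beat_shape: notch_ratio must lie in (0, 1)")
  }
  if (!(diastolic_peak_ratio >= 0 && diastolic_peak_ratio < 1)) {
    stop("beat_shape: diastolic_peak_ratio must lie in [0, 1)")
  }
  if (diastolic_peak_ratio > 0 && diastolic_peak_ratio <= notch_ratio) {
    stop("beat_shape: diastolic_peak_ratio must exceed notch_ratio")
  }
  if (mid_systolic_bump_amplitude < 0) {
    stop("beat_shape: mid_systolic_bump_amplitude must be >= 0")
  }
  if (!all(c("systolic", "bump") %in% names(component_widths))) {
    stop("beat_shape: component_widths needs elements 'systolic' and 'bump'")
  }
  structure(list(
    crest_time = crest_time,
    notch_time = notch_time,
    pulse_amplitude = pulse_amplitude,
    notch_ratio = notch_ratio,
    diastolic_peak_ratio = diastolic_peak_ratio,
    mid_systolic_bump_amplitude = mid_systolic_bump_amplitude,
    component_widths = component_widths,
    bump_position = bump_position
  ), class = "beat_shape")
}

gaussian_bump <- function(t, a, mu, w) a * exp(-(t - mu)^2 / (2 * w^2))

# Solve the Gaussian components of one beat. Returns amplitudes/centres/
# widths plus the analytic landmark times. Works on the unit systolic
# scale; the caller rescales to pulse_amplitude afterwards.
solve_beat_components <- function(shape) {
  tc <- shape$crest_time
  tn <- shape$notch_time
  ws <- unname(shape$component_widths["systolic"])
  wb <- unname(shape$component_widths["bump"])
  ab <- shape$mid_systolic_bump_amplitude
  tb <- tc + shape$bump_position * (tn - tc)
  r <- shape$notch_ratio
  d <- shape$diastolic_peak_ratio

  sysbump <- list(a = c(1, ab), mu = c(tc, tb), w = c(ws, wb))
  g_at <- function(cc, t) sum(cc$a * exp(-(t - cc$mu)^2 / (2 * cc$w^2)))
  gslope_at <- function(cc, t) {
    sum(-cc$a * (t - cc$mu) / cc$w^2 *
          exp(-(t - cc$mu)^2 / (2 * cc$w^2)))
  }
  find_peak <- function(cc, hi) {
    stats::optimize(function(t) g_at(cc, t), interval = c(0, hi),
                    maximum = TRUE, tol = 1e-8)$maximum
  }

  if (d > 0) {
    # Fixed point on the realized peak value: the notch and diastolic
    # heights are fractions of the *realized* systolic peak, which itself
    # includes dicrotic tails, so iterate the closed-form solve a few
    # times (converges geometrically; tails are small).
    pk <- 1
    td <- NA_real_
    for (pass in 1:4) {
      dv <- r * pk - g_at(sysbump, tn)  # height deficit to fill at the notch
      ds <- -gslope_at(sysbump, tn)     # down-slope magnitude at the notch
      if (dv <= 0 || ds <= 0) {
        stop("beat_shape: no valid dicrotic wave solution; the notch level ",
             "is below the systolic/bump envelope or the approach slope is ",
             "not negative")
      }
      ad_target <- d * pk - if (is.na(td)) 0 else g_at(sysbump, td)
      if (ad_target <= dv) {
        stop("beat_shape: diastolic_peak_ratio too small relative to ",
             "notch_ratio for a dicrotic wave to form")
      }
      wd2 <- 2 * log(ad_target / dv) * dv^2 / ds^2
      u <- -wd2 * ds / dv               # notch_time minus dicrotic centre
      td <- tn - u
      ad <- dv * exp(u^2 / (2 * wd2))
      comp <- list(a = c(sysbump$a, ad), mu = c(sysbump$mu, td),
                   w = c(sysbump$w, sqrt(wd2)))
      pk <- g_at(comp, find_peak(comp, tn))
    }
    # Certify the landmark really is a local minimum.
    curv <- sum(comp$a * ((tn - comp$mu)^2 / comp$w^4 - 1 / comp$w^2) *
                  exp(-(tn - comp$mu)^2 / (2 * comp$w^2)))
    if (!(curv > 0)) {
      stop("beat_shape: solved dicrotic wave does not produce a local ",
           "minimum at notch_time; adjust widths or ratios")
    }
    notch_t <- tn
  } else {
    comp <- sysbump
    notch_t <- NA_real_
  }

  # Systolic apex of the full sum (shifts O(1e-4 s) from crest_time when
  # bump/dicrotic tails are present).
  peak_t <- find_peak(comp, if (is.na(notch_t)) 2 * tc else notch_t)
  peak_v <- g_at(comp, peak_t)

  list(a = comp$a * shape$pulse_amplitude / peak_v,
       mu = comp$mu, w = comp$w,
       peak_time = peak_t, notch_time = notch_t)
}

# Vectorized continuous evaluation of the component sum at times t
# (seconds from beat foot).
eval_beat_components <- function(comp, t) {
  y <- numeric(length(t))
  for (k in seq_along(comp$a)) {
    y <- y + gaussian_bump(t, comp$a[k], comp$mu[k], comp$w[k])
  }
  y
}

#' Synthesize one PPG beat
#'
#' Samples a single pulse of `round(period * rate)` samples built from the
#' smooth component model of [beat_shape()]. The returned waveform starts
#' and ends at the foot level (a linear baseline through the two endpoint
#' values of the continuous model is subtracted, a sub-millisecond
#' perturbation of the landmarks). Landmark times of the continuous model
#' are attached as the `landmarks` attribute (`peak_time`, `notch_time`,
#' both in seconds from the beat foot; `notch_time` is the shape parameter
#' itself, exact by construction).
#'
#' @param shape A [beat_shape()] object.
#' @param period Beat period in seconds; must exceed `notch_time`.
#' @param rate Sampling rate in Hz (at least 25).
#' @return Numeric vector of samples with attribute `landmarks`.
#' @export
synth_beat_waveform <- function(shape, period, rate) {
  stopifnot(inherits(shape, "beat_shape"), is_pos_num(period),
            is_pos_num(rate))
  if (rate < 25) stop("synth_beat_waveform: rate must be at least 25 Hz")
  if (period <= shape$notch_time) {
    stop("synth_beat_waveform: period must exceed notch_time")
  }
  comp <- solve_beat_components(shape)
  n <- round(period * rate)
  t <- (seq_len(n) - 1) / rate
  y <- eval_beat_components(comp, t)
  y0 <- eval_beat_components(comp, 0)
  y1 <- eval_beat_components(comp, period)
  y <- y - (y0 + (y1 - y0) * t / period)
  attr(y, "landmarks") <- list(peak_time = comp$peak_time,
                               notch_time = comp$notch_time)
  y
}

#' Cohort generation parameters
#'
#' Bundles everything needed to simulate a class of subjects: resting
#' wrist PPG, 5-minute recordings by default, heart rate drawn per subject
#' from a cohort-level normal, multiplicative beat-to-beat shape jitter,
#' sinusoidal respiratory amplitude/baseline modulation, additive Gaussian
#' sensor noise, and occasional irregularly shaped beats (shape parameters
#' redrawn from a widened jitter distribution; all simulated subjects stay
#' in sinus rhythm, so no ectopy model).
#'
#' @param n_subjects Number of subjects.
#' @param hr_mean,hr_sd Cohort heart-rate mean and SD in bpm.
#' @param recordings_per_subject Integer range (length-2) of recordings
#'   drawn uniformly per subject; default `c(1, 5)`.
#' @param recording_duration Seconds per recording (default 300).
#' @param sampling_rate Hz, 25--250 (default 64).
#' @param beat_shape Class-mean [beat_shape()]; `NULL` uses the
#'   [beat_shape()] defaults.
#' @param beat_to_beat_cv Coefficient of variation of the multiplicative
#'   per-beat jitter applied to amplitude, time landmarks and bump height.
#' @param ibi_cv Coefficient of variation of per-beat interval jitter
#'   around the subject's mean interval (default 0.03).
#' @param resp_rate Respiratory rate in Hz.
#' @param resp_amplitude_mod Fractional amplitude modulation depth in
#'   \[0, 1).
#' @param resp_baseline_mod Additive baseline swing amplitude (signal
#'   units).
#' @param irregular_beat_prob Probability that a beat's shape is redrawn
#'   from a widened (x3.5 CV) jitter distribution.
#' @param noise_sd Additive white-noise SD (signal units).
#' @param seed Integer seed attached to the parameter set (used by
#'   [synth_cohort()] when no explicit seed is given).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 10,
                          hr_mean = 60,
                          hr_sd = 8,
                          recordings_per_subject = c(1L, 5L),
                          recording_duration = 300,
                          sampling_rate = 64,
                          beat_shape = NULL,
                          beat_to_beat_cv = 0.04,
                          ibi_cv = 0.03,
                          resp_rate = 0.25,
                          resp_amplitude_mod = 0.08,
                          resp_baseline_mod = 0.03,
                          irregular_beat_prob = 0.02,
                          noise_sd = 0.02,
                          seed = 1L) {
  if (is.null(beat_shape)) beat_shape <- beat_shape()
  stopifnot(is_count(n_subjects), is_pos_num(hr_mean), hr_sd >= 0,
            is_pos_num(recording_duration), is_pos_num(sampling_rate),
            inherits(beat_shape, "beat_shape"),
            beat_to_beat_cv >= 0, ibi_cv >= 0, is_pos_num(resp_rate),
            is_prob(irregular_beat_prob), noise_sd >= 0)
  if (!(resp_amplitude_mod >= 0 && resp_amplitude_mod < 1)) {
    stop("cohort_params: resp_amplitude_mod must lie in [0, 1)")
  }
  if (sampling_rate < 25 || sampling_rate > 250) {
    stop("cohort_params: sampling_rate must lie in [25, 250] Hz")
  }
  rps <- as.integer(recordings_per_subject)
  if (length(rps) != 2L || rps[1] < 1L || rps[2] > 5L || rps[1] > rps[2]) {
    stop("cohort_params: recordings_per_subject must be an integer range ",
         "within [1, 5]")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    hr_mean = hr_mean, hr_sd = hr_sd,
    recordings_per_subject = rps,
    recording_duration = recording_duration,
    sampling_rate = sampling_rate,
    beat_shape = beat_shape,
    beat_to_beat_cv = beat_to_beat_cv,
    ibi_cv = ibi_cv,
    resp_rate = resp_rate,
    resp_amplitude_mod = resp_amplitude_mod,
    resp_baseline_mod = resp_baseline_mod,
    irregular_beat_prob = irregular_beat_prob,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Construct a PPG recording object
#'
#' @param samples Numeric amplitude vector.
#' @param sampling_rate Hz.
#' @param subject_id,recording_id Opaque identifiers.
#' @param label One of `"healthy"`, `"oHCM"`, `"unknown"`.
#' @return Object of class `ppg_recording`.
#' @export
ppg_recording <- function(samples, sampling_rate, subject_id = "S1",
                          recording_id = "R1", label = "unknown") {
  stopifnot(is.numeric(samples), is_pos_num(sampling_rate))
  label <- match.arg(label, c("healthy", "oHCM", "unknown"))
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 subject_id = as.character(subject_id),
                 recording_id = as.character(recording_id),
                 label = label),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording %s/%s: %.1f s @ %g Hz, label=%s>\n",
              x$subject_id, x$recording_id,
              length(x$samples) / x$sampling_rate, x$sampling_rate, x$label))
  invisible(x)
}

# Truncated standard normal draw (vectorized), bounded at +/- lim sd.
rnorm_trunc <- function(n, lim = 3.5) {
  z <- stats::rnorm(n)
  pmin(pmax(z, -lim), lim)
}

#' Synthesize one wrist-PPG recording with ground truth
#'
#' Generates a single resting recording: inter-beat intervals from the
#' subject's heart rate with multiplicative jitter (`ibi_cv`), per-beat
#' shape jitter at `beat_to_beat_cv`, respiratory amplitude and baseline
#' modulation at `resp_rate`, occasional irregular beats, and additive
#' Gaussian noise. The accompanying ground truth records every beat onset
#' and landmark time actually used, which downstream tests use as a
#' segmentation oracle.
#'
#' @param cohort A [cohort_params()] object.
#' @param subject_seed Integer seed for this recording's randomness.
#' @param subject_hr Optional fixed subject heart rate (bpm); when `NULL`
#'   it is drawn from the cohort heart-rate model.
#' @param subject_id,recording_id Identifiers stored on the recording.
#' @param label Class label stored on the recording.
#' @return A list with elements `recording` (a [ppg_recording()]) and
#'   `truth` (list with `beat_onset_times`, `peak_times`, `notch_times`,
#'   `shapes`, `subject_hr`).
#' @export
synth_recording <- function(cohort, subject_seed, subject_hr = NULL,
                            subject_id = "S1", recording_id = "R1",
                            label = "unknown") {
  stopifnot(inherits(cohort, "cohort_params"))
  with_local_seed(subject_seed, {
    fs <- cohort$sampling_rate
    dur <- cohort$recording_duration
    n <- round(dur * fs)
    tgrid <- (seq_len(n) - 1) / fs

    if (is.null(subject_hr)) {
      subject_hr <- cohort$hr_mean + cohort$hr_sd * rnorm_trunc(1)
      subject_hr <- min(max(subject_hr, 30), 180)
    }
    ibi0 <- 60 / subject_hr

    # Draw beat onsets until the recording is covered.
    n_max <- ceiling(dur / ibi0 * 1.4) + 8L
    ibis <- ibi0 * (1 + cohort$ibi_cv * rnorm_trunc(n_max, 3))
    ibis <- pmax(ibis, 0.33)
    onsets <- cumsum(c(0, ibis))
    keep <- onsets < dur
    onsets <- onsets[keep]
    periods <- ibis[seq_len(length(onsets))]
    nb <- length(onsets)

    # Per-beat shape jitter (widened for irregular beats).
    cv <- cohort$beat_to_beat_cv
    irregular <- stats::runif(nb) < cohort$irregular_beat_prob
    infl <- ifelse(irregular, 3.5, 1)
    e_amp <- rnorm_trunc(nb); e_time <- rnorm_trunc(nb)
    e_bump <- rnorm_trunc(nb); e_r <- rnorm_trunc(nb)

    base <- cohort$beat_shape
    resp_phase <- 2 * pi * cohort$resp_rate * onsets
    amp_resp <- 1 + cohort$resp_amplitude_mod * sin(resp_phase)
    amps <- base$pulse_amplitude * (1 + cv * e_amp) * amp_resp
    amps <- pmax(amps, 0.05 * base$pulse_amplitude)

    peak_times <- numeric(nb)
    notch_times <- rep(NA_real_, nb)
    shapes <- vector("list", nb)
    comp_a <- vector("list", nb); comp_mu <- vector("list", nb)
    comp_w <- vector("list", nb)
    for (i in seq_len(nb)) {
      s_time <- 1 + cv * infl[i] * e_time[i]
      s_time <- min(max(s_time, 0.6), 1.6)
      crest <- base$crest_time * s_time
      notch <- base$notch_time * s_time
      # Keep the whole systolic complex inside the beat.
      lim <- 0.75 * periods[i]
      if (notch > lim) {
        shrink <- lim / notch
        crest <- crest * shrink; notch <- notch * shrink
        s_time <- s_time * shrink
      }
      bump <- max(base$mid_systolic_bump_amplitude *
                    (1 + 1.5 * cv * infl[i] * e_bump[i]), 0)
      r_i <- min(max(base$notch_ratio * (1 + 0.5 * cv * infl[i] * e_r[i]),
                     0.05), 0.9)
      d_i <- base$diastolic_peak_ratio
      if (d_i > 0) d_i <- min(max(d_i, r_i + 0.05), 0.95)
      # Jittered parameters can make the dicrotic solve infeasible
      # (notch level inside the systolic/bump envelope); fall back to
      # progressively tamer shapes, ending at the class mean, so the
      # generator never aborts and the ground truth stays consistent.
      mk <- function(crest., notch., r., d., bump., wscale.) {
        sh. <- beat_shape(crest_time = crest., notch_time = notch.,
                          pulse_amplitude = amps[i], notch_ratio = r.,
                          diastolic_peak_ratio = d.,
                          mid_systolic_bump_amplitude = bump.,
                          component_widths = base$component_widths * wscale.,
                          bump_position = base$bump_position)
        list(sh = sh., comp = solve_beat_components(sh.))
      }
      got <- tryCatch(mk(crest, notch, r_i, d_i, bump, s_time),
                      error = function(e) NULL)
      if (is.null(got)) {
        got <- tryCatch(mk(crest, notch, base$notch_ratio,
                           base$diastolic_peak_ratio,
                           base$mid_systolic_bump_amplitude, s_time),
                        error = function(e) NULL)
      }
      if (is.null(got)) {
        got <- mk(base$crest_time, base$notch_time, base$notch_ratio,
                  base$diastolic_peak_ratio,
                  base$mid_systolic_bump_amplitude, 1)
      }
      sh <- got$sh
      comp <- got$comp
      shapes[[i]] <- sh
      peak_times[i] <- onsets[i] + comp$peak_time
      if (!is.na(comp$notch_time)) notch_times[i] <- onsets[i] + comp$notch_time
      comp_a[[i]] <- comp$a; comp_mu[[i]] <- comp$mu; comp_w[[i]] <- comp$w
    }

    # Vectorized sample synthesis: map each sample to its beat, then
    # evaluate all Gaussian components with per-beat parameters.
    bidx <- findInterval(tgrid, onsets)
    inside <- bidx >= 1L
    tau <- tgrid[inside] - onsets[bidx[inside]]
    bi <- bidx[inside]
    ncomp_max <- max(vapply(comp_a, length, 1L))
    y <- numeric(sum(inside))
    for (k in seq_len(ncomp_max)) {
      ak <- vapply(comp_a, function(a) if (length(a) >= k) a[k] else 0, 1)
      muk <- vapply(comp_mu, function(m) if (length(m) >= k) m[k] else 0, 1)
      wk <- vapply(comp_w, function(w) if (length(w) >= k) w[k] else 1, 1)
      y <- y + ak[bi] * exp(-(tau - muk[bi])^2 / (2 * wk[bi]^2))
    }
    # Per-beat linear baseline so every beat window starts/ends at foot level.
    y0 <- numeric(nb); y1 <- numeric(nb)
    for (i in seq_len(nb)) {
      y0[i] <- sum(comp_a[[i]] * exp(-(0 - comp_mu[[i]])^2 / (2 * comp_w[[i]]^2)))
      y1[i] <- sum(comp_a[[i]] * exp(-(periods[i] - comp_mu[[i]])^2 /
                                       (2 * comp_w[[i]]^2)))
    }
    y <- y - (y0[bi] + (y1[bi] - y0[bi]) * tau / periods[bi])

    samples <- numeric(n)
    samples[inside] <- y
    samples <- samples +
      cohort$resp_baseline_mod * sin(2 * pi * cohort$resp_rate * tgrid)
    if (cohort$noise_sd > 0) {
      samples <- samples + stats::rnorm(n, sd = cohort$noise_sd)
    }

    # Ground truth keeps only beats fully contained in the recording.
    full <- (onsets + periods) <= dur + 1e-9
    truth <- list(
      beat_onset_times = onsets[full],
      peak_times = peak_times[full],
      notch_times = notch_times[full],
      shapes = shapes[full],
      subject_hr = subject_hr
    )
    list(recording = ppg_recording(samples, fs, subject_id, recording_id,
                                   label),
         truth = truth)
  })
}

#' Synthesize a labeled two-class cohort
#'
#' Generates `healthy$n_subjects + ohcm$n_subjects` subjects, each with a
#' uniformly drawn number of recordings within the configured range. All
#' recordings of one subject share that subject's heart rate. Fully
#' reproducible from `seed`.
#'
#' @param healthy,ohcm [cohort_params()] for the two classes.
#' @param seed Master integer seed (default: `healthy$seed`).
#' @return A list of class `ppg_cohort` with elements `recordings` (list of
#'   [ppg_recording()]), `truths` (matching ground-truth list), and
#'   `subjects` (data.frame of `subject_id`, `label`, `n_recordings`,
#'   `heart_rate`).
#' @export
synth_cohort <- function(healthy, ohcm, seed = healthy$seed) {
  stopifnot(inherits(healthy, "cohort_params"), inherits(ohcm, "cohort_params"))
  if (healthy$n_subjects == 0 || ohcm$n_subjects == 0) {
    warning("synth_cohort: one class has zero subjects; emitting a ",
            "single-class cohort")
  }
  recordings <- list(); truths <- list()
  sub_rows <- list()
  subj_counter <- 0L
  for (cls in c("healthy", "oHCM")) {
    par <- if (cls == "healthy") healthy else ohcm
    prefix <- if (cls == "healthy") "H" else "P"
    for (s in seq_len(par$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("%s%02d", prefix, s)
      subj_seed <- derive_seed(seed, subj_counter * 1000L)
      n_rec <- with_local_seed(subj_seed, {
        rng <- par$recordings_per_subject
        sample(seq(rng[1], rng[2]), 1L)
      })
      hr <- with_local_seed(derive_seed(seed, subj_counter * 1000L + 500L), {
        min(max(par$hr_mean + par$hr_sd * rnorm_trunc(1), 30), 180)
      })
      for (r in seq_len(n_rec)) {
        rid <- sprintf("%s_rec%d", sid, r)
        out <- synth_recording(par,
                               subject_seed = derive_seed(seed, subj_counter * 1000L + r),
                               subject_hr = hr, subject_id = sid,
                               recording_id = rid, label = cls)
        recordings[[rid]] <- out$recording
        truths[[rid]] <- out$truth
      }
      sub_rows[[sid]] <- data.frame(subject_id = sid, label = cls,
                                    n_recordings = n_rec, heart_rate = hr,
                                    stringsAsFactors = FALSE)
    }
  }
  structure(list(recordings = recordings, truths = truths,
                 subjects = do.call(rbind, c(sub_rows, make.row.names = FALSE)),
                 seed = as.integer(seed)),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  tab <- table(x$subjects$label)
  cat(sprintf("<ppg_cohort: %d subjects (%s), %d recordings, seed=%d>\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$recordings), x$seed))
  invisible(x)
}
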