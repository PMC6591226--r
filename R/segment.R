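#' Band-pass preprocess a PPG recording
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth band-pass
#' of 0.5--8 Hz. This removes baseline wander and high-frequency sensor
#' noise while keeping the pulse harmonics and the respiratory amplitude
#' modulation of the envelope. The output has (near-)zero mean and the
#' same length as the input.
#'
#' @param rec A [ppg_recording()].
#' @param band Pass band in Hz (default `c(0.5, 8)`).
#' @return The filtered [ppg_recording()].
#' @export
preprocess <- function(rec, band = c(0.5, 8)) {
  stopifnot(inherits(rec, "ppg_recording"))
  fs <- rec$sampling_rate
  if (fs < 25) stop("preprocess: sampling_rate must be at least 25 Hz")
  if (length(rec$samples) < 30 * fs) {
    stop("preprocess: recording shorter than 30 s; rejected")
  }
  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(2, c(band[1], hi) / (fs / 2), type = "pass")
  raw <- rec$samples
  rec$samples <- as.numeric(signal::filtfilt(bf, raw))
  # Companion wide-band channel (0.5 Hz to 2x the pass-band edge) kept
  # for fine localization of the dicrotic notch, whose dome/notch/
  # diastolic-wave detail sits near or above the pass-band edge.
  hi2 <- min(2 * hi, 0.45 * fs)
  if (hi2 > hi) {
    bf2 <- signal::butter(2, c(band[1], hi2) / (fs / 2), type = "pass")
    rec$notch_ref <- as.numeric(signal::filtfilt(bf2, raw))
  } else {
    rec$notch_ref <- rec$samples
  }
  rec
}

# Local maxima indices of x (strictly greater than left neighbour,
# greater-or-equal than right: plateau-left convention).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Prominence of a local maximum at index i: height above the higher of
# the two minima separating it from higher terrain (standard definition,
# evaluated within the supplied window).
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    left <- x[seq_len(i)]
    right <- x[i:length(x)]
    higher_l <- which(left > x[i])
    base_l <- if (length(higher_l)) {
      min(left[(max(higher_l)):i])
    } else min(left)
    higher_r <- which(right > x[i])
    base_r <- if (length(higher_r)) {
      min(right[1:(min(higher_r))])
    } else min(right)
    x[i] - max(base_l, base_r)
  }, 1)
}

#' Detect beat onsets in a preprocessed recording
#'
#' Finds systolic upstrokes as peaks of the first derivative using an
#' adaptive (quantile-based, hence gain-invariant) threshold with a
#' refractory period, then walks each upstroke back to the preceding
#' local minimum of the waveform (the beat foot). The systolic peak is
#' the maximum inside the beat window; the dicrotic notch is the most
#' prominent local minimum of the waveform between peak and window end,
#' with a second-derivative fallback when the waveform has no usable
#' minimum.
#'
#' @param rec A preprocessed [ppg_recording()].
#' @param refractory_s Minimum spacing between accepted upstrokes in
#'   seconds (default 0.33, i.e. heart rates up to about 180 bpm).
#' @param min_beats Minimum number of detected beats below which the
#'   recording is flagged unusable (default 10).
#' @return A data.frame of class `ppg_beats` with columns `onset_idx`,
#'   `peak_idx`, `notch_idx` (NA when absent), `end_idx` (half-open
#'   windows: a beat spans `[onset_idx, end_idx)`), `qualified`,
#'   `rejection_reason`. 1-based sample indices.
#' @export
detect_beat_onsets <- function(rec, refractory_s = 0.33, min_beats = 10) {
  stopifnot(inherits(rec, "ppg_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  d <- c(0, diff(x)) * fs

  pos <- d[d > 0]
  if (!length(pos) || stats::sd(x) == 0) {
    stop("detect_beat_onsets: recording unusable (no pulsatile activity)")
  }
  # Permissive slope gate first (relative to the 95th percentile of
  # positive slopes, hence gain-invariant), then validation of each
  # candidate upstroke by its foot-to-apex rise. The rise gate is what
  # rejects dicrotic/diastolic rebounds and mid-systolic "dome"
  # upstrokes, which can be almost as steep as a small beat's systolic
  # rise but carry much less amplitude.
  thr <- 0.15 * stats::quantile(pos, 0.95, names = FALSE)
  cand <- local_maxima(d)
  cand <- cand[d[cand] >= thr]
  if (!length(cand)) {
    stop("detect_beat_onsets: recording unusable (no upstrokes above ",
         "threshold)")
  }
  xs <- smooth_sg(x)
  ds <- c(0, diff(xs)) * fs
  back <- round(0.45 * fs)
  fwd <- round(0.35 * fs)
  n <- length(x)
  # Foot: walk back from the upstroke's slope peak to the last sample
  # whose slope has fallen to <= 4% of the peak slope. At a clean foot
  # this is the cycle minimum; it also handles feet that are slope
  # elbows rather than minima (slow filtered runoff rising into the
  # upstroke leaves no local minimum at the foot).
  foot_of <- function(i) {
    lo <- max(1L, i - back)
    idx <- lo:i
    small <- idx[ds[idx] <= 0.04 * ds[i]]
    as.integer(if (length(small)) small[length(small)]
               else lo + which.min(xs[idx]) - 1L)
  }
  feet <- vapply(cand, foot_of, integer(1))
  apex <- vapply(cand, function(i) max(xs[i:min(n, i + fwd)]), 1)
  rise <- apex - xs[feet]
  ok <- rise >= 0.3 * stats::quantile(rise, 0.75, names = FALSE)
  cand <- cand[ok]; rise <- rise[ok]
  # Refractory enforcement, keeping the larger rise in each clash.
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  for (j in seq_along(cand)) {
    i <- cand[j]
    if (!length(keep) || i - cand[keep[length(keep)]] >= refr) {
      keep <- c(keep, j)
    } else if (rise[j] > rise[keep[length(keep)]]) {
      keep[length(keep)] <- j
    }
  }
  # Onset: first rising sample after the cycle minimum preceding the
  # upstroke (the smoothed-waveform foot).
  onsets <- vapply(cand[keep], function(i) foot_of(i) + 1L, integer(1))
  onsets <- sort(unique(onsets))
  if (length(onsets) < min_beats + 1) {
    stop("detect_beat_onsets: recording unusable (fewer than ", min_beats,
         " beats detected)")
  }

  nb <- length(onsets) - 1L
  xn <- rec$notch_ref %||% x
  peak_idx <- integer(nb); notch_idx <- rep(NA_integer_, nb)
  for (b in seq_len(nb)) {
    o <- onsets[b]; e <- onsets[b + 1L]
    win <- x[o:(e - 1L)]
    p <- o + which.max(win) - 1L
    peak_idx[b] <- p
    notch_idx[b] <- find_notch(xn, o, p, e, fs)
  }
  out <- data.frame(beat_idx = seq_len(nb),
                    onset_idx = onsets[-length(onsets)],
                    peak_idx = peak_idx,
                    notch_idx = notch_idx,
                    end_idx = onsets[-1L],
                    qualified = NA,
                    rejection_reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ppg_beats", "data.frame")
  out
}

# Short zero-phase quadratic (Savitzky-Golay) smoother for landmark
# localization.
smooth_sg <- function(x, n = 7L) {
  if (length(x) <= n + 2L) return(x)
  as.numeric(signal::sgolayfilt(x, p = 2, n = n))
}

# Notch search within one beat. The dicrotic notch is located
# structurally: the diastolic wave is the last local maximum after the
# systolic peak with prominence at least 3% of the beat amplitude, and
# the notch is the waveform minimum between the preceding prominent
# maximum (the systolic peak itself, or the mid-systolic "dome" of
# spike-and-dome beats) and that diastolic wave. A plain
# deepest-minimum rule would land on the mid-systolic dip in dome
# morphology. Falls back to the first local maximum of the second
# derivative after the peak when no diastolic wave qualifies.
find_notch <- function(x, onset, peak, end, fs) {
  if (end - peak < 5L) return(NA_integer_)
  seg <- smooth_sg(x[peak:(end - 1L)], n = 7L)
  amp <- x[peak] - min(x[onset:(end - 1L)])
  if (amp <= 0) return(NA_integer_)
  # The diastolic wave crests within the first ~65% of the post-peak
  # window; later maxima are runoff noise.
  lim <- max(3L, round(0.65 * length(seg)))
  maxs <- local_maxima(seg)
  maxs <- maxs[maxs > 1L & maxs <= lim]
  if (length(maxs)) {
    prom <- peak_prominence(seg, maxs)
    maxs <- maxs[prom >= 0.03 * amp]
  }
  if (length(maxs)) {
    dia <- maxs[length(maxs)]
    prev <- maxs[maxs < dia]
    p0 <- if (length(prev)) prev[length(prev)] else 1L
    m <- p0 + which.min(seg[p0:dia]) - 1L
    if (m > 1L && m < dia) return(peak + m - 1L)
  }
  d2 <- diff(diff(seg))
  cand <- local_maxima(d2)
  cand <- cand[cand > 2L & cand <= lim]
  if (length(cand)) return(peak + cand[1] + 1L - 1L)
  NA_integer_
}

#' Qualify detected beats as classifier instances
#'
#' A beat is qualified when (a) its inter-beat interval lies in
#' `ibi_bounds_s`, (b) its pulse amplitude lies within
#' `amplitude_bounds_rel` times the recording's median beat amplitude,
#' and (c) its correlation with the recording's resampled median-beat
#' template is at least `template_corr_min`. The correlation gate is
#' deliberately loose: irregularly shaped beats carry diagnostic signal
#' in oHCM and must not be screened out wholesale. The first failing rule
#' is recorded as `rejection_reason`.
#'
#' @param beats A `ppg_beats` data.frame from [detect_beat_onsets()].
#' @param rec The matching [ppg_recording()] (preprocessed).
#' @param ibi_bounds_s Allowed inter-beat interval range in seconds.
#' @param amplitude_bounds_rel Allowed amplitude range relative to the
#'   recording median beat amplitude.
#' @param template_corr_min Minimum correlation with the median-beat
#'   template.
#' @param min_beats Minimum number of qualified beats below which the
#'   recording is flagged unusable.
#' @return The `ppg_beats` data.frame with `qualified` and
#'   `rejection_reason` filled in.
#' @export
qualify_beats <- function(beats, rec,
                          ibi_bounds_s = c(0.33, 2.0),
                          amplitude_bounds_rel = c(0.25, 4.0),
                          template_corr_min = 0.5,
                          min_beats = 10) {
  stopifnot(inherits(beats, "ppg_beats"), inherits(rec, "ppg_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  nb <- nrow(beats)
  if (nb < min_beats) {
    stop("qualify_beats: fewer than ", min_beats, " detected beats")
  }
  ibi <- (beats$end_idx - beats$onset_idx) / fs
  amp <- x[beats$peak_idx] - x[beats$onset_idx]
  med_amp <- stats::median(amp)
  tmpl <- beat_template(x, beats)
  corr <- vapply(seq_len(nb), function(b) {
    seg <- x[beats$onset_idx[b]:(beats$end_idx[b] - 1L)]
    rs <- resample_linear(seg, length(tmpl))
    if (stats::sd(rs) == 0 || stats::sd(tmpl) == 0) return(0)
    stats::cor(rs, tmpl)
  }, 1)

  reason <- rep(NA_character_, nb)
  reason[!(corr >= template_corr_min)] <- "template_correlation"
  reason[!(amp >= amplitude_bounds_rel[1] * med_amp &
             amp <= amplitude_bounds_rel[2] * med_amp)] <- "amplitude_bound"
  reason[!(ibi >= ibi_bounds_s[1] & ibi <= ibi_bounds_s[2])] <- "interval_bound"
  beats$qualified <- is.na(reason)
  beats$rejection_reason <- reason
  if (sum(beats$qualified) < min_beats) {
    stop("qualify_beats: fewer than ", min_beats, " qualified beats; ",
         "recording unusable")
  }
  beats
}

# Median-beat template: every beat resampled to a fixed length, then the
# pointwise median. Length 50 covers a beat at any plausible heart rate.
beat_template <- function(x, beats, len = 50L) {
  mat <- vapply(seq_len(nrow(beats)), function(b) {
    resample_linear(x[beats$onset_idx[b]:(beats$end_idx[b] - 1L)], len)
  }, numeric(len))
  apply(mat, 1, stats::median)
}

resample_linear <- function(y, len) {
  if (length(y) == 1L) return(rep(y, len))
  stats::approx(seq_along(y), y, n = len)$y
}

#' Segment a recording end to end
#'
#' Convenience wrapper: [preprocess()], [detect_beat_onsets()],
#' [qualify_beats()] with thresholds from a `segment` config block.
#'
#' @param rec A raw [ppg_recording()].
#' @param seg Segment settings list (see [read_config()]); `NULL` uses the
#'   defaults of the individual steps.
#' @return List with `rec` (the preprocessed recording) and `beats`
#'   (qualified `ppg_beats`).
#' @export
segment_recording <- function(rec, seg = NULL) {
  seg <- seg %||% list()
  pre <- preprocess(rec)
  beats <- detect_beat_onsets(pre,
                              refractory_s = seg$refractory_s %||% 0.33,
                              min_beats = seg$min_beats %||% 10)
  beats <- qualify_beats(beats, pre,
                         ibi_bounds_s = seg$ibi_bounds_s %||% c(0.33, 2.0),
                         amplitude_bounds_rel = seg$amplitude_bounds_rel %||% c(0.25, 4.0),
                         template_corr_min = seg$template_corr_min %||% 0.5,
                         min_beats = seg$min_beats %||% 10)
  list(rec = pre, beats = beats)
}
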