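#' The fixed 42-feature morphometric catalog
#'
#' Returns the immutable catalog describing the 42 pulse-wave features
#' computed per qualified beat, in fixed order F01--F42. The catalog
#' covers eight families: timing, amplitude, slope, width, area, second
#' derivative (the a--e waves of the twice-differentiated pulse), shape,
#' and beat-context/respiratory variation. Changing this catalog is a
#' breaking change; its version is recorded in serialized models.
#'
#' @return A data.frame with columns `id`, `name`, `group`, `unit`,
#'   `definition` (42 rows).
#' @export
feature_catalog <- function() {
  def <- function(id, name, group, unit, definition) {
    data.frame(id = id, name = name, group = group, unit = unit,
               definition = definition, stringsAsFactors = FALSE)
  }
  out <- rbind(
    def("F01", "ibi", "timing", "s", "inter-beat interval (onset to next onset)"),
    def("F02", "inst_hr", "timing", "bpm", "instantaneous heart rate, 60/F01"),
    def("F03", "crest_time", "timing", "s", "foot to systolic peak"),
    def("F04", "systolic_ejection_time", "timing", "s", "foot to dicrotic notch"),
    def("F05", "diastolic_time", "timing", "s", "notch to end of beat"),
    def("F06", "sys_dia_ratio", "timing", "", "F04 / F05"),
    def("F07", "peak_to_notch_time", "timing", "s", "systolic peak to notch"),
    def("F08", "crest_time_fraction", "timing", "", "F03 / F01"),
    def("F09", "pulse_amplitude", "amplitude", "au", "peak minus foot"),
    def("F10", "notch_height_ratio", "amplitude", "", "(notch - foot) / F09"),
    def("F11", "diastolic_peak_ratio", "amplitude", "", "(max after notch - foot) / F09"),
    def("F12", "peak_notch_drop", "amplitude", "", "(peak - notch) / F09"),
    def("F13", "norm_beat_mean", "amplitude", "", "mean of foot-subtracted beat / F09"),
    def("F14", "norm_beat_rms", "amplitude", "", "RMS of foot-subtracted beat / F09"),
    def("F15", "max_systolic_slope", "slope", "au/s", "max first derivative, foot to peak"),
    def("F16", "mean_systolic_slope", "slope", "au/s", "F09 / F03"),
    def("F17", "max_diastolic_downslope", "slope", "au/s", "max |negative derivative| after peak"),
    def("F18", "mean_diastolic_slope", "slope", "au/s", "(notch - end foot) / F05"),
    def("F19", "slope_ratio", "slope", "", "F15 / F17"),
    def("F20", "norm_max_upslope", "slope", "1/s", "F15 / F09"),
    def("F21", "width_25", "width", "s", "full width at 25% of F09"),
    def("F22", "width_50", "width", "s", "full width at 50% of F09"),
    def("F23", "width_75", "width", "s", "full width at 75% of F09"),
    def("F24", "width50_sys_fraction", "width", "", "fraction of F22 before the peak"),
    def("F25", "width_ratio_75_25", "width", "", "F23 / F21"),
    def("F26", "norm_area", "area", "", "trapezoidal area of amplitude-normalized beat per second"),
    def("F27", "systolic_area_fraction", "area", "", "area foot-to-notch over total area"),
    def("F28", "inflection_area_ratio", "area", "", "post-notch over pre-notch area"),
    def("F29", "area_amp_duration_ratio", "area", "1/s", "F26 / F01"),
    def("F30", "sdppg_a", "second_derivative", "au/s^2", "a-wave amplitude of the second derivative"),
    def("F31", "sdppg_b_a", "second_derivative", "", "b/a ratio"),
    def("F32", "sdppg_c_a", "second_derivative", "", "c/a ratio"),
    def("F33", "sdppg_d_a", "second_derivative", "", "d/a ratio"),
    def("F34", "sdppg_e_a", "second_derivative", "", "e/a ratio"),
    def("F35", "aging_index", "second_derivative", "", "(b - c - d - e) / a"),
    def("F36", "n_peaks", "shape", "count", "local maxima with prominence >= 5% of F09"),
    def("F37", "skewness", "shape", "", "skewness of the normalized beat"),
    def("F38", "kurtosis", "shape", "", "excess kurtosis of the normalized beat"),
    def("F39", "amp_resp_deviation", "context", "", "relative amplitude deviation from +/-5-beat moving mean"),
    def("F40", "ibi_resp_deviation", "context", "", "relative IBI deviation from +/-5-beat moving mean"),
    def("F41", "amp_cv_local", "context", "", "amplitude CV over the +/-5-beat window"),
    def("F42", "template_correlation", "context", "", "correlation with the recording median-beat template")
  )
  stopifnot(nrow(out) == 42L, !anyDuplicated(out$id))
  out
}

feature_ids <- function() sprintf("F%02d", 1:42)

safe_div <- function(a, b) {
  out <- a / b
  out[!is.finite(out)] <- NA_real_
  out
}

# Interpolated full width of foot-subtracted beat y at level `frac * amp`.
# Returns c(width_s, t_up) or c(NA, NA) when the level is never reached.
width_at <- function(y, peak_rel, frac, amp, fs) {
  level <- frac * amp
  above <- which(y >= level)
  if (!length(above)) return(c(NA_real_, NA_real_))
  i_up <- above[1]
  i_dn <- above[length(above)]
  t_up <- if (i_up == 1L) 1 else cross_time(y, i_up - 1L, level)
  t_dn <- if (i_dn == length(y)) length(y) else cross_time(y, i_dn, level)
  c((t_dn - t_up) / fs, (t_up - 1) / fs)
}

# a--e wave amplitudes of the second derivative of one beat.
# a is the dominant early maximum (systolic upstroke acceleration);
# b..e are the subsequent alternating extrema up to early diastole.
# Missing waves yield NA (ratios are later imputed as 0).
sdppg_waves <- function(d2, peak_rel, stop_rel) {
  n <- length(d2)
  if (n < 5L) return(rep(NA_real_, 5))
  a_win <- seq_len(min(n, peak_rel + 3L))
  ia <- which.max(d2[a_win])
  out <- c(d2[ia], NA, NA, NA, NA)
  hi <- min(n, stop_rel)
  if (ia >= hi - 1L) return(out)
  seg <- d2[ia:hi]
  mx <- local_maxima(seg); mn <- local_minima(seg)
  pos <- 1L
  for (k in 2:5) {
    cand <- if (k %% 2 == 0) mn else mx      # b,d are minima; c,e maxima
    cand <- cand[cand > pos]
    if (!length(cand)) break
    pos <- cand[1]
    out[k] <- seg[pos]
  }
  out
}

#' Extract the 42-feature vector for one beat
#'
#' Computes the full catalog for a single beat window. Amplitudes are
#' taken after subtracting the beat's foot level; amplitude-normalized
#' features divide by the pulse amplitude (peak minus foot). Context
#' features (F39--F42) use the supplied neighbourhood statistics and are
#' zero/one for an isolated beat.
#'
#' @param beat One-row slice of a `ppg_beats` data.frame.
#' @param rec The matching (preprocessed) [ppg_recording()].
#' @param context Optional list with `amp_window_mean`, `ibi_window_mean`,
#'   `amp_window_cv` (from the centred +/-5 qualified-beat window),
#'   `template` (median-beat template) and optionally `ys` (precomputed
#'   smoothed foot-subtracted beat); `NULL` treats the beat as isolated.
#' @return Named numeric vector of length 42 (NA where a feature is not
#'   computable; see [extract_recording_bag()] for the imputation rule).
#' @export
extract_beat_features <- function(beat, rec, context = NULL) {
  x <- rec$samples
  fs <- rec$sampling_rate
  o <- beat$onset_idx; p <- beat$peak_idx; e <- beat$end_idx
  n_idx <- beat$notch_idx
  f <- stats::setNames(rep(NA_real_, 42L), feature_ids())

  y <- x[o:(min(e, length(x) + 1L) - 1L)] - x[o]
  x_end <- x[min(e, length(x))] - x[o]
  p_rel <- p - o + 1L
  amp <- y[p_rel]

  f["F01"] <- (e - o) / fs
  f["F02"] <- 60 / f["F01"]
  f["F03"] <- (p - o) / fs
  f["F08"] <- f["F03"] / f["F01"]
  f["F09"] <- amp
  f["F13"] <- safe_div(mean(y), amp)
  f["F14"] <- safe_div(sqrt(mean(y^2)), amp)

  dy <- diff(y) * fs
  if (p_rel > 1L) f["F15"] <- max(dy[seq_len(p_rel - 1L)])
  f["F16"] <- safe_div(amp, f["F03"])
  if (p_rel < length(y)) f["F17"] <- max(-dy[p_rel:length(dy)])
  f["F19"] <- safe_div(f["F15"], f["F17"])
  f["F20"] <- safe_div(f["F15"], amp)

  if (is.finite(amp) && amp > 0) {
    w25 <- width_at(y, p_rel, 0.25, amp, fs)
    w50 <- width_at(y, p_rel, 0.50, amp, fs)
    w75 <- width_at(y, p_rel, 0.75, amp, fs)
    f["F21"] <- w25[1]; f["F22"] <- w50[1]; f["F23"] <- w75[1]
    f["F24"] <- safe_div(f["F03"] - w50[2], f["F22"])
    f["F25"] <- safe_div(f["F23"], f["F21"])
  }

  dt <- 1 / fs
  area_tot <- sum((y[-1] + y[-length(y)]) / 2) * dt
  f["F26"] <- safe_div(safe_div(area_tot, amp), f["F01"])
  f["F29"] <- f["F26"] / f["F01"]

  if (!is.na(n_idx) && n_idx > p && n_idx < e) {
    n_rel <- n_idx - o + 1L
    f["F04"] <- (n_idx - o) / fs
    f["F05"] <- (e - n_idx) / fs
    f["F06"] <- f["F04"] / f["F05"]
    f["F07"] <- (n_idx - p) / fs
    f["F10"] <- safe_div(y[n_rel], amp)
    f["F11"] <- safe_div(max(y[n_rel:length(y)]), amp)
    f["F12"] <- safe_div(amp - y[n_rel], amp)
    f["F18"] <- (y[n_rel] - x_end) / f["F05"]
    area_pre <- sum((y[2:n_rel] + y[1:(n_rel - 1L)]) / 2) * dt
    f["F27"] <- safe_div(area_pre, area_tot)
    f["F28"] <- safe_div(area_tot - area_pre, area_pre)
  }

  ys <- context$ys %||% smooth_sg(y)
  d2 <- diff(diff(ys)) * fs^2
  stop_rel <- if (!is.na(n_idx)) n_idx - o + 4L else round(0.7 * length(y))
  waves <- sdppg_waves(d2, p_rel, stop_rel)
  if (is.finite(waves[1]) && waves[1] != 0) {
    f["F30"] <- waves[1]
    rat <- waves[2:5] / waves[1]
    rat[!is.finite(rat)] <- 0
    f["F31"] <- rat[1]; f["F32"] <- rat[2]
    f["F33"] <- rat[3]; f["F34"] <- rat[4]
    f["F35"] <- (ifelse(is.na(waves[2]), 0, waves[2]) -
                   sum(ifelse(is.na(waves[3:5]), 0, waves[3:5]))) / waves[1]
  }

  if (is.finite(amp) && amp > 0) {
    # Peak counting uses the wide-band channel when available: the
    # narrow pass band used for onset detection merges closely spaced
    # systolic/dome/diastolic crests.
    yw <- context$yw %||% ys
    mx <- local_maxima(yw)
    if (length(mx)) {
      prom <- peak_prominence(yw, mx)
      f["F36"] <- sum(prom >= 0.05 * amp)
    } else f["F36"] <- 0
    f["F37"] <- sample_skewness(y)
    f["F38"] <- sample_kurtosis(y)
  }

  if (is.null(context)) {
    f["F39"] <- 0; f["F40"] <- 0; f["F41"] <- 0; f["F42"] <- 1
  } else {
    f["F39"] <- safe_div(amp - context$amp_window_mean, context$amp_window_mean)
    f["F40"] <- safe_div(f["F01"] - context$ibi_window_mean,
                         context$ibi_window_mean)
    f["F41"] <- context$amp_window_cv
    tmpl <- context$template
    rs <- resample_linear(y, length(tmpl))
    f["F42"] <- if (stats::sd(rs) > 0 && stats::sd(tmpl) > 0) {
      stats::cor(rs, tmpl)
    } else 0
  }
  f
}

#' Extract the feature bag for one recording
#'
#' Computes the 42-feature vector for every qualified beat (the
#' "instances" of the recording's bag), with centred +/-5-beat context
#' windows over qualified beats and per-recording mean imputation of
#' entries that could not be computed (absent notch with failed fallback,
#' degenerate denominators). A feature invalid in every beat is imputed
#' as zero.
#'
#' @param rec A preprocessed [ppg_recording()].
#' @param beats Qualified `ppg_beats` from [qualify_beats()]; `NULL` runs
#'   [segment_recording()] first (on the raw recording).
#' @param min_beats Minimum number of qualified beats (default 10).
#' @return A numeric matrix (beats x 42) of class `ppg_bag` with
#'   attributes `subject_id`, `recording_id`, `label`, `n_invalid`
#'   (count of imputed entries).
#' @export
extract_recording_bag <- function(rec, beats = NULL, min_beats = 10) {
  if (is.null(beats)) {
    seg <- segment_recording(rec)
    rec <- seg$rec; beats <- seg$beats
  }
  q <- beats[beats$qualified %in% TRUE, , drop = FALSE]
  if (nrow(q) < min_beats) {
    stop("extract_recording_bag: fewer than ", min_beats,
         " qualified beats; recording unusable")
  }
  x <- rec$samples
  fs <- rec$sampling_rate
  amps <- x[q$peak_idx] - x[q$onset_idx]
  ibis <- (q$end_idx - q$onset_idx) / fs
  tmpl <- beat_template(x, q)
  nb <- nrow(q)
  xs_all <- smooth_sg(x)   # one whole-recording smoothing pass
  xw_all <- if (is.null(rec$notch_ref)) NULL else smooth_sg(rec$notch_ref)

  mat <- matrix(NA_real_, nb, 42L, dimnames = list(NULL, feature_ids()))
  for (b in seq_len(nb)) {
    win <- max(1L, b - 5L):min(nb, b + 5L)
    o <- q$onset_idx[b]; e <- q$end_idx[b]
    ctx <- list(amp_window_mean = mean(amps[win]),
                ibi_window_mean = mean(ibis[win]),
                amp_window_cv = if (length(win) > 1L) {
                  stats::sd(amps[win]) / mean(amps[win])
                } else 0,
                template = tmpl,
                ys = xs_all[o:(e - 1L)] - x[o],
                yw = if (is.null(xw_all)) NULL else {
                  xw_all[o:(e - 1L)] - rec$notch_ref[o]
                })
    beat <- list(onset_idx = o, peak_idx = q$peak_idx[b],
                 notch_idx = q$notch_idx[b], end_idx = e)
    mat[b, ] <- extract_beat_features(beat, rec, ctx)
  }

  n_invalid <- sum(is.na(mat))
  for (j in seq_len(ncol(mat))) {
    bad <- is.na(mat[, j])
    if (any(bad)) {
      mat[bad, j] <- if (all(bad)) 0 else mean(mat[!bad, j])
    }
  }
  structure(mat, class = c("ppg_bag", class(mat)),
            subject_id = rec$subject_id, recording_id = rec$recording_id,
            label = rec$label, n_invalid = n_invalid)
}

#' Extract bags for a whole cohort
#'
#' Runs segmentation and feature extraction over every recording of a
#' [synth_cohort()] result (or any list of recordings), dropping
#' unusable recordings with a warning.
#'
#' @param cohort A `ppg_cohort`, or list with element `recordings`.
#' @param seg Segment settings list (see [read_config()]).
#' @return A list of class `ppg_bags`: `bags` (list of feature matrices),
#'   `meta` (data.frame: `subject_id`, `recording_id`, `label`,
#'   `n_beats`).
#' @export
extract_cohort_bags <- function(cohort, seg = NULL) {
  recs <- cohort$recordings %||% cohort
  bags <- list(); meta <- list()
  for (rid in names(recs)) {
    bag <- tryCatch({
      sg <- segment_recording(recs[[rid]], seg)
      extract_recording_bag(sg$rec, sg$beats,
                            min_beats = (seg$min_beats %||% 10))
    }, error = function(e) {
      warning("dropping unusable recording ", rid, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(bag)) next
    bags[[rid]] <- bag
    meta[[rid]] <- data.frame(subject_id = attr(bag, "subject_id"),
                              recording_id = rid,
                              label = attr(bag, "label"),
                              n_beats = nrow(bag),
                              stringsAsFactors = FALSE)
  }
  structure(list(bags = bags,
                 meta = do.call(rbind, c(meta, make.row.names = FALSE))),
            class = "ppg_bags")
}
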