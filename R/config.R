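#' Read a pipeline configuration file
#'
#' Loads a YAML configuration describing the synthetic cohorts, the
#' segmentation thresholds and the cross-validation settings, validating
#' every key. Unknown keys are rejected so that typos in a config never
#' pass silently.
#'
#' @param path Path to a YAML file, or one of the packaged regime names
#'   `"paper_regime"` / `"null_regime"`.
#' @return A list of class `pipeline_config` with elements `name`, `seed`,
#'   `synth` (list with `healthy` and `ohcm` [cohort_params()]),
#'   `segment` (threshold list) and `cv` (tuning/CV settings), plus a
#'   `config_hash` provenance string.
#' @export
read_config <- function(path) {
  if (path %in% c("paper_regime", "null_regime")) {
    path <- system.file("extdata", paste0(path, ".yaml"),
                        package = "ppgmiles", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  allowed_top <- c("name", "seed", "synth", "segment", "cv")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    stop("read_config: unknown top-level keys: ", paste(unknown, collapse = ", "))
  }
  for (req in allowed_top) {
    if (is.null(raw[[req]])) stop("read_config: missing key '", req, "'")
  }

  parse_shape <- function(x) {
    allowed <- c("crest_time", "notch_time", "pulse_amplitude", "notch_ratio",
                 "diastolic_peak_ratio", "mid_systolic_bump_amplitude",
                 "component_widths", "bump_position")
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("read_config: unknown beat_shape keys: ",
           paste(unknown, collapse = ", "))
    }
    cw <- unlist(x$component_widths)
    do.call(beat_shape, c(x[setdiff(names(x), "component_widths")],
                          list(component_widths = cw)))
  }
  parse_class <- function(x) {
    allowed <- c("n_subjects", "hr_mean", "hr_sd", "recordings_per_subject",
                 "recording_duration", "sampling_rate", "beat_to_beat_cv",
                 "ibi_cv", "resp_rate", "resp_amplitude_mod",
                 "resp_baseline_mod", "irregular_beat_prob", "noise_sd",
                 "beat_shape")
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("read_config: unknown cohort keys: ", paste(unknown, collapse = ", "))
    }
    x$beat_shape <- parse_shape(x$beat_shape)
    x$recordings_per_subject <- unlist(x$recordings_per_subject)
    do.call(cohort_params, c(x, list(seed = raw$seed)))
  }

  seg_allowed <- c("refractory_s", "ibi_bounds_s", "amplitude_bounds_rel",
                   "template_corr_min", "min_beats")
  unknown <- setdiff(names(raw$segment), seg_allowed)
  if (length(unknown)) {
    stop("read_config: unknown segment keys: ", paste(unknown, collapse = ", "))
  }
  cv_allowed <- c("inner_splits", "inner_train_frac", "n_boot", "pool_cap",
                  "tuning_pool_cap", "sigma_grid", "lambda_grid")
  unknown <- setdiff(names(raw$cv), cv_allowed)
  if (length(unknown)) {
    stop("read_config: unknown cv keys: ", paste(unknown, collapse = ", "))
  }
  seg <- lapply(raw$segment, unlist)
  cv <- lapply(raw$cv, unlist)
  stopifnot(cv$inner_train_frac > 0, cv$inner_train_frac < 1,
            cv$inner_splits >= 1, cv$pool_cap >= 1)

  cfg <- list(name = raw$name,
              seed = as.integer(raw$seed),
              synth = list(healthy = parse_class(raw$synth$healthy),
                           ohcm = parse_class(raw$synth$ohcm)),
              segment = seg,
              cv = cv)
  cfg$config_hash <- config_hash(raw)
  class(cfg) <- "pipeline_config"
  cfg
}

# Cheap deterministic provenance hash of the configuration contents
# (FNV-1a over the serialized key=value text).
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config '%s' seed=%d hash=%s>\n",
              x$name, x$seed, x$config_hash))
  invisible(x)
}
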