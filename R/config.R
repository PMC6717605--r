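#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis chain. Defaults encode
#' the published processing constants (0.1 Hz second-order high-pass,
#' 1000 Hz low-pass, 20% validation split, 10,000 Monte-Carlo iterations,
#' participant scores over up to 4 thin / 3 thicker boluses) together with
#' this package's own choices for the under-specified stages
#' (segmentation thresholds, feature set, shrinkage selection, operating
#' point).
#'
#' @param hp_corner_hz High-pass corner frequency in Hz. Removes sensor
#'   offset and baseline drift.
#' @param hp_order High-pass Butterworth order (applied forward-backward,
#'   so the effective attenuation is doubled).
#' @param lp_corner_hz Low-pass corner frequency in Hz.
#' @param lp_order Low-pass Butterworth order.
#' @param seg_window_ms RMS energy-envelope window, milliseconds.
#' @param seg_k_high Hysteresis entry threshold in robust (MAD) units
#'   above the envelope median.
#' @param seg_k_low Hysteresis exit threshold in MAD units.
#' @param seg_min_duration_ms Minimum segment duration, milliseconds.
#' @param seg_merge_gap_ms Segments closer than this gap are merged.
#' @param feature_set Feature-set selector; currently `"standard"` (30
#'   features, see [extract_features()]).
#' @param aggregate How multiple segments within one bolus trial are
#'   combined into a single feature row: `"mean"` or `"none"`
#'   (one row per segment).
#' @param shrinkage Shrinkage coefficient lambda in \[0, 1\] for the
#'   regularized LDA covariance, or `NULL` to select it analytically per
#'   fit (see [select_shrinkage()]).
#' @param priors Class priors for the discriminant: `"frequency"`
#'   (training-set frequencies) or `"equal"`.
#' @param n_iterations Monte-Carlo repetitions of the random
#'   participant-stratified split.
#' @param validation_fraction Fraction of participants set aside for
#'   validation at each iteration.
#' @param specificity_target Training-set specificity at which the
#'   operating point (decision threshold) is fixed.
#' @param bolus_cap_thin,bolus_cap_other Maximum number of boluses (in
#'   protocol order) entering the participant-level mean probability for
#'   thin and for thicker consistencies.
#' @param combined_moderate_training Include extremely thick boluses in
#'   the training pool of the moderately-thick safety classifier
#'   (validation stays moderately thick only).
#' @param seed Master seed for every stochastic step; `NULL` leaves the
#'   RNG state alone.
#'
#' @return An object of class `sws_config` (a named list).
#' @export
pipeline_config <- function(hp_corner_hz = 0.1,
                            hp_order = 2L,
                            lp_corner_hz = 1000,
                            lp_order = 4L,
                            seg_window_ms = 50,
                            seg_k_high = 5,
                            seg_k_low = 2,
                            seg_min_duration_ms = 200,
                            seg_merge_gap_ms = 300,
                            feature_set = "standard",
                            aggregate = "mean",
                            shrinkage = NULL,
                            priors = "frequency",
                            n_iterations = 10000L,
                            validation_fraction = 0.2,
                            specificity_target = 0.60,
                            bolus_cap_thin = 4L,
                            bolus_cap_other = 3L,
                            combined_moderate_training = TRUE,
                            seed = NULL) {
  cfg <- list(
    hp_corner_hz = as.numeric(hp_corner_hz),
    hp_order = as.integer(hp_order),
    lp_corner_hz = as.numeric(lp_corner_hz),
    lp_order = as.integer(lp_order),
    seg_window_ms = as.numeric(seg_window_ms),
    seg_k_high = as.numeric(seg_k_high),
    seg_k_low = as.numeric(seg_k_low),
    seg_min_duration_ms = as.numeric(seg_min_duration_ms),
    seg_merge_gap_ms = as.numeric(seg_merge_gap_ms),
    feature_set = match.arg(feature_set, c("standard")),
    aggregate = match.arg(aggregate, c("mean", "none")),
    shrinkage = if (is.null(shrinkage)) NULL else as.numeric(shrinkage),
    priors = match.arg(priors, c("frequency", "equal")),
    n_iterations = as.integer(n_iterations),
    validation_fraction = as.numeric(validation_fraction),
    specificity_target = as.numeric(specificity_target),
    bolus_cap_thin = as.integer(bolus_cap_thin),
    bolus_cap_other = as.integer(bolus_cap_other),
    combined_moderate_training = isTRUE(combined_moderate_training),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sws_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config An `sws_config` object.
#' @param fs Optional sampling rate in Hz; when given, filter corners are
#'   checked against the Nyquist frequency.
#' @export
validate_config <- function(config, fs = NULL) {
  stopifnot(inherits(config, "sws_config"))
  if (config$validation_fraction <= 0 || config$validation_fraction >= 1) {
    stop_config("validation_fraction must lie strictly between 0 and 1")
  }
  if (config$n_iterations < 1L) {
    stop_config("n_iterations must be >= 1")
  }
  if (config$hp_corner_hz <= 0 || config$lp_corner_hz <= 0) {
    stop_config("filter corner frequencies must be positive")
  }
  if (config$hp_order < 1L || config$lp_order < 1L) {
    stop_config("filter orders must be >= 1")
  }
  if (!is.null(config$shrinkage) &&
      (config$shrinkage < 0 || config$shrinkage > 1)) {
    stop_config("shrinkage must lie in [0, 1]")
  }
  if (config$specificity_target <= 0 || config$specificity_target > 1) {
    stop_config("specificity_target must lie in (0, 1]")
  }
  if (config$bolus_cap_thin < 1L || config$bolus_cap_other < 1L) {
    stop_config("bolus caps must be >= 1")
  }
  if (!is.null(fs)) {
    if (config$lp_corner_hz >= fs / 2 || config$hp_corner_hz >= fs / 2) {
      stop_config(sprintf(
        "filter corner at or above Nyquist (fs = %g Hz)", fs))
    }
  }
  invisible(config)
}

#' Read a configuration file
#'
#' The file is a flat `key = value` list; keys mirror the arguments of
#' [pipeline_config()]. Unknown keys are an error; missing keys keep
#' their defaults. `shrinkage = auto` requests analytic selection.
#'
#' @param path Path to the configuration file.
#' @return An `sws_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- formals(pipeline_config)
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_config(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) {
      stop_config(sprintf("unknown config key: '%s'", key))
    }
    args[[key]] <- if (key %in% c("feature_set", "aggregate", "priors")) {
      val
    } else if (key == "shrinkage" && identical(val, "auto")) {
      NULL
    } else if (key == "combined_moderate_training") {
      as.logical(val)
    } else {
      as.numeric(val)
    }
  }
  do.call(pipeline_config, args)
}

#' @export
print.sws_config <- function(x, ...) {
  cat("<sws_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "auto" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
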