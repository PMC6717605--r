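#' RMS energy envelope of a two-axis recording
#'
#' Windowed root-mean-square of the Euclidean magnitude of the two
#' axes: `env[i] = sqrt(mean((si^2 + ap^2)[window around i]))` with a
#' centered window. Output length equals input length (the window is
#' truncated at the edges).
#'
#' @param rec An [recording()].
#' @param window_ms Window length in milliseconds.
#' @return Non-negative numeric vector, same length as the recording.
#' @export
energy_envelope <- function(rec, window_ms = 50) {
  stopifnot(inherits(rec, "sws_recording"))
  if (window_ms <= 0) stop_config("window_ms must be positive")
  n <- length(rec$si)
  w <- max(1L, round(rec$fs * window_ms / 1000))
  if (w > n) stop_data("envelope window longer than the recording")
  mag2 <- rec$si^2 + rec$ap^2
  cs <- c(0, cumsum(mag2))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment regions of swallow activity
#'
#' Dual-threshold hysteresis on the RMS energy envelope: a candidate
#' region is a run of envelope samples above the exit threshold that
#' contains at least one sample above the entry threshold. Thresholds
#' are set robustly at `median(env) + k * mad(env)` with `k =
#' seg_k_high` (entry) and `seg_k_low` (exit); the median/MAD baseline
#' is insensitive to the bursts themselves while they occupy a minority
#' of the trial. Regions closer than `seg_merge_gap_ms` are merged, and
#' regions shorter than `seg_min_duration_ms` are discarded. The
#' procedure is deterministic and channel-synchronous (one segmentation
#' for both axes).
#'
#' @param rec A preprocessed [recording()].
#' @param config An [pipeline_config()].
#' @return A data.frame of class `sws_segments` with columns `start`,
#'   `end` (half-open sample indices, 1-based start), `start_s`,
#'   `end_s`; attribute `trial_id`.
#' @export
segment_swallows <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "sws_recording"))
  env <- energy_envelope(rec, config$seg_window_ms)
  base_med <- stats::median(env)
  base_mad <- stats::mad(env)
  enter <- base_med + config$seg_k_high * base_mad
  exit <- base_med + config$seg_k_low * base_mad
  above_low <- env >= exit
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (any(env[s:e] >= enter)) segs[[length(segs) + 1L]] <- c(s, e + 1L)
  }
  segs <- do.call(rbind, segs)
  fs <- rec$fs
  if (!is.null(segs)) {
    # merge regions separated by less than the merge gap
    gap <- round(fs * config$seg_merge_gap_ms / 1000)
    merged <- segs[1, , drop = FALSE]
    if (nrow(segs) > 1) {
      for (i in 2:nrow(segs)) {
        last <- nrow(merged)
        if (segs[i, 1] - merged[last, 2] < gap) {
          merged[last, 2] <- segs[i, 2]
        } else {
          merged <- rbind(merged, segs[i, ])
        }
      }
    }
    min_len <- round(fs * config$seg_min_duration_ms / 1000)
    merged <- merged[(merged[, 2] - merged[, 1]) >= min_len, , drop = FALSE]
    segs <- merged
  }
  if (is.null(segs) || nrow(segs) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      start_s = numeric(), end_s = numeric())
  } else {
    out <- data.frame(start = segs[, 1], end = segs[, 2],
                      start_s = (segs[, 1] - 1) / fs,
                      end_s = (segs[, 2] - 1) / fs)
  }
  attr(out, "trial_id") <- rec$trial_id
  class(out) <- c("sws_segments", "data.frame")
  out
}
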