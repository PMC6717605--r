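#' Dual-axis accelerometry recording
#'
#' One two-channel neck-surface acceleration time series for a single
#' bolus trial. The hardware samples both the superior-inferior (SI) and
#' anterior-posterior (AP) axes at 10 kHz through a 12-bit converter;
#' samples are stored as calibrated floating point because the
#' calibration units are device-specific and the pipeline is
#' unit-agnostic.
#'
#' @param si,ap Numeric vectors, SI and AP axis samples. Equal length,
#'   finite, non-empty.
#' @param fs Sampling rate in Hz.
#' @param bit_depth Converter resolution, metadata only.
#' @param trial_id Opaque trial identifier.
#' @return An object of class `sws_recording`.
#' @export
recording <- function(si, ap, fs = 10000, bit_depth = 12L,
                      trial_id = "trial") {
  si <- as.numeric(si); ap <- as.numeric(ap)
  if (length(si) == 0L) stop_data("recording channels must be non-empty")
  if (length(si) != length(ap)) {
    stop_data("si and ap channels must have the same length")
  }
  if (!all(is.finite(si)) || !all(is.finite(ap))) {
    stop_data("recording samples must be finite")
  }
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop_data("fs must be a positive number")
  structure(list(si = si, ap = ap, fs = fs,
                 bit_depth = as.integer(bit_depth),
                 trial_id = as.character(trial_id)),
            class = "sws_recording")
}

#' @export
print.sws_recording <- function(x, ...) {
  cat(sprintf("<sws_recording '%s'> %d samples x 2 axes @ %g Hz (%d-bit)\n",
              x$trial_id, length(x$si), x$fs, x$bit_depth))
  invisible(x)
}

#' @export
length.sws_recording <- function(x) length(x$si)

#' Read / write recording files
#'
#' The on-disk dialect is plain delimited text: a small `#`-prefixed
#' header (`fs_hz`, `bit_depth`, `trial_id`) followed by a two-column
#' CSV body with columns `si` and `ap`. Samples are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param path File path.
#' @return `read_recording` returns an `sws_recording`;
#'   `write_recording` returns `path` invisibly.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("recording file not found: %s", path))
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop_data(sprintf("%s: truncated recording file", path))
    if (!startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  cols <- strsplit(ln, ",", fixed = TRUE)[[1]]
  if (!identical(trimws(cols), c("si", "ap"))) {
    stop_data(sprintf("%s: recording body must have exactly columns si,ap", path))
  }
  body <- data.table::fread(path, skip = length(hdr) + 1L, header = FALSE,
                            sep = ",", col.names = c("si", "ap"),
                            colClasses = "numeric", showProgress = FALSE)
  fs <- suppressWarnings(as.numeric(meta[["fs_hz"]]))
  if (is.na(fs) || length(fs) == 0L || fs <= 0) {
    stop_data(sprintf("%s: missing or non-positive fs_hz header", path))
  }
  recording(body$si, body$ap, fs = fs,
            bit_depth = if (is.null(meta[["bit_depth"]])) 12L
                        else as.integer(meta[["bit_depth"]]),
            trial_id = if (is.null(meta[["trial_id"]])) "trial"
                       else meta[["trial_id"]])
}

#' @rdname read_recording
#' @param rec An `sws_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sws_recording"))
  hdr <- c("# swallowscreen-recording v1",
           sprintf("# fs_hz=%s", format(rec$fs, digits = 17)),
           sprintf("# bit_depth=%d", rec$bit_depth),
           sprintf("# trial_id=%s", rec$trial_id),
           "si,ap")
  body <- paste(sprintf("%.17g", rec$si), sprintf("%.17g", rec$ap), sep = ",")
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data(sprintf("cannot write recording to %s", path))
  invisible(path)
}
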