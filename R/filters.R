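#' Digital Butterworth filter coefficients
#'
#' Designs a low-pass or high-pass digital Butterworth filter by the
#' bilinear transform with corner prewarping, so the -3 dB point of the
#' digital filter lands exactly at `corner_hz`. Returns transfer
#' function coefficients `b` (numerator) and `a` (denominator,
#' `a[1] = 1`).
#'
#' @param order Filter order (poles of the analog prototype).
#' @param corner_hz Corner (-3 dB) frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numeric vectors `b` and `a`.
#' @export
butter_coeffs <- function(order, corner_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (corner_hz <= 0 || corner_hz >= fs / 2) {
    stop_config(sprintf("corner %g Hz outside (0, Nyquist = %g Hz)",
                        corner_hz, fs / 2))
  }
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * fs * tan(pi * corner_hz / fs)
  if (type == "low") {
    p <- warped * p
    z <- complex(0)
    gain <- warped^n
  } else {
    z <- rep(0 + 0i, n)
    p <- warped / p
    gain <- 1
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # pad zeros at z = -1 to match pole count
  zd <- c(zd, rep(-1 + 0i, n - length(zd)))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  # normalize exact unity at DC (low) / Nyquist (high)
  ref <- if (type == "low") sum(b) / sum(a) else
    sum(b * (-1)^(seq_along(b) - 1)) / sum(a * (-1)^(seq_along(a) - 1))
  list(b = b / ref, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# single-pass IIR filter y: a(z) Y = b(z) X, zero initial conditions
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                                sides = 1))
  v <- v[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and then backward so the net phase is
#' zero and the magnitude response is squared. Signal ends are padded
#' with an odd reflection to suppress edge transients.
#'
#' @param b,a Transfer function coefficients (see [butter_coeffs()]).
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_butter <- function(b, a, x) {
  n <- length(x)
  np <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  if (np > 0) {
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

#' Preprocess a recording
#'
#' Both axes are filtered identically: a high-pass Butterworth (default
#' second order, 0.1 Hz corner) removes offset and baseline drift, then
#' a low-pass Butterworth (default fourth order, 1000 Hz corner)
#' restricts the band to the swallow vibration content. Both filters
#' run forward-backward ([filtfilt_butter()]), avoiding group-delay
#' misalignment between the envelope and swallow events; the quoted
#' orders are the single-pass orders.
#'
#' @param rec An [recording()].
#' @param config An [pipeline_config()].
#' @return A filtered `sws_recording` of the same length, with
#'   attribute `filtered = TRUE`.
#' @export
preprocess <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "sws_recording"))
  validate_config(config, fs = rec$fs)
  if (rec$fs <= 2 * config$lp_corner_hz) {
    stop_config(sprintf(
      "sampling rate %g Hz too low for low-pass corner %g Hz",
      rec$fs, config$lp_corner_hz))
  }
  hp <- butter_coeffs(config$hp_order, config$hp_corner_hz, rec$fs, "high")
  lp <- butter_coeffs(config$lp_order, config$lp_corner_hz, rec$fs, "low")
  run <- function(x) {
    filtfilt_butter(lp$b, lp$a, filtfilt_butter(hp$b, hp$a, x))
  }
  out <- recording(run(rec$si), run(rec$ap), fs = rec$fs,
                   bit_depth = rec$bit_depth, trial_id = rec$trial_id)
  attr(out, "filtered") <- TRUE
  out
}

#' Analytic Butterworth magnitude response
#'
#' Closed-form magnitude of an order-`n` analog Butterworth filter,
#' `1/sqrt(1 + (f/fc)^(2n))` for a low-pass and the mirrored form for a
#' high-pass. Used as the independent oracle for the filtering stage;
#' forward-backward application squares the magnitude.
#'
#' @param f Frequencies in Hz.
#' @param corner_hz Corner frequency.
#' @param order Filter order.
#' @param type `"low"` or `"high"`.
#' @return Magnitude response in \[0, 1\].
#' @export
butter_magnitude <- function(f, corner_hz, order, type = c("low", "high")) {
  type <- match.arg(type)
  ratio <- if (type == "low") f / corner_hz else corner_hz / f
  1 / sqrt(1 + ratio^(2 * order))
}
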