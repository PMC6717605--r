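# Daubechies-4 (8-tap) scaling filter; the wavelet filter is the
# quadrature mirror. Used for the relative subband energy features.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

# one periodized DWT step; x length must be even
dwt_step <- function(x, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- length(x)
  idx <- outer(seq(0, n - 2, by = 2), seq_along(h) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

#' Multi-level discrete wavelet subband energies
#'
#' Periodized db4 DWT; returns the energy in each detail band
#' `d1..dL` (finest to coarsest) and the final approximation, either
#' raw or relative to the total. Signals with odd length at any level
#' are extended by repeating the last sample.
#'
#' @param x Numeric signal.
#' @param levels Number of decomposition levels.
#' @param relative Normalize energies to sum over all subbands.
#' @return Numeric vector `d1..dL` (relative energies omit the
#'   approximation band from the output but not from the total).
#' @export
wavelet_subband_energies <- function(x, levels = 5L, relative = TRUE) {
  a <- x
  energies <- numeric(levels)
  for (l in seq_len(levels)) {
    if (length(a) < 2L) {
      a <- c(a, rep(a[length(a)], 2L - length(a) + 1L))
    }
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    st <- dwt_step(a, DB4_H)
    energies[l] <- sum(st$detail^2)
    a <- st$approx
  }
  approx_energy <- sum(a^2)
  if (relative) {
    total <- sum(energies) + approx_energy
    if (total <= 0) return(rep(0, levels))
    energies <- energies / total
  }
  names(energies) <- paste0("d", seq_len(levels))
  energies
}

axis_features <- function(x, fs) {
  n <- length(x)
  dur <- n / fs
  xc <- x - mean(x)
  v <- mean(xc^2)
  out <- c(energy = sum(x^2) / dur, variance = v)
  if (v > 0) {
    out["skewness"] <- mean(xc^3) / v^1.5
    out["kurtosis"] <- mean(xc^4) / v^2 - 3
    out["zcr"] <- sum(diff(sign(ifelse(xc == 0, 1, xc))) != 0) / dur
    # one-sided periodogram, DC excluded
    nf <- n %/% 2L
    P <- Mod(stats::fft(xc))[2:(nf + 1L)]^2
    f <- (1:nf) * fs / n
    tp <- sum(P)
    cen <- sum(f * P) / tp
    out["spec_centroid"] <- cen
    out["spec_bandwidth"] <- sqrt(sum((f - cen)^2 * P) / tp)
    out["peak_freq"] <- f[which.max(P)]
    p <- P / tp
    p <- p[p > 0]
    out["spec_entropy"] <- -sum(p * log(p)) / log(nf)
    wav <- wavelet_subband_energies(xc, 5L)
  } else {
    # degenerate (constant) segment: moments and spectral shape by
    # convention zero
    out[c("skewness", "kurtosis", "zcr", "spec_centroid",
          "spec_bandwidth", "peak_freq", "spec_entropy")] <- 0
    wav <- rep(0, 5L)
  }
  names(wav) <- paste0("wav_e", 1:5)
  c(out, wav)
}

#' Feature names of a configuration
#'
#' @param config An [pipeline_config()].
#' @return Character vector of feature names in their fixed order.
#' @export
feature_names <- function(config = pipeline_config()) {
  per_axis <- c("energy", "variance", "skewness", "kurtosis", "zcr",
                "spec_centroid", "spec_bandwidth", "peak_freq",
                "spec_entropy", paste0("wav_e", 1:5))
  c(paste0("si_", per_axis), paste0("ap_", per_axis), "xcorr", "duration_s")
}

#' Extract the feature vector of one segment
#'
#' The default ("standard") set has 30 features: per axis,
#' duration-normalized energy, variance, skewness, excess kurtosis,
#' zero-crossing rate (crossings/s), spectral centroid, spectral
#' bandwidth, peak frequency, normalized spectral entropy and five db4
#' relative wavelet subband energies (14 each); plus the cross-axis
#' Pearson correlation and the segment duration in seconds. Degenerate
#' (constant) segments return zeros for moments, spectral shape and
#' correlation by convention, keeping every value finite.
#'
#' @param rec A (preprocessed) [recording()].
#' @param segment One row of [segment_swallows()] output, or any list
#'   with `start` and `end` half-open sample indices.
#' @param config An [pipeline_config()].
#' @return Named numeric vector of length 30.
#' @export
extract_features <- function(rec, segment, config = pipeline_config()) {
  stopifnot(inherits(rec, "sws_recording"))
  s <- as.integer(segment$start); e <- as.integer(segment$end)
  if (is.na(s) || is.na(e) || s < 1L || e <= s || e > length(rec$si) + 1L) {
    stop_data("segment indices outside the recording")
  }
  si <- rec$si[s:(e - 1L)]
  ap <- rec$ap[s:(e - 1L)]
  fsi <- axis_features(si, rec$fs)
  fap <- axis_features(ap, rec$fs)
  xc <- if (stats::sd(si) > 0 && stats::sd(ap) > 0) {
    stats::cor(si, ap)
  } else 0
  out <- c(stats::setNames(fsi, paste0("si_", names(fsi))),
           stats::setNames(fap, paste0("ap_", names(fap))),
           xcorr = xc, duration_s = length(si) / rec$fs)
  out[feature_names(config)]
}

#' Assemble the feature table of a cohort
#'
#' For every trial with a recording: preprocess, segment, extract
#' features per segment, and (by default) average feature-wise over the
#' segments of the trial so the classifier sees one row per bolus.
#' Trials whose segmentation finds no swallow activity are dropped with
#' a warning. Rows carry participant, consistency, bolus order and the
#' derived labels, which is what the participant-stratified evaluation
#' needs.
#'
#' @param x An `sws_cohort` whose trials reference recordings (via the
#'   `recordings` list or `recording_path` sidecar files).
#' @param config An [pipeline_config()].
#' @param base_dir Directory against which relative `recording_path`
#'   values resolve.
#' @return A data.frame of class `sws_features`: metadata columns
#'   `participant_id`, `consistency`, `bolus_index`, `segment`,
#'   `safety_label`, `efficiency_label`, then the feature columns
#'   (attribute `feature_names`).
#' @export
build_feature_table <- function(x, config = pipeline_config(),
                                base_dir = ".") {
  stopifnot(inherits(x, "sws_cohort"))
  if (!"safety_label" %in% names(x$trials)) x <- derive_labels(x)
  tr <- x$trials
  fn <- feature_names(config)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(tr))) {
    key <- trial_key(tr$participant_id[i], tr$consistency[i],
                     tr$bolus_index[i])
    rec <- NULL
    if (!is.null(x$recordings) && !is.null(x$recordings[[key]])) {
      rec <- x$recordings[[key]]
    } else if (!is.na(tr$recording_path[i])) {
      rp <- tr$recording_path[i]
      full <- if (file.exists(rp)) rp else file.path(base_dir, rp)
      rec <- read_recording(full)
    }
    if (is.null(rec)) next
    filt <- preprocess(rec, config)
    segs <- segment_swallows(filt, config)
    if (nrow(segs) == 0L) {
      dropped <- dropped + 1L
      next
    }
    fmat <- t(vapply(seq_len(nrow(segs)), function(j) {
      extract_features(filt, segs[j, ], config)
    }, numeric(length(fn))))
    meta <- tr[i, c("participant_id", "consistency", "bolus_index",
                    "safety_label", "efficiency_label")]
    if (config$aggregate == "mean") {
      rows[[length(rows) + 1L]] <-
        cbind(meta, segment = NA_integer_,
              as.data.frame(t(colMeans(fmat))))
    } else {
      for (j in seq_len(nrow(fmat))) {
        rows[[length(rows) + 1L]] <-
          cbind(meta, segment = j, as.data.frame(t(fmat[j, ])))
      }
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d trial(s) without detected swallow activity dropped",
                    dropped))
  }
  out <- if (length(rows) == 0L) {
    if (dropped == 0L && nrow(tr) > 0L &&
        all(is.na(tr$recording_path)) && is.null(x$recordings)) {
      warning("cohort has no recordings; feature table is empty")
    }
    meta <- data.frame(participant_id = character(),
                       consistency = character(), bolus_index = integer(),
                       safety_label = integer(), efficiency_label = integer(),
                       segment = integer(), stringsAsFactors = FALSE)
    for (f in fn) meta[[f]] <- numeric(0)
    meta
  } else {
    r <- do.call(rbind, rows)
    rownames(r) <- NULL
    r
  }
  attr(out, "feature_names") <- fn
  class(out) <- c("sws_features", "data.frame")
  out
}
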