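#' Cohort simulation parameters
#'
#' The stated world of the simulator mirrors the study cohort: 305
#' participants; six thin and three thicker boluses per consistency;
#' participant-level impairment prevalences equal to the published
#' per-consistency prevalence table; a per-bolus display model in
#' which an impaired participant shows the impairment on any given
#' bolus (thin safety uses conditional first-display hazards
#' back-computed from the published cumulative detection series, all
#' other tasks an i.i.d. 30% display rate conditioned on at least one
#' display so the observed participant-level prevalence matches the
#' latent parameter); silent aspiration in a third of safety-impaired
#' participants (23/70 on thin); and a small not-rateable rate.
#'
#' @param n_participants Number of participants.
#' @param safety_prevalence,efficiency_prevalence Named numeric vectors
#'   (one entry per consistency) of participant-level prevalences.
#' @param display_rate Per-bolus display probability given impairment.
#' @param thin_safety_first_display Cumulative first-display counts by
#'   thin bolus among safety-impaired participants; converted to
#'   per-bolus hazards. The default follows the published cumulative
#'   series (counts 24, 48, 59, 71, 75, 82 out of 82 detected).
#' @param silent_fraction Fraction of safety-impaired participants who
#'   are silent aspirators (their displayed boluses get PAS 8).
#' @param not_rateable_rate Probability that a rating cell is
#'   not-rateable.
#' @param seed Simulation seed.
#' @return An object of class `sws_cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    n_participants = 305L,
    safety_prevalence = c(thin = 0.230, mildly_thick = 0.139,
                          moderately_thick = 0.050, extremely_thick = 0.037),
    efficiency_prevalence = c(thin = 0.197, mildly_thick = 0.179,
                              moderately_thick = 0.182,
                              extremely_thick = 0.179),
    display_rate = 0.30,
    thin_safety_first_display = c(24, 48, 59, 71, 75, 82),
    silent_fraction = 23 / 70,
    not_rateable_rate = 0.01,
    seed = 1L) {
  probs <- c(safety_prevalence, efficiency_prevalence, display_rate,
             silent_fraction, not_rateable_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  cum <- thin_safety_first_display
  if (any(diff(cum) < 0) || any(cum < 0)) {
    stop_config("first-display counts must be non-negative, non-decreasing")
  }
  # conditional hazards: P(first display at k | impaired, none before).
  # The counts are read as a distribution over impaired participants;
  # the final hazard is 1 by construction, so every latent-impaired
  # participant displays within the series and the observed
  # participant-level prevalence is calibrated to the latent parameter.
  tot <- cum[length(cum)]
  if (tot <= 0) stop_config("first-display counts must end positive")
  surv <- c(tot, tot - cum)
  hazards <- diff(-surv) / surv[-length(surv)]
  hazards[!is.finite(hazards)] <- 1
  structure(list(n_participants = as.integer(n_participants),
                 safety_prevalence = safety_prevalence,
                 efficiency_prevalence = efficiency_prevalence,
                 display_rate = display_rate,
                 thin_safety_hazards = hazards,
                 silent_fraction = silent_fraction,
                 not_rateable_rate = not_rateable_rate,
                 seed = as.integer(seed)),
            class = "sws_cohort_sim_params")
}

# displays for one impaired participant over k boluses, conditioned on
# at least one display
iid_displays_conditioned <- function(k, rate) {
  # first display from the truncated geometric, later boluses i.i.d.
  pfirst <- rate * (1 - rate)^(0:(k - 1))
  first <- sample.int(k, 1L, prob = pfirst)
  d <- logical(k)
  d[first] <- TRUE
  if (first < k) {
    d[(first + 1):k] <- stats::runif(k - first) < rate
  }
  d
}

#' Simulate a cohort of rated bolus trials
#'
#' Draws latent per-consistency impairment for each participant,
#' expands the full bolus protocol, lets impaired participants display
#' the impairment per the display model, assigns Penetration-Aspiration
#' scores (displayed safety boluses: PAS 8 for silent aspirators, else
#' 3-7; safe boluses 1-2) and residue fills consistent with the binary
#' efficiency rule, truncates administered boluses by the stopping
#' rules, and finally blanks a small fraction of ratings as
#' not-rateable. Efficiency displays are conditioned on at least one
#' display among the administered boluses, so observed participant
#' prevalence matches the latent parameter. Fully reproducible from the
#' seed.
#'
#' @param params An [cohort_sim_params()].
#' @return An `sws_cohort` with derived labels.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "sws_cohort_sim_params"))
  with_seed(params$seed, {
    rows <- list()
    for (i in seq_len(params$n_participants)) {
      pid <- sprintf("S%04d", i)
      imp_s <- stats::runif(4) < params$safety_prevalence
      imp_e <- stats::runif(4) < params$efficiency_prevalence
      silent <- stats::runif(4) < params$silent_fraction
      trial <- list()
      for (ci in seq_along(consistency_levels())) {
        cs <- consistency_levels()[ci]
        k <- protocol_boluses(cs)
        if (imp_s[ci]) {
          if (cs == "thin") {
            h <- params$thin_safety_hazards
            disp <- logical(k)
            for (b in seq_len(k)) {
              if (!any(disp)) {
                disp[b] <- stats::runif(1) < h[b]
              } else {
                disp[b] <- stats::runif(1) < params$display_rate
              }
            }
          } else {
            disp <- iid_displays_conditioned(k, params$display_rate)
          }
        } else {
          disp <- rep(FALSE, k)
        }
        pas <- ifelse(disp,
                      if (imp_s[ci] && silent[ci]) 8L else
                        sample(3:7, k, replace = TRUE),
                      sample(1:2, k, replace = TRUE))
        trial[[cs]] <- data.frame(
          participant_id = pid, group = "simulated", consistency = cs,
          bolus_index = seq_len(k), pas = as.integer(pas),
          vallecular_fill = NA_real_, pyriform_fill = NA_real_,
          recording_path = NA_character_, stringsAsFactors = FALSE)
      }
      full <- do.call(rbind, trial)
      adm <- apply_stopping_rules(full)
      # efficiency displays on administered boluses only
      for (ci in seq_along(consistency_levels())) {
        cs <- consistency_levels()[ci]
        idx <- which(as.character(adm$consistency) == cs)
        k <- length(idx)
        if (k == 0L) next
        if (imp_e[ci]) {
          dispe <- iid_displays_conditioned(k, params$display_rate)
        } else {
          dispe <- rep(FALSE, k)
        }
        vall <- ifelse(dispe, stats::runif(k, 50, 100),
                       stats::runif(k, 0, 30) *
                         (stats::runif(k) < 0.3))
        pyr <- ifelse(dispe & stats::runif(k) < 0.4,
                      stats::runif(k, 50, 100),
                      stats::runif(k, 0, 20) * (stats::runif(k) < 0.2))
        adm$vallecular_fill[idx] <- vall
        adm$pyriform_fill[idx] <- pyr
      }
      # not-rateable cells
      n <- nrow(adm)
      adm$pas[stats::runif(n) < params$not_rateable_rate] <- NA_integer_
      nr_res <- stats::runif(n) < params$not_rateable_rate
      adm$vallecular_fill[nr_res] <- NA_real_
      adm$pyriform_fill[nr_res] <- NA_real_
      rows[[i]] <- adm
    }
    derive_labels(cohort(do.call(rbind, rows)))
  })
}

#' Signal simulation parameters
#'
#' The generator emulates what the segmentation and feature stages
#' need from a real trial: a quiet baseline of white sensor noise plus
#' slow motion drift, and one or more band-limited vibration bursts at
#' known (annotated) times. Class-conditional effects are multiplicative
#' shifts of burst properties for impaired trials: the frequency band
#' and duration stretch by `1 + 0.3 * class_effect` and the amplitude
#' by `1 + 0.2 * class_effect`.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Trial duration, seconds.
#' @param n_bursts Bursts per trial.
#' @param burst_duration_s Nominal burst duration, seconds.
#' @param band Burst frequency band, Hz (must fit below Nyquist).
#' @param snr_db Burst RMS over noise RMS, decibels.
#' @param class_effect Magnitude of the impaired-class shift (0 = no
#'   effect).
#' @param burst_jitter Swallow-to-swallow variability: lognormal
#'   standard deviation (on the log scale) applied multiplicatively to
#'   each burst's amplitude and duration (and, at half this value, to
#'   its frequency band). Real swallows vary considerably between
#'   presentations; without this the class effect would be trivially
#'   separable.
#' @param axis_correlation Correlation of the burst waveform across the
#'   two axes.
#' @param drift_amplitude,drift_freq_hz Low-frequency motion drift
#'   (largely removed by the high-pass stage).
#' @param seed Seed.
#' @return An object of class `sws_signal_sim_params`.
#' @export
signal_sim_params <- function(fs = 10000, duration_s = 4, n_bursts = 1L,
                              burst_duration_s = 0.45, band = c(70, 400),
                              snr_db = 10, class_effect = 1,
                              burst_jitter = 0.25,
                              axis_correlation = 0.5,
                              drift_amplitude = 1, drift_freq_hz = 0.05,
                              seed = 1L) {
  if (snr_db <= -Inf || !is.finite(snr_db)) stop_config("snr_db must be finite")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop_config("band must satisfy 0 < low < high < fs/2")
  }
  if (burst_jitter < 0) stop_config("burst_jitter must be non-negative")
  structure(list(fs = fs, duration_s = duration_s,
                 n_bursts = as.integer(n_bursts),
                 burst_duration_s = burst_duration_s, band = band,
                 snr_db = snr_db, class_effect = class_effect,
                 burst_jitter = burst_jitter,
                 axis_correlation = axis_correlation,
                 drift_amplitude = drift_amplitude,
                 drift_freq_hz = drift_freq_hz, seed = as.integer(seed)),
            class = "sws_signal_sim_params")
}

# band-limited unit-RMS noise packet with a Tukey window
band_packet <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  # Tukey taper (25% each side)
  taper <- round(0.25 * n)
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(taper) / taper))
  w[seq_len(taper)] <- ramp
  w[(n - taper + 1):n] <- rev(ramp)
  x <- x * w
  x / sqrt(mean(x^2))
}

#' Simulate one dual-axis recording with ground-truth bursts
#'
#' @param impaired Binary class of the trial; impaired trials receive
#'   the class-effect shift.
#' @param params An [signal_sim_params()].
#' @param onsets_s Optional burst onset times (seconds); drawn uniformly
#'   away from the edges when `NULL`.
#' @param trial_id Identifier stored in the recording.
#' @return An `sws_recording` with attribute `bursts`, a data.frame of
#'   ground-truth `onset_s` and `duration_s`.
#' @export
simulate_recording <- function(impaired = 0L, params = signal_sim_params(),
                               onsets_s = NULL, trial_id = "sim") {
  stopifnot(inherits(params, "sws_signal_sim_params"))
  with_seed(params$seed, {
    fs <- params$fs
    n <- round(params$duration_s * fs)
    eff <- if (impaired == 1L) params$class_effect else 0
    dur <- params$burst_duration_s * (1 + 0.3 * eff)
    band <- params$band * (1 + 0.3 * eff)
    if (band[2] >= fs / 2) band[2] <- 0.99 * fs / 2
    amp <- 10^(params$snr_db / 20) * (1 + 0.2 * eff)
    nb <- params$n_bursts
    if (is.null(onsets_s) && nb > 0L) {
      # one burst per equal time slot, jittered within it, edges avoided
      margin <- 0.2
      slot <- (params$duration_s - 2 * margin) / nb
      if (slot <= dur) stop_config("trial too short for the requested bursts")
      onsets_s <- margin + (seq_len(nb) - 1) * slot +
        stats::runif(nb, 0, slot - dur)
    } else if (is.null(onsets_s)) {
      onsets_s <- numeric(0)
    }
    si <- stats::rnorm(n)
    ap <- stats::rnorm(n)
    t <- seq_len(n) / fs
    drift <- params$drift_amplitude *
      sin(2 * pi * params$drift_freq_hz * t + stats::runif(1, 0, 2 * pi))
    si <- si + drift
    ap <- ap + 0.8 * drift
    rho <- params$axis_correlation
    jit <- params$burst_jitter
    durs <- numeric(nb)
    for (b in seq_len(nb)) {
      # per-swallow variability on top of the class shift
      amp_b <- amp * exp(stats::rnorm(1, 0, jit))
      dur_b <- dur * exp(stats::rnorm(1, 0, jit))
      band_b <- band * exp(stats::rnorm(1, 0, jit / 2))
      if (band_b[2] >= fs / 2) band_b[2] <- 0.99 * fs / 2
      durs[b] <- dur_b
      s <- round(onsets_s[b] * fs) + 1L
      e <- min(s + round(dur_b * fs) - 1L, n)
      m <- e - s + 1L
      if (m < 8L) next
      core <- band_packet(m, fs, band_b)
      other <- band_packet(m, fs, band_b)
      si[s:e] <- si[s:e] + amp_b * core
      ap[s:e] <- ap[s:e] + amp_b * (rho * core + sqrt(1 - rho^2) * other)
    }
    rec <- recording(si, ap, fs = fs, trial_id = trial_id)
    attr(rec, "bursts") <- data.frame(onset_s = onsets_s,
                                      duration_s = durs)
    rec
  })
}

#' Attach simulated recordings to a cohort
#'
#' Generates one recording per trial of the requested consistency,
#' impaired trials (by the chosen outcome's bolus label) receiving the
#' class-effect shift. Recordings are stored in the cohort's
#' `recordings` list keyed by trial.
#'
#' @param x An `sws_cohort` with derived labels.
#' @param params An [signal_sim_params()]; per-trial seeds are derived
#'   from `params$seed`.
#' @param consistency Which consistency to simulate signals for.
#' @param outcome Which bolus label drives the class effect.
#' @return The cohort with populated `recordings`.
#' @export
simulate_cohort_recordings <- function(x, params = signal_sim_params(),
                                       consistency = "thin",
                                       outcome = c("safety", "efficiency")) {
  stopifnot(inherits(x, "sws_cohort"))
  outcome <- match.arg(outcome)
  if (!"safety_label" %in% names(x$trials)) x <- derive_labels(x)
  cs <- match.arg(consistency, consistency_levels())
  idx <- which(as.character(x$trials$consistency) == cs)
  recs <- if (is.null(x$recordings)) list() else x$recordings
  lab <- x$trials[[paste0(outcome, "_label")]]
  for (j in seq_along(idx)) {
    i <- idx[j]
    key <- trial_key(x$trials$participant_id[i], x$trials$consistency[i],
                     x$trials$bolus_index[i])
    p <- params
    p$seed <- (params$seed + 7919L * j) %% .Machine$integer.max
    cls <- lab[i]
    recs[[key]] <- simulate_recording(
      impaired = if (!is.na(cls)) cls else 0L, params = p, trial_id = key)
  }
  x$recordings <- recs
  x
}
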