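#' Deterministic reconstruction of the study's outcome structure
#'
#' Builds, without sampling, a cohort whose derived labels reproduce
#' the published prevalence table and the cumulative
#' detection-by-bolus series:
#'
#' * 305 participants with at least two rateable thin boluses (1730
#'   thin boluses; 125 unsafe concentrated so exactly 70 participants
#'   are safety-impaired; 23 of them silent aspirators with PAS 8);
#'   plus 15 participants contributing a single rateable thin bolus
#'   (present in the videofluoroscopy population but below the
#'   two-bolus inclusion rule), giving the 320-participant denominator
#'   of the cumulative detection curve;
#' * thin first-impaired-bolus counts 24/48/59/71/75/82 across the 320,
#'   i.e. 7.5 / 15.0 / 18.4 / 22.2 / 23.4 / 25.6% cumulative detection
#'   (the printed 18.5% at bolus 3 is arithmetically unreachable for
#'   any single denominator; 18.4 is the closest attainable value);
#' * mildly thick: 872 boluses / 302 participants, 51 unsafe boluses in
#'   42 participants (6 boluses safety-not-rateable so the rateable
#'   denominator is 866), 86 inefficient boluses in 54 participants,
#'   16 silent aspirators;
#' * moderately thick: 833 boluses / 281 participants, 17 unsafe in 14,
#'   75 inefficient in 51 (one participant residue-not-rateable
#'   throughout, participant denominator 280), 2 silent;
#' * extremely thick: 794 boluses / 268 participants, 11 unsafe in 10,
#'   67 inefficient in 48, 2 silent.
#'
#' Bolus counts per participant respect the stopping rules (a
#' consistency stops at its second penetration-aspiration event; no
#' participant accrues more than two events in total here).
#'
#' @return An `sws_cohort` with derived labels.
#' @export
make_table2_fixture <- function() {
  pid <- sprintf("P%03d", 1:305)
  xid <- sprintf("X%02d", 1:15)

  ## ---- thin: first-event bolus for the 70 impaired of the core 305
  first_ev <- rep(1:6, times = c(12, 24, 11, 12, 4, 7))  # ids 1..70
  # one-event participants: all of k=6, all of k=5, and 4 of k=4
  one_event <- c(48:51, 60:70)
  two_event <- setdiff(1:70, one_event)
  # second event position: start adjacent, then push later boluses out
  # until the administered thin boluses of the 305 sum to 1730
  second_ev <- stats::setNames(first_ev[two_event] + 1L, two_event)
  target_sum <- 1730L - 235L * 6L - length(one_event) * 6L
  i <- 1L
  while (sum(second_ev) < target_sum) {
    id <- as.character(two_event[i])
    if (second_ev[id] < 6L) second_ev[id] <- second_ev[id] + 1L
    i <- if (i == length(two_event)) 1L else i + 1L
  }
  stopifnot(sum(second_ev) == target_sum)

  thin_boluses <- integer(305)
  thin_boluses[] <- 6L
  thin_boluses[two_event] <- second_ev[as.character(two_event)]

  silent_thin <- 1:23
  eff_thin <- 140:199              # 60 efficiency-impaired, 55 with 2 boluses
  eff_thin2 <- 140:194
  nr_resid_thin <- 200:213         # one residue-not-rateable bolus each

  rows <- list()
  add <- function(pid_, cs, b, pas, vall, pyr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = pid_, group = NA_character_, consistency = cs,
      bolus_index = b, pas = pas, vallecular_fill = vall,
      pyriform_fill = pyr, recording_path = NA_character_,
      stringsAsFactors = FALSE)
  }
  safe_pas <- function(k) rep_len(c(1L, 2L), k)
  unsafe_pas_pool <- rep_len(c(3L, 4L, 5L, 6L, 7L), 400)

  for (i in 1:305) {
    nb <- thin_boluses[i]
    pas <- safe_pas(nb)
    if (i <= 70) {
      ev <- first_ev[i]
      pas[ev] <- if (i %in% silent_thin) 8L else unsafe_pas_pool[i]
      if (i %in% two_event) pas[second_ev[as.character(i)]] <-
          unsafe_pas_pool[i + 70]
    }
    vall <- rep(0, nb); pyr <- rep(0, nb)
    vall[] <- rep_len(c(0, 5, 10, 0, 20, 0), nb)
    if (i %in% eff_thin) {
      n_ineff <- if (i %in% eff_thin2) 2L else 1L
      vall[seq_len(n_ineff)] <- c(60, 75)[seq_len(n_ineff)]
    }
    if (i %in% nr_resid_thin) {
      vall[nb] <- NA; pyr[nb] <- NA
    }
    add(pid[i], "thin", seq_len(nb), pas, vall, pyr)
  }
  # 15 single-bolus participants; 12 impaired on their only bolus
  for (j in 1:15) {
    add(xid[j], "thin", 1L, if (j <= 12) 5L else 1L, 0, 0)
  }

  ## ---- mildly thick: participants 1..302
  mild_imp <- 71:112               # 42 impaired
  mild_two_event <- 71:79          # stop at bolus 2
  mild_silent <- 71:86
  mild_two_bolus_other <- 278:302  # 25 short series for data availability
  mild_nr_pas <- 264:269
  mild_eff <- 210:263              # 54 impaired
  mild_eff2 <- 210:241             # 32 with two inefficient boluses
  for (i in 1:302) {
    nb <- if (i %in% mild_two_event || i %in% mild_two_bolus_other) 2L else 3L
    pas <- safe_pas(nb)
    if (i %in% mild_two_event) {
      pas[1:2] <- c(if (i %in% mild_silent) 8L else 4L, 5L)
    } else if (i %in% mild_imp) {
      ev <- 1L + (i %% 3L)
      pas[ev] <- if (i %in% mild_silent) 8L else unsafe_pas_pool[i]
    }
    if (i %in% mild_nr_pas) pas[nb] <- NA_integer_
    vall <- rep_len(c(0, 10, 0), nb); pyr <- rep(0, nb)
    if (i %in% mild_eff) {
      n_ineff <- if (i %in% mild_eff2) 2L else 1L
      pyr[seq_len(n_ineff)] <- c(55, 90)[seq_len(n_ineff)]
    }
    add(pid[i], "mildly_thick", seq_len(nb), pas, vall, pyr)
  }

  ## ---- moderately thick: participants 1..281
  mod_imp <- 113:126               # 14 impaired
  mod_two_event <- 113:115
  mod_silent <- 113:114
  mod_two_bolus_other <- 275:281
  mod_eff <- 150:200               # 51 impaired
  mod_eff2 <- 150:173              # 24 with two inefficient boluses
  mod_nr_all <- 265L               # residue never rateable
  for (i in 1:281) {
    nb <- if (i %in% mod_two_event || i %in% mod_two_bolus_other) 2L else 3L
    pas <- safe_pas(nb)
    if (i %in% mod_two_event) {
      pas[1:2] <- c(if (i %in% mod_silent) 8L else 3L, 6L)
    } else if (i %in% mod_imp) {
      pas[1L + (i %% 3L)] <- unsafe_pas_pool[i]
    }
    vall <- rep(0, nb); pyr <- rep_len(c(0, 15, 0), nb)
    if (i %in% mod_eff) {
      n_ineff <- if (i %in% mod_eff2) 2L else 1L
      vall[seq_len(n_ineff)] <- c(65, 50)[seq_len(n_ineff)]
    }
    if (i == mod_nr_all) {
      vall[] <- NA; pyr[] <- NA
    }
    add(pid[i], "moderately_thick", seq_len(nb), pas, vall, pyr)
  }

  ## ---- extremely thick: participants 1..268
  ext_imp <- 220:229               # 10 impaired
  ext_two_event <- 220L
  ext_silent <- 220:221
  ext_two_bolus_other <- 260:268
  ext_eff <- 80:127                # 48 impaired
  ext_eff2 <- 80:98                # 19 with two inefficient boluses
  for (i in 1:268) {
    nb <- if (i %in% ext_two_event || i %in% ext_two_bolus_other) 2L else 3L
    pas <- safe_pas(nb)
    if (i %in% ext_two_event) {
      pas[1:2] <- c(8L, 7L)
    } else if (i %in% ext_imp) {
      pas[1L + (i %% 3L)] <- if (i %in% ext_silent) 8L else unsafe_pas_pool[i]
    }
    vall <- rep(0, nb); pyr <- rep(0, nb)
    if (i %in% ext_eff) {
      n_ineff <- if (i %in% ext_eff2) 2L else 1L
      pyr[seq_len(n_ineff)] <- c(70, 85)[seq_len(n_ineff)]
    }
    add(pid[i], "extremely_thick", seq_len(nb), pas, vall, pyr)
  }

  trials <- do.call(rbind, rows)
  derive_labels(cohort(trials))
}
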