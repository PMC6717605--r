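#' Participant status per consistency
#'
#' Rolls bolus-level labels up to one row per participant x
#' consistency: safety and efficiency impairment (via
#' [rollup_participant()]), silent aspiration (any PAS 8 bolus) and the
#' number of rateable boluses per outcome.
#'
#' @param x An `sws_cohort` (labels are derived on the fly if absent).
#' @return A data.frame with columns `participant_id`, `consistency`,
#'   `safety_impaired`, `efficiency_impaired`, `silent_aspirator`,
#'   `n_safety_rateable`, `n_efficiency_rateable`, `n_boluses`.
#' @export
participant_status <- function(x) {
  stopifnot(inherits(x, "sws_cohort"))
  if (!"safety_label" %in% names(x$trials)) x <- derive_labels(x)
  tr <- x$trials
  if (nrow(tr) == 0L) {
    return(data.frame(participant_id = character(), consistency = character(),
                      safety_impaired = integer(),
                      efficiency_impaired = integer(),
                      silent_aspirator = integer(),
                      n_safety_rateable = integer(),
                      n_efficiency_rateable = integer(),
                      n_boluses = integer(), stringsAsFactors = FALSE))
  }
  key <- interaction(tr$participant_id, tr$consistency, drop = TRUE)
  pieces <- lapply(split(tr, key), function(g) {
    data.frame(
      participant_id = g$participant_id[1],
      consistency = as.character(g$consistency[1]),
      safety_impaired = rollup_participant(g$safety_label),
      efficiency_impaired = rollup_participant(g$efficiency_label),
      silent_aspirator = if (all(is.na(g$pas))) NA_integer_ else
        as.integer(any(g$pas == 8L, na.rm = TRUE)),
      n_safety_rateable = sum(!is.na(g$safety_label)),
      n_efficiency_rateable = sum(!is.na(g$efficiency_label)),
      n_boluses = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Prevalence of impaired safety and efficiency
#'
#' Reproduces the shape of the published prevalence table: for each
#' consistency and outcome, the number and percentage of impaired
#' boluses and of impaired participants. Denominators exclude missing
#' (not-rateable) labels; participants enter an outcome's denominators
#' only with at least `min_boluses` rateable boluses for that outcome
#' (default 2, mirroring the "complete data for at least 2 boluses"
#' inclusion rule), and only their boluses count at the bolus level.
#' Percentages are rounded half-up to one decimal.
#'
#' @param x An `sws_cohort`.
#' @param min_boluses Minimum rateable boluses per participant.
#' @return A data.frame, one row per consistency x outcome, class
#'   `sws_prevalence`.
#' @export
prevalence_summary <- function(x, min_boluses = 2L) {
  stopifnot(inherits(x, "sws_cohort"))
  if (!"safety_label" %in% names(x$trials)) x <- derive_labels(x)
  tr <- x$trials
  rows <- list()
  for (cs in consistency_levels()) {
    sub <- tr[as.character(tr$consistency) == cs, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (outcome in c("safety", "efficiency")) {
      lab <- sub[[paste0(outcome, "_label")]]
      ok <- !is.na(lab)
      n_rateable <- tapply(ok, sub$participant_id, sum)
      included <- names(n_rateable)[n_rateable >= min_boluses]
      keep <- ok & sub$participant_id %in% included
      bolus_n <- sum(keep)
      bolus_imp <- sum(lab[keep] == 1L)
      p_imp <- tapply(lab[keep], sub$participant_id[keep], rollup_participant)
      part_n <- length(p_imp)
      part_imp <- sum(unlist(p_imp) == 1L, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        consistency = cs, outcome = outcome,
        bolus_n = bolus_n, bolus_impaired_n = bolus_imp,
        bolus_pct = pct1(bolus_imp, bolus_n),
        participant_n = part_n, participant_impaired_n = part_imp,
        participant_pct = pct1(part_imp, part_n),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(consistency = character(), outcome = character(),
               bolus_n = integer(), bolus_impaired_n = integer(),
               bolus_pct = numeric(), participant_n = integer(),
               participant_impaired_n = integer(),
               participant_pct = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  class(out) <- c("sws_prevalence", "data.frame")
  out
}

#' Cumulative detection curve by bolus number
#'
#' For participants administered a given consistency, the fraction whose
#' first impaired bolus occurs at or before bolus `k`, as a percentage
#' of all participants with at least one rateable bolus of that
#' consistency (including those contributing a single bolus, who cannot
#' enter the two-bolus prevalence denominators). The curve is
#' non-decreasing in `k` by construction.
#'
#' @param x An `sws_cohort`.
#' @param consistency One consistency label.
#' @param outcome `"safety"` or `"efficiency"`.
#' @return Named numeric vector of cumulative percentages, one entry per
#'   bolus index `1..max`; attribute `n` holds the participant
#'   denominator, attribute `counts` the cumulative counts.
#' @export
cumulative_detection_curve <- function(x, consistency = "thin",
                                       outcome = c("safety", "efficiency")) {
  stopifnot(inherits(x, "sws_cohort"))
  outcome <- match.arg(outcome)
  if (!"safety_label" %in% names(x$trials)) x <- derive_labels(x)
  cs <- match.arg(consistency, consistency_levels())
  sub <- x$trials[as.character(x$trials$consistency) == cs, , drop = FALSE]
  lab <- sub[[paste0(outcome, "_label")]]
  sub <- sub[!is.na(lab), , drop = FALSE]
  lab <- lab[!is.na(lab)]
  if (nrow(sub) == 0L) return(structure(numeric(0), n = 0L))
  n_den <- length(unique(sub$participant_id))
  kmax <- max(sub$bolus_index)
  pos <- sub[lab == 1L, , drop = FALSE]
  first_pos <- tapply(pos$bolus_index, pos$participant_id, min)
  counts <- vapply(seq_len(kmax),
                   function(k) sum(first_pos <= k), integer(1))
  curve <- pct1(counts, n_den)
  names(curve) <- as.character(seq_len(kmax))
  structure(curve, n = n_den, counts = counts)
}

#' Silent aspiration summary
#'
#' Counts participants with at least one PAS-8 bolus (material below the
#' vocal folds with no ejection response) on the given consistency.
#' Denominator and inclusion rule match [prevalence_summary()].
#'
#' @inheritParams cumulative_detection_curve
#' @param min_boluses Minimum rateable PAS boluses per participant.
#' @return List with `n_participants`, `n_silent`, `pct`.
#' @export
silent_aspiration_summary <- function(x, consistency = "thin",
                                      min_boluses = 2L) {
  stopifnot(inherits(x, "sws_cohort"))
  cs <- match.arg(consistency, consistency_levels())
  sub <- x$trials[as.character(x$trials$consistency) == cs, , drop = FALSE]
  ok <- !is.na(sub$pas)
  n_rateable <- tapply(ok, sub$participant_id, sum)
  included <- names(n_rateable)[n_rateable >= min_boluses]
  sub <- sub[ok & sub$participant_id %in% included, , drop = FALSE]
  silent <- tapply(sub$pas == 8L, sub$participant_id, any)
  n <- length(included)
  n_silent <- sum(unlist(silent))
  list(n_participants = n, n_silent = n_silent, pct = pct1(n_silent, n))
}

#' @export
print.sws_prevalence <- function(x, ...) {
  cat("Prevalence of impaired swallowing safety and efficiency\n")
  cat(sprintf("%-18s %-11s %8s %6s %6s %8s %6s %6s\n", "consistency",
              "outcome", "boluses", "n", "%", "parts", "n", "%"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-18s %-11s %8d %6d %6.1f %8d %6d %6.1f\n",
                x$consistency[i], x$outcome[i], x$bolus_n[i],
                x$bolus_impaired_n[i], x$bolus_pct[i], x$participant_n[i],
                x$participant_impaired_n[i], x$participant_pct[i]))
  }
  invisible(x)
}
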