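#' Binary swallowing-safety label from a PAS score
#'
#' Penetration-Aspiration Scale scores 1-2 are safe (no airway entry or
#' entry with clearance above the vocal folds); scores 3-8 are unsafe.
#' Not-rateable scores (`NA`) stay missing.
#'
#' @param pas Integer vector of PAS scores in 1-8, `NA` = not-rateable.
#' @return Integer vector, 0 = safe, 1 = unsafe, `NA` = missing.
#' @export
map_pas_to_safety <- function(pas) {
  pas <- as.integer(pas)
  if (any(!is.na(pas) & (pas < 1L | pas > 8L))) {
    stop_data("PAS scores must lie in 1-8")
  }
  ifelse(is.na(pas), NA_integer_, as.integer(pas >= 3L))
}

#' Binary swallowing-efficiency label from residue fill ratings
#'
#' A bolus is inefficient when post-swallow residue fills at least 50%
#' of the valleculae and/or the pyriform sinuses. The disjunction makes
#' one rateable fill >= 50 sufficient for impairment regardless of the
#' other space; but a not-rateable space together with a sub-threshold
#' rateable one leaves the label missing, because impairment in the
#' obscured space cannot be excluded.
#'
#' @param vallecular_fill,pyriform_fill Fill percentages in \[0, 100\],
#'   `NA` = not-rateable.
#' @return Integer vector, 0 = efficient, 1 = inefficient, `NA`.
#' @export
map_residue_to_efficiency <- function(vallecular_fill, pyriform_fill) {
  v <- as.numeric(vallecular_fill); p <- as.numeric(pyriform_fill)
  if (any(!is.na(v) & (v < 0 | v > 100)) ||
      any(!is.na(p) & (p < 0 | p > 100))) {
    stop_data("residue fills must lie in [0, 100]")
  }
  pos <- (!is.na(v) & v >= 50) | (!is.na(p) & p >= 50)
  neg <- !is.na(v) & v < 50 & !is.na(p) & p < 50
  ifelse(pos, 1L, ifelse(neg, 0L, NA_integer_))
}

#' Participant-level "at least one positive" roll-up
#'
#' A participant is impaired on a consistency if at least one bolus of
#' that consistency is impaired; unimpaired if every rateable bolus is
#' unimpaired and at least one rateable bolus exists; missing otherwise.
#'
#' @param labels Integer vector of per-bolus binary labels (`NA` =
#'   missing).
#' @return Single integer 0/1 or `NA`.
#' @export
rollup_participant <- function(labels) {
  labels <- as.integer(labels)
  if (any(labels == 1L, na.rm = TRUE)) return(1L)
  if (any(!is.na(labels))) return(0L)
  NA_integer_
}

#' Attach derived binary labels to a cohort
#'
#' Adds `safety_label` ([map_pas_to_safety()]) and `efficiency_label`
#' ([map_residue_to_efficiency()]) columns to the trial table.
#'
#' @param x An `sws_cohort`.
#' @return The cohort with label columns added.
#' @export
derive_labels <- function(x) {
  stopifnot(inherits(x, "sws_cohort"))
  x$trials$safety_label <- map_pas_to_safety(x$trials$pas)
  x$trials$efficiency_label <- map_residue_to_efficiency(
    x$trials$vallecular_fill, x$trials$pyriform_fill)
  x
}

#' Apply the protocol stopping rules
#'
#' Testing of one stimulus is discontinued after two
#' penetration-aspiration events on that stimulus, and the whole
#' protocol terminates after five events in total. An event is a
#' rateable PAS >= 3 (the same binarization as the safety label; a
#' not-rateable bolus is not counted as an event). The administered set
#' is therefore a prefix within each consistency: boluses strictly
#' after the second event of their consistency, or strictly after the
#' fifth event overall, are dropped.
#'
#' @param trials A trial data.frame (as in [cohort()]) for a single
#'   participant, any order; internally ordered by protocol sequence
#'   (consistency, then bolus index).
#' @return The administered subset of `trials`, in protocol order.
#' @export
apply_stopping_rules <- function(trials) {
  if (nrow(trials) == 0L) return(trials)
  cons <- as_consistency(trials$consistency)
  ord <- order(cons, trials$bolus_index)
  trials <- trials[ord, , drop = FALSE]
  cons <- cons[ord]
  event <- !is.na(trials$pas) & trials$pas >= 3L
  keep <- logical(nrow(trials))
  total <- 0L
  per <- stats::setNames(integer(4), consistency_levels())
  for (i in seq_len(nrow(trials))) {
    cs <- as.character(cons[i])
    if (total >= 5L) break
    if (per[[cs]] >= 2L) next
    keep[i] <- TRUE
    if (event[i]) {
      per[[cs]] <- per[[cs]] + 1L
      total <- total + 1L
    }
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
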