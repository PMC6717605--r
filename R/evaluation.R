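#' Participant-stratified random split
#'
#' Randomly sets aside a fraction of participants for validation,
#' stratified by the participant-level reference status so class
#' proportions are preserved on each side; all boluses of a participant
#' land on the same side. A stratum with a single participant goes to
#' training with a warning.
#'
#' @param status Data.frame with columns `participant_id` and `status`
#'   (binary participant-level label).
#' @param fraction Validation fraction, strictly in (0, 1).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return List with character vectors `train` and `validation`.
#' @export
make_split <- function(status, fraction = 0.2, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) {
    stop_config("validation fraction must lie strictly between 0 and 1")
  }
  stopifnot(all(c("participant_id", "status") %in% names(status)))
  with_seed(seed, {
    val <- character()
    for (s in unique(status$status)) {
      ids <- status$participant_id[status$status == s]
      if (length(ids) == 1L) {
        warning(sprintf("stratum %s has a single participant; kept in training",
                        s))
        next
      }
      n_val <- round(fraction * length(ids))
      if (n_val >= 1L) val <- c(val, sample(ids, n_val))
    }
    list(train = setdiff(status$participant_id, val), validation = val)
  })
}

#' Participant-level mean predicted probability
#'
#' Averages the per-bolus probabilities of the first `min(k, cap)`
#' boluses in protocol order, where the cap is 4 for thin liquids and 3
#' for thicker consistencies: in a deployed screen only the earliest
#' sips would be collected.
#'
#' @param probs Per-bolus probabilities of impairment.
#' @param consistency Consistency of the boluses.
#' @param config An [pipeline_config()] (holds the caps).
#' @param bolus_index Protocol order of each probability; defaults to
#'   the given order.
#' @return Mean probability, or `NA` for zero boluses.
#' @export
participant_score <- function(probs, consistency = "thin",
                              config = pipeline_config(),
                              bolus_index = seq_along(probs)) {
  if (length(probs) == 0L) return(NA_real_)
  cap <- if (as.character(consistency)[1] == "thin") {
    config$bolus_cap_thin
  } else {
    config$bolus_cap_other
  }
  ord <- order(bolus_index)
  mean(probs[ord][seq_len(min(cap, length(probs)))])
}

#' Tie-aware ROC AUC
#'
#' Area under the receiver operating characteristic by the
#' Mann-Whitney convention: the probability that a random impaired
#' score exceeds a random unimpaired score, ties counting one half.
#'
#' @param scores Numeric scores (higher = more impaired).
#' @param labels Binary labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fix the operating point on training data
#'
#' Chooses the decision threshold (call impaired when `score >=
#' threshold`) as the smallest threshold whose training-set specificity
#' reaches the target; the threshold is then applied unchanged to
#' validation data. The near-constant ~60% specificity across the
#' published tasks motivates the default target of 0.60.
#'
#' @param scores Training scores.
#' @param labels Training binary labels.
#' @param target_specificity Required training specificity.
#' @return The threshold (numeric scalar).
#' @export
operating_point <- function(scores, labels, target_specificity = 0.60) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop_data("operating point needs both classes in the training data")
  }
  neg <- scores[labels == 0L]
  cand <- c(sort(unique(scores)), Inf)
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  cand[which(spec >= target_specificity)[1]]
}

sens_spec <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  c(sensitivity = mean(pred[labels == 1L] == 1L),
    specificity = mean(pred[labels == 0L] == 0L))
}

#' Monte-Carlo repeated random sub-sampling evaluation
#'
#' The published validation design: at every iteration a fresh
#' stratified participant split is drawn, the regularized discriminant
#' is re-fitted on the training boluses, validation boluses are scored
#' (bolus-level AUC), validation participants are scored by the capped
#' mean probability against roll-up reference labels
#' (participant-level AUC), and sensitivity/specificity are measured at
#' the operating point fixed on training participants. Results are the
#' mean and standard deviation over iterations, on the percent scale.
#'
#' For the moderately-thick safety task the training pool also includes
#' extremely thick boluses of training participants (impaired examples
#' are scarce on moderately thick), while validation pools stay
#' moderately thick only; participants contributing solely
#' extremely-thick rows are kept permanently in training.
#'
#' Iterations whose validation split contains a single class are
#' skipped and counted; a warning is raised if more than 20% skip.
#'
#' @param features An `sws_features` table (or data.frame with the same
#'   metadata columns and feature columns).
#' @param consistency Target consistency of the task.
#' @param outcome `"safety"` or `"efficiency"`.
#' @param config An [pipeline_config()]; `n_iterations`,
#'   `validation_fraction`, `specificity_target`, caps, priors and
#'   shrinkage are honoured. The master `seed` (or the `seed` argument)
#'   makes the whole evaluation reproducible.
#' @param seed Overrides `config$seed`.
#' @return An `sws_eval` object: consistency, outcome, iteration count,
#'   skip count, and mean/SD of bolus AUC, participant AUC, sensitivity
#'   and specificity (percent).
#' @export
monte_carlo_evaluate <- function(features, consistency = "thin",
                                 outcome = c("safety", "efficiency"),
                                 config = pipeline_config(), seed = NULL) {
  outcome <- match.arg(outcome)
  cs <- match.arg(consistency, consistency_levels())
  seed <- if (!is.null(seed)) seed else config$seed
  lab_col <- paste0(outcome, "_label")
  fn <- attr(features, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(features),
                  c("participant_id", "consistency", "bolus_index",
                    "segment", "safety_label", "efficiency_label"))
  }
  df <- as.data.frame(features)
  df <- df[!is.na(df[[lab_col]]), , drop = FALSE]

  combined <- config$combined_moderate_training &&
    cs == "moderately_thick" && outcome == "safety"
  pool_cs <- if (combined) c(cs, "extremely_thick") else cs
  df <- df[as.character(df$consistency) %in% pool_cs, , drop = FALSE]
  target <- as.character(df$consistency) == cs

  if (sum(target) == 0L) stop_data("no labelled rows for this task")

  # participant reference status: roll-up over ALL rateable boluses of
  # the target consistency
  status_tab <- tapply(df[[lab_col]][target], df$participant_id[target],
                       rollup_participant)
  status <- data.frame(participant_id = names(status_tab),
                       status = as.integer(status_tab),
                       stringsAsFactors = FALSE)
  status <- status[!is.na(status$status), , drop = FALSE]
  extra_only <- setdiff(unique(df$participant_id), status$participant_id)
  if (!any(status$status == 1L)) {
    stop_data("no impaired participants for this task")
  }

  x_all <- as.matrix(df[fn])
  it_stats <- matrix(NA_real_, config$n_iterations, 4,
                     dimnames = list(NULL, c("bolus_auc", "participant_auc",
                                             "sensitivity", "specificity")))
  skipped <- 0L
  for (it in seq_len(config$n_iterations)) {
    it_seed <- if (is.null(seed)) NULL else (seed + it) %% .Machine$integer.max
    split <- suppressWarnings(
      make_split(status, config$validation_fraction, it_seed))
    tr_ids <- c(split$train, extra_only)
    tr_rows <- df$participant_id %in% tr_ids
    va_rows <- df$participant_id %in% split$validation & target
    y_tr <- df[[lab_col]][tr_rows]
    y_va <- df[[lab_col]][va_rows]
    if (length(unique(y_tr)) < 2L || length(unique(y_va)) < 2L ||
        sum(y_tr == 1L) < 2L || sum(y_tr == 0L) < 2L) {
      skipped <- skipped + 1L
      next
    }
    model <- fit_rlda(x_all[tr_rows, , drop = FALSE], y_tr,
                      lambda = config$shrinkage, priors = config$priors)
    p_va <- predict_proba(model, x_all[va_rows, , drop = FALSE])
    bolus_auc <- roc_auc(p_va, y_va)

    # participant level: capped mean probability vs roll-up status
    p_tr_target <- predict_proba(
      model, x_all[tr_rows & target, , drop = FALSE])
    part_score <- function(rows, probs) {
      ids <- df$participant_id[rows]
      sapply(split(seq_along(probs), ids), function(ii) {
        participant_score(probs[ii], cs, config,
                          df$bolus_index[rows][ii])
      })
    }
    sc_va <- part_score(va_rows, p_va)
    st_va <- status$status[match(names(sc_va), status$participant_id)]
    part_auc <- roc_auc(sc_va, st_va)

    sc_tr <- part_score(tr_rows & target, p_tr_target)
    st_tr <- status$status[match(names(sc_tr), status$participant_id)]
    keep_tr <- !is.na(st_tr)
    res <- c(NA_real_, NA_real_)
    if (any(st_tr[keep_tr] == 1L) && any(st_tr[keep_tr] == 0L)) {
      thr <- operating_point(sc_tr[keep_tr], st_tr[keep_tr],
                             config$specificity_target)
      res <- sens_spec(sc_va, st_va, thr)
    }
    it_stats[it, ] <- c(bolus_auc, part_auc, res[1], res[2])
  }
  if (skipped > 0.2 * config$n_iterations) {
    warning(sprintf("%d of %d iterations skipped (single-class validation)",
                    skipped, config$n_iterations))
  }
  m <- function(col) 100 * mean(it_stats[, col], na.rm = TRUE)
  s <- function(col) 100 * stats::sd(it_stats[, col], na.rm = TRUE)
  structure(list(
    consistency = cs, outcome = outcome,
    n_iterations = config$n_iterations, n_skipped = skipped,
    bolus_auc_mean = m("bolus_auc"), bolus_auc_sd = s("bolus_auc"),
    participant_auc_mean = m("participant_auc"),
    participant_auc_sd = s("participant_auc"),
    sensitivity_mean = m("sensitivity"), sensitivity_sd = s("sensitivity"),
    specificity_mean = m("specificity"), specificity_sd = s("specificity"),
    iteration_stats = it_stats), class = "sws_eval")
}

#' @export
print.sws_eval <- function(x, ...) {
  cat(sprintf("<sws_eval> %s / %s (%d iterations, %d skipped)\n",
              x$consistency, x$outcome, x$n_iterations, x$n_skipped))
  cat(sprintf("  bolus AUC        %5.1f +/- %4.1f %%\n",
              x$bolus_auc_mean, x$bolus_auc_sd))
  cat(sprintf("  participant AUC  %5.1f +/- %4.1f %%\n",
              x$participant_auc_mean, x$participant_auc_sd))
  cat(sprintf("  sensitivity      %5.1f +/- %4.1f %%\n",
              x$sensitivity_mean, x$sensitivity_sd))
  cat(sprintf("  specificity      %5.1f +/- %4.1f %%\n",
              x$specificity_mean, x$specificity_sd))
  invisible(x)
}

#' Run the six-classifier suite
#'
#' Safety and efficiency classifiers for thin, mildly thick and
#' moderately thick liquids (six tasks). The moderately-thick safety
#' task uses the combined-training rule when enabled in the
#' configuration. Tasks without impaired participants are skipped with
#' a notice and reported as `NULL`.
#'
#' @inheritParams monte_carlo_evaluate
#' @return Named list of six `sws_eval` results (or `NULL` for skipped
#'   tasks), class `sws_suite`.
#' @export
run_suite <- function(features, config = pipeline_config(), seed = NULL) {
  tasks <- expand.grid(
    consistency = c("thin", "mildly_thick", "moderately_thick"),
    outcome = c("safety", "efficiency"), stringsAsFactors = FALSE)
  out <- vector("list", nrow(tasks))
  names(out) <- paste(tasks$consistency, tasks$outcome, sep = ".")
  for (i in seq_len(nrow(tasks))) {
    nm <- paste(tasks$consistency[i], tasks$outcome[i], sep = ".")
    out[i] <- list(tryCatch(
      monte_carlo_evaluate(features, tasks$consistency[i],
                           tasks$outcome[i], config, seed = seed),
      sws_data_error = function(e) {
        message(sprintf("task %s skipped: %s", nm, conditionMessage(e)))
        NULL
      }))
  }
  class(out) <- "sws_suite"
  out
}

#' @export
print.sws_suite <- function(x, ...) {
  cat(sprintf("%-18s %-11s %16s %16s %16s %16s\n", "consistency",
              "outcome", "bolus AUC %", "part. AUC %", "sens %", "spec %"))
  for (nm in names(x)) {
    e <- x[[nm]]
    if (is.null(e)) {
      cat(sprintf("%-30s skipped\n", nm))
      next
    }
    f <- function(m, s) sprintf("%5.1f +/- %4.1f", m, s)
    cat(sprintf("%-18s %-11s %16s %16s %16s %16s\n", e$consistency,
                e$outcome, f(e$bolus_auc_mean, e$bolus_auc_sd),
                f(e$participant_auc_mean, e$participant_auc_sd),
                f(e$sensitivity_mean, e$sensitivity_sd),
                f(e$specificity_mean, e$specificity_sd)))
  }
  invisible(x)
}

#' Sample size for a fixed-design validation study
#'
#' Exact-binomial power computation for jointly demonstrating
#' sensitivity and specificity: with `N * prevalence` expected impaired
#' participants and the rest unimpaired, the study must reject, with
#' overall power `power`, the one-sided nulls that sensitivity is at
#' most `null_sens` and that specificity is at most `null_spec` (each
#' at level `alpha`, independence of the two tests assumed), when the
#' true operating characteristics equal the targets. This is this
#' package's own documented method; the method behind the published
#' range was not stated, so no equality with it is claimed. The display
#' rate and bolus count do not enter the computation; they are echoed
#' in the returned assumptions because the targets are only attainable
#' when impairment is displayed within the boluses the score averages.
#'
#' @param prevalence Participant-level prevalence of impairment.
#' @param per_swallow_display_rate Assumed probability that an impaired
#'   participant displays the impairment on a given bolus.
#' @param n_boluses Boluses entering the participant score.
#' @param sens_target,spec_target True operating characteristics to be
#'   demonstrated.
#' @param power Required joint power.
#' @param null_sens,null_spec One-sided null hypotheses to beat.
#' @param alpha One-sided level per outcome.
#' @return Required number of participants `N` (integer), with
#'   attribute `assumptions`.
#' @export
validation_sample_size <- function(prevalence,
                                   per_swallow_display_rate = 0.30,
                                   n_boluses = 4L,
                                   sens_target = 0.86, spec_target = 0.60,
                                   power = 0.90,
                                   null_sens = 0.70, null_spec = 0.50,
                                   alpha = 0.05) {
  rates <- c(prevalence, per_swallow_display_rate, sens_target, spec_target,
             power, null_sens, null_spec, alpha)
  if (any(rates <= 0) || any(rates >= 1)) {
    stop_config("all rates must lie strictly in (0, 1)")
  }
  if (sens_target <= null_sens || spec_target <= null_spec) {
    stop_config("targets must exceed their null values; infeasible design")
  }
  one_sided_power <- function(n, p_null, p_true) {
    # an empty arm is vacuous: in the prevalence -> 1 limit only the
    # positives-side requirement remains
    if (n < 1L) return(1)
    # smallest k with P(X >= k | p_null) <= alpha
    k <- stats::qbinom(1 - alpha, n, p_null) + 1L
    stats::pbinom(k - 1L, n, p_true, lower.tail = FALSE)
  }
  for (N in 10:100000) {
    n1 <- round(N * prevalence)
    n0 <- N - n1
    pw <- one_sided_power(n1, null_sens, sens_target) *
      one_sided_power(n0, null_spec, spec_target)
    if (pw >= power) {
      assumptions <- list(prevalence = prevalence,
                          per_swallow_display_rate = per_swallow_display_rate,
                          n_boluses = n_boluses,
                          sens_target = sens_target,
                          spec_target = spec_target,
                          null_sens = null_sens, null_spec = null_spec,
                          alpha_one_sided = alpha, power = power,
                          achieved_power = pw,
                          method = paste("joint one-sided exact binomial",
                                         "tests, independence assumed"))
      message(sprintf(
        paste0("sample size N = %d (exact binomial; sens %g vs null %g, ",
               "spec %g vs null %g, alpha %g one-sided each, joint power ",
               "%.3f >= %g)"),
        N, sens_target, null_sens, spec_target, null_spec, alpha, pw, power))
      return(structure(N, assumptions = assumptions))
    }
  }
  stop_config("no N up to 100000 attains the requested power")
}
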