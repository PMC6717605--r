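#' Cohort of bolus trials
#'
#' The unit of analysis is one bolus administration ("trial"): a
#' participant swallows one sip of a given consistency, the simultaneous
#' videofluoroscopy is rated (Penetration-Aspiration Scale 1-8;
#' vallecular and pyriform residue fill percentages), and optionally a
#' recording of the accelerometry signal is attached. Ratings that the
#' central raters could not see are not-rateable and stored as `NA`.
#'
#' @param trials A data.frame with columns `participant_id`, `group`,
#'   `consistency`, `bolus_index`, `pas`, `vallecular_fill`,
#'   `pyriform_fill`, `recording_path`. `NA` in a rating column means
#'   not-rateable.
#' @param participants Optional data.frame of participant metadata with
#'   at least `participant_id`; derived from `trials` when `NULL`.
#' @param recordings Optional named list of [recording()] objects keyed
#'   by `trial_key(participant_id, consistency, bolus_index)`.
#' @return An object of class `sws_cohort`: a list with elements
#'   `trials`, `participants`, `recordings`.
#' @export
cohort <- function(trials, participants = NULL, recordings = NULL) {
  required <- c("participant_id", "group", "consistency", "bolus_index",
                "pas", "vallecular_fill", "pyriform_fill", "recording_path")
  if (nrow(trials) == 0L && !all(required %in% names(trials))) {
    trials <- empty_trials()
  }
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop_data(sprintf("trials table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  trials <- as.data.frame(trials)[required]
  trials$participant_id <- as.character(trials$participant_id)
  trials$group <- as.character(trials$group)
  trials$consistency <- as_consistency(trials$consistency)
  trials$bolus_index <- as.integer(trials$bolus_index)
  trials$pas <- as.integer(trials$pas)
  trials$vallecular_fill <- as.numeric(trials$vallecular_fill)
  trials$pyriform_fill <- as.numeric(trials$pyriform_fill)
  trials$recording_path <- as.character(trials$recording_path)

  if (nrow(trials) > 0) {
    if (any(is.na(trials$bolus_index)) || any(trials$bolus_index < 1L)) {
      stop_data("bolus_index must be a positive integer")
    }
    bad_pas <- which(!is.na(trials$pas) & (trials$pas < 1L | trials$pas > 8L))
    if (length(bad_pas) > 0) {
      stop_data(sprintf("PAS out of range 1-8 in trial row %d", bad_pas[1]))
    }
    for (col in c("vallecular_fill", "pyriform_fill")) {
      bad <- which(!is.na(trials[[col]]) &
                   (trials[[col]] < 0 | trials[[col]] > 100))
      if (length(bad) > 0) {
        stop_data(sprintf("%s outside [0, 100] in trial row %d", col, bad[1]))
      }
    }
    key <- trial_key(trials$participant_id, trials$consistency,
                     trials$bolus_index)
    if (anyDuplicated(key)) {
      stop_data(sprintf(
        "duplicate (participant, consistency, bolus_index): %s",
        key[duplicated(key)][1]))
    }
  }

  if (is.null(participants)) {
    participants <- unique(trials[c("participant_id", "group")])
    rownames(participants) <- NULL
  } else {
    participants <- as.data.frame(participants)
    if (!"participant_id" %in% names(participants)) {
      stop_data("participants table lacks participant_id")
    }
    participants$participant_id <- as.character(participants$participant_id)
    orphan <- setdiff(trials$participant_id, participants$participant_id)
    if (length(orphan) > 0) {
      stop_data(sprintf("trial participant(s) missing from participants: %s",
                        paste(utils::head(orphan, 3), collapse = ", ")))
    }
  }

  structure(list(trials = trials, participants = participants,
                 recordings = recordings),
            class = "sws_cohort")
}

empty_trials <- function() {
  data.frame(participant_id = character(), group = character(),
             consistency = character(), bolus_index = integer(),
             pas = integer(), vallecular_fill = numeric(),
             pyriform_fill = numeric(), recording_path = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.sws_cohort <- function(x, ...) {
  cat(sprintf("<sws_cohort> %d trials, %d participants\n",
              nrow(x$trials), nrow(x$participants)))
  if (nrow(x$trials) > 0) {
    tab <- table(as.character(x$trials$consistency))
    for (nm in intersect(consistency_levels(), names(tab))) {
      cat(sprintf("  %-18s %4d boluses\n", nm, tab[[nm]]))
    }
  }
  invisible(x)
}

#' Unique trial key
#'
#' @param participant_id,consistency,bolus_index Trial identifiers.
#' @return Character key, unique per trial within a valid cohort.
#' @export
trial_key <- function(participant_id, consistency, bolus_index) {
  paste(participant_id, as.character(consistency), bolus_index, sep = "/")
}

#' Read / write the cohort table
#'
#' The cohort dialect is a comma-delimited table, one row per bolus,
#' with a mandatory header `participant_id, group, consistency,
#' bolus_index, pas, vallecular_fill, pyriform_fill, recording_path`.
#' The token `NR` marks a not-rateable rating and round-trips to `NA`.
#' `write_cohort` writes recording sidecar files (one per trial holding
#' a recording) next to the table under `<stem>_recordings/`.
#'
#' @param path Path of the cohort CSV file.
#' @param load_recordings Read recording sidecars referenced by
#'   `recording_path` (relative paths resolve against the table's
#'   directory).
#' @return `read_cohort` returns an `sws_cohort`; `write_cohort` the
#'   path, invisibly.
#' @export
read_cohort <- function(path, load_recordings = FALSE) {
  if (!file.exists(path)) stop_data(sprintf("cohort file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("participant_id", "group", "consistency", "bolus_index",
                "pas", "vallecular_fill", "pyriform_fill", "recording_path")
  if (!identical(names(raw), required)) {
    stop_data(sprintf("%s: header must be exactly: %s", path,
                      paste(required, collapse = ",")))
  }
  parse_num <- function(x, col) {
    x <- trimws(x)
    x[x == "NR" | x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop_data(sprintf("%s: cannot parse %s ('%s') in data row %d",
                        path, col, x[bad[1]], bad[1]))
    }
    out
  }
  trials <- data.frame(
    participant_id = raw$participant_id,
    group = ifelse(trimws(raw$group) == "", NA, raw$group),
    consistency = raw$consistency,
    bolus_index = parse_num(raw$bolus_index, "bolus_index"),
    pas = parse_num(raw$pas, "pas"),
    vallecular_fill = parse_num(raw$vallecular_fill, "vallecular_fill"),
    pyriform_fill = parse_num(raw$pyriform_fill, "pyriform_fill"),
    recording_path = ifelse(trimws(raw$recording_path) == "", NA,
                            raw$recording_path),
    stringsAsFactors = FALSE)
  co <- cohort(trials)
  if (load_recordings) {
    base <- dirname(path)
    idx <- which(!is.na(co$trials$recording_path))
    recs <- list()
    for (i in idx) {
      rp <- co$trials$recording_path[i]
      full <- if (file.exists(rp)) rp else file.path(base, rp)
      key <- trial_key(co$trials$participant_id[i], co$trials$consistency[i],
                       co$trials$bolus_index[i])
      recs[[key]] <- read_recording(full)
    }
    co$recordings <- recs
  }
  co
}

#' @rdname read_cohort
#' @param x An `sws_cohort`.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "sws_cohort"))
  trials <- x$trials
  if (!is.null(x$recordings) && length(x$recordings) > 0) {
    recdir <- paste0(sub("\\.[^.]*$", "", path), "_recordings")
    dir.create(recdir, showWarnings = FALSE, recursive = TRUE)
    key <- trial_key(trials$participant_id, trials$consistency,
                     trials$bolus_index)
    for (k in names(x$recordings)) {
      i <- match(k, key)
      if (is.na(i)) next
      fn <- file.path(basename(recdir), paste0(gsub("/", "_", k), ".csv"))
      write_recording(x$recordings[[k]], file.path(dirname(path), fn))
      trials$recording_path[i] <- fn
    }
  }
  fmt <- function(v) ifelse(is.na(v), "NR", format(v, trim = TRUE, digits = 15))
  out <- data.frame(
    participant_id = trials$participant_id,
    group = ifelse(is.na(trials$group), "", trials$group),
    consistency = as.character(trials$consistency),
    bolus_index = trials$bolus_index,
    pas = fmt(trials$pas),
    vallecular_fill = fmt(trials$vallecular_fill),
    pyriform_fill = fmt(trials$pyriform_fill),
    recording_path = ifelse(is.na(trials$recording_path), "",
                            trials$recording_path),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data(sprintf("cannot write cohort to %s", path))
  invisible(path)
}
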