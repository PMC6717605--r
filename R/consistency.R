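#' Stimulus consistency levels
#'
#' The barium swallow protocol administers four liquid consistencies in a
#' fixed order: six sips of thin liquid, then three sips each of mildly
#' thick, moderately thick and extremely thick liquid. Consistencies form
#' an ordered scale (thin < mildly thick < moderately thick < extremely
#' thick).
#'
#' @return Character vector of the four consistency labels in protocol
#'   order.
#' @export
consistency_levels <- function() {
  c("thin", "mildly_thick", "moderately_thick", "extremely_thick")
}

#' Coerce to a consistency factor
#'
#' @param x Character vector of consistency labels.
#' @return Ordered factor over the closed set of consistency levels.
#' @export
as_consistency <- function(x) {
  lv <- consistency_levels()
  bad <- setdiff(unique(as.character(x)), lv)
  if (length(bad) > 0) {
    stop_data(sprintf("unknown consistency label(s): %s",
                      paste(bad, collapse = ", ")))
  }
  factor(as.character(x), levels = lv, ordered = TRUE)
}

#' Number of boluses scheduled per consistency
#'
#' Thin liquids are offered six times; every thicker consistency three
#' times. Stopping rules may truncate the schedule.
#'
#' @param consistency Consistency label(s).
#' @return Integer vector of scheduled bolus counts.
#' @export
protocol_boluses <- function(consistency = consistency_levels()) {
  ifelse(as.character(consistency) == "thin", 6L, 3L)
}

# condition helpers: config errors exit 2 on the CLI, data errors exit 3
stop_config <- function(msg, call. = FALSE) {
  stop(structure(class = c("sws_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg, call. = FALSE) {
  stop(structure(class = c("sws_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# round-half-up to one decimal, the convention of the printed tables
pct1 <- function(n, total) {
  r <- floor(1000 * n / total + 0.5) / 10
  r[!is.finite(r)] <- NA_real_
  r
}
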