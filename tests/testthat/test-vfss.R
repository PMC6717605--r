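test_that("PAS binarization splits 1-2 vs 3-8 and is monotone", {
  expect_identical(map_pas_to_safety(c(1L, 2L)), c(0L, 0L))
  expect_identical(map_pas_to_safety(c(3L, 8L)), c(1L, 1L))
  expect_true(is.na(map_pas_to_safety(NA)))
  expect_error(map_pas_to_safety(9L), class = "sws_data_error")
  expect_error(map_pas_to_safety(0L), class = "sws_data_error")
  # monotone non-decreasing in PAS
  expect_true(all(diff(map_pas_to_safety(1:8)) >= 0))
})

test_that("residue rule: >=50% in either space, missing-safe semantics", {
  expect_identical(map_residue_to_efficiency(50, 0), 1L)    # boundary incl.
  expect_identical(map_residue_to_efficiency(49.9, 49.9), 0L)
  expect_identical(map_residue_to_efficiency(0, 100), 1L)   # disjunction
  # rateable >= 50 dominates a not-rateable partner
  expect_identical(map_residue_to_efficiency(NA, 60), 1L)
  # not-rateable partner below threshold cannot exclude impairment
  expect_true(is.na(map_residue_to_efficiency(NA, 10)))
  expect_true(is.na(map_residue_to_efficiency(NA, NA)))
  expect_error(map_residue_to_efficiency(101, 0), class = "sws_data_error")
})

test_that("participant roll-up implements 'at least one positive'", {
  expect_identical(rollup_participant(c(0L, 1L, 0L)), 1L)
  expect_identical(rollup_participant(c(0L, 0L, 0L)), 0L)
  expect_true(is.na(rollup_participant(c(NA, NA))))
  expect_identical(rollup_participant(c(NA, 1L)), 1L)
  expect_identical(rollup_participant(c(NA, 0L)), 0L)
  # monotonicity: adding a positive never clears impairment
  set.seed(1)
  for (i in 1:20) {
    labs <- sample(c(0L, 1L, NA), 5, replace = TRUE)
    expect_identical(rollup_participant(c(labs, 1L)), 1L)
  }
})

test_that("stopping rules: per-stimulus and whole-protocol examples", {
  full <- make_trials(n = 6, pas = c(5L, 6L, 1L, 1L, 1L, 1L))
  full <- rbind(full, make_trials(consistency = "mildly_thick", n = 3,
                                  pas = rep(1L, 3)))
  adm <- apply_stopping_rules(full)
  # thin stops after the second event; mildly thick proceeds
  expect_identical(adm$bolus_index[as.character(adm$consistency) == "thin"],
                   1:2)
  expect_identical(sum(as.character(adm$consistency) == "mildly_thick"), 3L)

  # five events in total terminate everything downstream
  tr <- rbind(
    make_trials(n = 6, pas = c(5L, 5L, 1L, 1L, 1L, 1L)),
    make_trials(consistency = "mildly_thick", n = 3, pas = c(5L, 5L, 1L)),
    make_trials(consistency = "moderately_thick", n = 3, pas = c(5L, 1L, 1L)),
    make_trials(consistency = "extremely_thick", n = 3, pas = rep(1L, 3)))
  adm <- apply_stopping_rules(tr)
  expect_identical(nrow(adm[as.character(adm$consistency) ==
                              "moderately_thick", ]), 1L)
  expect_identical(sum(as.character(adm$consistency) == "extremely_thick"), 0L)

  # all safe: the full 15-bolus barium protocol is administered
  tr <- rbind(make_trials(n = 6),
              make_trials(consistency = "mildly_thick", n = 3),
              make_trials(consistency = "moderately_thick", n = 3),
              make_trials(consistency = "extremely_thick", n = 3))
  expect_identical(nrow(apply_stopping_rules(tr)), 15L)
})

test_that("stopping rules agree with an exhaustive event-count oracle", {
  # independent oracle: walk the protocol counting events directly
  oracle <- function(pas) {
    sched <- rep(consistency_levels(), times = c(6, 3, 3, 3))
    keep <- logical(15)
    per <- c(thin = 0, mildly_thick = 0, moderately_thick = 0,
             extremely_thick = 0)
    tot <- 0
    for (i in 1:15) {
      if (tot >= 5 || per[sched[i]] >= 2) next
      keep[i] <- TRUE
      if (pas[i] >= 3) {
        per[sched[i]] <- per[sched[i]] + 1
        tot <- tot + 1
      }
    }
    keep
  }
  proto <- rbind(make_trials(n = 6),
                 make_trials(consistency = "mildly_thick", n = 3),
                 make_trials(consistency = "moderately_thick", n = 3),
                 make_trials(consistency = "extremely_thick", n = 3))
  check_seq <- function(pas) {
    tr <- proto
    tr$pas <- pas
    adm <- apply_stopping_rules(tr)
    got <- paste(adm$consistency, adm$bolus_index)
    want <- paste(proto$consistency, proto$bolus_index)[oracle(pas)]
    identical(got, want)
  }
  # exhaustive over the first 10 positions (safe tail), sampled length-15
  for (bits in 0:1023) {
    pas <- c(ifelse(bitwAnd(bits, 2^(0:9)) > 0, 5L, 1L), rep(1L, 5))
    expect_true(check_seq(pas))
  }
  set.seed(99)
  for (i in 1:300) {
    expect_true(check_seq(sample(c(1L, 5L), 15, replace = TRUE)))
  }
})

test_that("prevalence summary: trivial cohorts and rounding", {
  co <- derive_labels(cohort(make_trials(n = 6)))
  prev <- prevalence_summary(co)
  expect_identical(unique(prev$bolus_pct), 0)
  expect_identical(unique(prev$participant_pct), 0)

  empty <- prevalence_summary(cohort(data.frame()))
  expect_identical(nrow(empty), 0L)

  # percentages equal 100*n/N rounded half-up to one decimal
  for (r in seq_len(nrow(prev))) {
    expect_equal(prev$bolus_pct[r],
                 floor(1000 * prev$bolus_impaired_n[r] /
                         prev$bolus_n[r] + 0.5) / 10)
  }
})

test_that("participants below the two-bolus rule are excluded", {
  tr <- rbind(make_trials("A", n = 3, pas = c(5L, 1L, 1L)),
              make_trials("B", n = 1, pas = 5L),
              make_trials("C", n = 3, pas = c(NA, NA, 1L)))
  co <- derive_labels(cohort(tr))
  prev <- prevalence_summary(co)
  saf <- prev[prev$outcome == "safety", ]
  expect_identical(saf$participant_n, 1L)    # only A has >= 2 rateable
  expect_identical(saf$bolus_n, 3L)          # only A's boluses count
  expect_identical(saf$participant_impaired_n, 1L)
})

test_that("cumulative detection curve is monotone with a sane denominator", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    tr <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_trials(sprintf("P%02d", i), n = 6,
                  pas = sample(c(1L, 1L, 1L, 5L, NA), 6, replace = TRUE))
    }))
    co <- derive_labels(cohort(tr))
    cc <- cumulative_detection_curve(co, "thin", "safety")
    expect_true(all(diff(cc) >= 0))
    expect_true(all(cc >= 0 & cc <= 100))
  }
})

test_that("silent aspiration counts a participant once", {
  tr <- rbind(make_trials("A", n = 3, pas = c(8L, 8L, 1L)),
              make_trials("B", n = 3, pas = c(1L, 1L, 1L)))
  s <- silent_aspiration_summary(derive_labels(cohort(tr)), "thin")
  expect_identical(s$n_silent, 1L)
  expect_identical(s$n_participants, 2L)
  expect_equal(s$pct, 50)
  none <- silent_aspiration_summary(
    derive_labels(cohort(make_trials(n = 3))), "thin")
  expect_identical(none$n_silent, 0L)
  expect_equal(none$pct, 0)
})

test_that("participant status: silent aspiration implies unsafe", {
  fx <- fixture_cache()
  st <- participant_status(fx)
  sil <- st[!is.na(st$silent_aspirator) & st$silent_aspirator == 1L, ]
  expect_true(all(sil$safety_impaired == 1L))
})

test_that("table fixture passes validation and matches stated cardinalities", {
  fx <- fixture_cache()
  expect_s3_class(fx, "sws_cohort")
  thin <- fx$trials[as.character(fx$trials$consistency) == "thin", ]
  n_rateable <- tapply(!is.na(thin$pas), thin$participant_id, sum)
  expect_identical(sum(n_rateable >= 2), 305L)
  prev <- prevalence_summary(fx)
  expect_identical(prev$bolus_n[prev$consistency == "thin" &
                                  prev$outcome == "safety"], 1730L)
  expect_identical(prev$participant_n[prev$consistency == "mildly_thick" &
                                        prev$outcome == "safety"], 302L)
  # round trip through the cohort dialect
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fx, path)
  back <- read_cohort(path)
  cols <- c("participant_id", "consistency", "bolus_index", "pas",
            "vallecular_fill", "pyriform_fill")
  expect_equal(back$trials[cols], fx$trials[cols])
})
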