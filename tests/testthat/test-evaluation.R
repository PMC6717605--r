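test_that("stratified split preserves class proportions and determinism", {
  status <- data.frame(participant_id = sprintf("P%03d", 1:100),
                       status = rep(c(1L, 0L), c(23, 77)))
  sp <- make_split(status, 0.2, seed = 42)
  expect_length(sp$validation, 20L)
  n_imp <- sum(status$status[match(sp$validation,
                                   status$participant_id)] == 1L)
  expect_true(n_imp %in% 4:5)
  expect_identical(sort(c(sp$train, sp$validation)),
                   status$participant_id)
  expect_identical(make_split(status, 0.2, seed = 42), sp)
  expect_false(identical(make_split(status, 0.2, seed = 43)$validation,
                         sp$validation))
  expect_error(make_split(status, 0), class = "sws_config_error")
  solo <- data.frame(participant_id = c("A", "B", "C"),
                     status = c(1L, 0L, 0L))
  expect_warning(sp2 <- make_split(solo, 0.4, seed = 1), "single")
  expect_true("A" %in% sp2$train)
})

test_that("participant score caps boluses in protocol order", {
  cfg <- pipeline_config()
  expect_equal(participant_score(c(0.2, 0.4, 0.6, 0.8, 0.9, 0.9),
                                 "thin", cfg), 0.5)
  expect_equal(participant_score(c(0.3, 0.6), "mildly_thick", cfg), 0.45)
  expect_equal(participant_score(0.7, "thin", cfg), 0.7)
  # protocol order, not given order: first available boluses count
  expect_equal(participant_score(c(0.9, 0.1), "thin", cfg,
                                 bolus_index = c(5, 1)),
               mean(c(0.1, 0.9)))
  expect_equal(participant_score(c(0.9, 0.1, 0.5), "mildly_thick", cfg,
                                 bolus_index = c(3, 1, 2)),
               mean(c(0.1, 0.5, 0.9)))
  expect_true(is.na(participant_score(numeric(0))))
})

test_that("AUC agrees with the exhaustive pair-count oracle", {
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
    tot / (length(pos) * length(neg))
  }
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(roc_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_true(is.na(roc_auc(1:4, rep(1, 4))))
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    s <- sample(1:8, n, replace = TRUE)  # heavy ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), pair_auc(s, y), tolerance = 1e-12)
  }
})

test_that("operating point hits the training specificity target", {
  sens_spec_test <- function(s, y, thr) {
    c(sensitivity = mean(s[y == 1L] >= thr),
      specificity = mean(s[y == 0L] < thr))
  }
  # fully separated scores: perfect sensitivity at any target
  set.seed(41)
  s <- c(rnorm(50), rnorm(50) + 10)
  y <- rep(c(0L, 1L), each = 50)
  thr <- operating_point(s, y, 0.6)
  expect_equal(unname(sens_spec_test(s, y, thr)["sensitivity"]), 1)
  expect_gte(unname(sens_spec_test(s, y, thr)["specificity"]), 0.6)

  # target 1: threshold above every negative training score
  thr1 <- operating_point(s, y, 1.0)
  expect_gt(thr1, max(s[y == 0L]))

  # null identity: with uninformative scores, validation sensitivity
  # approaches 1 - specificity target
  set.seed(14)
  str <- runif(2000); ytr <- rbinom(2000, 1, 0.5)
  sva <- runif(2000); yva <- rbinom(2000, 1, 0.5)
  thr <- operating_point(str, ytr, 0.6)
  sens <- mean(sva[yva == 1] >= thr)
  expect_lt(abs(sens - 0.4), 0.05)
  expect_error(operating_point(1:5, rep(1L, 5)), class = "sws_data_error")
})

test_that("monte carlo evaluation is reproducible and calibrated", {
  ft <- make_feature_table(n_participants = 60, shift = 0, seed = 15)
  cfg <- pipeline_config(n_iterations = 60)
  r1 <- monte_carlo_evaluate(ft, "thin", "safety", cfg, seed = 7)
  r2 <- monte_carlo_evaluate(ft, "thin", "safety", cfg, seed = 7)
  expect_identical(r1$iteration_stats, r2$iteration_stats)
  expect_s3_class(r1, "sws_eval")
  expect_true(all(c(r1$bolus_auc_mean, r1$participant_auc_mean) >= 0))
  expect_true(all(c(r1$bolus_auc_mean, r1$participant_auc_mean) <= 100))

  # strong effect: near-ceiling AUC
  ft2 <- make_feature_table(n_participants = 60, shift = 5, seed = 16)
  r3 <- monte_carlo_evaluate(ft2, "thin", "safety", cfg, seed = 8)
  expect_gte(r3$bolus_auc_mean, 97)
})

test_that("a single Monte-Carlo iteration equals a manual run", {
  ft <- make_feature_table(n_participants = 50, shift = 1.5, seed = 17)
  cfg <- pipeline_config(n_iterations = 1L, shrinkage = 0.2)
  seed <- 31L
  r <- monte_carlo_evaluate(ft, "thin", "safety", cfg, seed = seed)

  # manual replication of iteration 1 with the same derived seed
  fn <- attr(ft, "feature_names")
  status_tab <- tapply(ft$safety_label, ft$participant_id,
                       rollup_participant)
  status <- data.frame(participant_id = names(status_tab),
                       status = as.integer(status_tab))
  sp <- make_split(status, 0.2, seed = seed + 1L)
  tr <- ft$participant_id %in% sp$train
  va <- ft$participant_id %in% sp$validation
  m <- fit_rlda(as.matrix(ft[tr, fn]), ft$safety_label[tr], lambda = 0.2)
  bolus_auc <- roc_auc(predict_proba(m, as.matrix(ft[va, fn])),
                       ft$safety_label[va])
  expect_equal(unname(r$iteration_stats[1, "bolus_auc"]), bolus_auc,
               tolerance = 1e-12)
})

test_that("participant-level AUC dominates bolus-level AUC directionally", {
  wins <- 0L
  for (rep in 1:10) {
    ft <- make_feature_table(n_participants = 70, shift = 1.2,
                             display = 1, seed = 400 + rep)
    cfg <- pipeline_config(n_iterations = 40)
    r <- monte_carlo_evaluate(ft, "thin", "safety", cfg, seed = rep)
    if (r$participant_auc_mean >= r$bolus_auc_mean) wins <- wins + 1L
  }
  # averaging independent per-bolus noise sharpens the participant score
  expect_gte(wins, 8L)
})

test_that("combined-training rule pools extreme rows, degrades gracefully", {
  # moderate data alone has a single impaired participant ->
  # training folds are single-class without the extreme pool
  ft_mod <- make_feature_table(n_participants = 30, prevalence = 0.25,
                               shift = 0.7, k = 3,
                               consistency = "moderately_thick", seed = 18)
  ft_ext <- make_feature_table(n_participants = 30, prevalence = 0.25,
                               shift = 0.7, k = 3,
                               consistency = "extremely_thick", seed = 19)
  ft_ext$participant_id <- sub("^Q", "E", ft_ext$participant_id)
  both <- rbind(ft_mod, ft_ext)
  attr(both, "feature_names") <- attr(ft_mod, "feature_names")
  cfg <- pipeline_config(n_iterations = 20)
  r <- monte_carlo_evaluate(both, "moderately_thick", "safety", cfg,
                            seed = 9)
  expect_s3_class(r, "sws_eval")
  # with the flag off and no extreme data the task still runs
  cfg2 <- pipeline_config(n_iterations = 20,
                          combined_moderate_training = FALSE)
  r2 <- monte_carlo_evaluate(ft_mod, "moderately_thick", "safety", cfg2,
                             seed = 9)
  expect_s3_class(r2, "sws_eval")
  # results differ: the extreme pool changed the training data
  expect_false(identical(r$iteration_stats, r2$iteration_stats))
})

test_that("suite runs six tasks and skips impossible ones with notice", {
  parts <- list()
  for (cs in c("thin", "mildly_thick", "moderately_thick")) {
    ftc <- make_feature_table(n_participants = 40, shift = 2,
                              k = if (cs == "thin") 6 else 3,
                              consistency = cs,
                              seed = match(cs, consistency_levels()))
    parts[[cs]] <- ftc
  }
  ft <- do.call(rbind, parts)
  attr(ft, "feature_names") <- attr(parts[[1]], "feature_names")
  cfg <- pipeline_config(n_iterations = 10)
  suite <- run_suite(ft, cfg, seed = 3)
  expect_length(suite, 6L)
  expect_named(suite, c("thin.safety", "mildly_thick.safety",
                        "moderately_thick.safety", "thin.efficiency",
                        "mildly_thick.efficiency",
                        "moderately_thick.efficiency"),
               ignore.order = TRUE)
  expect_true(all(vapply(suite, inherits, logical(1), "sws_eval")))

  # all-healthy cohort: every task skipped with a notice, none errors
  healthy <- make_feature_table(n_participants = 20, prevalence = 1e-9,
                                shift = 0, seed = 20)
  expect_message(s2 <- run_suite(healthy, cfg, seed = 1), "skipped")
  expect_true(all(vapply(s2, is.null, logical(1))))
})

test_that("sample size computation is monotone with sane limits", {
  suppressMessages({
    n_base <- validation_sample_size(0.6)
    n_power <- validation_sample_size(0.6, power = 0.95)
    expect_gte(n_power, n_base)
    # prevalence -> 1 limit: the (empty) specificity arm is vacuous and
    # N approaches the positives-only requirement
    n_hi <- validation_sample_size(0.995)
    n1_needed <- 10
    while (stats::pbinom(stats::qbinom(0.95, n1_needed, 0.70), n1_needed,
                         0.86, lower.tail = FALSE) < 0.90) {
      n1_needed <- n1_needed + 1
    }
    expect_lte(abs(n_hi - n1_needed), 1)
    expect_lt(n_hi, n_base)
  })
  expect_error(validation_sample_size(0.6, sens_target = 0.65),
               class = "sws_config_error")
  expect_error(validation_sample_size(1.2), class = "sws_config_error")
  expect_message(validation_sample_size(0.6), "sample size N")
  n <- suppressMessages(validation_sample_size(0.6))
  expect_true(!is.null(attr(n, "assumptions")))
})
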