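# shared builders for the test suite; everything is generated in code

# minimal valid trial table
make_trials <- function(pid = "P1", consistency = "thin", n = 2,
                        pas = rep(1L, n), vall = rep(0, n),
                        pyr = rep(0, n)) {
  data.frame(participant_id = pid, group = NA_character_,
             consistency = consistency, bolus_index = seq_len(n),
             pas = pas, vallecular_fill = vall, pyriform_fill = pyr,
             recording_path = NA_character_, stringsAsFactors = FALSE)
}

# synthetic per-bolus feature table with controllable class effect:
# features ~ N(shift * label, 1); participants get `k` boluses each and
# impaired participants display on each bolus with `display`
make_feature_table <- function(n_participants = 80, prevalence = 0.3,
                               shift = 2, n_features = 6, k = 6,
                               display = 0.5, consistency = "thin",
                               seed = 1) {
  set.seed(seed)
  status <- rbinom(n_participants, 1, prevalence)
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    lab <- if (status[i] == 1) {
      l <- rbinom(k, 1, display)
      if (sum(l) == 0) l[sample.int(k, 1)] <- 1L
      l
    } else rep(0L, k)
    data.frame(participant_id = sprintf("Q%04d", i),
               consistency = consistency, bolus_index = seq_len(k),
               safety_label = as.integer(lab),
               efficiency_label = as.integer(lab),
               stringsAsFactors = FALSE)
  }))
  X <- matrix(rnorm(nrow(rows) * n_features), ncol = n_features) +
    shift * rows$safety_label
  colnames(X) <- paste0("f", seq_len(n_features))
  ft <- cbind(rows, X)
  attr(ft, "feature_names") <- colnames(X)
  ft
}

# fast signal parameters used throughout the tests (4 kHz keeps the
# 1000 Hz low-pass corner below Nyquist while cutting runtime)
test_signal_params <- function(...) {
  args <- utils::modifyList(list(fs = 4000, duration_s = 4), list(...))
  do.call(signal_sim_params, args)
}

fixture_cache <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_table2_fixture()
    fx
  }
})
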