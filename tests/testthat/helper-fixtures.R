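# Shared small synthetic cohort, built once per test run.
.fixture_env <- new.env()

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      cohort_config(n_participants = 8, trials_per_condition = 80,
                    block_size = 40, seed = 101))
  }
  .fixture_env$cohort
}

# deterministic toy trial table for exclusion-rule fixtures
toy_trial_row <- function(participant_id = "p001", session = "decision",
                          condition = "slow", rt = 1000, choice = "right",
                          movement_correct = TRUE, decision_correct = TRUE,
                          frame_rate_ok = TRUE, premature_press = FALSE,
                          steps = paste(rep("R", 179), collapse = "")) {
  data.frame(participant_id = participant_id, session = session,
             condition = condition, block_index = 1L, trial_id = 1L,
             trial_type = "obvious", winner = "right", rt = rt,
             choice = choice, decision_correct = decision_correct,
             commit_frame = 10L, tap1 = 180, tap2 = 180, tap3 = 180,
             tap4 = 180, movement_correct = movement_correct,
             frame_rate_ok = frame_rate_ok,
             premature_press = premature_press, steps = steps,
             stringsAsFactors = FALSE)
}

toy_srt_rows <- function(participant_id = "p001", session = "decision",
                         condition = "none", rt = rep(400, 10),
                         premature = rep(FALSE, 10)) {
  data.frame(participant_id = participant_id, session = session,
             condition = condition, rt = rt, premature = premature,
             stringsAsFactors = FALSE)
}

toy_dataset <- function(trials, srt) {
  structure(list(trials = trials, srt = srt,
                 meta = list(schema_version = 1L, seed = 0L)),
            class = "tokens_dataset")
}
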