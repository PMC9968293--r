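#' Generative agent parameters for one simulated participant
#'
#' The agent integrates the actual frame-wise evidence of a trial: the
#' accumulator gains `gain` per evidence frame plus Gaussian noise, commits
#' when it reaches `bound` (per condition), and presses the key after a
#' motor delay. This is deliberately richer than the analysis-side
#' drift-diffusion model — the agent sees the real frame sequence, which is
#' what makes psychophysical kernels non-flat. Tap intervals are truncated
#' Normal draws (floor 60 ms) per condition.
#'
#' @param gain Evidence weight per frame.
#' @param accum_noise_sd Per-frame accumulator noise SD.
#' @param bound Named vector `c(fast = , slow = )`: commitment threshold in
#'   accumulator units per condition.
#' @param motor_delay_mean Named vector (`fast`, `slow`, optionally `none`
#'   for the snake-free SRT block; defaults to the fast/slow mean): mean
#'   commitment-to-keypress delay, ms.
#' @param motor_delay_sd Trial-to-trial motor delay SD, ms.
#' @param tap_interval_mean Named vector (`fast`, `slow`): mean inter-tap
#'   interval, ms.
#' @param tap_interval_sd Trial-to-trial tap interval SD, ms.
#' @param lapse_prob Probability of an invalid trial (split evenly between
#'   anticipations and no-responses). Must be < 0.2.
#' @param max_tap_speed Calibrated maximum tapping speed, taps per second;
#'   snake speeds are fractions of this.
#' @param forced_commit_frame Deadline urgency: if the bound is not reached
#'   by this frame (per condition), the agent commits to the currently
#'   leading accumulator state anyway, as participants facing the 3000-ms
#'   timeout do. `NULL` (default) disables forcing, leaving such trials as
#'   no-responses.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(gain = 1, accum_noise_sd = 0.6,
                         bound = c(fast = 8.3, slow = 15.5),
                         motor_delay_mean = c(fast = 330, slow = 480),
                         motor_delay_sd = 60,
                         tap_interval_mean = c(fast = 172, slow = 188),
                         tap_interval_sd = 25,
                         lapse_prob = 0.04,
                         max_tap_speed = 7,
                         forced_commit_frame = NULL) {
  stopifnot(all(bound > 0), accum_noise_sd >= 0, motor_delay_sd >= 0,
            tap_interval_sd >= 0, all(tap_interval_mean > 0),
            lapse_prob >= 0, lapse_prob < 0.2, max_tap_speed > 0)
  if (!"none" %in% names(motor_delay_mean))
    motor_delay_mean <- c(motor_delay_mean,
                          none = mean(motor_delay_mean[c("fast", "slow")]))
  if (!is.null(forced_commit_frame) &&
      length(forced_commit_frame) == 1L && is.null(names(forced_commit_frame)))
    forced_commit_frame <- c(fast = forced_commit_frame,
                             slow = forced_commit_frame)
  structure(list(gain = gain, accum_noise_sd = accum_noise_sd,
                 bound = bound, motor_delay_mean = motor_delay_mean,
                 motor_delay_sd = motor_delay_sd,
                 tap_interval_mean = tap_interval_mean,
                 tap_interval_sd = tap_interval_sd,
                 lapse_prob = lapse_prob, max_tap_speed = max_tap_speed,
                 forced_commit_frame = forced_commit_frame),
            class = "agent_params")
}

draw_motor_delay <- function(agent, condition, n = 1) {
  pmax(stats::rnorm(n, agent$motor_delay_mean[[condition]],
                    agent$motor_delay_sd), 50)
}

#' Simulate one decision-phase response
#'
#' Noisy accumulation of the frame sequence: `X_k = X_{k-1} + gain * step_k
#' + eps_k`, commitment at the first frame where `|X_k|` reaches the
#' condition's bound, choice by the accumulator's sign, and reaction time
#' equal to the end of the commitment frame plus a motor delay draw
#' (truncated at 50 ms). If the agent has a `forced_commit_frame`, the
#' growing deadline pressure forces commitment to the current leader at that
#' frame; otherwise trials with no commitment by the last frame, or with
#' `rt` beyond the 3000-ms timeout, are returned as no-responses.
#'
#' @param agent An [agent_params()].
#' @param seq A `frame_sequence` (see [generate_frame_sequence()]).
#' @param condition `"fast"` or `"slow"`.
#' @param design A [task_design()].
#' @return List with `choice` (`"left"`/`"right"`/`"none"`), `commit_frame`
#'   (NA if none) and `rt` in ms (NA if none).
#' @export
simulate_decision <- function(agent, seq, condition,
                              design = task_design()) {
  n <- length(seq$steps)
  x <- cumsum(agent$gain * seq$steps +
                stats::rnorm(n, 0, agent$accum_noise_sd))
  b <- agent$bound[[condition]]
  hit <- which(abs(x) >= b)
  forced <- agent$forced_commit_frame[[condition]] %||% Inf
  if (length(hit) == 0 && !is.finite(forced))
    return(list(choice = "none", commit_frame = NA_integer_, rt = NA_real_))
  k <- min(if (length(hit)) hit[1] else n, forced, n)
  if (x[k] == 0)  # dead tie at forced commitment: guess
    x[k] <- sample(c(-1, 1), 1)
  rt <- k * frame_ms(design) + draw_motor_delay(agent, condition)
  if (rt > design$decision_timeout)
    return(list(choice = "none", commit_frame = NA_integer_, rt = NA_real_))
  list(choice = if (x[k] > 0) "right" else "left",
       commit_frame = as.integer(k), rt = rt)
}

#' Simulate the movement-phase tapping sequence
#'
#' Draws four inter-tap intervals from a truncated Normal (floor 60 ms).
#' Movement correctness depends on the session: in the decision session the
#' four taps only have to finish inside the 3000-ms movement phase; in the
#' movement session a snake moving at a fixed fraction of the participant's
#' maximum tapping speed must not collide with the caterpillar. In
#' fast-tapping blocks the snake starts one tap unit (36 degrees) behind and
#' chases at 85% of maximum speed; in slow-tapping blocks it starts one unit
#' ahead and retreats at 59.5%. The collision check is applied tap by tap on
#' the tap-unit track: a chasing snake catches up during tap `j` when the
#' cumulative tap time exceeds `j / v_snake`; a retreating snake is caught
#' when the caterpillar completes tap `j` before `(j - 1) / v_snake`.
#'
#' @param agent An [agent_params()].
#' @param condition `"fast"`, `"slow"` (movement session), or the decision
#'   session's conditions (no snake).
#' @param session `"decision"` or `"movement"`.
#' @param design A [task_design()].
#' @return List with `tap_intervals` (4 values, ms) and `movement_correct`.
#' @export
simulate_tapping <- function(agent, condition, session,
                             design = task_design()) {
  iv <- pmax(stats::rnorm(design$n_taps_after_decision,
                          agent$tap_interval_mean[[condition]],
                          agent$tap_interval_sd), 60)
  ok <- sum(iv) <= design$movement_timeout
  if (ok && session == "movement") {
    tj <- cumsum(iv) / 1000  # s
    j <- seq_along(iv)
    if (condition == "fast") {
      v_snake <- design$snake_fast_fraction * agent$max_tap_speed
      ok <- all(tj < j / v_snake)
    } else {
      v_snake <- design$snake_slow_fraction * agent$max_tap_speed
      ok <- all(tj > (j - 1) / v_snake)
    }
  }
  list(tap_intervals = iv, movement_correct = ok)
}

#' Simulate a block of simple-reaction-time trials
#'
#' The SRT task strips the decision away: the correct response is known in
#' advance, so the reaction time is a fixed stimulus-detection latency plus
#' the same motor delay the agent uses in the main task. Premature presses
#' (uniform on (0, 140) ms) are injected at the agent's lapse probability.
#'
#' @param agent An [agent_params()].
#' @param condition `"fast"`, `"slow"`, or `"none"` (no snake).
#' @param n_trials Number of trials.
#' @param detection_latency Constant detection latency, ms.
#' @return data.frame with columns `condition`, `rt` (ms), `premature`.
#' @export
simulate_srt_block <- function(agent, condition, n_trials,
                               detection_latency = 180) {
  premature <- stats::runif(n_trials) < agent$lapse_prob
  rt <- detection_latency + draw_motor_delay(agent, condition, n_trials)
  rt[premature] <- stats::runif(sum(premature), 0, 140)
  data.frame(condition = condition, rt = rt, premature = premature,
             stringsAsFactors = FALSE)
}

#' Cohort configuration with planted condition effects
#'
#' The defaults state the simulated world at the scale of the study they
#' emulate: about 60 participants, two sessions of 2 conditions x 4 blocks
#' x 40 trials, 40-trial SRT blocks, and planted fast-minus-slow effects of
#' the magnitudes seen in the behavioral and modelling results — in the
#' decision session a lower commitment bound and a ~150 ms shorter motor
#' delay in fast blocks plus a 16-ms tap-interval reduction; in the movement
#' session a slightly lower bound in fast-tapping blocks, unchanged motor
#' delay, and a ~115-ms tap-interval reduction enforced by the snake.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Main-task trials per condition (>= 160 for a
#'   study-faithful run; must be divisible into blocks of `block_size`).
#' @param block_size Trials per block; must be mixture-legal (multiple of 10).
#' @param srt_trials_per_block SRT trials per block.
#' @param seed Master seed; per-participant seeds derive from it.
#' @param decision,movement Per-session generator group means: named lists
#'   with `bound`, `motor_delay`, `tap_interval`, each `c(fast =, slow =)`.
#' @param gain,accum_noise_sd Accumulator settings (shared).
#' @param motor_delay_sd,tap_interval_sd Within-participant trial-to-trial
#'   SDs, ms.
#' @param between Between-participant variation: named list with `bound_cv`
#'   (lognormal coefficient of variation of a shared bound multiplier),
#'   `motor_delay_sd`, `tap_interval_sd` (shared shifts, ms) and
#'   `condition_jitter` (ms, independent per-condition wobble of motor delay
#'   and tap interval — what makes planted differences vary across
#'   participants).
#' @param lapse_prob Invalid-trial probability.
#' @param max_tap_speed Calibrated maximum tapping speed, taps/s.
#' @param detection_latency SRT detection latency, ms.
#' @param frame_rate_fail_prob Probability a trial's recorded frame rate
#'   deviated by >= 1 Hz (trial later excluded).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 58,
                          trials_per_condition = 160,
                          block_size = 40,
                          srt_trials_per_block = 40,
                          seed = 1,
                          decision = list(
                            bound = c(fast = 8.3, slow = 15.5),
                            motor_delay = c(fast = 330, slow = 480),
                            tap_interval = c(fast = 172, slow = 188)),
                          movement = list(
                            bound = c(fast = 12.1, slow = 13.2),
                            motor_delay = c(fast = 420, slow = 420),
                            tap_interval = c(fast = 146, slow = 265)),
                          gain = 1,
                          accum_noise_sd = 0.6,
                          motor_delay_sd = 60,
                          tap_interval_sd = 15,
                          between = list(bound_cv = 0.15,
                                         motor_delay_sd = 40,
                                         tap_interval_sd = 20,
                                         condition_jitter = 5),
                          lapse_prob = 0.04,
                          max_tap_speed = 7,
                          detection_latency = 180,
                          frame_rate_fail_prob = 0.01) {
  if (trials_per_condition %% block_size != 0)
    stop("trials_per_condition must be a multiple of block_size")
  cfg <- list(n_participants = n_participants,
              trials_per_condition = trials_per_condition,
              block_size = block_size,
              srt_trials_per_block = srt_trials_per_block,
              seed = seed, decision = decision, movement = movement,
              gain = gain, accum_noise_sd = accum_noise_sd,
              motor_delay_sd = motor_delay_sd,
              tap_interval_sd = tap_interval_sd, between = between,
              lapse_prob = lapse_prob, max_tap_speed = max_tap_speed,
              detection_latency = detection_latency,
              frame_rate_fail_prob = frame_rate_fail_prob)
  class(cfg) <- "cohort_config"
  cfg
}

# draw one participant's agents (both sessions) around the group means
draw_participant <- function(cfg) {
  b <- cfg$between
  bound_mult <- exp(stats::rnorm(1, 0, b$bound_cv))
  md_shift <- stats::rnorm(1, 0, b$motor_delay_sd)
  ti_shift <- stats::rnorm(1, 0, b$tap_interval_sd)
  mk_agent <- function(sess) {
    md <- pmax(sess$motor_delay + md_shift +
                 stats::rnorm(2, 0, b$condition_jitter), 120)
    # deadline urgency: commit to the leader while the motor delay still
    # (typically) fits inside the decision timeout
    forced <- pmin(pmax(floor((3000 - md - 2 * cfg$motor_delay_sd) /
                                (1000 / 60)), 30), 179)
    agent_params(
      gain = cfg$gain, accum_noise_sd = cfg$accum_noise_sd,
      bound = sess$bound * bound_mult,
      motor_delay_mean = md,
      forced_commit_frame = forced,
      motor_delay_sd = cfg$motor_delay_sd,
      tap_interval_mean = pmax(
        sess$tap_interval + ti_shift +
          stats::rnorm(2, 0, b$condition_jitter), 80),
      tap_interval_sd = cfg$tap_interval_sd,
      lapse_prob = cfg$lapse_prob,
      max_tap_speed = cfg$max_tap_speed)
  }
  list(decision = mk_agent(cfg$decision), movement = mk_agent(cfg$movement))
}

simulate_main_session <- function(agent, session, pid, cfg, design) {
  n_blocks_per_cond <- cfg$trials_per_condition / cfg$block_size
  block_conds <- sample(rep(c("fast", "slow"), n_blocks_per_cond))
  rows <- vector("list", length(block_conds) * cfg$block_size)
  ri <- 0
  trial_id <- 0
  for (bi in seq_along(block_conds)) {
    cond <- block_conds[bi]
    seqs <- make_trial_list(cfg$block_size, design)
    for (s in seqs) {
      trial_id <- trial_id + 1
      lapse <- stats::runif(1)
      premature <- FALSE
      if (lapse < agent$lapse_prob / 2) {
        # anticipation: press before any evidence is useful
        dec <- list(choice = sample(c("left", "right"), 1),
                    commit_frame = NA_integer_,
                    rt = stats::runif(1, 1, 140))
        premature <- TRUE
      } else if (lapse < agent$lapse_prob) {
        dec <- list(choice = "none", commit_frame = NA_integer_,
                    rt = NA_real_)
      } else {
        dec <- simulate_decision(agent, s, cond, design)
      }
      responded <- dec$choice != "none"
      if (responded) {
        tap <- simulate_tapping(agent, cond, session, design)
      } else {
        tap <- list(tap_intervals = rep(NA_real_, 4),
                    movement_correct = FALSE)
      }
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        participant_id = pid, session = session, condition = cond,
        block_index = bi, trial_id = trial_id,
        trial_type = s$trial_type, winner = s$winner,
        rt = dec$rt, choice = dec$choice,
        decision_correct = responded && dec$choice == s$winner,
        commit_frame = dec$commit_frame,
        tap1 = tap$tap_intervals[1], tap2 = tap$tap_intervals[2],
        tap3 = tap$tap_intervals[3], tap4 = tap$tap_intervals[4],
        movement_correct = tap$movement_correct,
        frame_rate_ok = stats::runif(1) >= cfg$frame_rate_fail_prob,
        premature_press = premature,
        steps = paste(ifelse(s$steps > 0, "R", "L"), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete cohort (both sessions plus SRT blocks)
#'
#' Every participant performs the decision session (fast/slow decision
#' blocks plus one snake-free SRT block) and the movement session (fast/slow
#' tapping blocks plus fast and slow SRT blocks). Per-participant agents are
#' drawn around the configured group means; the exact agents are stored in
#' the metadata as ground truth so planted effects can be recomputed. Fully
#' reproducible: participant `i` is simulated under seed `seed + i`.
#'
#' @param cfg A [cohort_config()].
#' @return Object of class `tokens_dataset`: list with `trials` (main-task
#'   table, one row per trial including the frame sequence as an "L"/"R"
#'   string), `srt` (SRT table) and `meta` (config, seed, schema version,
#'   per-participant ground-truth parameters).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  design <- task_design()
  trials <- list(); srt <- list(); truth <- list()
  for (i in seq_len(cfg$n_participants)) {
    set.seed(cfg$seed + i)
    pid <- sprintf("p%03d", i)
    agents <- draw_participant(cfg)
    truth[[pid]] <- lapply(agents, function(a) {
      list(bound = as.list(a$bound),
           motor_delay_mean = as.list(a$motor_delay_mean),
           tap_interval_mean = as.list(a$tap_interval_mean))
    })
    trials[[length(trials) + 1]] <-
      simulate_main_session(agents$decision, "decision", pid, cfg, design)
    trials[[length(trials) + 1]] <-
      simulate_main_session(agents$movement, "movement", pid, cfg, design)
    s1 <- simulate_srt_block(agents$decision, "none",
                             cfg$srt_trials_per_block,
                             cfg$detection_latency)
    s1$session <- "decision"
    s23 <- do.call(rbind, lapply(sample(c("fast", "slow")), function(cc)
      simulate_srt_block(agents$movement, cc, cfg$srt_trials_per_block,
                         cfg$detection_latency)))
    s23$session <- "movement"
    ss <- rbind(s1, s23)
    ss$participant_id <- pid
    srt[[length(srt) + 1]] <- ss
  }
  trials <- do.call(rbind, trials)
  srt <- do.call(rbind, srt)[, c("participant_id", "session", "condition",
                                 "rt", "premature")]
  rownames(trials) <- rownames(srt) <- NULL
  structure(list(trials = trials, srt = srt,
                 meta = list(schema_version = 1L, seed = cfg$seed,
                             config = unclass(cfg), ground_truth = truth)),
            class = "tokens_dataset")
}

trials_schema <- c("participant_id", "session", "condition", "block_index",
                   "trial_id", "trial_type", "winner", "rt", "choice",
                   "decision_correct", "commit_frame", "tap1", "tap2",
                   "tap3", "tap4", "movement_correct", "frame_rate_ok",
                   "premature_press", "steps")
srt_schema <- c("participant_id", "session", "condition", "rt", "premature")

#' Write a dataset to a directory
#'
#' Writes `trials.csv`, `srt.csv` and `meta.json` (seed, config, ground
#' truth, schema version). The round trip through [read_dataset()] is
#' lossless for analysis purposes.
#'
#' @param dataset A `tokens_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tokens_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$srt, file.path(dir, "srt.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the schema; a missing column or an unknown schema version is a
#' hard error naming the problem.
#'
#' @param dir Directory containing `trials.csv`, `srt.csv`, `meta.json`.
#' @return A `tokens_dataset`.
#' @export
read_dataset <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  srt <- utils::read.csv(file.path(dir, "srt.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  for (col in trials_schema)
    if (!col %in% names(trials)) stop("trials.csv: missing column ", col)
  for (col in srt_schema)
    if (!col %in% names(srt)) stop("srt.csv: missing column ", col)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported schema version: ", meta$schema_version)
  structure(list(trials = trials, srt = srt, meta = meta),
            class = "tokens_dataset")
}
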