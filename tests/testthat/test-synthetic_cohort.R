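test_that("noiseless agent commits deterministically at the exact crossing", {
  a <- agent_params(gain = 1, accum_noise_sd = 0, bound = c(fast = 5, slow = 5),
                    motor_delay_mean = c(fast = 300, slow = 300),
                    motor_delay_sd = 0)
  s <- list(steps = rep(1L, 179), trial_type = "obvious", winner = "right")
  class(s) <- "frame_sequence"
  set.seed(1)
  d <- simulate_decision(a, s, "fast")
  expect_equal(d$choice, "right")
  expect_equal(d$commit_frame, 5L)
  expect_equal(d$rt, 5 * 1000 / 60 + 300)

  # commit frame equals first crossing of the noiseless cumulative sum
  set.seed(2)
  sq <- generate_frame_sequence("random")
  d2 <- simulate_decision(a, sq, "slow")
  expected <- which(abs(cumsum(sq$steps)) >= 5)[1]
  expect_equal(d2$commit_frame, expected)
})

test_that("unreachable bound yields a no-response unless urgency forces commitment", {
  s <- list(steps = rep(1L, 179), trial_type = "obvious", winner = "right")
  class(s) <- "frame_sequence"
  a <- agent_params(bound = c(fast = Inf, slow = Inf))
  set.seed(3)
  d <- simulate_decision(a, s, "fast")
  expect_equal(d$choice, "none")
  expect_true(is.na(d$rt))

  af <- agent_params(bound = c(fast = Inf, slow = Inf),
                     forced_commit_frame = 100)
  set.seed(3)
  df <- simulate_decision(af, s, "fast")
  expect_equal(df$commit_frame, 100L)
  expect_equal(df$choice, "right")
})

test_that("choices are symmetric on mirrored evidence", {
  set.seed(4)
  a <- agent_params()
  choices <- character(400)
  for (i in seq_along(choices)) {
    steps <- sample(c(-1L, 1L), 179, replace = TRUE)
    s <- structure(list(steps = steps, trial_type = "random",
                        winner = if (sum(steps) > 0) "right" else "left"),
                   class = "frame_sequence")
    choices[i] <- simulate_decision(a, s, "fast")$choice
  }
  responded <- choices != "none"
  p_right <- mean(choices[responded] == "right")
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / sum(responded)) + 0.02)
})

test_that("tapping correctness follows timeout and snake collision rules", {
  a <- agent_params(tap_interval_mean = c(fast = 174, slow = 174),
                    tap_interval_sd = 0, max_tap_speed = 7)
  set.seed(5)
  t1 <- simulate_tapping(a, "fast", "decision")
  expect_equal(t1$tap_intervals, rep(174, 4))
  expect_true(t1$movement_correct)

  a2 <- agent_params(tap_interval_mean = c(fast = 900, slow = 900),
                     tap_interval_sd = 0)
  expect_false(simulate_tapping(a2, "fast", "decision")$movement_correct)

  # chasing snake at 85% of 7 taps/s: constant tapping slower than
  # 1 / 5.95 s = 168 ms must collide at the predictable tap
  a3 <- agent_params(tap_interval_mean = c(fast = 200, slow = 200),
                     tap_interval_sd = 0, max_tap_speed = 7)
  expect_false(simulate_tapping(a3, "fast", "movement")$movement_correct)
  a4 <- agent_params(tap_interval_mean = c(fast = 150, slow = 150),
                     tap_interval_sd = 0, max_tap_speed = 7)
  expect_true(simulate_tapping(a4, "fast", "movement")$movement_correct)
  # retreating snake at 59.5%: tapping faster than 240 ms intervals collides
  expect_false(simulate_tapping(a4, "slow", "movement")$movement_correct)
  a5 <- agent_params(tap_interval_mean = c(fast = 150, slow = 265),
                     tap_interval_sd = 0, max_tap_speed = 7)
  expect_true(simulate_tapping(a5, "slow", "movement")$movement_correct)
})

test_that("slow conditions are never harder to tap correctly than fast ones", {
  set.seed(6)
  a <- agent_params(tap_interval_mean = c(fast = 160, slow = 280),
                    tap_interval_sd = 20, max_tap_speed = 7)
  fast_ok <- mean(replicate(1000,
    simulate_tapping(a, "fast", "movement")$movement_correct))
  slow_ok <- mean(replicate(1000,
    simulate_tapping(a, "slow", "movement")$movement_correct))
  expect_gte(slow_ok, fast_ok)
})

test_that("SRT reaction times follow the motor-delay model", {
  a0 <- agent_params(motor_delay_mean = c(fast = 400, slow = 400),
                     motor_delay_sd = 0, lapse_prob = 0)
  set.seed(7)
  b <- simulate_srt_block(a0, "fast", 50, detection_latency = 0)
  expect_true(all(b$rt == 400))
  expect_true(all(!b$premature))

  a1 <- agent_params(motor_delay_mean = c(fast = 400, slow = 400),
                     motor_delay_sd = 60, lapse_prob = 0)
  set.seed(8)
  b1 <- simulate_srt_block(a1, "slow", 10000, detection_latency = 180)
  expect_lt(abs(mean(b1$rt) - 580), 2 * 60 / sqrt(10000) + 1)
})

test_that("cohort bookkeeping, determinism and ground-truth metadata hold", {
  cfg <- cohort_config(n_participants = 2, trials_per_condition = 20,
                       block_size = 20, seed = 99)
  ds <- simulate_cohort(cfg)
  expect_equal(nrow(ds$trials), 2 * 2 * 2 * 20)
  expect_equal(nrow(ds$srt), 2 * 3 * 40)
  expect_true(all(ds$trials$rt <= 3000, na.rm = TRUE))
  expect_true(all(ds$trials$choice[is.na(ds$trials$rt)] == "none"))
  # reproducible from the seed
  ds2 <- simulate_cohort(cfg)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$srt, ds2$srt)
  # ground truth records every planted quantity
  gt <- ds$meta$ground_truth$p001$decision
  expect_equal(sort(names(gt)),
               sort(c("bound", "motor_delay_mean", "tap_interval_mean")))
  expect_true(gt$bound$slow > gt$bound$fast)
})

test_that("null planting yields a near-null recovered tap-duration difference", {
  cfg <- cohort_config(
    n_participants = 8, trials_per_condition = 40, block_size = 40,
    seed = 7,
    decision = list(bound = c(fast = 12, slow = 12),
                    motor_delay = c(fast = 400, slow = 400),
                    tap_interval = c(fast = 180, slow = 180)),
    between = list(bound_cv = 0.1, motor_delay_sd = 30,
                   tap_interval_sd = 15, condition_jitter = 3))
  ds <- simulate_cohort(cfg)
  ex <- apply_exclusions(ds)
  ep <- suppressWarnings(compute_endpoints(ex))
  d <- ep[ep$session == "decision", ]
  w <- merge(d[d$condition == "fast", c("participant_id", "tap_duration")],
             d[d$condition == "slow", c("participant_id", "tap_duration")],
             by = "participant_id")
  expect_lt(abs(mean(w[[2]] - w[[3]], na.rm = TRUE)), 10)
})

test_that("datasets survive the CSV round trip and schema errors are named", {
  ds <- small_cohort()
  dir <- file.path(tempdir(), "tokentap-roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$trials$rt, ds$trials$rt)
  expect_equal(back$trials$steps, ds$trials$steps)
  expect_equal(back$srt$rt, ds$srt$rt)
  expect_equal(back$meta$seed, ds$meta$seed)

  broken <- ds$trials[, setdiff(names(ds$trials), "winner")]
  utils::write.csv(broken, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "winner")
  unlink(dir, recursive = TRUE)
})
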