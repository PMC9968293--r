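test_that("exclusion rules remove exactly the planted invalid trials", {
  rows <- do.call(rbind, c(
    lapply(1:7, function(i) toy_trial_row(rt = 1000 + i)),
    list(toy_trial_row(rt = NA, choice = "none"),           # no response
         toy_trial_row(rt = NA, choice = "none"),
         toy_trial_row(rt = 100, premature_press = TRUE))))  # anticipation
  ds <- toy_dataset(rows, toy_srt_rows())
  ex <- apply_exclusions(ds)
  expect_equal(nrow(ex$trials), 7)
  expect_equal(unname(ex$report$counts["no_response"]), 2)
  expect_equal(unname(ex$report$counts["premature_press"]), 1)
  expect_equal(unname(ex$report$counts["anticipation"]), 0)

  # all-valid table produces an all-zero report
  ds2 <- toy_dataset(do.call(rbind, lapply(1:5, function(i)
    toy_trial_row(rt = 1000 + i))), toy_srt_rows())
  expect_true(all(apply_exclusions(ds2)$report$counts == 0))

  # decision-duration anticipation rule: rt - mean SRT < 150
  ds3 <- toy_dataset(rbind(toy_trial_row(rt = 540),   # 540 - 400 = 140 < 150
                           toy_trial_row(rt = 560)),
                     toy_srt_rows(rt = rep(400, 10)))
  ex3 <- apply_exclusions(ds3)
  expect_equal(nrow(ex3$trials), 1)
  expect_equal(unname(ex3$report$counts["anticipation"]), 1)

  # frame-rate violations and fast SRT trials are removed
  ds4 <- toy_dataset(rbind(toy_trial_row(rt = 1000),
                           toy_trial_row(rt = 1000, frame_rate_ok = FALSE)),
                     toy_srt_rows(rt = c(rep(400, 9), 30)))
  ex4 <- apply_exclusions(ds4)
  expect_equal(unname(ex4$report$counts["frame_rate"]), 1)
  expect_equal(unname(ex4$report$counts["srt_anticipation"]), 1)
  expect_equal(nrow(ex4$srt), 9)
})

test_that("retained fraction tracks the planted lapse probability", {
  ds <- small_cohort()
  lapse <- ds$meta$config$lapse_prob
  ex <- apply_exclusions(ds)
  lost <- 1 - ex$report$retained_fraction[["main"]]
  # lapses plus genuine early/timeout/frame-rate losses; the planted lapse
  # rate must be visible and the total stay in a realistic band
  expect_gt(lost, lapse / 2)
  expect_lt(lost, lapse + 0.12)
})

test_that("endpoint measures reproduce hand-computable cases", {
  rows <- do.call(rbind, lapply(1:6, function(i) toy_trial_row(rt = 1000)))
  ds <- toy_dataset(rows, toy_srt_rows(rt = rep(400, 10)))
  ep <- compute_endpoints(apply_exclusions(ds))
  expect_equal(ep$decision_duration, 600)
  expect_equal(ep$tap_duration, 180)
  expect_equal(ep$movement_accuracy, 1)

  # response at the final frame choosing the winner: success probability 1
  late <- do.call(rbind, lapply(1:6, function(i)
    toy_trial_row(rt = 2983, choice = "right")))
  ds2 <- toy_dataset(late, toy_srt_rows(rt = rep(400, 10)))
  ep2 <- compute_endpoints(apply_exclusions(ds2))
  expect_equal(ep2$success_probability, 1)
})

test_that("endpoints are invariant to trial order and match generator truth", {
  ds <- small_cohort()
  ex <- apply_exclusions(ds)
  ep <- suppressWarnings(compute_endpoints(ex))

  ex_shuf <- ex
  set.seed(1)
  ex_shuf$trials <- ex_shuf$trials[sample.int(nrow(ex_shuf$trials)), ]
  ep_shuf <- suppressWarnings(compute_endpoints(ex_shuf))
  expect_equal(ep, ep_shuf)

  # tap durations recovered close to each participant's planted means
  gt <- ds$meta$ground_truth
  d <- ep[ep$session == "movement" & ep$condition == "slow", ]
  planted <- vapply(d$participant_id, function(p)
    gt[[p]]$movement$tap_interval_mean$slow, 0)
  expect_lt(max(abs(d$tap_duration - planted), na.rm = TRUE), 12)

  # an agent that commits on the leading banana scores above chance
  expect_true(all(ep$success_probability > 0.5, na.rm = TRUE))
})

test_that("sign test matches exact binomial hand computations", {
  r <- paired_sign_test(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(r$value, 6)
  expect_equal(r$p, 2 * (1 / 2)^6)

  r2 <- paired_sign_test(c(-1, 1, -1, 1), c(0, 0, 0, 0))
  expect_equal(r2$p, 1.0)

  # 2 positives among 58: far below 1e-12, same order as published values
  x <- c(rep(1, 2), rep(-1, 56))
  r3 <- paired_sign_test(x, rep(0, 58))
  expect_equal(r3$value, 2)
  expect_equal(r3$p, 2 * pbinom(2, 58, 0.5))
  expect_lt(r3$p, 1e-12)

  r4 <- paired_sign_test(rep(0, 6), rep(0, 6))
  expect_true(r4$all_zero)
  expect_equal(r4$p, 1)
})

test_that("signed-rank wrapper agrees with stats::wilcox.test", {
  set.seed(9)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  r <- wilcoxon_signed_rank(x, y)
  w <- wilcox.test(x, y, paired = TRUE)
  expect_equal(r$value, unname(w$statistic))
  expect_equal(r$p, w$p.value)
})

test_that("robust Spearman flags gross planted outliers and none under the null", {
  set.seed(10)
  n <- 50
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.8)
  xo <- c(x, rnorm(5, 10, 0.3)); yo <- c(y, rnorm(5, -10, 0.3))
  r <- spearman_robust(xo, yo)
  expect_true(all(r$outlier[(n + 1):(n + 5)]))
  expect_gt(r$rho_clean, r$rho_full)

  # strictly monotone data: rho 1
  r2 <- spearman_robust(1:20, (1:20)^2)
  expect_equal(r2$rho_full, 1.0)

  # false-flag rate bounded under a clean bivariate normal
  flags <- replicate(20, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    mean(spearman_robust(x, y)$outlier)
  })
  expect_lt(mean(flags), 0.10)

  expect_error(spearman_robust(rep(1, 20), rnorm(20)), "constant")
})

test_that("Spearman rho equals Pearson on ranks with matching t statistic", {
  set.seed(11)
  x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_robust(x, y)
  rho_ranks <- cor(rank(x), rank(y))
  expect_equal(r$rho_full, rho_ranks)
  expect_equal(r$t_full, rho_ranks * sqrt(28 / (1 - rho_ranks^2)))
})

test_that("within-subject CIs center correctly and cover at the nominal rate", {
  # identical condition patterns across participants: zero half-width
  m <- matrix(rep(c(1, 2, 3), 10), nrow = 10, byrow = TRUE) + rnorm(10)
  ci <- within_subject_ci(m)
  expect_equal(ci$ci_halfwidth, rep(0, 3), tolerance = 1e-10)
  expect_equal(ci$mean, colMeans(m))

  # C = 2: Morey factor sqrt(2) exactly
  set.seed(12)
  m2 <- matrix(rnorm(40), 20, 2)
  ci2 <- within_subject_ci(m2)
  centered <- m2 - rowMeans(m2) + mean(m2)
  manual <- sd(centered[, 1]) / sqrt(20) * qt(0.975, 19) * sqrt(2)
  expect_equal(ci2$ci_halfwidth[1], manual)

  # the half-width reflects within-subject noise only: adding large
  # between-subject variance must not widen it
  set.seed(13)
  reps <- t(replicate(200, {
    subj <- rnorm(12, 0, 5)               # large between-subject variance
    within <- matrix(rnorm(24, 0, 1), 12, 2)
    hw_between <- within_subject_ci(cbind(subj, subj + 1) + within)$ci_halfwidth[1]
    shift <- matrix(c(0, 1), 12, 2, byrow = TRUE)
    hw_pure <- within_subject_ci(shift + within)[["ci_halfwidth"]][1]
    c(hw_between, hw_pure)
  }))
  expect_equal(mean(reps[, 1]), mean(reps[, 2]), tolerance = 0.02)
  # and it matches the paired-t theory for C = 2:
  # half-width = qt(.975, n-1) * sd(diff) / sqrt(2 n)
  set.seed(15)
  m3 <- cbind(rnorm(15), rnorm(15, 1))
  hw <- within_subject_ci(m3)$ci_halfwidth
  theory <- qt(0.975, 14) * sd(m3[, 1] - m3[, 2]) / sqrt(2 * 15)
  expect_equal(hw, rep(theory, 2))
})

test_that("Holm adjustment matches hand computation and stats::p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.06, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(14)
  p <- runif(10)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  expect_true(all(holm_adjust(p) >= p))
})
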