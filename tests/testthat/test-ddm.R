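test_that("first-passage density is zero before t0 and normalizes to 1", {
  p <- ddm_params(a = 3.17, v = 0.97, t0 = 0.73)
  expect_equal(wfpt_density(0.72, p, "upper"), 0)
  expect_equal(wfpt_density(c(0.1, 0.5, 0.73), p, "lower"), c(0, 0, 0))

  for (pars in list(c(1, 0.5, 0.2), c(3.17, 0.97, 0.73), c(2, -1, 0.4),
                    c(0.8, 3, 0.1))) {
    p <- ddm_params(pars[1], pars[2], pars[3])
    total <- stats::integrate(function(t) wfpt_density(t, p, "upper"),
                              p$t0, Inf, rel.tol = 1e-9)$value +
      stats::integrate(function(t) wfpt_density(t, p, "lower"),
                       p$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("simulated walks match the analytic density and closed forms", {
  set.seed(30)
  p <- ddm_params(a = 2, v = 1, t0 = 0.3)
  n <- 20000
  s <- simulate_ddm(p, n)
  expect_true(all(!is.na(s$rt)))

  # absorption probability: 1 / (1 + exp(-a v)) at the unbiased start point
  p_up <- 1 / (1 + exp(-p$a * p$v))
  se <- sqrt(p_up * (1 - p_up) / n)
  expect_lt(abs(mean(s$upper) - p_up), 3 * se + 0.005)

  # mean decision time: (a / 2v) tanh(v a / 2)
  mdt <- (p$a / (2 * p$v)) * tanh(p$v * p$a / 2)
  se_t <- sd(s$rt) / sqrt(n)
  expect_lt(abs(mean(s$rt - p$t0) - mdt), 3 * se_t + 0.01)

  # density histogram oracle: binned upper-boundary rts against the
  # integrated analytic density
  up <- s$rt[s$upper == 1]
  breaks <- seq(p$t0, p$t0 + 3, by = 0.25)
  obs <- hist(up[up < p$t0 + 3], breaks = breaks, plot = FALSE)$counts / n
  expected <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(function(t) wfpt_density(t, p, "upper"),
                     breaks[i], breaks[i + 1])$value, 0)
  se_bin <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(obs - expected) < 4 * se_bin + 0.004))
})

test_that("drift symmetry: zero drift splits the boundaries evenly", {
  set.seed(31)
  s <- simulate_ddm(ddm_params(a = 1.5, v = 0, t0 = 0.2), 10000)
  expect_lt(abs(mean(s$upper) - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
})

test_that("MLE fitting recovers generating parameters and is deterministic", {
  set.seed(32)
  truth <- ddm_params(a = 3.17, v = 0.97, t0 = 0.73)
  s <- simulate_ddm(truth, 400, include_outliers = TRUE, max_rt = 3)
  d <- rbind(
    data.frame(rt = s$rt, correct = s$upper == 1, condition = "slow"),
    { s2 <- simulate_ddm(truth, 400, include_outliers = TRUE, max_rt = 3)
      data.frame(rt = s2$rt, correct = s2$upper == 1, condition = "fast") })
  set.seed(33)
  f <- fit_subject_mle(d, ddm_model_spec())
  expect_lt(abs(f$estimates[["a"]] - 3.17) / 3.17, 0.10)
  expect_lt(abs(f$estimates[["v"]] - 0.97) / 0.97, 0.20)
  expect_lt(abs(f$estimates[["t0"]] - 0.73) / 0.73, 0.10)
  set.seed(33)
  f2 <- fit_subject_mle(d, ddm_model_spec())
  expect_identical(f$estimates, f2$estimates)
  expect_error(fit_subject_mle(d[1:60, ], ddm_model_spec()), ">= 50")
})

test_that("nested specs order by likelihood when the drift truly differs", {
  set.seed(34)
  slow <- simulate_ddm(ddm_params(a = 3, v = 0.8, t0 = 0.6), 300)
  fast <- simulate_ddm(ddm_params(a = 2, v = 1.6, t0 = 0.4), 300)
  d <- rbind(data.frame(rt = slow$rt, correct = slow$upper == 1,
                        condition = "slow"),
             data.frame(rt = fast$rt, correct = fast$upper == 1,
                        condition = "fast"))
  set.seed(35)
  f_small <- fit_subject_mle(d, ddm_model_spec(c("a", "t0")))
  set.seed(35)
  f_full <- fit_subject_mle(d, ddm_model_spec(c("a", "t0", "v")))
  expect_gt(f_full$loglik, f_small$loglik)
  expect_lt(f_full$aic, f_small$aic)
  expect_lt(f_full$estimates[["d_a"]], 0)
  expect_gt(f_full$estimates[["d_v"]], 0)
})

test_that("Gelman-Rubin statistic separates mixed from unmixed chains", {
  set.seed(36)
  c1 <- matrix(rnorm(2000), ncol = 2,
               dimnames = list(NULL, c("x", "y")))
  c2 <- matrix(rnorm(2000), ncol = 2,
               dimnames = list(NULL, c("x", "y")))
  r_ok <- gelman_rubin(list(c1, c2))
  expect_true(all(r_ok < 1.05))
  c3 <- c2; c3[, 1] <- c3[, 1] + 5
  r_bad <- gelman_rubin(list(c1, c3))
  expect_gt(r_bad[["x"]], 1.1)
  expect_lt(r_bad[["y"]], 1.05)
  # hand-checked formula on a tiny case
  a <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "z"))
  b <- matrix(c(2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "z"))
  n <- 4
  W <- (var(a[, 1]) + var(b[, 1])) / 2
  B <- n * var(c(mean(a), mean(b)))
  expect_equal(gelman_rubin(list(a, b))[["z"]],
               sqrt(((n - 1) / n * W + B / n) / W))
})

test_that("hierarchical sampler retains the scheduled sample count and converges", {
  set.seed(37)
  mk <- function(i) {
    a <- max(rnorm(1, 3, 0.3), 1); t0 <- max(rnorm(1, 0.6, 0.05), 0.2)
    s1 <- simulate_ddm(ddm_params(a, 1, t0), 120)
    s2 <- simulate_ddm(ddm_params(max(a - 1, 0.5), 1, max(t0 - 0.3, 0.05)),
                       120)
    rbind(data.frame(subject = i, rt = s1$rt, correct = s1$upper == 1,
                     condition = "slow"),
          data.frame(subject = i, rt = s2$rt, correct = s2$upper == 1,
                     condition = "fast"))
  }
  dat <- do.call(rbind, lapply(1:8, mk))
  fit <- fit_hierarchical(dat, ddm_model_spec(c("a", "t0")),
                          burn = 300, n_iter = 600, thin = 3, chains = 2,
                          seed = 5)
  expect_equal(fit$n_samples, 2 * 200)
  expect_true(all(is.finite(fit$rhat)))
  expect_true(is.finite(fit$BPIC))
  expect_gt(fit$pD, 0)
  # the planted negative condition effects are recovered as near-certain
  expect_gt(as.numeric(fit$effect_probabilities[["a"]]), 0.95)
  expect_gt(as.numeric(fit$effect_probabilities[["t0"]]), 0.95)
  # deterministic under the same seed
  fit2 <- fit_hierarchical(dat, ddm_model_spec(c("a", "t0")),
                           burn = 300, n_iter = 600, thin = 3, chains = 2,
                           seed = 5)
  expect_identical(fit$samples, fit2$samples)
})

test_that("BPIC comparison ranks by the deviance formula", {
  mk_fit <- function(Dbar, pD)
    structure(list(BPIC = Dbar + 2 * pD, DIC = Dbar + pD, Dbar = Dbar,
                   pD = pD, converged = TRUE), class = "ddm_fit_hier")
  fits <- list(simple = mk_fit(1000, 10), complex = mk_fit(1000, 25))
  tab <- compare_models(fits)
  expect_equal(tab$model[1], "simple")
  expect_true(attr(tab, "complete"))
  expect_equal(tab$BPIC, tab$Dbar + 2 * tab$pD)
  tab2 <- compare_models(list(simple = mk_fit(1000, 10), missing = NULL))
  expect_false(attr(tab2, "complete"))
  expect_equal(nrow(tab2), 1)
})

test_that("effect probabilities count negative posterior mass with resolution label", {
  x <- -abs(rnorm(4000))
  p <- effect_probability(x)
  expect_equal(as.numeric(p), 1.0)
  expect_equal(attr(p, "label"), "> 99.975%")
  expect_equal(as.numeric(effect_probability(abs(rnorm(2000)) + 0.01)), 0)
  set.seed(38)
  p3 <- effect_probability(rnorm(4000))
  expect_lt(abs(as.numeric(p3) - 0.5), 0.03)
})

test_that("posterior predictive checks pass on own data and flag a planted misfit", {
  set.seed(39)
  truth <- ddm_params(a = 2.2, v = 1.2, t0 = 0.4)
  s <- simulate_ddm(truth, 300)
  d <- data.frame(rt = s$rt, correct = s$upper == 1, condition = "slow")
  by_cond <- data.frame(condition = "slow", a = 2.2, v = 1.2, t0 = 0.4)
  ppc <- posterior_predictive_check(by_cond, d, n_rep = 100)
  expect_lt(mean(ppc$flagged), 0.25)

  wrong <- data.frame(condition = "slow", a = 2.2, v = 1.2, t0 = 0.7)
  ppc2 <- posterior_predictive_check(wrong, d, n_rep = 100)
  med <- ppc2[ppc2$measure == "rt_correct" & ppc2$quantile == 0.5, ]
  expect_true(all(med$flagged))

  # empty condition is skipped silently
  ppc3 <- posterior_predictive_check(
    data.frame(condition = "fast", a = 2, v = 1, t0 = 0.3), d, n_rep = 10)
  expect_equal(nrow(ppc3), 0)
})
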