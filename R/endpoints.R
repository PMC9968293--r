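#' Apply the trial-exclusion rules
#'
#' Removes, in this order of precedence: (a) trials with no response in the
#' decision phase; (b) premature presses in the pre-decision phase; (c)
#' main-task trials whose frame rate deviated by at least 1 Hz from 60 Hz;
#' (d) anticipations — main-task trials whose per-trial decision duration
#' (reaction time minus the participant's mean SRT in the matching block)
#' is below 150 ms. SRT trials are dropped when premature or faster than
#' 50 ms. In the movement session the matching SRT block shares the trial's
#' condition; in the decision session the single snake-free SRT block is
#' used for both conditions. Participants with no valid SRT trials in a
#' required block are dropped with a warning.
#'
#' @param dataset A `tokens_dataset` (see [simulate_cohort()]).
#' @param min_decision_ms Anticipation cutoff on decision duration, ms.
#' @param min_srt_ms Anticipation cutoff on SRT reaction time, ms.
#' @return List of class `filtered_dataset`: `trials` (retained main-task
#'   trials with an `srt_mean` column attached), `srt` (retained SRT
#'   trials), `srt_means` (participant x session x condition table) and
#'   `report` (counts per exclusion rule and retained fractions).
#' @export
apply_exclusions <- function(dataset, min_decision_ms = 150,
                             min_srt_ms = 50) {
  trials <- dataset$trials
  srt <- dataset$srt

  srt_bad <- srt$premature | is.na(srt$rt) | srt$rt < min_srt_ms
  srt_keep <- srt[!srt_bad, , drop = FALSE]
  srt_means <- stats::aggregate(rt ~ participant_id + session + condition,
                                data = srt_keep, FUN = mean)
  names(srt_means)[names(srt_means) == "rt"] <- "srt_mean"

  # matching SRT condition: movement session matches the trial condition,
  # decision session uses the single snake-free block
  key_trial <- paste(trials$participant_id, trials$session,
                     ifelse(trials$session == "movement",
                            trials$condition, "none"))
  key_srt <- paste(srt_means$participant_id, srt_means$session,
                   srt_means$condition)
  trials$srt_mean <- srt_means$srt_mean[match(key_trial, key_srt)]

  no_srt <- unique(trials$participant_id[is.na(trials$srt_mean)])
  if (length(no_srt)) {
    warning("dropping participant(s) with no valid SRT trials: ",
            paste(no_srt, collapse = ", "))
    trials <- trials[!trials$participant_id %in% no_srt, , drop = FALSE]
  }

  no_resp <- is.na(trials$rt) | trials$choice == "none"
  premature <- !no_resp & trials$premature_press
  frame_bad <- !no_resp & !premature & !trials$frame_rate_ok
  anticip <- !no_resp & !premature & !frame_bad &
    (trials$rt - trials$srt_mean) < min_decision_ms
  keep <- !(no_resp | premature | frame_bad | anticip)

  report <- list(
    counts = c(no_response = sum(no_resp), premature_press = sum(premature),
               frame_rate = sum(frame_bad), anticipation = sum(anticip),
               srt_anticipation = sum(srt_bad)),
    n_main = nrow(trials), n_srt = nrow(srt),
    retained_fraction = c(main = mean(keep), srt = mean(!srt_bad)))

  structure(list(trials = trials[keep, , drop = FALSE], srt = srt_keep,
                 srt_means = srt_means, report = report),
            class = "filtered_dataset")
}

#' Per-trial objective success probability at the moment of response
#'
#' Maps each reaction time to its containing frame (ceiling on the 60-Hz
#' grid, capped at the last frame), takes the chosen banana's frame-count
#' lead at that frame, and evaluates [success_probability()] with the frames
#' still to come.
#'
#' @param steps_string "L"/"R" frame string of the trial.
#' @param rt Reaction time, ms.
#' @param choice `"left"` or `"right"`.
#' @param design A [task_design()].
#' @return Probability that the chosen banana ends up longer.
#' @export
trial_success_probability <- function(steps_string, rt, choice,
                                      design = task_design()) {
  steps <- steps_from_string(steps_string)
  f <- min(max(ceiling(rt / frame_ms(design)), 1L), design$n_frames)
  lead <- sum(steps[seq_len(f)]) * if (choice == "right") 1L else -1L
  success_probability(lead, design$n_frames - f)
}

#' Compute the behavioral endpoint table
#'
#' Per participant x session x condition: decision duration (mean reaction
#' time minus the matching SRT block's mean), mean objective success
#' probability at the response frame, tap duration (the four inter-tap
#' intervals averaged within and then across trials), and movement accuracy
#' (fraction of movement-correct trials). Decision duration and success
#' probability are computed over movement-correct trials; movement accuracy
#' over decision-correct trials; tap duration over trials with a complete
#' tap sequence. Cells with fewer than `min_trials` usable trials are set
#' missing with a warning.
#'
#' @param filtered A `filtered_dataset` from [apply_exclusions()].
#' @param min_trials Minimum usable trials per cell and measure.
#' @param design A [task_design()].
#' @return data.frame with columns `participant_id`, `session`, `condition`,
#'   `decision_duration`, `success_probability`, `tap_duration`,
#'   `movement_accuracy` and the per-measure trial counts.
#' @export
compute_endpoints <- function(filtered, min_trials = 5,
                              design = task_design()) {
  stopifnot(inherits(filtered, "filtered_dataset"))
  tr <- filtered$trials
  cells <- unique(tr[, c("participant_id", "session", "condition")])
  cells <- cells[order(cells$participant_id, cells$session,
                       cells$condition), ]
  out <- vector("list", nrow(cells))
  starved <- 0L
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    d <- tr[tr$participant_id == cc$participant_id &
              tr$session == cc$session & tr$condition == cc$condition, ]
    dec <- d[d$movement_correct, ]           # decision measures
    mov <- d[d$decision_correct, ]           # movement accuracy
    taps <- d[stats::complete.cases(d[, c("tap1", "tap2", "tap3", "tap4")]),
              c("tap1", "tap2", "tap3", "tap4")]
    decision_duration <- success_prob <- tap_duration <- move_acc <- NA_real_
    if (nrow(dec) >= min_trials) {
      decision_duration <- mean(dec$rt) - dec$srt_mean[1]
      success_prob <- mean(mapply(trial_success_probability, dec$steps,
                                  dec$rt, dec$choice,
                                  MoreArgs = list(design = design)))
    } else starved <- starved + 1L
    if (nrow(taps) >= min_trials)
      tap_duration <- mean(rowMeans(taps))
    if (nrow(mov) >= min_trials)
      move_acc <- mean(mov$movement_correct)
    out[[i]] <- data.frame(
      participant_id = cc$participant_id, session = cc$session,
      condition = cc$condition, decision_duration = decision_duration,
      success_probability = success_prob, tap_duration = tap_duration,
      movement_accuracy = move_acc, n_decision = nrow(dec),
      n_tap = nrow(taps), n_movement = nrow(mov),
      stringsAsFactors = FALSE)
  }
  if (starved > 0)
    warning(starved, " cell(s) had fewer than ", min_trials,
            " usable trials; endpoint set to NA")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact paired sign test
#'
#' `S` is the number of positive paired differences (zeros dropped); the
#' p-value is the exact two-sided binomial tail probability
#' `min(1, 2 * min(P(X <= S), P(X >= S)))` with `X ~ Binomial(n, 1/2)`.
#' The median difference is reported with a distribution-free
#' order-statistic confidence interval at (at least) 95% coverage.
#'
#' @param x,y Equal-length paired observations.
#' @return Object of class `paired_test`: list with `statistic` (`"S"`),
#'   `value`, `p`, `n` (non-zero pairs), `median_diff`, `ci` and
#'   `all_zero` flag.
#' @export
paired_sign_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0)
    return(structure(list(statistic = "S", value = 0, p = 1, n = 0,
                          median_diff = 0, ci = c(NA, NA), all_zero = TRUE),
                     class = "paired_test"))
  s <- sum(dn > 0)
  p <- min(1, 2 * min(stats::pbinom(s, n, 0.5),
                      stats::pbinom(s - 1, n, 0.5, lower.tail = FALSE)))
  ds <- sort(d)
  m <- length(ds)
  lo_i <- stats::qbinom(0.025, m, 0.5)
  ci <- c(ds[max(lo_i, 1)], ds[min(m - lo_i + 1, m)])
  structure(list(statistic = "S", value = s, p = p, n = n,
                 median_diff = stats::median(d), ci = ci,
                 all_zero = FALSE),
            class = "paired_test")
}

#' Wilcoxon signed-rank test (paired)
#'
#' Thin wrapper around [stats::wilcox.test()] (exact where possible, else
#' normal approximation with mid-ranks for ties), reporting the `V`
#' statistic, the pseudomedian difference and its confidence interval.
#'
#' @param x,y Equal-length paired observations.
#' @return Object of class `paired_test` with `statistic = "V"`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  w <- suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                           conf.int = TRUE))
  structure(list(statistic = "V", value = unname(w$statistic),
                 p = w$p.value, n = sum(x[ok] != y[ok]),
                 median_diff = unname(w$estimate),
                 ci = unname(w$conf.int), all_zero = all(x[ok] == y[ok])),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("%s = %g, p = %.3g, n = %d, median diff = %.4g [%.4g, %.4g]\n",
              x$statistic, x$value, x$p, x$n, x$median_diff,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Spearman correlation with MCD-based outlier robustness check
#'
#' Spearman's rho with `t = rho * sqrt((n - 2) / (1 - rho^2))` and its
#' two-sided p-value, plus the same test repeated after removing bivariate
#' outliers. Outliers are flagged by robust Mahalanobis distances from a
#' reweighted fast minimum-covariance-determinant fit: the raw MCD (subset
#' size `h = floor((n + 3) / 2)`, via `MASS::cov.mcd`) yields initial
#' distances; points within the 97.5% chi-square(2) cutoff are used for a
#' consistency-corrected reweighted location/scatter estimate, whose
#' distances give the final mask. Confidence intervals use the Fisher
#' transform with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y Numeric vectors, `n >= 10`.
#' @param cutoff_p Chi-square quantile used as outlier cutoff.
#' @return Object of class `robust_correlation`: `rho_full`, `t_full`,
#'   `p_full`, `ci_full`, `outlier` (logical mask), `rho_clean`, `t_clean`,
#'   `p_clean`, `ci_clean`, `n`.
#' @export
spearman_robust <- function(x, y, cutoff_p = 0.975) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("spearman_robust needs n >= 10")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  spearman <- function(x, y) {
    n <- length(x)
    rho <- stats::cor(x, y, method = "spearman")
    t <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
    z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
    list(rho = rho, t = t, p = p, ci = ci)
  }
  full <- spearman(x, y)

  X <- cbind(x, y)
  q <- stats::qchisq(cutoff_p, df = 2)
  h <- floor((n + 3) / 2)
  raw <- MASS::cov.mcd(X, quantile.used = h)
  d2 <- stats::mahalanobis(X, raw$center, raw$cov)
  w <- d2 <= q
  # consistency-corrected reweighted estimate
  cf <- stats::pchisq(q, df = 4) / stats::pchisq(q, df = 2)
  ctr <- colMeans(X[w, , drop = FALSE])
  cv <- stats::cov(X[w, , drop = FALSE]) / cf
  d2 <- stats::mahalanobis(X, ctr, cv)
  outlier <- d2 > q

  clean <- spearman(x[!outlier], y[!outlier])
  structure(list(rho_full = full$rho, t_full = full$t, p_full = full$p,
                 ci_full = full$ci, outlier = outlier,
                 rho_clean = clean$rho, t_clean = clean$t,
                 p_clean = clean$p, ci_clean = clean$ci, n = n),
            class = "robust_correlation")
}

#' Within-subject condition means and confidence intervals
#'
#' Cousineau centering (each participant's values shifted so their personal
#' mean equals the grand mean) removes between-subject variance; the
#' half-width of the 95% t-based interval of each condition mean on the
#' centered data is inflated by the Morey factor `sqrt(C / (C - 1))` for
#' `C` conditions. Participants with missing cells are dropped with a
#' warning.
#'
#' @param values Numeric matrix or data.frame, participants x conditions.
#' @return data.frame with `condition`, `mean`, `ci_halfwidth`, `n`.
#' @export
within_subject_ci <- function(values) {
  m <- as.matrix(values)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning("dropping ", sum(!complete), " participant(s) with missing cells")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); C <- ncol(m)
  stopifnot(n >= 2, C >= 2)
  centered <- m - rowMeans(m) + mean(m)
  morey <- sqrt(C / (C - 1))
  data.frame(
    condition = colnames(m) %||% paste0("c", seq_len(C)),
    mean = colMeans(m),
    ci_halfwidth = apply(centered, 2, stats::sd) / sqrt(n) *
      stats::qt(0.975, n - 1) * morey,
    n = n, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the p-values, multiplies the i-th smallest by `(m - i + 1)`,
#' enforces monotonicity by running maxima, caps at 1, and restores the
#' input order.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  if (m <= 1) return(pvals)
  ord <- order(pvals)
  adj <- pmin(cummax((m - seq_len(m) + 1) * pvals[ord]), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
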