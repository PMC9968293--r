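#' Sliding-window momentary evidence sums
#'
#' Sums the -1/+1 evidence steps over windows of a fixed timespan, moved one
#' frame at a time across the trial. Legal timespans are whole numbers of
#' frames on the 60-Hz grid: 200, 300, 400 or 500 ms (12, 18, 24, 30
#' frames). Each window is indexed by its final frame — the first moment at
#' which all of the summed evidence has been seen.
#'
#' @param steps Integer vector of -1/+1 steps (or an "L"/"R" string).
#' @param timespan Window length, ms.
#' @param design A [task_design()].
#' @return Numeric vector of window sums; element `i` is the window ending
#'   at frame `w + i - 1` (attribute `end_frame` gives the frame indices).
#' @export
momentary_evidence_series <- function(steps, timespan,
                                      design = task_design()) {
  if (is.character(steps)) steps <- steps_from_string(steps)
  w <- timespan / frame_ms(design)
  if (abs(w - round(w)) > 1e-9)
    stop("timespan must be a whole number of frames; legal values include ",
         "200, 300, 400, 500 ms")
  w <- as.integer(round(w))
  n <- length(steps)
  if (w > n) stop("timespan longer than the trial")
  cs <- cumsum(steps)
  sums <- cs[w:n] - c(0, cs)[seq.int(1, n - w + 1)]
  attr(sums, "end_frame") <- seq.int(w, n)
  attr(sums, "window_frames") <- w
  sums
}

#' Response-locked psychophysical kernel
#'
#' For every lag relative to the response, correlates the momentary-evidence
#' window sum presented at that lag with the signed decision (-1 left,
#' +1 right) across trials. The response is mapped to its containing frame
#' (ceiling on the 60-Hz grid); lag 0 is the window ending at the response
#' frame and negative lags precede the response. Trials whose reaction time
#' is too short to contain a given lag simply drop out at that lag; lags
#' retaining fewer than `min_per_lag` trials are left undefined. Trials
#' faster than 150 ms are discarded up front.
#'
#' @param trials data.frame with columns `steps` ("L"/"R" strings), `rt`
#'   (ms) and `choice` (`"left"`/`"right"`).
#' @param timespan Window length, ms.
#' @param design A [task_design()].
#' @param min_rt_ms Anticipation cutoff.
#' @param min_trials Minimum trials for a kernel to be computed at all.
#' @param min_per_lag Minimum trials per lag for a defined correlation.
#' @return Object of class `psychophysical_kernel`: data.frame with
#'   `lag_frames`, `lag_ms`, `r`, `n`; attributes `timespan`, `n_trials`,
#'   `median_rt`.
#' @export
compute_kernel <- function(trials, timespan, design = task_design(),
                           min_rt_ms = 150, min_trials = 30,
                           min_per_lag = 10) {
  keep <- !is.na(trials$rt) & trials$rt >= min_rt_ms &
    trials$choice %in% c("left", "right")
  trials <- trials[keep, , drop = FALSE]
  nt <- nrow(trials)
  if (nt < min_trials)
    stop("kernel refused: only ", nt, " usable trials (need ", min_trials,
         ")")
  w <- as.integer(round(timespan / frame_ms(design)))
  n <- design$n_frames
  resp_frame <- pmin(pmax(ceiling(trials$rt / frame_ms(design)), 1L), n)
  decision <- ifelse(trials$choice == "right", 1, -1)

  lag_min <- min(w - resp_frame)
  lag_max <- max(n - resp_frame)
  lags <- lag_min:lag_max
  ev <- matrix(NA_real_, nt, length(lags))
  for (i in seq_len(nt)) {
    sums <- momentary_evidence_series(trials$steps[i], timespan, design)
    ends <- attr(sums, "end_frame")
    cols <- ends - resp_frame[i] - lag_min + 1L
    ev[i, cols] <- sums
  }
  r <- rep(NA_real_, length(lags))
  n_lag <- integer(length(lags))
  for (j in seq_along(lags)) {
    idx <- which(!is.na(ev[, j]))
    n_lag[j] <- length(idx)
    if (n_lag[j] >= min_per_lag) {
      e <- ev[idx, j]
      if (stats::sd(e) > 0 && stats::sd(decision[idx]) > 0)
        r[j] <- stats::cor(e, decision[idx])
      else r[j] <- 0
    }
  }
  out <- data.frame(lag_frames = lags, lag_ms = lags * frame_ms(design),
                    r = r, n = n_lag)
  structure(out, class = c("psychophysical_kernel", "data.frame"),
            timespan = timespan, n_trials = nt,
            median_rt = stats::median(trials$rt))
}

#' Kernel slope and peak-latency statistics
#'
#' The peak is the lag of the maximum correlation within the decision
#' window, from the expected decision onset (minus the median reaction
#' time) to the response; ties break toward the lag closest to the
#' response. The slope is the ordinary least-squares slope of the kernel
#' against time (in correlation units per second) from decision onset to
#' the peak; the peak latency is the time from the peak to the response.
#'
#' @param kernel A `psychophysical_kernel` (or data.frame with `lag_ms`,
#'   `r`).
#' @param median_rt Median reaction time, ms; defaults to the kernel's own.
#' @return List of class `kernel_stats`: `slope` (1/s), `peak_latency`
#'   (ms), `peak_lag` (ms), `median_rt` (ms).
#' @export
kernel_stats <- function(kernel, median_rt = attr(kernel, "median_rt")) {
  if (is.null(median_rt)) stop("median_rt required")
  seg <- kernel[kernel$lag_ms >= -median_rt & kernel$lag_ms <= 0 &
                  !is.na(kernel$r), , drop = FALSE]
  if (nrow(seg) == 0)
    stop("kernel undefined over the decision window; stats refused")
  peak_r <- max(seg$r)
  cand <- seg$lag_ms[seg$r == peak_r]
  peak_lag <- cand[which.max(cand)]        # tie-break: closest to response
  rise <- seg[seg$lag_ms <= peak_lag, , drop = FALSE]
  slope <- if (nrow(rise) >= 2)
    unname(stats::coef(stats::lm(r ~ I(lag_ms / 1000), data = rise))[2])
  else 0
  structure(list(slope = slope, peak_latency = -peak_lag,
                 peak_lag = peak_lag, median_rt = median_rt),
            class = "kernel_stats")
}

#' Compute kernels and their statistics for a whole dataset
#'
#' Convenience layer: per participant x session x condition x timespan,
#' computes the kernel and its slope/peak-latency statistics. Cells whose
#' kernel is refused (too few trials) are skipped.
#'
#' @param trials Main-task trial table (movement-correct filtering is the
#'   caller's choice; rt and choice validity are enforced here).
#' @param timespans Window lengths, ms.
#' @param design A [task_design()].
#' @return data.frame: `participant_id`, `session`, `condition`,
#'   `timespan`, `slope`, `peak_latency`, `median_rt`.
#' @export
kernel_stats_table <- function(trials, timespans = c(200, 300, 400, 500),
                               design = task_design()) {
  cells <- unique(trials[, c("participant_id", "session", "condition")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    d <- trials[trials$participant_id == cc$participant_id &
                  trials$session == cc$session &
                  trials$condition == cc$condition, ]
    for (ts in timespans) {
      st <- tryCatch({
        k <- compute_kernel(d, ts, design)
        kernel_stats(k)
      }, error = function(e) NULL)
      if (is.null(st)) next
      out[[length(out) + 1]] <- data.frame(
        participant_id = cc$participant_id, session = cc$session,
        condition = cc$condition, timespan = ts, slope = st$slope,
        peak_latency = st$peak_latency, median_rt = st$median_rt,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare kernel statistics between conditions
#'
#' For each session, measure (slope, peak latency) and timespan: computes
#' fast-minus-slow paired differences across participants, applies a
#' Shapiro-Wilk normality gate (alpha 0.05) to choose between a paired
#' t-test and the Wilcoxon signed-rank test (degenerate all-equal
#' differences fall back to the exact sign test), and Holm-adjusts the four
#' timespans' p-values within each session and measure.
#'
#' @param stats_table Output of [kernel_stats_table()].
#' @return data.frame with one row per session x measure x timespan:
#'   `mean_diff`, `test` used, `p`, `p_holm`, `n`.
#' @export
compare_kernel_stats <- function(stats_table) {
  out <- list()
  for (sess in unique(stats_table$session)) {
    for (measure in c("slope", "peak_latency")) {
      rows <- list()
      for (ts in sort(unique(stats_table$timespan))) {
        d <- stats_table[stats_table$session == sess &
                           stats_table$timespan == ts, ]
        wide <- merge(d[d$condition == "fast",
                        c("participant_id", measure)],
                      d[d$condition == "slow",
                        c("participant_id", measure)],
                      by = "participant_id", suffixes = c("_fast", "_slow"))
        diffs <- wide[[paste0(measure, "_fast")]] -
          wide[[paste0(measure, "_slow")]]
        diffs <- diffs[!is.na(diffs)]
        n <- length(diffs)
        if (n < 3) next
        sw_p <- tryCatch(stats::shapiro.test(diffs)$p.value,
                         error = function(e) 0)
        if (sw_p >= 0.05) {
          test <- "t"
          p <- stats::t.test(diffs)$p.value
        } else if (length(unique(diffs)) == 1) {
          test <- "sign"
          p <- paired_sign_test(diffs, rep(0, n))$p
        } else {
          test <- "wilcoxon"
          p <- suppressWarnings(stats::wilcox.test(diffs)$p.value)
        }
        rows[[length(rows) + 1]] <- data.frame(
          session = sess, measure = measure, timespan = ts,
          mean_diff = mean(diffs), test = test, p = p, n = n,
          stringsAsFactors = FALSE)
      }
      if (!length(rows)) next
      block <- do.call(rbind, rows)
      block$p_holm <- holm_adjust(block$p)
      out[[length(out) + 1]] <- block
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
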