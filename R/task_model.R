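#' Task design constants for the banana-growth Tokens task
#'
#' Bundles the fixed stimulus parameters of the task: two bananas grow around
#' a circular track at 60 Hz, and on every screen refresh exactly one of them
#' is extended by 2 degrees. A trial's decision phase lasts 179 frames
#' (2983 ms), so that one banana always finishes strictly longer. After the
#' decision key press, four further taps (36 degrees each) move a caterpillar
#' during a fixed 3000-ms movement phase. Trials come in four difficulty
#' types mixed 30/30/20/20 (obvious/ambiguous/misleading/random); in the
#' movement session a snake chases at 85% (fast blocks) or retreats at 59.5%
#' (slow blocks) of the participant's maximum tapping speed.
#'
#' The classification constants (`p_band_lo`, `p_band_hi`, `early_frames`,
#' `burnin_frames`) operationalize the qualitative trial-type definitions:
#' they are stored here, not hard-coded, so they can be changed without
#' touching the classifier.
#'
#' @param frame_rate Screen refresh rate in Hz.
#' @param n_frames Number of evidence frames per decision phase (must be odd).
#' @param degrees_per_frame Angular growth per frame, degrees.
#' @param decision_timeout Decision-phase timeout, ms.
#' @param movement_timeout Movement-phase duration, ms.
#' @param n_taps_after_decision Number of taps required after the decision press.
#' @param degrees_per_tap Caterpillar advance per tap, degrees.
#' @param type_mixture Named proportions of the four trial types; must sum to 1.
#' @param snake_fast_fraction Chasing-snake speed as fraction of maximum
#'   tapping speed (fast-tapping blocks).
#' @param snake_slow_fraction Retreating-snake speed as fraction of maximum
#'   tapping speed (slow-tapping blocks).
#' @param p_band_lo,p_band_hi Running-success-probability band edges used by
#'   [classify_trial_type()] for the obvious and misleading types.
#' @param ambiguous_band_lo,ambiguous_band_hi Wider probability band inside
#'   which an ambiguous trial must remain over the early horizon. A trial
#'   whose winner's running success probability stays strictly inside
#'   (0.4, 0.6) for 90 frames is a roughly 1-in-30000 event, so the
#'   ambiguous band is wider than the obvious/misleading thresholds: 0.3/0.7
#'   keeps the race visually neck-and-neck (lead within about 5 frames)
#'   while making rejection sampling practical (about 7% acceptance).
#' @param early_frames Last frame still counted as "early/halfway" (frames).
#' @param burnin_frames Frames ignored at trial start when requiring an
#'   obvious trial's sustained lead.
#' @return An object of class `task_design` (a named list).
#' @examples
#' d <- task_design()
#' d$n_frames * d$degrees_per_frame  # 358 degrees of total growth
#' @export
task_design <- function(frame_rate = 60,
                        n_frames = 179,
                        degrees_per_frame = 2,
                        decision_timeout = 3000,
                        movement_timeout = 3000,
                        n_taps_after_decision = 4,
                        degrees_per_tap = 36,
                        type_mixture = c(obvious = 0.30, ambiguous = 0.30,
                                         misleading = 0.20, random = 0.20),
                        snake_fast_fraction = 0.85,
                        snake_slow_fraction = 0.595,
                        p_band_lo = 0.4,
                        p_band_hi = 0.6,
                        ambiguous_band_lo = 0.3,
                        ambiguous_band_hi = 0.7,
                        early_frames = 90,
                        burnin_frames = 30) {
  if (n_frames %% 2 != 1L)
    stop("n_frames must be odd so that one banana always finishes longer")
  if (abs(sum(type_mixture) - 1) > 1e-12)
    stop("type_mixture must sum to 1")
  if (!identical(sort(names(type_mixture)), sort(trial_types())))
    stop("type_mixture must be named: ", paste(trial_types(), collapse = ", "))
  d <- list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
            degrees_per_frame = degrees_per_frame,
            decision_timeout = decision_timeout,
            movement_timeout = movement_timeout,
            n_taps_after_decision = as.integer(n_taps_after_decision),
            degrees_per_tap = degrees_per_tap,
            type_mixture = type_mixture[trial_types()],
            snake_fast_fraction = snake_fast_fraction,
            snake_slow_fraction = snake_slow_fraction,
            p_band_lo = p_band_lo, p_band_hi = p_band_hi,
            ambiguous_band_lo = ambiguous_band_lo,
            ambiguous_band_hi = ambiguous_band_hi,
            early_frames = as.integer(early_frames),
            burnin_frames = as.integer(burnin_frames))
  class(d) <- "task_design"
  d
}

#' The closed set of trial-type labels
#' @return Character vector of the four labels.
#' @export
trial_types <- function() c("obvious", "ambiguous", "misleading", "random")

#' Frame duration in milliseconds
#' @param design A [task_design()].
#' @return Milliseconds per frame (1000/60 by default).
#' @export
frame_ms <- function(design = task_design()) 1000 / design$frame_rate

#' Objective success probability given the current evidence state
#'
#' Probability that a designated banana finishes strictly longer, given it
#' currently leads by `delta` frames and `remaining` frames are still to be
#' shown, under the model that each remaining frame independently extends
#' either banana with probability 1/2. With `K ~ Binomial(remaining, 1/2)`
#' frames going to the designated banana, its final lead is
#' `delta + 2K - remaining`, so the value returned is
#' `P(delta + 2K - remaining > 0)`. Ties (possible only when
#' `delta + remaining` is even) count as failures, so
#' `f(delta) + f(-delta) = 1` holds exactly when no tie is possible.
#'
#' @param delta Signed frame-count lead of the designated banana (vectorized).
#' @param remaining Number of frames not yet shown (vectorized, >= 0).
#' @return Probability in `[0, 1]`, vectorized over inputs.
#' @seealso [success_probability_oracle()] for the exhaustive-enumeration
#'   reference implementation.
#' @examples
#' success_probability(3, 0)   # lead decides: 1
#' success_probability(0, 1)   # symmetric: 0.5
#' success_probability(1, 2)   # 0.75
#' @export
success_probability <- function(delta, remaining) {
  if (any(remaining < 0)) stop("invalid evidence state: remaining < 0")
  if (any(remaining != round(remaining)) || any(delta != round(delta)))
    stop("delta and remaining must be integers")
  # success iff K > (remaining - delta)/2
  stats::pbinom(floor((remaining - delta) / 2), size = remaining, prob = 0.5,
                lower.tail = FALSE)
}

#' Success probability by exhaustive enumeration (test oracle)
#'
#' Identical contract to [success_probability()], computed by enumerating all
#' `2^remaining` assignments of the remaining frames. Deliberately
#' independent of the binomial-tail implementation; refuses `remaining > 20`.
#'
#' @inheritParams success_probability
#' @return Probability in `[0, 1]` (scalar).
#' @export
success_probability_oracle <- function(delta, remaining) {
  stopifnot(length(delta) == 1L, length(remaining) == 1L)
  if (remaining < 0) stop("invalid evidence state: remaining < 0")
  if (remaining > 20) stop("refusing enumeration for remaining > 20")
  if (remaining == 0) return(as.numeric(delta > 0))
  n_success <- 0L
  for (code in 0:(2^remaining - 1)) {
    # bit b set = frame b+1 goes to the designated banana
    k <- sum(bitwAnd(bitwShiftR(code, 0:(remaining - 1L)), 1L))
    if (delta + 2L * k - remaining > 0L) n_success <- n_success + 1L
  }
  n_success / 2^remaining
}

#' Classify a frame sequence into one of the four trial types
#'
#' Uses the running success probability `p_w(t)` of the eventual winner
#' (computed from its lead after frame `t` and the frames still to come).
#' With the default bands, "early" horizon 90 frames (about half the trial)
#' and burn-in 30 frames, the rules are applied in order:
#' \describe{
#'   \item{obvious}{`p_w(t) >= 0.6` for every frame after the burn-in (an
#'     early lead, sustained to the end).}
#'   \item{misleading}{`p_w(t) <= 0.4` at some frame within the early
#'     horizon, yet the winner prevails.}
#'   \item{ambiguous}{`0.3 < p_w(t) < 0.7` for every frame within the early
#'     horizon (the race stays undecided until about halfway).}
#'   \item{random}{anything else.}
#' }
#'
#' Because `p_w` is monotone in the winner's lead at a fixed number of
#' remaining frames, each probability band is equivalent to an integer band
#' on the lead itself; those thresholds are precomputed per design and
#' cached, making classification cheap enough for rejection sampling.
#'
#' @param steps Integer vector of -1/+1 evidence steps (full trial length).
#' @param design A [task_design()].
#' @return One of `"obvious"`, `"ambiguous"`, `"misleading"`, `"random"`.
#' @export
classify_trial_type <- function(steps, design = task_design()) {
  n <- design$n_frames
  if (length(steps) != n) stop("sequence must have length ", n)
  if (!all(steps %in% c(-1L, 1L))) stop("steps must be -1 or +1")
  total <- sum(steps)
  if (total == 0) stop("no winner: sequence sums to zero")
  lead <- cumsum(steps) * sign(total)
  th <- type_thresholds(design)
  early <- seq_len(design$early_frames)
  after_burnin <- (design$burnin_frames + 1L):n
  if (all(lead[after_burnin] >= th$obvious_min[after_burnin]))
    return("obvious")
  if (any(lead[early] <= th$misleading_max[early])) return("misleading")
  if (all(lead[early] > th$ambiguous_lo[early] &
            lead[early] < th$ambiguous_hi[early]))
    return("ambiguous")
  "random"
}

.threshold_cache <- new.env(parent = emptyenv())

# integer lead thresholds equivalent to the probability bands:
#   obvious_min[t]    = smallest lead with p_w >= p_band_hi
#   misleading_max[t] = largest lead with p_w <= p_band_lo
#   ambiguous_lo/hi   = band (exclusive) equivalent to the ambiguous p-band
type_thresholds <- function(design) {
  key <- paste(design$n_frames, design$p_band_lo, design$p_band_hi,
               design$ambiguous_band_lo, design$ambiguous_band_hi,
               sep = "|")
  cached <- .threshold_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- design$n_frames
  obvious_min <- misleading_max <- ambiguous_lo <- ambiguous_hi <-
    integer(n)
  for (t in seq_len(n)) {
    r <- n - t
    ds <- seq.int(-min(t, 60L), min(t, 60L))
    p <- success_probability(ds, r)
    obvious_min[t] <- if (any(p >= design$p_band_hi))
      ds[which(p >= design$p_band_hi)[1]] else t + 1L
    misleading_max[t] <- if (any(p <= design$p_band_lo))
      max(ds[p <= design$p_band_lo]) else -(t + 1L)
    lo <- ds[p <= design$ambiguous_band_lo]
    hi <- ds[p >= design$ambiguous_band_hi]
    ambiguous_lo[t] <- if (length(lo)) max(lo) else -(t + 1L)
    ambiguous_hi[t] <- if (length(hi)) hi[1] else t + 1L
  }
  th <- list(obvious_min = obvious_min, misleading_max = misleading_max,
             ambiguous_lo = ambiguous_lo, ambiguous_hi = ambiguous_hi)
  .threshold_cache[[key]] <- th
  th
}

#' Generate a frame sequence of a requested trial type
#'
#' Rejection-samples uniform fair-coin step sequences until
#' [classify_trial_type()] returns the requested type, which keeps the
#' per-frame marginal distribution within a type close to uniform. For the
#' `"random"` type the first draw is accepted unconditionally (any growth
#' pattern is legal), so its classified label may be any of the four.
#'
#' @param trial_type One of [trial_types()].
#' @param design A [task_design()].
#' @param max_draws Rejection budget before failing.
#' @return A `frame_sequence`: list with `steps` (-1/+1 integer vector),
#'   `trial_type` (requested label) and `winner` (`"left"` or `"right"`).
#' @export
generate_frame_sequence <- function(trial_type, design = task_design(),
                                    max_draws = 1e5) {
  trial_type <- match.arg(trial_type, trial_types())
  for (i in seq_len(max_draws)) {
    steps <- sample(c(-1L, 1L), design$n_frames, replace = TRUE)
    if (trial_type == "random" ||
        classify_trial_type(steps, design) == trial_type) {
      seq_out <- list(steps = steps, trial_type = trial_type,
                      winner = if (sum(steps) > 0) "right" else "left")
      class(seq_out) <- "frame_sequence"
      return(seq_out)
    }
  }
  stop("failed to generate a '", trial_type, "' sequence within ",
       max_draws, " draws")
}

#' Mirror a frame sequence left/right
#' @param seq A `frame_sequence`.
#' @return The sequence with steps negated and winner flipped.
#' @keywords internal
mirror_sequence <- function(seq) {
  seq$steps <- -seq$steps
  seq$winner <- if (seq$winner == "right") "left" else "right"
  seq
}

#' Build a trial list with the exact design mixture
#'
#' Deterministic composition (counts are `n_trials` times the mixture, which
#' must be integers — e.g. any multiple of 10 with the default 30/30/20/20
#' mixture), shuffled presentation order. Winner sides are counterbalanced to
#' within one trial per type by mirror-imaging every second accepted
#' sequence.
#'
#' @param n_trials Number of trials; each mixture share must be an integer.
#' @param design A [task_design()].
#' @return A list of `frame_sequence` objects, length `n_trials`.
#' @examples
#' trials <- make_trial_list(10)
#' table(vapply(trials, `[[`, "", "trial_type"))
#' @export
make_trial_list <- function(n_trials, design = task_design()) {
  counts <- design$type_mixture * n_trials
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("n_trials = ", n_trials, " is not divisible by the type mixture; ",
         "use a multiple of 10")
  counts <- round(counts)
  trials <- list()
  for (ty in names(counts)) {
    for (i in seq_len(counts[[ty]])) {
      s <- generate_frame_sequence(ty, design)
      # counterbalance winner side within type to within one trial
      want_right <- i %% 2L == 1L
      if ((s$winner == "right") != want_right) s <- mirror_sequence(s)
      trials[[length(trials) + 1L]] <- s
    }
  }
  trials[sample.int(length(trials))]
}

#' Serialize frame sequences to a data frame
#'
#' One row per trial with columns `trial_id`, `trial_type`, `winner` and
#' `steps`, the latter a string of "L"/"R" characters (one per frame).
#'
#' @param trials List of `frame_sequence` objects.
#' @return A data.frame.
#' @export
sequences_to_frame <- function(trials) {
  data.frame(
    trial_id = seq_along(trials),
    trial_type = vapply(trials, `[[`, "", "trial_type"),
    winner = vapply(trials, `[[`, "", "winner"),
    steps = vapply(trials, function(s)
      paste(ifelse(s$steps > 0, "R", "L"), collapse = ""), ""),
    stringsAsFactors = FALSE
  )
}

#' Decode an "L"/"R" step string back to -1/+1 steps
#' @param steps_string String of "L" and "R" characters.
#' @return Integer vector of -1/+1.
#' @export
steps_from_string <- function(steps_string) {
  ch <- strsplit(steps_string, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("L", "R"))) stop("steps string may contain only L and R")
  ifelse(ch == "R", 1L, -1L)
}
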