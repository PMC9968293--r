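#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. `cohort` holds arguments for
#' [cohort_config()]; `stat` chooses the paired test (`"sign"`, the exact
#' sign test, or `"signed_rank"`); `ddm` controls the model-fitting stage
#' (`mode` `"mle"` or `"hier"`, the fitted `spec`, and — in hierarchical
#' mode — whether all five candidate specs are compared and the MCMC
#' schedule); `kernels` sets the analysis timespans.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cohort = list(),            # overrides for cohort_config()
    seed = 1,
    stat = "sign",
    ddm = list(mode = "mle", spec = "a+t0+v", compare = FALSE,
               mcmc = list(burn = 5000, n_iter = 6000, thin = 3,
                           chains = 2)),
    kernels = list(timespans = c(200, 300, 400, 500))
  )
}

#' Validate and complete a pipeline configuration
#'
#' Fills missing entries from [default_config()] and rejects unknown keys
#' (no silent typos), recursively.
#'
#' @param config Partial configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  merge_checked <- function(def, cfg, path = "") {
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(cfg)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]])) &&
          is.list(cfg[[k]]) && k != "cohort") {
        def[[k]] <- merge_checked(def[[k]], cfg[[k]], paste0(path, k, "$"))
      } else {
        def[[k]] <- cfg[[k]]
      }
    }
    def
  }
  cfg <- merge_checked(default_config(), config)
  if (!cfg$stat %in% c("sign", "signed_rank"))
    stop("stat must be 'sign' or 'signed_rank'")
  if (!cfg$ddm$mode %in% c("mle", "hier"))
    stop("ddm$mode must be 'mle' or 'hier'")
  cohort_unknown <- setdiff(names(cfg$cohort),
                            names(formals(cohort_config)))
  if (length(cohort_unknown))
    stop("unknown config key(s): ",
         paste0("cohort$", cohort_unknown, collapse = ", "))
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

paired_by_condition <- function(endpoints, session, measure, stat) {
  d <- endpoints[endpoints$session == session, ]
  wide <- merge(d[d$condition == "fast", c("participant_id", measure)],
                d[d$condition == "slow", c("participant_id", measure)],
                by = "participant_id", suffixes = c("_fast", "_slow"))
  x <- wide[[paste0(measure, "_fast")]]
  y <- wide[[paste0(measure, "_slow")]]
  ok <- !is.na(x) & !is.na(y)
  test <- if (stat == "sign") paired_sign_test(x[ok], y[ok])
          else wilcoxon_signed_rank(x[ok], y[ok])
  list(session = session, measure = measure,
       mean_fast = mean(x[ok]), mean_slow = mean(y[ok]),
       median_fast = stats::median(x[ok]),
       median_slow = stats::median(y[ok]),
       mean_diff = mean(x[ok] - y[ok]),
       statistic = test$statistic, value = test$value, p = test$p,
       n = test$n)
}

ddm_data_from_trials <- function(trials, session) {
  d <- trials[trials$session == session & !is.na(trials$rt) &
                trials$choice != "none", ]
  data.frame(subject = d$participant_id, rt = d$rt / 1000,
             correct = d$decision_correct, condition = d$condition,
             stringsAsFactors = FALSE)
}

#' Run the full simulate - endpoints - DDM - kernels pipeline
#'
#' Simulates a cohort from the configuration, applies the exclusion rules,
#' computes endpoint measures and paired condition tests per session, fits
#' the drift-diffusion model (per-subject maximum likelihood by default,
#' with paired tests on the per-subject condition differences; optionally a
#' hierarchical fit with candidate-model BPIC comparison), derives
#' psychophysical kernels and their condition statistics, and assembles a
#' machine-readable report including a planted-versus-recovered comparison
#' against the generator's ground truth. All randomness flows from
#' `config$seed`; a rerun with the same configuration reproduces the same
#' numbers. With `out_dir` set, every intermediate is persisted
#' (`trials.csv`, `srt.csv`, `meta.json`, `endpoints.csv`,
#' `kernel_stats.csv`, `report.json`).
#'
#' @param config Partial configuration, see [default_config()].
#' @param out_dir Optional output directory.
#' @return List of class `run_report`: per-stage `status`, key statistics,
#'   the planted-vs-recovered table, configuration hash.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  report <- list(config = cfg, config_hash = config_hash(cfg),
                 package_version = as.character(utils::packageVersion(
                   "tokentap")),
                 stages = list())
  status <- function(nm, ok, err = NULL)
    report$stages[[nm]] <<- list(ok = ok, error = err)

  # -- simulate ------------------------------------------------------------
  dataset <- tryCatch({
    cc <- do.call(cohort_config,
                  c(cfg$cohort[setdiff(names(cfg$cohort), "seed")],
                    list(seed = cfg$seed)))
    ds <- simulate_cohort(cc)
    if (!is.null(out_dir)) write_dataset(ds, out_dir)
    status("simulate", TRUE)
    ds
  }, error = function(e) { status("simulate", FALSE, conditionMessage(e))
                           NULL })
  if (is.null(dataset)) return(structure(report, class = "run_report"))

  # -- endpoints -----------------------------------------------------------
  endpoint_stage <- tryCatch({
    excl <- apply_exclusions(dataset)
    ep <- suppressWarnings(compute_endpoints(excl))
    tests <- list()
    for (sess in c("decision", "movement"))
      for (ms in c("decision_duration", "success_probability",
                   "tap_duration", "movement_accuracy"))
        tests[[paste(sess, ms, sep = ".")]] <-
          paired_by_condition(ep, sess, ms, cfg$stat)
    # coregulation correlations (instructed change vs. induced change)
    cors <- list()
    for (sess in c("decision", "movement")) {
      d <- ep[ep$session == sess, ]
      wide <- merge(d[d$condition == "fast", ],
                    d[d$condition == "slow", ],
                    by = "participant_id", suffixes = c("_fast", "_slow"))
      ddur <- wide$decision_duration_fast - wide$decision_duration_slow
      dtap <- wide$tap_duration_fast - wide$tap_duration_slow
      ok <- !is.na(ddur) & !is.na(dtap)
      cors[[sess]] <- tryCatch({
        r <- spearman_robust(ddur[ok], dtap[ok])
        list(rho_full = r$rho_full, p_full = r$p_full,
             n_outliers = sum(r$outlier), rho_clean = r$rho_clean,
             p_clean = r$p_clean)
      }, error = function(e) list(error = conditionMessage(e)))
    }
    if (!is.null(out_dir))
      utils::write.csv(ep, file.path(out_dir, "endpoints.csv"),
                       row.names = FALSE)
    status("endpoints", TRUE)
    list(exclusions = excl$report, endpoints = ep, tests = tests,
         correlations = cors, filtered = excl)
  }, error = function(e) { status("endpoints", FALSE, conditionMessage(e))
                           NULL })
  report$exclusions <- endpoint_stage$exclusions
  report$endpoint_tests <- endpoint_stage$tests
  report$correlations <- endpoint_stage$correlations

  # -- ddm -----------------------------------------------------------------
  ddm_stage <- tryCatch({
    if (is.null(endpoint_stage)) stop("endpoints stage failed upstream")
    spec <- ddm_candidate_specs()[[cfg$ddm$spec]]
    if (is.null(spec)) stop("unknown ddm spec: ", cfg$ddm$spec)
    res <- list()
    for (sess in c("decision", "movement")) {
      dd <- ddm_data_from_trials(endpoint_stage$filtered$trials, sess)
      if (cfg$ddm$mode == "mle") {
        set.seed(cfg$seed)
        fits <- lapply(split(dd, dd$subject), function(sd)
          tryCatch(fit_subject_mle(sd, spec, min_trials = 20),
                   error = function(e) NULL))
        fits <- fits[!vapply(fits, is.null, TRUE)]
        est <- t(vapply(fits, `[[`, numeric(length(spec_par_names(spec))),
                        "estimates"))
        diffs <- list()
        for (p in spec$flex) {
          dcol <- est[, paste0("d_", p)]
          t <- if (cfg$stat == "sign")
            paired_sign_test(dcol, rep(0, length(dcol)))
          else wilcoxon_signed_rank(dcol, rep(0, length(dcol)))
          diffs[[p]] <- list(mean = mean(dcol), statistic = t$statistic,
                             value = t$value, p = t$p)
        }
        res[[sess]] <- list(mode = "mle", n_subjects = length(fits),
                            group_means = colMeans(est), effects = diffs)
      } else {
        m <- cfg$ddm$mcmc
        if (isTRUE(cfg$ddm$compare)) {
          fits <- lapply(ddm_candidate_specs(), function(sp)
            tryCatch(fit_hierarchical(dd, sp, burn = m$burn,
                                      n_iter = m$n_iter, thin = m$thin,
                                      chains = m$chains, seed = cfg$seed),
                     error = function(e) NULL))
          cmp <- compare_models(fits)
          best <- fits[[cmp$model[1]]]
          res[[sess]] <- list(mode = "hier", comparison = cmp,
                              best = cmp$model[1],
                              effects = as.list(best$effect_probabilities),
                              rhat = best$rhat)
        } else {
          fit <- fit_hierarchical(dd, spec, burn = m$burn,
                                  n_iter = m$n_iter, thin = m$thin,
                                  chains = m$chains, seed = cfg$seed)
          res[[sess]] <- list(mode = "hier", BPIC = fit$BPIC,
                              effects = as.list(fit$effect_probabilities),
                              rhat = fit$rhat)
        }
      }
    }
    status("ddm", TRUE)
    res
  }, error = function(e) { status("ddm", FALSE, conditionMessage(e)); NULL })
  report$ddm <- ddm_stage

  # -- kernels -------------------------------------------------------------
  kernel_stage <- tryCatch({
    if (is.null(endpoint_stage)) stop("endpoints stage failed upstream")
    kt <- kernel_stats_table(endpoint_stage$filtered$trials,
                             cfg$kernels$timespans)
    cmp <- compare_kernel_stats(kt)
    if (!is.null(out_dir))
      utils::write.csv(kt, file.path(out_dir, "kernel_stats.csv"),
                       row.names = FALSE)
    status("kernels", TRUE)
    list(stats = kt, tests = cmp)
  }, error = function(e) { status("kernels", FALSE, conditionMessage(e))
                           NULL })
  report$kernel_tests <- kernel_stage$tests

  # -- planted vs recovered ------------------------------------------------
  report$recovery <- tryCatch(
    recovery_table(dataset, endpoint_stage$endpoints),
    error = function(e) NULL)

  report$ok <- all(vapply(report$stages, `[[`, TRUE, "ok"))
  if (!is.null(out_dir)) {
    slim <- report[setdiff(names(report), "config")]
    slim$ddm <- lapply(slim$ddm, function(s)
      s[setdiff(names(s), c("comparison"))])
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  structure(report, class = "run_report")
}

# planted group differences (from ground-truth agents) vs recovered endpoint
# differences
recovery_table <- function(dataset, endpoints) {
  truth <- dataset$meta$ground_truth
  planted <- function(sess, field) {
    vals <- vapply(truth, function(p)
      p[[sess]][[field]]$fast - p[[sess]][[field]]$slow, 0)
    mean(vals)
  }
  rec <- function(sess, measure) {
    d <- endpoints[endpoints$session == sess, ]
    wide <- merge(d[d$condition == "fast", c("participant_id", measure)],
                  d[d$condition == "slow", c("participant_id", measure)],
                  by = "participant_id", suffixes = c("_f", "_s"))
    mean(wide[[2]] - wide[[3]], na.rm = TRUE)
  }
  data.frame(
    session = c("decision", "decision", "movement"),
    quantity = c("tap_interval", "motor_delay+commit", "tap_interval"),
    planted = c(planted("decision", "tap_interval_mean"),
                NA,  # decision-duration shift mixes bound and motor delay
                planted("movement", "tap_interval_mean")),
    recovered = c(rec("decision", "tap_duration"),
                  rec("decision", "decision_duration"),
                  rec("movement", "tap_duration")))
}

#' @export
print.run_report <- function(x, ...) {
  cat("tokentap pipeline report (config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm,
                if (x$stages[[nm]]$ok) "ok"
                else paste("FAILED:", x$stages[[nm]]$error)))
  if (!is.null(x$endpoint_tests)) {
    cat("endpoint condition effects (fast - slow):\n")
    for (t in x$endpoint_tests)
      cat(sprintf("  %-9s %-19s diff %9.3f  %s = %g, p = %.3g\n",
                  t$session, t$measure, t$mean_diff, t$statistic, t$value,
                  t$p))
  }
  invisible(x)
}
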