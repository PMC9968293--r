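#' Drift-diffusion model parameters
#'
#' Container for the parameters of a two-boundary Wiener diffusion with
#' noise scale 1: boundary separation `a` (decision threshold, the
#' speed-accuracy tradeoff), drift rate `v` (evidence-accumulation
#' efficiency, units per second), non-decision time `t0` (sensory and motor
#' latency outside deliberation, seconds), and relative start point `z`,
#' fixed at 0.5 (no response bias; the task requires equal left/right
#' responses). Five percent of responses are treated as outliers spread
#' uniformly over the observed response-time range.
#'
#' @param a Boundary separation, > 0.
#' @param v Drift rate (positive drifts toward the upper boundary).
#' @param t0 Non-decision time in seconds, >= 0.
#' @param z Relative start point; fixed at 0.5.
#' @param outlier_frac Contaminant mixture weight; fixed default 0.05.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(a, v, t0, z = 0.5, outlier_frac = 0.05) {
  stopifnot(a > 0, t0 >= 0, z > 0, z < 1,
            outlier_frac >= 0, outlier_frac < 1)
  structure(list(a = a, v = v, t0 = t0, z = z, outlier_frac = outlier_frac),
            class = "ddm_params")
}

#' First-passage-time density of the Wiener diffusion
#'
#' Density of responses terminating at the given boundary at time `t`
#' (seconds, measured from stimulus onset; the non-decision time `t0` shifts
#' the density). Zero for `t <= t0`. Computed by the dual small-time /
#' large-time series representation, switching automatically to whichever
#' expansion needs fewer terms for absolute error `err`.
#'
#' @param t Vector of times in seconds.
#' @param params A [ddm_params()].
#' @param boundary `"upper"` or `"lower"`.
#' @param err Absolute truncation error of the series, default `1e-7`.
#' @return Vector of densities (units 1/s). The densities of the two
#'   boundaries jointly integrate to 1 over `(t0, Inf)`.
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         err = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  cpp_wfpt_density(t, params$a, params$v, params$t0, params$z,
                   as.integer(boundary == "upper"), err)
}

#' Simulate the drift-diffusion process
#'
#' Euler-Maruyama simulation with step `dt` (default `1e-4` s). Optionally
#' replaces a fraction of trials with uniform contaminants on
#' `(0, max_rt]`, assigned to either boundary with probability 1/2, matching
#' the likelihood's outlier model.
#'
#' @param params A [ddm_params()].
#' @param n Number of trials.
#' @param include_outliers Add the contaminant mixture component?
#' @param max_rt Upper edge of the contaminant window (s); required when
#'   `include_outliers = TRUE`.
#' @param dt Integration step, s.
#' @param max_t Give-up time (s); unabsorbed walks get `NA` rt.
#' @return data.frame with columns `rt` (s) and `upper` (1 = upper boundary).
#' @export
simulate_ddm <- function(params, n, include_outliers = FALSE, max_rt = NULL,
                         dt = 1e-4, max_t = 10) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  out <- cpp_simulate_ddm(as.integer(n), params$a, params$v, params$t0,
                          params$z, dt, max_t)
  if (include_outliers && params$outlier_frac > 0) {
    if (is.null(max_rt)) stop("max_rt needed for outlier simulation")
    is_out <- stats::runif(n) < params$outlier_frac
    n_out <- sum(is_out)
    if (n_out > 0) {
      out$rt[is_out] <- stats::runif(n_out, 0, max_rt)
      out$upper[is_out] <- stats::rbinom(n_out, 1, 0.5)
    }
  }
  out
}

# ---- model specification -------------------------------------------------

#' Condition-dependence specification for DDM fits
#'
#' Declares which of the three parameters (threshold `a`, non-decision time
#' `t0`, drift `v`) may differ between the slow and fast condition. Flexible
#' parameters are fitted as a slow-condition intercept plus a fast-condition
#' difference, so within-subject effects are read directly off the
#' difference parameters.
#'
#' @param flex Character subset of `c("a", "t0", "v")`.
#' @return Object of class `ddm_model_spec`.
#' @export
ddm_model_spec <- function(flex = character()) {
  stopifnot(all(flex %in% c("a", "t0", "v")))
  flex <- intersect(c("a", "t0", "v"), flex)  # canonical order
  label <- if (length(flex) == 0) "none" else paste(flex, collapse = "+")
  structure(list(flex = flex, label = label), class = "ddm_model_spec")
}

#' The five candidate model specifications compared in the analysis
#'
#' All parameters fixed; threshold only; non-decision time only; threshold
#' and non-decision time; threshold, non-decision time and drift.
#'
#' @return Named list of [ddm_model_spec()] objects.
#' @export
ddm_candidate_specs <- function() {
  list(none       = ddm_model_spec(),
       a          = ddm_model_spec("a"),
       t0         = ddm_model_spec("t0"),
       `a+t0`     = ddm_model_spec(c("a", "t0")),
       `a+t0+v`   = ddm_model_spec(c("a", "t0", "v")))
}

# parameter vector layout for a spec: a, v, t0, then d_<p> for each flexible p
spec_par_names <- function(spec) {
  c("a", "v", "t0",
    if (length(spec$flex)) paste0("d_", spec$flex))
}

# resolve per-trial parameter vectors from a named parameter vector
resolve_params <- function(par, spec, fast) {
  a <- rep(par[["a"]], length(fast))
  v <- rep(par[["v"]], length(fast))
  t0 <- rep(par[["t0"]], length(fast))
  if ("a" %in% spec$flex) a <- a + par[["d_a"]] * fast
  if ("v" %in% spec$flex) v <- v + par[["d_v"]] * fast
  if ("t0" %in% spec$flex) t0 <- t0 + par[["d_t0"]] * fast
  list(a = a, v = v, t0 = t0)
}

# data loglik for one subject's trials under a named parameter vector
ddm_spec_loglik <- function(par, spec, rt, upper, fast, outlier_frac, max_rt) {
  p <- resolve_params(par, spec, fast)
  if (any(p$a <= 0.05) || any(p$t0 < 0)) return(-Inf)
  cpp_ddm_loglik(rt, upper, p$a, p$v, p$t0, outlier_frac, max_rt)
}

check_ddm_data <- function(data) {
  need <- c("rt", "correct", "condition")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(data$condition %in% c("slow", "fast")))
    stop("condition must be 'slow' or 'fast'")
  invisible(data)
}

# EZ-style moment-matching start values (edge-corrected accuracy)
ez_start <- function(rt, correct) {
  n <- length(rt)
  pc <- min(max(mean(correct), 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
  vrt <- max(stats::var(rt), 1e-4)
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^(1 / 4)
  v <- min(max(v, 0.1), 6)
  a <- min(max(L / v, 0.5), 5)
  mdt <- (a / (2 * v)) * tanh(v * a / 2)
  t0 <- min(max(mean(rt) - mdt, 0.05), 1.5)
  c(a = a, v = v, t0 = t0)
}

#' Fit the drift-diffusion model to one subject by maximum likelihood
#'
#' Maximizes the `0.95 * WFPT + 0.05 * uniform` mixture likelihood over the
#' free parameters of a [ddm_model_spec()], with correct responses on the
#' upper and errors on the lower boundary and start point fixed at 0.5.
#' Reaction times below 150 ms are discarded as anticipation errors before
#' fitting. Optimization is bounded (`nlminb`) and multi-start: the first
#' start comes from EZ-style moment matching, the rest are jittered.
#'
#' @param data data.frame with columns `rt` (seconds), `correct` (logical),
#'   `condition` (`"slow"`/`"fast"`).
#' @param spec A [ddm_model_spec()].
#' @param n_starts Number of optimizer starts (>= 5 recommended).
#' @param min_trials Minimum usable trials per condition.
#' @param min_rt Anticipation cutoff, seconds.
#' @return Object of class `ddm_fit_mle` with elements `estimates` (named
#'   vector), `loglik`, `deviance`, `aic`, `bic`, `n`, `spec`,
#'   `by_condition` (resolved a/v/t0 per condition) and `convergence`.
#' @export
fit_subject_mle <- function(data, spec = ddm_model_spec(c("a", "t0")),
                            n_starts = 5, min_trials = 50, min_rt = 0.150) {
  check_ddm_data(data)
  data <- data[!is.na(data$rt) & data$rt >= min_rt, , drop = FALSE]
  cnt <- table(factor(data$condition, c("slow", "fast")))
  if (any(cnt < min_trials))
    stop("need >= ", min_trials, " trials per condition after the ",
         min_rt * 1000, "-ms filter (have ", paste(cnt, collapse = "/"), ")")
  rt <- data$rt
  upper <- as.integer(data$correct)
  fast <- as.numeric(data$condition == "fast")
  max_rt <- max(rt)
  pn <- spec_par_names(spec)

  lower <- c(a = 0.2, v = -10, t0 = 0.02,
             d_a = -6, d_v = -10, d_t0 = -2)[pn]
  upper_b <- c(a = 8, v = 10, t0 = 2.5,
               d_a = 6, d_v = 10, d_t0 = 2)[pn]

  base <- ez_start(rt, upper == 1)
  start0 <- c(base, stats::setNames(rep(0, length(pn) - 3), pn[-(1:3)]))[pn]
  nll <- function(par) {
    names(par) <- pn
    -ddm_spec_loglik(par, spec, rt, upper, fast, 0.05, max_rt)
  }
  best <- NULL
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    st <- start0
    if (s > 1) {
      st <- start0 + stats::rnorm(length(pn), 0, c(0.5, 0.5, 0.1,
                                                   rep(0.2, length(pn) - 3)))
      st <- pmin(pmax(st, lower + 1e-3), upper_b - 1e-3)
    }
    fit <- tryCatch(
      stats::nlminb(st, nll, lower = lower, upper = upper_b,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (!is.null(fit$convergence) && fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best))
    stop("DDM fit failed to converge from any of ", n_starts, " starts")
  est <- stats::setNames(best$par, pn)
  ll <- -best$objective
  k <- length(pn)
  by_cond <- do.call(rbind, lapply(c("slow", "fast"), function(cond) {
    p <- resolve_params(est, spec, as.numeric(cond == "fast"))
    data.frame(condition = cond, a = p$a[1], v = p$v[1], t0 = p$t0[1])
  }))
  structure(list(estimates = est, loglik = ll, deviance = -2 * ll,
                 aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(length(rt)),
                 n = length(rt), spec = spec, by_condition = by_cond,
                 convergence = conv),
            class = "ddm_fit_mle")
}

# ---- hierarchical MCMC ---------------------------------------------------

#' Default weakly-informative priors for the hierarchical DDM
#'
#' Group means: threshold `Normal(2, 2)` truncated above 0.1; drift
#' `Normal(0, 5)`; non-decision time `Normal(0.4, 1)` truncated at 0;
#' condition differences `Normal(0, 2)` (threshold, drift) and
#' `Normal(0, 1)` (non-decision time). All group standard deviations are
#' Half-Normal(1).
#'
#' @return Named list of `c(mean, sd)` prior settings plus `sigma_scale`.
#' @export
ddm_default_priors <- function() {
  list(a = c(2, 2), v = c(0, 5), t0 = c(0.4, 1),
       d_a = c(0, 2), d_v = c(0, 2), d_t0 = c(0, 1),
       sigma_scale = 1)
}

prior_mu_trunc <- function(name) {
  # lower truncation of group-mean priors (intercepts only)
  switch(name, a = 0.1, t0 = 0, -Inf)
}

rtruncnorm1 <- function(mean, sd, lower) {
  if (!is.finite(lower)) return(stats::rnorm(1, mean, sd))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(1, plo, 1)
  u <- min(u, 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

#' Fit the hierarchical drift-diffusion model by MCMC
#'
#' Subject-level parameters are drawn from Normal group distributions
#' (mean + sd per parameter); flexible parameters get a slow-condition
#' intercept and a fast-condition difference, both hierarchical. Sampling is
#' Metropolis-within-Gibbs: joint random-walk updates of each subject's
#' parameter vector (scales adapted during burn-in only), conjugate Gibbs
#' updates of group means (with prior truncation where applicable), and
#' log-scale random-walk updates of group standard deviations under
#' Half-Normal priors. The default schedule discards 5000 burn-in sweeps and
#' keeps every third of 6000 subsequent sweeps in each of 2 chains, giving
#' 4000 retained samples per parameter. Convergence is summarized by the
#' Gelman-Rubin statistic on all group-level parameters (< 1.1 is
#' conventionally satisfactory); the fit is flagged if any exceeds 1.1.
#'
#' @param data data.frame with columns `subject`, `rt` (s), `correct`,
#'   `condition` (`"slow"`/`"fast"`).
#' @param spec A [ddm_model_spec()].
#' @param burn Burn-in sweeps per chain.
#' @param n_iter Post-burn-in sweeps per chain.
#' @param thin Keep every `thin`-th sweep.
#' @param chains Number of chains.
#' @param priors See [ddm_default_priors()].
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param min_rt Anticipation cutoff, seconds.
#' @param progress Print progress lines?
#' @return Object of class `ddm_fit_hier`: `samples` (data.frame of group
#'   parameters with `chain` column), `rhat`, `converged`, `Dbar`, `Dhat`,
#'   `pD`, `BPIC`, `DIC`, `effect_probabilities` (per flexible parameter,
#'   the posterior probability that the fast-minus-slow difference is
#'   negative), `subject_means`, `spec`.
#' @export
fit_hierarchical <- function(data, spec = ddm_model_spec(c("a", "t0")),
                             burn = 5000, n_iter = 6000, thin = 3,
                             chains = 2, priors = ddm_default_priors(),
                             seed = 1, min_rt = 0.150, progress = FALSE) {
  check_ddm_data(data)
  if (!"subject" %in% names(data)) stop("missing columns: subject")
  data <- data[!is.na(data$rt) & data$rt >= min_rt, , drop = FALSE]
  subjects <- sort(unique(data$subject))
  ns <- length(subjects)
  if (ns < 2) stop("hierarchical fit needs >= 2 subjects")
  pn <- spec_par_names(spec)
  np <- length(pn)
  dat <- lapply(subjects, function(s) {
    d <- data[data$subject == s, ]
    list(rt = d$rt, upper = as.integer(d$correct),
         fast = as.numeric(d$condition == "fast"), max_rt = max(d$rt))
  })

  # start from per-subject MLE fits (shared across chains, jittered per chain)
  set.seed(seed)
  mle <- t(vapply(dat, function(d) {
    f <- tryCatch(
      fit_subject_mle(data.frame(rt = d$rt, correct = d$upper == 1,
                                 condition = ifelse(d$fast == 1, "fast",
                                                    "slow")),
                      spec, n_starts = 3, min_trials = 5, min_rt = 0),
      error = function(e) NULL)
    if (is.null(f)) stats::setNames(c(2, 1, 0.3, rep(0, np - 3)), pn)
    else f$estimates
  }, numeric(np)))
  colnames(mle) <- pn

  subj_ll <- function(theta, d)
    ddm_spec_loglik(stats::setNames(theta, pn), spec, d$rt, d$upper, d$fast,
                    0.05, d$max_rt)

  keep_per_chain <- floor(n_iter / thin)
  all_samples <- list()
  all_D <- list()
  theta_sum <- matrix(0, ns, np)
  theta_n <- 0

  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    theta <- mle + matrix(stats::rnorm(ns * np, 0, 0.05), ns, np)
    theta[, "a"] <- pmax(theta[, "a"], 0.3)
    theta[, "t0"] <- pmax(theta[, "t0"], 0.05)
    mu <- colMeans(theta)
    sigma <- pmax(apply(theta, 2, stats::sd), 0.05)
    ll <- vapply(seq_len(ns), function(i) subj_ll(theta[i, ], dat[[i]]),
                 0)
    if (any(!is.finite(ll))) {
      for (i in which(!is.finite(ll))) {
        theta[i, ] <- c(2, 1, 0.3, rep(0, np - 3))
        ll[i] <- subj_ll(theta[i, ], dat[[i]])
      }
    }
    scale_theta <- matrix(0.08, ns, np)
    scale_sigma <- rep(0.3, np)
    acc_theta <- rep(0, ns); acc_sigma <- rep(0, np)
    n_window <- 0

    samp <- matrix(NA_real_, keep_per_chain, 2 * np)
    colnames(samp) <- c(paste0("mu_", pn), paste0("sigma_", pn))
    Dvec <- numeric(keep_per_chain)
    kept <- 0

    total <- burn + n_iter
    for (it in seq_len(total)) {
      # subject-level joint random-walk updates
      for (i in seq_len(ns)) {
        prop <- theta[i, ] + stats::rnorm(np, 0, scale_theta[i, ])
        ll_prop <- subj_ll(prop, dat[[i]])
        if (is.finite(ll_prop)) {
          lr <- ll_prop - ll[i] +
            sum(stats::dnorm(prop, mu, sigma, log = TRUE)) -
            sum(stats::dnorm(theta[i, ], mu, sigma, log = TRUE))
          if (log(stats::runif(1)) < lr) {
            theta[i, ] <- prop; ll[i] <- ll_prop
            acc_theta[i] <- acc_theta[i] + 1
          }
        }
      }
      # group means: conjugate Gibbs with prior truncation
      for (j in seq_len(np)) {
        pr <- priors[[pn[j]]]
        prec <- ns / sigma[j]^2 + 1 / pr[2]^2
        m <- (sum(theta[, j]) / sigma[j]^2 + pr[1] / pr[2]^2) / prec
        mu[j] <- rtruncnorm1(m, 1 / sqrt(prec), prior_mu_trunc(pn[j]))
      }
      # group sds: log-scale random walk, Half-Normal prior
      for (j in seq_len(np)) {
        prop <- sigma[j] * exp(stats::rnorm(1, 0, scale_sigma[j]))
        lr <- sum(stats::dnorm(theta[, j], mu[j], prop, log = TRUE)) -
          sum(stats::dnorm(theta[, j], mu[j], sigma[j], log = TRUE)) +
          stats::dnorm(prop, 0, priors$sigma_scale, log = TRUE) -
          stats::dnorm(sigma[j], 0, priors$sigma_scale, log = TRUE) +
          log(prop) - log(sigma[j])   # Jacobian of the log transform
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          sigma[j] <- prop
          acc_sigma[j] <- acc_sigma[j] + 1
        }
      }
      n_window <- n_window + 1
      # adapt proposal scales during burn-in only
      if (it <= burn && it %% 50 == 0) {
        rate_t <- acc_theta / n_window
        scale_theta <- scale_theta *
          matrix(exp(rate_t - 0.3), ns, np, byrow = FALSE)
        rate_s <- acc_sigma / n_window
        scale_sigma <- pmin(pmax(scale_sigma * exp(rate_s - 0.4), 0.01), 2)
        scale_theta <- pmin(pmax(scale_theta, 0.002), 1)
        acc_theta[] <- 0; acc_sigma[] <- 0; n_window <- 0
      }
      if (it > burn && (it - burn) %% thin == 0 && kept < keep_per_chain) {
        kept <- kept + 1
        samp[kept, ] <- c(mu, sigma)
        Dvec[kept] <- -2 * sum(ll)
        theta_sum <- theta_sum + theta
        theta_n <- theta_n + 1
      }
      if (progress && it %% 500 == 0)
        message(sprintf("[%s] chain %d sweep %d/%d", spec$label, ch, it,
                        total))
    }
    all_samples[[ch]] <- samp[seq_len(kept), , drop = FALSE]
    all_D[[ch]] <- Dvec[seq_len(kept)]
  }

  rhat <- gelman_rubin(all_samples)
  theta_bar <- theta_sum / theta_n
  Dhat <- -2 * sum(vapply(seq_len(ns), function(i)
    subj_ll(theta_bar[i, ], dat[[i]]), 0))
  Dbar <- mean(unlist(all_D))
  pD <- Dbar - Dhat
  samples <- as.data.frame(do.call(rbind, all_samples))
  samples$chain <- rep(seq_len(chains), vapply(all_samples, nrow, 0L))
  eff <- NULL
  if (length(spec$flex)) {
    eff <- vapply(spec$flex, function(p)
      effect_probability(samples[[paste0("mu_d_", p)]]), 0)
  }
  structure(list(samples = samples, rhat = rhat,
                 converged = all(rhat < 1.1, na.rm = TRUE),
                 Dbar = Dbar, Dhat = Dhat, pD = pD,
                 BPIC = Dbar + 2 * pD, DIC = Dbar + pD,
                 effect_probabilities = eff,
                 subject_means = theta_bar, subjects = subjects,
                 spec = spec, n_samples = nrow(samples)),
            class = "ddm_fit_hier")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio, computed per column over a
#' list of equally-sized chain matrices. Values below 1.1 are conventionally
#' taken to indicate convergence.
#'
#' @param chains List of numeric matrices (iterations x parameters), one per
#'   chain, with identical column names.
#' @return Named vector of PSRF values.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(length(chains) >= 2)
  n <- min(vapply(chains, nrow, 0L))
  chains <- lapply(chains, function(m) m[seq_len(n), , drop = FALSE])
  m <- length(chains)
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(chains, function(cm) cm[, j], numeric(n))
    means <- colMeans(x)
    B <- n * stats::var(means)
    W <- mean(apply(x, 2, stats::var))
    if (W < 1e-12) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0, USE.NAMES = FALSE) -> r
  stats::setNames(r, colnames(chains[[1]]))
}

#' Compare fitted models by information criteria
#'
#' Ranks hierarchical fits by the bias-corrected Bayesian Predictive
#' Information Criterion, `BPIC = Dbar + 2 * pD`, where `Dbar` is the
#' posterior mean deviance and `pD = Dbar - D(posterior mean)` the effective
#' number of parameters; `DIC = Dbar + pD` is reported alongside. Lower is
#' better. Missing (failed) fits yield a partial table with a flag.
#'
#' @param fits Named list of `ddm_fit_hier` objects (NULL entries allowed).
#' @return data.frame sorted by BPIC with columns `model`, `BPIC`, `DIC`,
#'   `Dbar`, `pD`, `converged`; attribute `complete` is FALSE if any fit was
#'   missing.
#' @export
compare_models <- function(fits) {
  ok <- !vapply(fits, is.null, TRUE)
  tab <- do.call(rbind, lapply(names(fits)[ok], function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, BPIC = f$BPIC, DIC = f$DIC, Dbar = f$Dbar,
               pD = f$pD, converged = f$converged)
  }))
  tab <- tab[order(tab$BPIC), ]
  rownames(tab) <- NULL
  attr(tab, "complete") <- all(ok)
  tab
}

#' Posterior probability that a within-subject effect is negative
#'
#' Fraction of posterior samples of a fast-minus-slow difference parameter
#' that fall below zero. Probabilities above 0.97 are conventionally taken
#' as evidence that the effect exists. The attribute `label` renders the
#' value with the resolution afforded by the sample count: a fraction of 1
#' with 4000 samples is reported as "> 99.975%" (exceeding 3999 of 4000).
#'
#' @param samples Numeric vector of posterior difference samples (>= 1000
#'   advised).
#' @return Probability in `[0, 1]` with attribute `label`.
#' @export
effect_probability <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  p <- mean(samples < 0)
  label <- if (p == 1) sprintf("> %.3f%%", 100 * (n - 1) / n)
           else if (p == 0) sprintf("< %.3f%%", 100 / n)
           else sprintf("%.2f%%", 100 * p)
  structure(p, label = label)
}

#' Posterior predictive check of a fitted DDM
#'
#' Simulates data from the fitted per-condition parameters and compares
#' observed response-time quantiles (correct and error separately) and
#' accuracy against the simulation distribution. Observed quantiles falling
#' outside the simulated 95% interval are flagged.
#'
#' @param fit A `ddm_fit_mle`, or a data.frame like its `by_condition`
#'   element (columns `condition`, `a`, `v`, `t0`).
#' @param data Observed trials (columns `rt`, `correct`, `condition`).
#' @param n_rep Number of simulated replicate datasets per condition.
#' @param probs Quantile probabilities.
#' @return data.frame with one row per condition x boundary x quantile plus
#'   accuracy rows: observed value, simulated mean and 95% interval, flag.
#' @export
posterior_predictive_check <- function(fit, data, n_rep = 200,
                                       probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  by_cond <- if (inherits(fit, "ddm_fit_mle")) fit$by_condition else fit
  check_ddm_data(data)
  out <- list()
  for (ci in seq_len(nrow(by_cond))) {
    cond <- by_cond$condition[ci]
    obs <- data[data$condition == cond & !is.na(data$rt), ]
    if (nrow(obs) == 0) next
    pars <- ddm_params(by_cond$a[ci], by_cond$v[ci], by_cond$t0[ci])
    n_obs <- nrow(obs)
    sim_q <- array(NA_real_, c(n_rep, 2, length(probs)))
    sim_acc <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      s <- simulate_ddm(pars, n_obs, dt = 5e-4)
      s <- s[!is.na(s$rt), ]
      sim_acc[r] <- mean(s$upper == 1)
      for (b in 1:2) {
        rts <- s$rt[s$upper == (2 - b)]  # b=1 upper/correct, b=2 lower/error
        if (length(rts) >= 5) sim_q[r, b, ] <- stats::quantile(rts, probs)
      }
    }
    for (b in 1:2) {
      rts <- obs$rt[obs$correct == (b == 1)]
      if (length(rts) < 5) next
      oq <- stats::quantile(rts, probs)
      for (k in seq_along(probs)) {
        qs <- sim_q[, b, k]
        qs <- qs[is.finite(qs)]
        if (length(qs) < 10) next
        lo <- stats::quantile(qs, 0.025); hi <- stats::quantile(qs, 0.975)
        out[[length(out) + 1]] <- data.frame(
          condition = cond, measure = ifelse(b == 1, "rt_correct",
                                             "rt_error"),
          quantile = probs[k], observed = unname(oq[k]),
          sim_mean = mean(qs), sim_lo = unname(lo), sim_hi = unname(hi),
          flagged = oq[k] < lo || oq[k] > hi)
      }
    }
    out[[length(out) + 1]] <- data.frame(
      condition = cond, measure = "accuracy", quantile = NA,
      observed = mean(obs$correct),
      sim_mean = mean(sim_acc),
      sim_lo = unname(stats::quantile(sim_acc, 0.025)),
      sim_hi = unname(stats::quantile(sim_acc, 0.975)),
      flagged = mean(obs$correct) < stats::quantile(sim_acc, 0.025) ||
        mean(obs$correct) > stats::quantile(sim_acc, 0.975))
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
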