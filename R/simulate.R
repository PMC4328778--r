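## Piecewise-exponential death-time generation (two-step: multinomial
## interval, then truncated exponential within it), the survey observation
## processes for both record types, and the percent-bias / RMSE evaluation
## harness over replicated simulated datasets.

#' Simulation scenario configuration
#'
#' Encodes one cell of the simulation design: a two-season hazard implied by
#' an annual survival probability (in-season : off-season hazard ratio 2,
#' hunting season days 274--365 of each 365-day year, study day 1 = 1
#' January), weekly surveys, staggered entry uniform on integer days 1--30,
#' and given numbers of known-fate and marked individuals.  Studies with
#' annual survival of 0.85 run 1569 days so that enough deaths occur for
#' estimation; all others run 477 days.
#'
#' @param annual_survival Annual survival probability in (0, 1).
#' @param detection_p Per-survey detection probability of marked animals.
#' @param n_radio,n_marked Numbers of known-fate and marked individuals.
#' @param hazard_ratio In-season : off-season hazard ratio.
#' @param season_start,season_end In-season day-of-year window.
#' @param study_length Study length in days; default 477, or 1569 when
#'   `annual_survival >= 0.85`.
#' @param entry_days Integer days on which entry times are drawn uniformly.
#' @param survey_period Days between surveys (default weekly).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(annual_survival = 0.25, detection_p = 0.2,
                       n_radio = 40, n_marked = 40,
                       hazard_ratio = 2, season_start = 274,
                       season_end = 365, study_length = NULL,
                       entry_days = 1:30, survey_period = 7) {
  if (is.null(study_length))
    study_length <- if (annual_survival >= 0.85) 1569 else 477
  if (study_length < max(entry_days))
    stop("'study_length' must cover the entry window")
  rates <- annual_survival_to_rates(annual_survival, hazard_ratio,
                                    hunting_days = season_end - season_start + 1)
  structure(list(annual_survival = annual_survival,
                 detection_p = detection_p,
                 n_radio = n_radio, n_marked = n_marked,
                 hazard_ratio = hazard_ratio,
                 season_start = season_start, season_end = season_end,
                 study_length = study_length, entry_days = entry_days,
                 survey_period = survey_period,
                 rates = rates,
                 spec = hazard_seasonal(rates, season_start, season_end)),
            class = "sim_config")
}

#' Interval death probabilities of a piecewise-constant hazard
#'
#' For an individual entering at `entry`, partitions `[entry, study_end]`
#' into the hazard's constant-rate segments and returns the probability of
#' dying in each segment together with the probability of surviving past
#' `study_end`:
#' `q_k = prod_{l<k} exp(-lambda_l t_l) * (1 - exp(-lambda_k t_k))`, with
#' individual-specific segment lengths `t_l` (staggered entry makes the
#' partition individual-specific).  The probabilities sum to one exactly.
#'
#' @param spec A [hazard_spec()].
#' @param entry Entry time, `entry < study_end`.
#' @param study_end End of the study.
#' @return List with `prob` (death-in-segment probabilities), `survive`,
#'   and the segment `start`, `end`, `rate`.
#' @export
interval_death_probs <- function(spec, entry, study_end) {
  if (entry >= study_end) stop("'entry' must be before 'study_end'")
  seg <- hazard_segments(spec, entry, study_end)
  rate <- exp(seg$log_rate)
  len <- seg$end - seg$start
  H <- rate * len
  surv_before <- exp(-cumsum(c(0, H[-length(H)])))
  q <- surv_before * -expm1(-H)
  list(prob = q, survive = exp(-sum(H)),
       start = seg$start, end = seg$end, rate = rate)
}

#' Draw a death time from a piecewise-constant hazard
#'
#' Two-step draw: first the death segment from the multinomial of
#' [interval_death_probs()] (the survive outcome returns `Inf`, treated as
#' right-censored downstream), then the time within the segment from the
#' truncated exponential with that segment's rate by inverse CDF.  The
#' resulting distribution is exactly piecewise-exponential on
#' `[entry, study_end]`.
#'
#' @inheritParams interval_death_probs
#' @return A death time in `(entry, study_end]`, or `Inf` if the individual
#'   outlives the study.
#' @export
draw_death_time <- function(spec, entry, study_end) {
  dp <- interval_death_probs(spec, entry, study_end)
  m <- length(dp$prob)
  k <- sample.int(m + 1L, 1L, prob = c(dp$prob, dp$survive))
  if (k > m) return(Inf)
  lam <- dp$rate[k]
  len <- dp$end[k] - dp$start[k]
  u <- stats::runif(1)
  x <- if (lam * len < 1e-12) u * len
       else -log1p(u * expm1(-lam * len)) / lam
  dp$start[k] + x
}

#' Observe a death time through the known-fate process
#'
#' The death is recorded to the survey interval containing it: `last_alive`
#' is the interval's lower bound (never before entry), `first_dead` its
#' upper bound.  Death at exactly a survey time counts as death before that
#' survey.  An individual outliving the study is right-censored at the last
#' survey time.
#'
#' @param death Death time (may be `Inf`).
#' @param entry Entry time.
#' @param schedule A [survey_schedule()].
#' @param covariates,id Passed through to the record.
#' @return A [radio_record()].
#' @export
observe_radio <- function(death, entry, schedule, covariates = NULL,
                          id = NULL) {
  if (death <= entry) stop("death time must be after entry")
  st <- schedule$stimes
  if (death > schedule$study_end) {
    return(radio_record(entry, max(entry, st[length(st)]),
                        covariates = covariates, id = id))
  }
  idx <- sum(st < death)  # death at a survey time belongs to the interval below
  lower <- if (idx == 0L) entry else max(entry, st[idx])
  upper <- if (idx < length(st)) st[idx + 1L] else schedule$study_end
  radio_record(entry, lower, upper, covariates = covariates, id = id)
}

#' Observe a death time through the marked-animal process
#'
#' Bernoulli(`p`) detection draws at every survey at which the animal is
#' alive (strictly before its death time and after entry); the record keeps
#' the full 0/1 history, the last sighting and the sighting count, and is
#' right-censored (marked deaths are never recovered).
#'
#' @inheritParams observe_radio
#' @param p Per-survey detection probability.
#' @return A [mark_record()].
#' @export
observe_marked <- function(death, entry, p, schedule, covariates = NULL,
                           id = NULL) {
  st <- schedule$stimes
  after <- st > entry
  alive <- after & st < death
  det <- integer(sum(after))
  det[st[after] < death] <- as.integer(stats::runif(sum(alive)) < p)
  nn <- sum(det)
  last_seen <- if (nn > 0L) st[after][max(which(det == 1L))] else NA
  mark_record(entry, last_seen = last_seen, nn = nn, history = det,
              covariates = covariates, id = id)
}

#' Simulate one integrated dataset
#'
#' Entry times uniform on the configured integer days, death times from the
#' seasonal piecewise-exponential hazard, and observation through the
#' known-fate and marked processes on the weekly schedule.  Uses the current
#' RNG state; `set.seed()` beforehand for reproducibility.
#'
#' @param config A [sim_config()].
#' @return List with `data` (an [event_data()]), `schedule`, and `truth`
#'   (a data frame of true entry/death/censoring per individual).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- weekly_schedule(config$study_length, config$survey_period)
  n <- config$n_radio + config$n_marked
  type <- rep(c("radio", "marked"), c(config$n_radio, config$n_marked))
  entry <- sample(config$entry_days, n, replace = TRUE)
  death <- vapply(entry, function(e)
    draw_death_time(config$spec, e, config$study_length), numeric(1))
  radio <- marked <- list()
  for (i in seq_len(n)) {
    if (type[i] == "radio")
      radio[[length(radio) + 1L]] <-
        observe_radio(death[i], entry[i], schedule, id = i)
    else
      marked[[length(marked) + 1L]] <-
        observe_marked(death[i], entry[i], config$detection_p, schedule,
                       id = i)
  }
  list(data = event_data(radio, marked), schedule = schedule,
       truth = data.frame(id = seq_len(n), type = type, entry = entry,
                          death = death,
                          censored = death > config$study_length))
}

#' Percent bias and RMSE of a simulation scenario
#'
#' Replicates the scenario end to end: simulate a dataset, fit the
#' integrated two-season model, record the posterior means of `lambda1`,
#' `lambda2` and `p`, and summarize percent bias
#' `PBS = 100 (mean estimate - truth) / truth` and
#' `RMSE = sqrt(mean (estimate - truth)^2)` against the generating values.
#' Each replicate gets its own dataset and chain with a seed derived from
#' `seed`; replicates whose chain fails the Geweke screen (|z| > 3 on any
#' parameter) are flagged in the output but not dropped.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of simulate-fit replicates.
#' @param control An [mcmc_control()] for the per-replicate fits (one chain
#'   per replicate by default; its `seed` is overridden per replicate).
#' @param seed Master seed from which per-replicate seeds are derived.
#' @param rep_seeds Optional explicit per-replicate seeds (overrides
#'   `seed`); used to share simulated randomness across scenario arms.
#' @return List with `summary` (one row per parameter: truth, mean
#'   estimate, `pbs`, `rmse`, and `coverage95`, the fraction of replicates
#'   whose central 95% credible interval contains the truth), `estimates`
#'   (per-replicate posterior means and Geweke flag), and `config`.
#' @export
evaluate_scenario <- function(config, n_replicates = 100,
                              control = mcmc_control(n_iter = 10000),
                              seed = 1, rep_seeds = NULL) {
  if (n_replicates < 2) stop("'n_replicates' must be at least 2")
  if (is.null(rep_seeds)) {
    set.seed(seed)
    rep_seeds <- sample.int(2147480000L, n_replicates)
  }
  est <- matrix(NA_real_, n_replicates, 3,
                dimnames = list(NULL, c("lambda1", "lambda2", "p")))
  covered <- matrix(NA, n_replicates, 3)
  gew_ok <- logical(n_replicates)
  truth <- c(config$rates, config$detection_p)
  names(truth) <- c("lambda1", "lambda2", "p")
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    sim <- simulate_dataset(config)
    ctl <- control
    ctl$seed <- rep_seeds[r]
    fit <- fit_seasonal(sim$data, sim$schedule, control = ctl)
    m <- as.matrix(fit)
    est[r, ] <- colMeans(m)
    ci <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
    covered[r, ] <- truth >= ci[1, ] & truth <= ci[2, ]
    z <- tryCatch(geweke_z(fit), error = function(e) NA_real_)
    gew_ok[r] <- all(is.finite(z)) && all(abs(z) <= 3)
  }
  mean_est <- colMeans(est)
  summary <- data.frame(
    parameter = names(truth), truth = unname(truth),
    mean = unname(mean_est),
    pbs = unname(100 * (mean_est - truth) / truth),
    rmse = unname(sqrt(colMeans((est - rep(truth, each = n_replicates))^2))),
    coverage95 = unname(colMeans(covered)))
  if (any(!gew_ok))
    message(sum(!gew_ok), " of ", n_replicates,
            " replicate chains flagged by the Geweke screen (|z| > 3)")
  list(summary = summary,
       estimates = data.frame(replicate = seq_len(n_replicates), est,
                              geweke_ok = gew_ok),
       config = config)
}

#' Sample-composition experiment
#'
#' Varies how a fixed total sample is split between known-fate and marked
#' individuals and evaluates each composition with [evaluate_scenario()].
#' The same per-replicate seeds are reused at every grid point (common
#' random numbers), which sharpens comparisons of RMSE across compositions.
#'
#' @param radio_counts Grid of known-fate counts, each in `[0, total_n]`.
#' @param total_n Total number of individuals (default 80).
#' @param annual_survival,detection_p Scenario parameters (defaults 0.55 and
#'   0.20).
#' @inheritParams evaluate_scenario
#' @param ... Further arguments to [sim_config()].
#' @return List with `curves` (a data frame of pbs/rmse per parameter and
#'   composition) and the per-composition `results`.
#' @export
composition_experiment <- function(radio_counts = c(0, 40, 80), total_n = 80,
                                   annual_survival = 0.55, detection_p = 0.2,
                                   n_replicates = 100,
                                   control = mcmc_control(n_iter = 10000),
                                   seed = 1, ...) {
  if (any(radio_counts < 0 | radio_counts > total_n))
    stop("'radio_counts' must lie in [0, total_n]")
  set.seed(seed)
  rep_seeds <- sample.int(2147480000L, n_replicates)
  results <- lapply(radio_counts, function(nr) {
    cfg <- sim_config(annual_survival = annual_survival,
                      detection_p = detection_p,
                      n_radio = nr, n_marked = total_n - nr, ...)
    evaluate_scenario(cfg, n_replicates = n_replicates, control = control,
                      rep_seeds = rep_seeds)
  })
  curves <- do.call(rbind, lapply(seq_along(radio_counts), function(i) {
    s <- results[[i]]$summary
    s$n_radio <- radio_counts[i]
    s
  }))
  list(curves = curves, results = results, radio_counts = radio_counts)
}
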