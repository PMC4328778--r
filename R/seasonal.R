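## Sufficient-statistic design and fitting for the two-season hazard model
## (off-season rate lambda1, in-season rate lambda2, detection p) used by
## the simulation studies.  The likelihood depends on the data only through
## summed season-specific exposures, death-interval exposure pairs, the
## collapsed binomial detection counts, and per-record never-seen-again tail
## increments; those are precomputed here and evaluated in compiled code.

## cumulative in-season time on [0, t) for a periodic window
## [start-1, end) + 365 y
season_time_before <- function(t, season_start = 274, season_end = 365) {
  s0 <- season_start - 1
  len <- season_end - s0
  y <- floor(t / 365)
  rem <- t - 365 * y
  y * len + pmin(pmax(rem - s0, 0), len)
}

## (off-season, in-season) exposure of the interval [t0, t1]
season_exposure <- function(t0, t1, season_start = 274, season_end = 365) {
  hunt <- season_time_before(t1, season_start, season_end) -
    season_time_before(t0, season_start, season_end)
  c(t1 - t0 - hunt, hunt)
}

#' Precompute the sufficient statistics of the seasonal model
#'
#' Collapses an integrated dataset into the quantities the two-season
#' likelihood actually depends on: total off-/in-season exposure while known
#' alive, per-death interval exposure pairs, pooled sighting counts, and the
#' per-record inter-survey exposure increments that drive the
#' never-seen-again tails.
#'
#' @param data An [event_data()].
#' @param schedule A [survey_schedule()].
#' @param season_start,season_end Day-of-year window of the in-season
#'   period (defaults 274..365).
#' @return A list consumed by [fit_seasonal()] and the compiled likelihood.
#' @keywords internal
build_seasonal_design <- function(data, schedule,
                                  season_start = 274, season_end = 365) {
  SE <- c(0, 0)
  dD1 <- dD2 <- numeric(0)
  nn <- navail <- 0
  tail_ptr <- 0L
  tail_d1 <- tail_d2 <- numeric(0)
  for (rec in data$radio) {
    SE <- SE + season_exposure(rec$entry, rec$last_alive,
                               season_start, season_end)
    if (is.finite(rec$first_dead)) {
      e <- season_exposure(rec$last_alive, rec$first_dead,
                           season_start, season_end)
      dD1 <- c(dD1, e[1]); dD2 <- c(dD2, e[2])
    }
  }
  for (rec in data$marked) {
    tstar <- tstar_of(rec)
    SE <- SE + season_exposure(rec$entry, tstar, season_start, season_end)
    nn <- nn + rec$nn
    navail <- navail + n_avail_of(rec, schedule)
    if (is.finite(rec$first_dead)) {
      e <- season_exposure(tstar, rec$first_dead, season_start, season_end)
      dD1 <- c(dD1, e[1]); dD2 <- c(dD2, e[2])
      next
    }
    rem <- schedule$stimes[schedule$stimes > tstar]
    bounds <- c(tstar, rem)
    for (k in seq_along(rem)) {
      e <- season_exposure(bounds[k], bounds[k + 1], season_start, season_end)
      tail_d1 <- c(tail_d1, e[1]); tail_d2 <- c(tail_d2, e[2])
    }
    tail_ptr <- c(tail_ptr, length(tail_d1))
  }
  list(SE1 = SE[1], SE2 = SE[2], dD1 = dD1, dD2 = dD2,
       nn = nn, navail = navail,
       tail_ptr = as.integer(tail_ptr), tail_d1 = tail_d1, tail_d2 = tail_d2,
       season_start = season_start, season_end = season_end)
}

#' Joint log-likelihood of the seasonal model (compiled path)
#'
#' Evaluates the same joint likelihood as [joint_loglik()] with a
#' [hazard_seasonal()] spec, but from the precomputed sufficient statistics.
#'
#' @param lambda1,lambda2 Off- and in-season daily hazard rates.
#' @param p Detection probability.
#' @param design From [build_seasonal_design()].
#' @return Scalar log-likelihood.
#' @keywords internal
loglik_seasonal <- function(lambda1, lambda2, p, design) {
  .loglik_seasonal_cpp(lambda1, lambda2, p, design)
}

#' Fit the two-season integrated model
#'
#' Adaptive componentwise random-walk Metropolis on `(log lambda1,
#' log lambda2, p)` with uniform priors on the log rates and the
#' Bayes-Laplace uniform(0, 1) prior on `p`.  Starting values are drawn from
#' dispersed uniform distributions.  This is the compiled fast path used by
#' the simulation harness; [eventfuse()] dispatches to it for seasonal
#' models without covariates.
#'
#' @param data An [event_data()].
#' @param schedule A [survey_schedule()].
#' @param control An [mcmc_control()].
#' @param log_rate_bounds Support of the uniform prior on each log rate.
#' @param season_start,season_end In-season day-of-year window.
#' @param design Optionally a prebuilt [build_seasonal_design()] result.
#' @return An `ef_samples` object with parameters `lambda1`, `lambda2`, `p`
#'   (rates on the natural scale).
#' @export
fit_seasonal <- function(data, schedule, control = mcmc_control(),
                         log_rate_bounds = c(-12, 0),
                         season_start = 274, season_end = 365,
                         design = NULL) {
  if (is.null(design))
    design <- build_seasonal_design(data, schedule, season_start, season_end)
  n_keep <- control$n_iter - control$burn_in
  nm <- c("lambda1", "lambda2", "p")
  draws <- array(NA_real_, c(n_keep, 3, control$n_chains),
                 dimnames = list(NULL, nm, NULL))
  accept <- matrix(NA_real_, control$n_chains, 3)
  for (chain in seq_len(control$n_chains)) {
    set.seed(control$seed + chain - 1L)
    init <- c(stats::runif(2, -9, -3), stats::runif(1, 0.05, 0.95))
    res <- .sample_seasonal_cpp(design, control$n_iter, control$burn_in,
                                init, log_rate_bounds[1], log_rate_bounds[2],
                                control$target_accept, control$step0)
    draws[, , chain] <- res$draws
    accept[chain, ] <- res$accept
  }
  structure(list(draws = draws, lp = NULL, accept = accept,
                 control = control, param_names = nm, design = design),
            class = "ef_samples")
}
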