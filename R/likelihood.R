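## Joint likelihood for integrated event-time data: interval-censored
## known-fate records and imperfectly detected unknown-fate records share
## one hazard function, and the marked records additionally inform (and
## depend on) a per-survey detection probability.

## stable log(1 - exp(-H)) for H > 0
log1mexp <- function(H) {
  out <- numeric(length(H))
  small <- H <= log(2)
  out[small] <- log(-expm1(-H[small]))
  out[!small] <- log1p(-exp(-H[!small]))
  out[H <= 0] <- -Inf
  out
}

#' Log-likelihood of a known-fate (radio-collared) record
#'
#' Conditional on being alive at entry (left truncation), the record
#' contributes survival from entry to the last-known-alive time and, when the
#' death interval is observed, the probability of dying within
#' `[last_alive, first_dead]`:
#' `log S(e -> r) + log(1 - S(r -> s))`, or just `log S(e -> r)` for a
#' right-censored record.  An optional Bernoulli detection term over the
#' surveys between entry and the last detection can be included when the
#' known-fate animals were searched for like marked ones; by default it is
#' omitted, since a functioning transmitter usually makes detection easier
#' than for marked animals.
#'
#' @param rec A [radio_record()].
#' @param spec A [hazard_spec()].
#' @param effect Optional [covariate_effect()]; covariate values are taken
#'   from `rec$covariates`.
#' @param p Detection probability (used only with `include_detection`).
#' @param schedule A [survey_schedule()] (used only with
#'   `include_detection`).
#' @param include_detection Include the per-survey Bernoulli detection term?
#' @return Log-likelihood contribution (scalar).
#' @export
loglik_radio <- function(rec, spec, effect = NULL, p = NULL, schedule = NULL,
                         include_detection = FALSE) {
  stopifnot(inherits(rec, "radio_record"))
  covs <- rec$covariates
  ll <- -cumulative_hazard(spec, rec$entry, rec$last_alive, effect, covs)
  if (is.finite(rec$first_dead)) {
    H <- cumulative_hazard(spec, rec$last_alive, rec$first_dead, effect, covs)
    ll <- ll + log1mexp(H)
  }
  if (include_detection) {
    if (is.null(rec$detections) || is.null(schedule) || is.null(p))
      stop("detection term needs 'detections', 'schedule' and 'p'")
    d <- rec$detections
    last1 <- if (any(d == 1L)) max(which(d == 1L)) else 0L
    if (last1 > 0L) {
      d <- d[seq_len(last1)]
      ll <- ll + detection_loglik_binomial(sum(d), length(d), p)
    }
  }
  if (!is.finite(ll) && !identical(ll, -Inf)) stop("nonfinite hazard term")
  ll
}

#' Collapsed (binomial) detection log-likelihood
#'
#' With a detection probability constant across surveys, the product of
#' per-survey Bernoulli terms between the first survey after entry and the
#' last survey at which the animal was seen collapses to a binomial kernel:
#' `nn * log(p) + (n_avail - nn) * log(1 - p)`, with the convention
#' `0 * log(0) = 0`.
#'
#' @param nn Number of sightings.
#' @param n_avail Number of detection opportunities (surveys from the first
#'   survey after entry through the last survey at which the animal was
#'   seen).
#' @param p Detection probability in `[0, 1]`.
#' @return Log-probability (scalar), `-Inf` when the data are impossible
#'   under `p`.
#' @export
detection_loglik_binomial <- function(nn, n_avail, p) {
  if (nn < 0 || nn > n_avail) stop("'nn' must lie in [0, n_avail]")
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  ll <- 0
  if (nn > 0) ll <- ll + nn * log(p)
  if (n_avail - nn > 0) ll <- ll + (n_avail - nn) * log1p(-p)
  ll
}

#' Never-seen-again tail probability of a marked record
#'
#' The probability of everything observed after the last sighting of a
#' right-censored marked animal: nothing.  Given alive at the last sighting
#' time `t*` (entry, if never seen), the animal either died in one of the
#' inter-survey intervals after `t*` -- missing each survey it was alive for
#' with probability `1 - p` -- or survived to the last survey and was missed
#' every time.  Death censors later detection opportunities, so the
#' post-death latent histories sum to one and drop out.  With remaining
#' survey times `u_1 < ... < u_m`:
#' \deqn{\sum_{k=1}^{m} [S(t^* \to u_{k-1}) - S(t^* \to u_k)] (1-p)^{k-1}
#'       + S(t^* \to u_m) (1-p)^m}
#' (with `u_0 = t*`).  Time after the last survey carries no observation and
#' is treated as uninformative.
#'
#' @inheritParams loglik_radio
#' @param rec A right-censored [mark_record()].
#' @param p Per-survey detection probability.
#' @param schedule A [survey_schedule()].
#' @return A probability in `[0, 1]`; equals 1 exactly when `p = 0`.
#' @export
tail_probability <- function(rec, spec, p, schedule, effect = NULL) {
  stopifnot(inherits(rec, "mark_record"), inherits(schedule, "survey_schedule"))
  if (is.finite(rec$first_dead))
    stop("tail probability applies to right-censored records only")
  tstar <- tstar_of(rec)
  rem <- schedule$stimes[schedule$stimes > tstar]
  if (length(rem) == 0L) return(1)
  covs <- rec$covariates
  H <- cumhaz_at_points(spec, tstar, rem, effect, covs)
  surv <- exp(-H)
  q <- 1 - p
  m <- length(rem)
  death_terms <- (c(1, surv[-m]) - surv) * q^(seq_len(m) - 1L)
  sum(death_terms) + surv[m] * q^m
}

#' Log-likelihood of an unknown-fate (marked) record
#'
#' Three multiplicative elements: survival while known alive (entry to last
#' sighting), the collapsed Bernoulli detection process over the surveys up
#' to the last sighting, and the never-seen-again tail accounting for the
#' unknown fate afterwards.  If the animal was recovered dead
#' (`first_dead` finite), the tail is replaced by an interval-death term as
#' for a known-fate record.
#'
#' @inheritParams tail_probability
#' @return Log-likelihood contribution (scalar).
#' @export
loglik_marked <- function(rec, spec, p, schedule, effect = NULL) {
  stopifnot(inherits(rec, "mark_record"))
  covs <- rec$covariates
  tstar <- tstar_of(rec)
  ll <- -cumulative_hazard(spec, rec$entry, tstar, effect, covs)
  ll <- ll + detection_loglik_binomial(rec$nn, n_avail_of(rec, schedule), p)
  if (is.finite(rec$first_dead)) {
    H <- cumulative_hazard(spec, tstar, rec$first_dead, effect, covs)
    ll <- ll + log1mexp(H)
  } else {
    tail <- tail_probability(rec, spec, p, schedule, effect)
    ll <- ll + log(max(tail, 1e-300))
  }
  ll
}

#' Joint log-likelihood of an integrated dataset
#'
#' Sums the per-record contributions of known-fate and marked records under
#' independent death times.  Both components share the hazard parameters --
#' this sharing is what lets the imperfectly detected marked animals inform
#' (and be informed by) the hazard estimated from the known fates.
#'
#' @param data An [event_data()] (or a list with elements `radio`,
#'   `marked`).
#' @inheritParams loglik_marked
#' @param include_detection Include the optional detection term for the
#'   known-fate records (default off)?
#' @return Scalar joint log-likelihood.
#' @export
joint_loglik <- function(data, spec, p, schedule, effect = NULL,
                         include_detection = FALSE) {
  if (length(data$radio) == 0L && length(data$marked) == 0L)
    stop("empty dataset: no radio or marked records")
  ll <- 0
  for (rec in data$radio)
    ll <- ll + loglik_radio(rec, spec, effect = effect, p = p,
                            schedule = schedule,
                            include_detection = include_detection)
  for (rec in data$marked)
    ll <- ll + loglik_marked(rec, spec, p, schedule, effect)
  ll
}
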