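## Piecewise-constant hazard functions on a continuous time axis (days).
## Intervals are half-open [a, b); calendar-periodic ("seasonal") lookups
## repeat with period 365 days and daily age offsets may be layered on top.

#' Specify a piecewise-constant hazard function
#'
#' A `hazard_spec` describes the baseline mortality hazard as a function of
#' continuous time (in days).  Three layouts are supported: a constant rate,
#' a piecewise-constant rate with fixed change points, and a calendar-periodic
#' ("seasonal") rate that alternates between an off-season and an in-season
#' value every 365-day year.  Optional additive log-hazard offsets on a daily
#' grid (`age_effects`) allow a smoothed age profile on top of the baseline.
#'
#' @param kind `"constant"` or `"piecewise"`.
#' @param log_rates Per-interval log baseline hazard (per day).  Length 1 for
#'   `"constant"`; `length(change_points) + 1` for `"piecewise"` with change
#'   points; length 2 (off-season, in-season) for a seasonal spec.
#' @param change_points Strictly increasing interior breakpoints (days).
#'   Interval `j` is `[cp[j-1], cp[j])`.
#' @param season_start,season_end Day-of-year bounds (inclusive) of the
#'   in-season window for a calendar-periodic hazard, e.g. 274 and 365 for a
#'   hunting season running 1 October through 31 December with the study
#'   starting 1 January.  Periodic with period 365; no leap years.
#' @param age_effects Optional numeric vector of additive log-hazard offsets
#'   for successive one-day age intervals `[origin + k - 1, origin + k)`.
#' @param origin Time at which the hazard (and the age grid) starts; times
#'   before `origin` are outside the support.
#' @return An object of class `"hazard_spec"`.
#' @seealso [hazard_at()], [cumulative_hazard()], [annual_survival_to_rates()]
#' @examples
#' # constant 0.01 / day
#' hazard_spec("constant", log_rates = log(0.01))
#' # seasonal: hunting season doubles the hazard
#' hazard_spec("piecewise", log_rates = log(c(0.003, 0.006)),
#'             season_start = 274, season_end = 365)
#' @export
hazard_spec <- function(kind = c("constant", "piecewise"),
                        log_rates,
                        change_points = NULL,
                        season_start = NULL, season_end = NULL,
                        age_effects = NULL,
                        origin = 0) {
  kind <- match.arg(kind)
  log_rates <- as.numeric(log_rates)
  if (any(!is.finite(log_rates)))
    stop("'log_rates' must be finite (rates strictly positive)")
  seasonal <- !is.null(season_start)
  if (seasonal) {
    if (is.null(season_end)) stop("'season_end' required with 'season_start'")
    if (kind != "piecewise") stop("a seasonal hazard must have kind 'piecewise'")
    if (!is.null(change_points))
      stop("supply either 'change_points' or a season window, not both")
    if (season_start < 1 || season_end > 365 || season_start > season_end)
      stop("season window must satisfy 1 <= start <= end <= 365")
    if (length(log_rates) != 2L)
      stop("a seasonal spec needs exactly 2 log rates (off-season, in-season)")
  } else if (kind == "piecewise") {
    change_points <- as.numeric(change_points)
    if (length(change_points) < 1L)
      stop("piecewise spec needs change points (or a season window)")
    if (is.unsorted(change_points, strictly = TRUE))
      stop("'change_points' must be strictly increasing")
    if (length(log_rates) != length(change_points) + 1L)
      stop("need one log rate per interval: length(change_points) + 1")
    if (any(change_points <= origin))
      stop("'change_points' must lie after 'origin'")
  } else {
    if (length(log_rates) != 1L) stop("constant spec takes a single log rate")
  }
  if (!is.null(age_effects)) {
    age_effects <- as.numeric(age_effects)
    if (any(!is.finite(age_effects))) stop("'age_effects' must be finite")
  }
  structure(list(kind = kind, log_rates = log_rates,
                 change_points = change_points,
                 season_start = if (seasonal) as.numeric(season_start),
                 season_end = if (seasonal) as.numeric(season_end),
                 age_effects = age_effects, origin = as.numeric(origin)),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("Piecewise-constant hazard spec\n")
  if (!is.null(x$season_start)) {
    cat(sprintf("  seasonal (period 365 d): in-season days %d-%d of year\n",
                x$season_start, x$season_end))
    cat(sprintf("  rates/day: off-season %.6g, in-season %.6g\n",
                exp(x$log_rates[1]), exp(x$log_rates[2])))
  } else if (x$kind == "piecewise") {
    cat(sprintf("  change points: %s\n",
                paste(format(x$change_points), collapse = ", ")))
    cat(sprintf("  rates/day: %s\n",
                paste(format(exp(x$log_rates), digits = 4), collapse = ", ")))
  } else {
    cat(sprintf("  constant rate %.6g / day\n", exp(x$log_rates)))
  }
  if (!is.null(x$age_effects))
    cat(sprintf("  + %d daily age-interval log-hazard offsets\n",
                length(x$age_effects)))
  invisible(x)
}

#' Proportional-hazards covariate effects
#'
#' Bundles named log hazard-ratio coefficients with the standardization
#' (mean, sd) applied to each continuous covariate, so that effects can be
#' mapped back to the original covariate scale.
#'
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param center,scale Optional named numeric vectors recording the mean and
#'   standard deviation by which each covariate was standardized (missing
#'   entries mean "not standardized", i.e. center 0, scale 1).
#' @return An object of class `"covariate_effect"`.
#' @export
covariate_effect <- function(coefficients, center = NULL, scale = NULL) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("'coefficients' must be named")
  structure(list(coefficients = coefficients,
                 center = center, scale = scale),
            class = "covariate_effect")
}

#' Linear predictor of a covariate effect
#'
#' @param effect A [covariate_effect()] (or `NULL` for no covariates).
#' @param covariates Named vector (or single-row list/data.frame) of covariate
#'   values on the scale the coefficients were estimated on.
#' @return The scalar log hazard-ratio contribution `sum(beta * x)`.
#' @export
linear_predictor <- function(effect, covariates = NULL) {
  if (is.null(effect) || length(effect$coefficients) == 0L) return(0)
  nm <- names(effect$coefficients)
  if (is.null(covariates))
    stop("covariates required for effect on: ", paste(nm, collapse = ", "))
  covariates <- unlist(covariates)
  missing_nm <- setdiff(nm, names(covariates))
  if (length(missing_nm))
    stop("unknown covariate name(s): ", paste(missing_nm, collapse = ", "))
  x <- covariates[nm]
  if (anyNA(x))
    stop("covariates must be complete when evaluating the hazard ",
         "(impute upstream)")
  sum(effect$coefficients * x)
}

## baseline log rate at time t (vectorized); no age offset, no covariates
base_log_rate_at <- function(spec, t) {
  if (!is.null(spec$season_start)) {
    tm <- t %% 365
    in_season <- tm >= (spec$season_start - 1) & tm < spec$season_end
    spec$log_rates[1L + in_season]
  } else if (spec$kind == "piecewise") {
    spec$log_rates[findInterval(t, spec$change_points) + 1L]
  } else {
    rep(spec$log_rates, length(t))
  }
}

age_offset_at <- function(spec, t) {
  if (is.null(spec$age_effects)) return(rep(0, length(t)))
  k <- floor(t - spec$origin) + 1L
  k <- pmin(pmax(k, 1L), length(spec$age_effects))
  spec$age_effects[k]
}

#' Evaluate the hazard rate
#'
#' Returns the instantaneous event rate (per day) at time `t`:
#' `exp(log baseline(t) + age offset(t) + x'beta)`.
#'
#' @inheritParams linear_predictor
#' @param spec A [hazard_spec()].
#' @param t Time in days (vectorized); must be at or after `spec$origin`.
#' @return Strictly positive hazard rate(s), per day.
#' @examples
#' sp <- hazard_spec("constant", log(0.01))
#' hazard_at(sp, 5)  # 0.01
#' @export
hazard_at <- function(spec, t, effect = NULL, covariates = NULL) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(t < spec$origin))
    stop("time before the hazard origin (", spec$origin, ")")
  lp <- linear_predictor(effect, covariates)
  exp(base_log_rate_at(spec, t) + age_offset_at(spec, t) + lp)
}

## Exact segment decomposition of [t0, t1]: returns boundaries and the
## per-segment log rate (baseline + age offset, no covariates).
hazard_segments <- function(spec, t0, t1) {
  breaks <- numeric(0)
  if (!is.null(spec$season_start)) {
    s0 <- spec$season_start - 1
    s1 <- spec$season_end
    years <- seq.int(floor(t0 / 365), floor(t1 / 365))
    breaks <- c(outer(c(s0, s1), years * 365, `+`))
  } else if (spec$kind == "piecewise") {
    breaks <- spec$change_points
  }
  if (!is.null(spec$age_effects)) {
    k <- length(spec$age_effects)
    breaks <- c(breaks, spec$origin + seq_len(k - 1L),
                spec$origin + k)  # offsets clip beyond the grid
  }
  breaks <- sort(unique(breaks[breaks > t0 & breaks < t1]))
  bounds <- c(t0, breaks, t1)
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  list(start = bounds[-length(bounds)], end = bounds[-1],
       log_rate = base_log_rate_at(spec, mid) + age_offset_at(spec, mid))
}

## cumulative hazard from t0 to each of several (sorted, >= t0) points in a
## single segment sweep; used by the never-seen-again tails where calling
## cumulative_hazard per survey would be quadratic in the schedule length
cumhaz_at_points <- function(spec, t0, pts, effect = NULL,
                             covariates = NULL) {
  tmax <- pts[length(pts)]
  if (tmax == t0) return(numeric(length(pts)))
  seg <- hazard_segments(spec, t0, tmax)
  bounds <- sort(unique(c(t0, seg$end, pts)))
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  lp <- linear_predictor(effect, covariates)
  rate <- exp(base_log_rate_at(spec, mid) + age_offset_at(spec, mid) + lp)
  cumb <- c(0, cumsum(rate * diff(bounds)))
  cumb[findInterval(pts, bounds)]
}

#' Cumulative hazard over an interval
#'
#' Integrates the hazard exactly over `[t0, t1]` by summing rate times
#' overlap for each piecewise-constant segment.  Additive over partitions:
#' `H(a, c) = H(a, b) + H(b, c)` exactly.
#'
#' @inheritParams hazard_at
#' @param t0,t1 Interval endpoints in days, `t0 <= t1`.
#' @return Nonnegative cumulative hazard.
#' @export
cumulative_hazard <- function(spec, t0, t1, effect = NULL, covariates = NULL) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (t0 > t1) stop("'t0' must not exceed 't1'")
  if (t0 < spec$origin) stop("interval starts before the hazard origin")
  if (t0 == t1) return(0)
  seg <- hazard_segments(spec, t0, t1)
  lp <- linear_predictor(effect, covariates)
  sum(exp(seg$log_rate + lp) * (seg$end - seg$start))
}

#' Survival probability over an interval
#'
#' `exp(-cumulative_hazard(spec, t0, t1, ...))`; the probability of
#' surviving from `t0` to `t1` given alive at `t0`.
#'
#' @inheritParams cumulative_hazard
#' @return A probability in (0, 1].
#' @export
survival_prob <- function(spec, t0, t1, effect = NULL, covariates = NULL) {
  exp(-cumulative_hazard(spec, t0, t1, effect, covariates))
}

#' Seasonal daily hazard rates implied by an annual survival probability
#'
#' For a two-season year (an in-season window, e.g. hunting, whose hazard is
#' `hazard_ratio` times the off-season hazard), solves
#' `exp(-lambda1 * (year_days - hunting_days) - r * lambda1 * hunting_days)
#'  = annual_survival` in closed form:
#' `lambda1 = -log(S) / ((year_days - hunting_days) + r * hunting_days)`,
#' with `lambda2 = r * lambda1`.
#'
#' @param annual_survival Probability of surviving a whole year, in (0, 1).
#' @param hazard_ratio In-season : off-season hazard ratio (positive).
#' @param hunting_days Number of in-season days per year.
#' @param year_days Days per year (default 365, no leap years).
#' @return Named numeric vector `c(nonhunting = lambda1, hunting = lambda2)`
#'   in events per day.
#' @examples
#' annual_survival_to_rates(0.25)  # c(0.0030335, 0.0060669)
#' @export
annual_survival_to_rates <- function(annual_survival, hazard_ratio = 2,
                                     hunting_days = 92, year_days = 365) {
  if (!is.finite(annual_survival) || annual_survival <= 0 ||
      annual_survival >= 1)
    stop("'annual_survival' must lie strictly between 0 and 1")
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be positive")
  if (hunting_days < 0 || hunting_days > year_days)
    stop("'hunting_days' must lie in [0, year_days]")
  lambda1 <- -log(annual_survival) /
    ((year_days - hunting_days) + hazard_ratio * hunting_days)
  c(nonhunting = lambda1, hunting = hazard_ratio * lambda1)
}

#' Serialize a hazard spec to / from a plain configuration list
#'
#' The list form (keys `kind`, `log_rates`, `change_points`,
#' `season_start`, `season_end`, `age_effects`, `origin`) round-trips
#' through JSON/YAML-style configuration files.
#'
#' @param spec A [hazard_spec()].
#' @param x A list as produced by `hazard_spec_to_list` (or parsed from a
#'   config file).
#' @return `hazard_spec_to_list` returns a named list;
#'   `hazard_spec_from_list` returns a [hazard_spec()].
#' @export
hazard_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "hazard_spec"))
  Filter(Negate(is.null),
         spec[c("kind", "log_rates", "change_points", "season_start",
                "season_end", "age_effects", "origin")])
}

#' @rdname hazard_spec_to_list
#' @export
hazard_spec_from_list <- function(x) {
  do.call(hazard_spec, x[intersect(names(x),
                                   c("kind", "log_rates", "change_points",
                                     "season_start", "season_end",
                                     "age_effects", "origin"))])
}

#' Seasonal hazard spec used by the simulation design
#'
#' Convenience wrapper building the calendar-periodic two-rate hazard of the
#' simulation studies: study day 1 is 1 January, the in-season (hunting)
#' window is days `season_start`..`season_end` of each 365-day year.
#'
#' @param rates Numeric length-2 vector of daily rates (off-season,
#'   in-season), e.g. from [annual_survival_to_rates()].
#' @param season_start,season_end Day-of-year window, default 274..365.
#' @return A [hazard_spec()].
#' @export
hazard_seasonal <- function(rates, season_start = 274, season_end = 365) {
  hazard_spec("piecewise", log_rates = log(rates),
              season_start = season_start, season_end = season_end)
}
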