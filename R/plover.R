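## Synthetic generator for a shorebird-chick monitoring study: chicks are
## radio-tagged at 1 day of age and checked daily until they are 30 days
## old.  Transmitters fail (battery exhaustion around 18 days, plus earlier
## intermittent malfunctions), after which a chick's fate is unknown and it
## is searched for daily with constant detection probability -- exactly the
## structure the integrated likelihood was built for.  Default effect sizes
## are plausible field-scale values on the log-hazard scale; the data are
## synthetic and are not a reconstruction of any real dataset.

#' Configuration of the synthetic chick survival generator
#'
#' @param n_chicks Number of chicks (default 234).
#' @param max_age Age (days) at which survivors fledge and are censored
#'   (default 30; daily surveys at ages 2..30).
#' @param log_hazard_young Log daily mortality hazard for the first age
#'   region (ages 1 to `age_cut`).
#' @param age_effect_old Additive log-hazard contrast for ages `age_cut` and
#'   older (negative = hazard drops after the first days of life).
#' @param age_cut Age (days) at which the baseline hazard changes (default
#'   4: the first three daily intervals are the high-hazard region).
#' @param coefs Named log hazard-ratio effects for the covariates.
#'   Continuous covariates (mass, tarsus) act per standard deviation.
#' @param detection_p Daily detection probability of a chick with a failed
#'   transmitter.
#' @param battery_mean Mean transmitter battery life in days (default ~18;
#'   battery life is 15 days plus geometric jitter).
#' @param malfunction_rate Daily rate of early transmitter malfunction
#'   (exponential onset).  Together with the battery this calibrates the
#'   fraction of chicks whose fate is known.
#' @param miss_chick_sex,miss_adult_sex Fractions of chicks whose own sex /
#'   tending-adult sex covariate is missing.
#' @param habitat_probs Multinomial probabilities of the nest-habitat
#'   classes (grassland reference, prairie dog colony, agricultural,
#'   unknown).
#' @return A list of class `"plover_config"`.
#' @export
plover_config <- function(n_chicks = 234, max_age = 30,
                          log_hazard_young = -2.2, age_effect_old = -0.48,
                          age_cut = 4,
                          coefs = c(mass = -0.35, tarsus = 0.15,
                                    habitat_prairie_dog = 0.10,
                                    habitat_agricultural = -0.52,
                                    habitat_unknown = 0.89,
                                    year_2011 = -0.19, year_2012 = -0.55,
                                    chick_sex = 0.02, adult_sex = 0.08),
                          detection_p = 0.75,
                          battery_mean = 18, malfunction_rate = 0.12,
                          miss_chick_sex = 44 / 234,
                          miss_adult_sex = 72 / 234,
                          habitat_probs = c(grassland = 0.45,
                                            prairie_dog = 0.25,
                                            agricultural = 0.20,
                                            unknown = 0.10)) {
  structure(list(n_chicks = n_chicks, max_age = max_age,
                 log_hazard_young = log_hazard_young,
                 age_effect_old = age_effect_old, age_cut = age_cut,
                 coefs = coefs, detection_p = detection_p,
                 battery_mean = battery_mean,
                 malfunction_rate = malfunction_rate,
                 miss_chick_sex = miss_chick_sex,
                 miss_adult_sex = miss_adult_sex,
                 habitat_probs = habitat_probs),
            class = "plover_config")
}

#' The full covariate formula of the synthetic chick study
#' @return A RHS-only formula naming every generated covariate.
#' @export
plover_formula <- function() {
  ~ mass + tarsus + habitat_prairie_dog + habitat_agricultural +
    habitat_unknown + year_2011 + year_2012 + chick_sex + adult_sex
}

#' Generate a synthetic chick survival dataset
#'
#' Chicks enter at age 1 with covariates (standardized size measures,
#' habitat and year dummies, two 0/1 sex covariates), die according to a
#' piecewise age hazard (elevated before `age_cut`) scaled by their
#' covariates, and are monitored daily to age `max_age`.  A chick whose
#' transmitter outlives its outcome (death or fledging) yields a known-fate
#' record with daily interval censoring; a chick whose transmitter fails
#' first becomes an unknown-fate record from the failure day onward, with
#' daily Bernoulli detection at probability `detection_p` while alive.  The
#' two sex covariates are masked at the configured rates.  Uses the current
#' RNG state.
#'
#' @param config A [plover_config()].
#' @return List with `data` (an [event_data()]), `schedule` (daily surveys,
#'   age axis), `truth` (per-chick death/failure ages and the generating
#'   parameter values), and `effect` (the generating [covariate_effect()]
#'   including the standardization applied).
#' @export
generate_plover_dataset <- function(config = plover_config()) {
  stopifnot(inherits(config, "plover_config"))
  n <- config$n_chicks
  schedule <- survey_schedule(seq(2, config$max_age), config$max_age)
  mass_raw <- stats::rnorm(n, 10, 1.2)
  tarsus_raw <- stats::rnorm(n, 30, 1.5)
  habitat <- sample(names(config$habitat_probs), n, replace = TRUE,
                    prob = config$habitat_probs)
  year <- sample(2010:2012, n, replace = TRUE)
  chick_sex <- stats::rbinom(n, 1, 0.5)
  adult_sex <- stats::rbinom(n, 1, 0.5)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  X <- cbind(mass = std(mass_raw), tarsus = std(tarsus_raw),
             habitat_prairie_dog = as.numeric(habitat == "prairie_dog"),
             habitat_agricultural = as.numeric(habitat == "agricultural"),
             habitat_unknown = as.numeric(habitat == "unknown"),
             year_2011 = as.numeric(year == 2011),
             year_2012 = as.numeric(year == 2012),
             chick_sex = chick_sex, adult_sex = adult_sex)
  stopifnot(all(names(config$coefs) %in% colnames(X)))
  lp <- drop(X[, names(config$coefs), drop = FALSE] %*% config$coefs)
  base_rates <- exp(config$log_hazard_young +
                    c(0, config$age_effect_old))
  death <- vapply(seq_len(n), function(i) {
    spec_i <- hazard_spec("piecewise",
                          log_rates = log(base_rates) + lp[i],
                          change_points = config$age_cut, origin = 1)
    draw_death_time(spec_i, 1, config$max_age)
  }, numeric(1))
  battery <- 15 + stats::rgeom(n, 1 / (config$battery_mean - 15 + 1))
  malf <- stats::rexp(n, config$malfunction_rate)
  fail_age <- 1 + pmin(battery, malf)
  outcome <- pmin(death, config$max_age)
  known <- outcome <= fail_age
  ## mask the sex covariates
  miss_c <- sample(n, round(config$miss_chick_sex * n))
  miss_a <- sample(n, round(config$miss_adult_sex * n))
  radio <- marked <- list()
  for (i in seq_len(n)) {
    cv <- X[i, ]
    if (i %in% miss_c) cv[["chick_sex"]] <- NA_real_
    if (i %in% miss_a) cv[["adult_sex"]] <- NA_real_
    if (known[i]) {
      rec <- observe_radio(death[i], 1, schedule, covariates = cv, id = i)
      radio[[length(radio) + 1L]] <- rec
    } else {
      e <- floor(fail_age[i])
      st <- schedule$stimes
      after <- st > e
      det <- integer(sum(after))
      alive <- st[after] < death[i]
      det[alive] <- as.integer(stats::runif(sum(alive)) < config$detection_p)
      nn <- sum(det)
      last_seen <- if (nn > 0) st[after][max(which(det == 1L))] else NA
      marked[[length(marked) + 1L]] <-
        mark_record(e, last_seen = last_seen, history = det,
                    covariates = cv, id = i)
    }
  }
  effect <- covariate_effect(config$coefs,
                             center = c(mass = mean(mass_raw),
                                        tarsus = mean(tarsus_raw)),
                             scale = c(mass = stats::sd(mass_raw),
                                       tarsus = stats::sd(tarsus_raw)))
  list(data = event_data(radio, marked), schedule = schedule,
       truth = data.frame(id = seq_len(n), death = death,
                          fail_age = fail_age, known_fate = known,
                          lp = lp),
       effect = effect, config = config)
}

#' Fit and compare the three candidate age-hazard models
#'
#' Fits a constant-hazard model, a piecewise model with one change at
#' `age_cut`, and a random-walk smoothed age-effect model -- all sharing the
#' same proportional-hazards covariates and detection model -- and ranks
#' them by DIC.
#'
#' @param data An [event_data()] on the daily age grid.
#' @param schedule The daily [survey_schedule()].
#' @param formula Covariate formula (default [plover_formula()] restricted
#'   to covariates actually present; pass `NULL` for no covariates).
#' @param age_cut Change point of the piecewise model (default 4).
#' @param impute Names of 0/1 covariates that may be missing.
#' @param priors A [prior_spec()]; default uses uniform(-5, 5) on the
#'   intercept as well as the contrasts.
#' @param control An [mcmc_control()] shared by the three fits.
#' @param models Subset of `c("constant", "piecewise", "rw")` to fit.
#' @return List with `dic_table` (one row per model, sorted), `fits`, and
#'   `best` (name of the lowest-DIC model).
#' @export
fit_case_models <- function(data, schedule, formula = plover_formula(),
                            age_cut = 4,
                            impute = c("chick_sex", "adult_sex"),
                            priors = prior_spec(log_rate = prior_uniform(-5, 5)),
                            control = mcmc_control(n_iter = 4000),
                            models = c("constant", "piecewise", "rw")) {
  fits <- lapply(stats::setNames(models, models), function(fam) {
    eventfuse(data, schedule, family = fam, formula = formula,
              age_cuts = if (fam == "piecewise") age_cut else NULL,
              impute = impute, priors = priors, control = control)
  })
  dics <- lapply(fits, dic_fit)
  tab <- data.frame(model = models,
                    DIC = vapply(dics, `[[`, numeric(1), "DIC"),
                    pD = vapply(dics, `[[`, numeric(1), "pD"),
                    Dbar = vapply(dics, `[[`, numeric(1), "Dbar"))
  tab <- tab[order(tab$DIC), ]
  list(dic_table = tab, fits = fits, best = tab$model[1])
}

#' Check the proportional-hazards assumption of a fitted grid model
#'
#' Identifies the covariates whose credible interval excludes zero in the
#' supplied fit, refits the model with covariate-by-age interaction terms
#' for those covariates, and reports whether each interaction's credible
#' interval includes zero (inclusion is consistent with proportional
#' hazards).
#'
#' @param fit An `eventfuse` fit from a grid family.
#' @param level Credible level (default 0.95).
#' @param control Optional [mcmc_control()] for the refit (default: the
#'   fit's own).
#' @return List with `report` (a data frame, empty if no covariate is
#'   eligible) and `refit` (the interaction fit, or `NULL`).
#' @export
ph_assumption_check <- function(fit, level = 0.95, control = NULL) {
  stopifnot(inherits(fit, "eventfuse"))
  if (fit$family == "seasonal")
    stop("interaction check applies to the grid families")
  xn <- fit$design$xnames
  if (!length(xn))
    return(list(report = data.frame(), refit = NULL))
  ci <- confint(fit, parm = xn, level = level)
  eligible <- xn[ci[, 1] > 0 | ci[, 2] < 0]
  if (!length(eligible))
    return(list(report = data.frame(), refit = NULL))
  if (is.null(control)) control <- fit$control
  refit <- eventfuse(fit$data, fit$schedule, family = fit$family,
                     formula = stats::reformulate(xn),
                     age_cuts = fit$age_cuts, origin = fit$origin,
                     interactions = eligible,
                     impute = names(fit$design$miss),
                     priors = fit$priors, control = control)
  inm <- paste0(eligible, ":age")
  ici <- confint(refit, parm = inm, level = level)
  report <- data.frame(covariate = eligible,
                       lower = ici[, 1], upper = ici[, 2],
                       includes_zero = ici[, 1] <= 0 & ici[, 2] >= 0,
                       row.names = NULL)
  list(report = report, refit = refit)
}
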