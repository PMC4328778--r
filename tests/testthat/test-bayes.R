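test_that("neighborhood matrix follows the boundary/interior weight rule", {
  H4 <- build_neighborhood_matrix(4)
  expect_equal(H4, rbind(c(0, 1, 0, 0), c(0.5, 0, 0.5, 0),
                         c(0, 0.5, 0, 0.5), c(0, 0, 1, 0)))
  ## every row sums to one, so I - H is singular (intrinsic prior)
  for (k in c(2, 5, 29)) {
    H <- build_neighborhood_matrix(k)
    expect_equal(rowSums(H), rep(1, k))
    expect_lt(abs(det(diag(k) - H)), 1e-10)
  }
  expect_error(build_neighborhood_matrix(1), "at least 2")
})

test_that("RW1 prior matches hand arithmetic and the dense oracle", {
  ## quadratic form of increments (1, -1, -1): 3; tau = 1
  expect_equal(rw_age_log_prior(c(0, 1, 0, -1), 1), -1.5)
  ## a constant vector maximizes the density at fixed tau
  set.seed(3)
  for (i in 1:5) {
    a <- stats::rnorm(6, sd = 0.5)
    expect_lte(rw_age_log_prior(a, 0.7), rw_age_log_prior(rep(1, 6), 0.7))
  }
  ## doubling tau changes the density by -(k-1) log 2 + (3/4) * quad/2
  a <- c(0.3, -0.1, 0.4, -0.6)
  qf <- sum(diff(a)^2)
  expect_equal(rw_age_log_prior(a, 2) - rw_age_log_prior(a, 1),
               -3 * log(2) + (qf / 2) * (1 - 1 / 4))
  ## dense constrained-Gaussian oracle at k <= 6: log-density differences
  ## across both age vectors and tau values must agree exactly
  for (k in 3:6) {
    a1 <- stats::rnorm(k); a1 <- a1 - mean(a1)
    a2 <- stats::rnorm(k); a2 <- a2 - mean(a2)
    for (tau in c(0.5, 1.3)) {
      expect_equal(rw_age_log_prior(a1, tau) - rw_age_log_prior(a2, tau),
                   dense_rw1_logdens(a1, tau) - dense_rw1_logdens(a2, tau),
                   tolerance = 1e-9)
    }
    ## tau dependence at fixed ages: -(k-1) log(tau2/tau1) + quad term
    expect_equal(rw_age_log_prior(a1, 1.5) - rw_age_log_prior(a1, 0.5),
                 dense_rw1_logdens(a1, 1.5) - dense_rw1_logdens(a1, 0.5),
                 tolerance = 1e-9)
  }
  expect_error(rw_age_log_prior(c(0, 1), 0), "positive")
})

test_that("log_prior composes blocks and rejects out-of-support values", {
  pr <- prior_spec()
  ## all-uniform in-support: a constant independent of the value
  p1 <- log_prior(list(log_rates = c(-6, -5), p = 0.3), pr)
  p2 <- log_prior(list(log_rates = c(-8, -2), p = 0.9), pr)
  expect_equal(p1, p2)
  expect_equal(log_prior(list(p = 1.2), pr), -Inf)
  expect_equal(log_prior(list(log_rates = 5), pr), -Inf)
  ## imputed value adds its Bernoulli log-mass
  base <- list(impute_pi = c(sex = 0.5))
  with_val <- c(base, list(impute_values = list(sex = 1)))
  expect_equal(log_prior(with_val, pr) - log_prior(base, pr), log(0.5))
  ## prior presets
  expect_equal(prior_preset("uniform5")$logd(6), -Inf)
  expect_equal(prior_preset("gauss224")$logd(0), dnorm(0, 0, 2.24, log = TRUE))
  expect_equal(prior_preset("t5")$logd(1), dt(1, 5, log = TRUE))
})

test_that("posterior mode of a one-parameter model matches grid search", {
  set.seed(21)
  sched <- survey_schedule(c(10, 20, 30), study_end = 30)
  dat <- event_data(
    radio = list(radio_record(0, 10, 20), radio_record(2, 30)),
    marked = list(mark_record(0, last_seen = 10, history = c(1, 0, 0))))
  template <- hazard_spec("constant", -3)
  f <- function(lr) log_posterior(list(log_rates = lr, p = 0.4), dat, sched,
                                  template, prior_spec())
  mode_grid <- grid_opt_1d(f, -8, -1)
  mode_opt <- stats::optimize(f, c(-8, -1), maximum = TRUE)$maximum
  expect_equal(mode_grid, mode_opt, tolerance = 1e-3)
  ## flat priors: posterior equals likelihood plus a constant
  ll <- function(lr) joint_loglik(dat, hazard_spec("constant", lr), 0.4,
                                  sched)
  expect_equal(f(-3) - f(-5), ll(-3) - ll(-5), tolerance = 1e-12)
})

test_that("imputed covariate posterior masses are a valid two-point law", {
  sched <- survey_schedule(c(10, 20), study_end = 20)
  cv <- c(sex = NA_real_)
  dat <- event_data(radio = list(radio_record(0, 10, 20, covariates = cv)))
  template <- hazard_spec("constant", -3)
  pr <- prior_spec()
  lp <- vapply(0:1, function(v)
    log_posterior(list(log_rates = -3, coef = c(sex = 0.8),
                       impute_pi = c(sex = 0.5),
                       impute_values = list(sex = v)),
                  dat, sched, template, pr), numeric(1))
  post <- exp(lp) / sum(exp(lp))
  expect_equal(sum(post), 1)
  expect_true(all(post > 0 & post < 1))
  ## hand check: with lambda = exp(-3), the higher-hazard value (1) gives
  ## log-lik -1.109 + log(1 - exp(-1.108)) < the value-0 log-lik, so the
  ## posterior mass of value 1 must fall below the prior 0.5
  expect_lt(post[2], 0.5)
})

test_that("prior-only sampling recovers the declared prior moments", {
  ## likelihood switched off: the sampler must reproduce the prior
  pr <- prior_spec()
  lp <- function(th) log_prior(list(log_rates = th[1], p = th[2]), pr)
  s <- run_chains(lp, init = c(-6, 0.5),
                  control = mcmc_control(n_iter = 40000, seed = 9),
                  param_names = c("lr", "p"))
  m <- as.matrix(s)
  ## uniform(-12, 0) on the log rate; uniform(0, 1) on p
  expect_lt(abs(mean(m[, "lr"]) + 6), 0.25)
  expect_lt(abs(stats::var(m[, "lr"]) - 144 / 12), 1.4)
  expect_lt(abs(mean(m[, "p"]) - 0.5), 0.025)
  expect_lt(abs(stats::quantile(m[, "p"], 0.9) - 0.9), 0.03)
})

test_that("log_posterior stays finite on the interior of the support", {
  toy <- toy_dataset()
  template <- hazard_spec("constant", -3)
  set.seed(4)
  for (i in 1:20) {
    lp <- log_posterior(list(log_rates = stats::runif(1, -10, -0.5),
                             p = stats::runif(1, 0.01, 0.99)),
                        toy$data, toy$schedule, template, prior_spec())
    expect_true(is.finite(lp))
  }
})
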