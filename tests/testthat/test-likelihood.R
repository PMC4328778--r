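test_that("known-fate contributions match hand-derived values", {
  sp <- hazard_spec("constant", log(0.01))
  ## death bracketed in [14, 21] after surviving 0 -> 14
  rec <- radio_record(0, 14, 21)
  expect_equal(loglik_radio(rec, sp), -0.14 + log(1 - exp(-0.07)),
               tolerance = 1e-12)
  expect_equal(loglik_radio(rec, sp), -2.834056, tolerance = 1e-6)
  ## right-censored: pure survival
  expect_equal(loglik_radio(radio_record(0, 28), sp), -0.28)
  ## vanishing hazard: certain survival
  sp0 <- hazard_spec("constant", log(1e-14))
  expect_equal(loglik_radio(radio_record(0, 28), sp0), 0, tolerance = 1e-10)
  ## staggered entry conditions on survival to entry
  expect_equal(loglik_radio(radio_record(100, 114, 121), sp),
               loglik_radio(radio_record(0, 14, 21), sp))
  expect_error(radio_record(0, 21, 14), "after")
})

test_that("collapsed binomial detection kernel follows its conventions", {
  expect_equal(detection_loglik_binomial(3, 5, 0.4),
               3 * log(0.4) + 2 * log(0.6))
  expect_equal(detection_loglik_binomial(3, 5, 0.4), -3.770524,
               tolerance = 1e-6)
  expect_equal(detection_loglik_binomial(0, 0, 0.7), 0)
  expect_equal(detection_loglik_binomial(4, 4, 1), 0)
  expect_equal(detection_loglik_binomial(0, 3, 0), 0)
  expect_equal(detection_loglik_binomial(1, 3, 0), -Inf)
  expect_error(detection_loglik_binomial(4, 3, 0.5), "n_avail")
})

test_that("never-seen-again tail mixes death and nondetection correctly", {
  sched <- survey_schedule(c(5, 10), study_end = 10)
  sp <- hazard_spec("constant", log(0.1))
  rec <- mark_record(0, last_seen = 5, history = c(1, 0))
  ## one remaining survey: die before it, or survive and be missed
  expect_equal(tail_probability(rec, sp, p = 0.5, sched),
               (1 - exp(-0.5)) + exp(-0.5) * 0.5, tolerance = 1e-12)
  expect_equal(tail_probability(rec, sp, p = 0.5, sched), 0.696734,
               tolerance = 1e-6)
  ## p = 0: no information, total probability one -- for any hazard/schedule
  set.seed(7)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    spr <- hazard_spec("piecewise",
                       log_rates = stats::runif(k, -5, -0.5),
                       change_points = sort(stats::runif(k - 1, 1, 25)))
    st <- sort(sample(1:28, sample(2:5, 1)))
    schr <- survey_schedule(st, study_end = 28)
    e <- stats::runif(1, 0, st[1])
    recr <- mark_record(e)
    expect_equal(tail_probability(recr, spr, p = 0, schr), 1,
                 tolerance = 1e-12)
  }
  ## p = 1: survivors would surely be seen
  expect_equal(tail_probability(rec, sp, p = 1, sched), 1 - exp(-0.5),
               tolerance = 1e-12)
  ## no remaining surveys
  rec2 <- mark_record(0, last_seen = 10, history = c(1, 1))
  expect_equal(tail_probability(rec2, sp, p = 0.3, sched), 1)
})

test_that("marked likelihood composes its three elements", {
  sched <- survey_schedule(c(5, 10), study_end = 10)
  sp <- hazard_spec("constant", log(0.1))
  rec <- mark_record(0, last_seen = 5, history = c(1, 0))
  expect_equal(loglik_marked(rec, sp, p = 0.5, sched),
               -0.5 + log(0.5) + log(0.696734), tolerance = 1e-6)
  ## never-detected: reduces to the tail from entry
  rec0 <- mark_record(0, history = c(0, 0))
  expect_equal(loglik_marked(rec0, sp, p = 0.4, sched),
               log(tail_probability(rec0, sp, 0.4, sched)))
  ## p = 0 and never seen: no information at all
  expect_equal(loglik_marked(rec0, sp, p = 0, sched), 0)
})

test_that("marked likelihood is a probability distribution over histories", {
  ## exhaustive enumeration on short schedules, randomized hazards,
  ## detection levels, and staggered entries
  set.seed(42)
  for (i in 1:8) {
    S <- sample(2:4, 1)
    st <- sort(sample(2:30, S))
    sched <- survey_schedule(st, study_end = max(st))
    k <- sample(1:3, 1)
    spr <- if (k == 1) hazard_spec("constant", stats::runif(1, -4, -1))
           else hazard_spec("piecewise",
                            log_rates = stats::runif(k, -4, -1),
                            change_points = sort(stats::runif(k - 1, 1,
                                                              max(st) - 1)))
    p <- stats::runif(1)
    e <- stats::runif(1, 0, st[1])
    enum <- enumerate_marked_histories(spr, p, sched, e)
    expect_equal(enum$total, 1, tolerance = 1e-10)
  }
})

test_that("marked likelihood agrees with a fine-grid discrete-time oracle", {
  sched <- survey_schedule(c(6, 12, 18), study_end = 18)
  sp <- hazard_spec("piecewise", log_rates = c(-2.2, -3.1),
                    change_points = 9)
  for (h in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(1, 1, 1))) {
    rec <- mark_record(1, last_seen = if (any(h == 1))
      sched$stimes[max(which(h == 1))] else NA, history = h)
    exact <- exp(loglik_marked(rec, sp, p = 0.35, sched))
    approx <- discrete_marked_lik(rec, sp, p = 0.35, sched, h = 0.02)
    expect_equal(approx, exact, tolerance = 5e-3)
  }
})

test_that("marked likelihood is continuous and decreasing in p for all-miss", {
  sched <- survey_schedule(c(5, 10, 15), study_end = 15)
  sp <- hazard_spec("constant", log(0.05))
  rec <- mark_record(0, history = c(0, 0, 0))
  ps <- seq(0, 0.99, by = 0.01)
  ll <- vapply(ps, function(p) loglik_marked(rec, sp, p, sched), numeric(1))
  expect_true(all(diff(ll) < 0))
  expect_lt(max(abs(diff(ll))), 0.25)  # no jumps
})

test_that("joint likelihood sums per-record contributions", {
  toy <- toy_dataset()
  sp <- hazard_spec("constant", log(0.02))
  single <- event_data(radio = toy$data$radio[1])
  expect_equal(joint_loglik(single, sp, p = 0.3, toy$schedule),
               loglik_radio(toy$data$radio[[1]], sp))
  ll_all <- joint_loglik(toy$data, sp, p = 0.3, toy$schedule)
  ll_r <- joint_loglik(event_data(radio = toy$data$radio), sp, 0.3,
                       toy$schedule)
  ll_m <- joint_loglik(event_data(marked = toy$data$marked), sp, 0.3,
                       toy$schedule)
  expect_equal(ll_all, ll_r + ll_m)
  expect_error(joint_loglik(event_data(), sp, 0.3, toy$schedule), "empty")
})

test_that("with perfect detection and known fates, the MLE matches a grid search", {
  ## pure known-fate data: classical interval-censored likelihood in 1
  ## parameter; compare the maximizer against a grid-search oracle
  set.seed(9)
  sched <- weekly_schedule(140)
  true_rate <- 0.02
  sp_true <- hazard_spec("constant", log(true_rate))
  recs <- lapply(1:150, function(i) {
    e <- sample(1:14, 1)
    d <- e + stats::rexp(1, true_rate)
    observe_radio(min(d, Inf), e, sched)
  })
  dat <- event_data(radio = recs)
  f <- function(lr) joint_loglik(dat, hazard_spec("constant", lr), p = 1,
                                 sched)
  mle <- grid_opt_1d(f, log(0.005), log(0.08))
  opt <- stats::optimize(f, c(log(0.005), log(0.08)), maximum = TRUE)$maximum
  expect_equal(mle, opt, tolerance = 1e-3)
  expect_equal(exp(mle), true_rate, tolerance = 0.25)
})
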