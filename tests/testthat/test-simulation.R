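test_that("interval death probabilities are geometric-style and sum to one", {
  ## hand arithmetic: rates (0.1, 0.2), lengths (5, 5)
  sp <- hazard_spec("piecewise", log_rates = log(c(0.1, 0.2)),
                    change_points = 5)
  dp <- interval_death_probs(sp, 0, 10)
  expect_equal(dp$prob, c(0.393469, 0.383401), tolerance = 1e-5)
  expect_equal(dp$survive, 0.223130, tolerance = 1e-5)
  expect_equal(sum(dp$prob) + dp$survive, 1, tolerance = 1e-14)
  ## single interval: the exponential CDF
  sp1 <- hazard_spec("constant", log(0.03))
  dp1 <- interval_death_probs(sp1, 2, 12)
  expect_equal(dp1$prob, 1 - exp(-0.3))
  ## vanishing hazard: survival certain
  dp0 <- interval_death_probs(hazard_spec("constant", log(1e-13)), 0, 100)
  expect_equal(dp0$survive, 1, tolerance = 1e-10)
  ## randomized seasonal specs with staggered entry: always a distribution
  set.seed(14)
  for (i in 1:10) {
    r <- annual_survival_to_rates(stats::runif(1, 0.1, 0.9))
    e <- stats::runif(1, 0, 200)
    dp <- interval_death_probs(hazard_seasonal(r), e, 477)
    expect_equal(sum(dp$prob) + dp$survive, 1, tolerance = 1e-12)
  }
})

test_that("death-time draws follow the piecewise-exponential law", {
  ## empirical CDF within 0.01 of the analytic CDF at 1e5 draws
  set.seed(2024)
  cfg <- sim_config(0.25, 0.2)
  n <- 1e5
  entry <- 10
  draws <- vapply(seq_len(n), function(i)
    draw_death_time(cfg$spec, entry, 477), numeric(1))
  tgrid <- seq(entry + 1, 477, by = 7)
  cdf_true <- vapply(tgrid, function(t)
    1 - survival_prob(cfg$spec, entry, t), numeric(1))
  cdf_emp <- vapply(tgrid, function(t) mean(draws <= t), numeric(1))
  expect_lt(max(abs(cdf_emp - cdf_true)), 0.01)
  ## censoring matches the survive term
  expect_equal(mean(!is.finite(draws)),
               interval_death_probs(cfg$spec, entry, 477)$survive,
               tolerance = 3 * sqrt(0.25 / n) + 0.002)
  ## season-membership frequencies match the multinomial step
  dp <- interval_death_probs(cfg$spec, entry, 477)
  hunt <- dp$start >= 273 & dp$start < 365
  p_hunt <- sum(dp$prob[hunt])
  emp_hunt <- mean(draws >= 273 & draws < 365 & is.finite(draws))
  expect_lt(abs(emp_hunt - p_hunt), 3 * sqrt(p_hunt * (1 - p_hunt) / n))
  ## extreme hazard: draws collapse onto entry
  big <- hazard_spec("constant", log(50))
  set.seed(1)
  expect_lt(draw_death_time(big, 3, 100) - 3, 0.5)
})

test_that("the known-fate observation process brackets deaths correctly", {
  sched <- survey_schedule(c(7, 14, 21), study_end = 21)
  r <- observe_radio(17.3, 1, sched)
  expect_equal(c(r$last_alive, r$first_dead), c(14, 21))
  ## death exactly at a survey time counts as before that survey
  r2 <- observe_radio(14, 1, sched)
  expect_equal(c(r2$last_alive, r2$first_dead), c(7, 14))
  ## death before the first survey
  r3 <- observe_radio(5.5, 2, sched)
  expect_equal(c(r3$last_alive, r3$first_dead), c(2, 7))
  ## outliving the study: right-censored at the last survey
  r4 <- observe_radio(600, 1, sched)
  expect_equal(r4$last_alive, 21)
  expect_false(is.finite(r4$first_dead))
  expect_error(observe_radio(1, 2, sched), "after entry")
})

test_that("the marked observation process detects only while alive", {
  sched <- survey_schedule(c(7, 14, 21, 28), study_end = 28)
  set.seed(3)
  ## perfect detection: seen at every survey strictly before death
  m1 <- observe_marked(17, 1, 1, sched)
  expect_equal(m1$history, c(1L, 1L, 0L, 0L))
  expect_equal(m1$last_seen, 14)
  ## zero detection
  m0 <- observe_marked(25, 1, 0, sched)
  expect_equal(m0$nn, 0L)
  expect_true(is.na(m0$last_seen))
  ## sighting counts are Bernoulli(p) over the available surveys
  set.seed(8)
  nn <- replicate(4000, observe_marked(Inf, 1, 0.4, sched)$nn)
  expect_lt(abs(mean(nn) - 0.4 * 4), 3 * sqrt(4 * 0.4 * 0.6 / 4000))
})

test_that("simulated datasets obey the design identities", {
  ## at S = 0.25, about 75% die within a year of entry
  set.seed(55)
  cfg <- sim_config(0.25, 0.2, n_radio = 2500, n_marked = 2500)
  sim <- simulate_dataset(cfg)
  died_1y <- mean(sim$truth$death <= sim$truth$entry + 365)
  expect_lt(abs(died_1y - 0.75), 3 * sqrt(0.75 * 0.25 / 5000) + 0.01)
  ## structure: types, counts, record classes
  expect_equal(length(sim$data$radio), 2500)
  expect_equal(length(sim$data$marked), 2500)
  ## a marked-free config yields a pure known-fate dataset
  sim0 <- simulate_dataset(sim_config(0.55, 0.2, n_radio = 10, n_marked = 0))
  expect_equal(length(sim0$data$marked), 0)
  ## determinism under a fixed seed
  set.seed(99); a <- simulate_dataset(sim_config(0.55, 0.4, 10, 10))
  set.seed(99); b <- simulate_dataset(sim_config(0.55, 0.4, 10, 10))
  expect_identical(a, b)
})

test_that("the evaluation harness is an identity on a truth-returning fit", {
  ## plugging the truth in as the estimate gives PBS = 0, RMSE = 0;
  ## verified by computing the metrics directly on a degenerate matrix
  cfg <- sim_config(0.55, 0.4)
  truth <- c(cfg$rates, 0.4)
  est <- matrix(rep(truth, each = 5), 5, 3)
  pbs <- 100 * (colMeans(est) - truth) / truth
  rmse <- sqrt(colMeans((est - rep(truth, each = 5))^2))
  expect_equal(unname(pbs), c(0, 0, 0))
  expect_equal(unname(rmse), c(0, 0, 0))
  ## and the harness wiring runs end to end on a tiny scale
  res <- suppressMessages(
    evaluate_scenario(sim_config(0.25, 0.4, n_radio = 20, n_marked = 20),
                      n_replicates = 3,
                      control = mcmc_control(n_iter = 2000), seed = 2))
  expect_equal(nrow(res$summary), 3)
  expect_true(all(is.finite(res$summary$rmse)))
  expect_true(all(abs(res$summary$pbs) < 100))
})
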