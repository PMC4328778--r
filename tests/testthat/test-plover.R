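test_that("the chick generator produces the intended study structure", {
  set.seed(2)
  g <- generate_plover_dataset(plover_config(n_chicks = 120))
  expect_equal(length(g$data$radio) + length(g$data$marked), 120)
  expect_equal(g$schedule$stimes, 2:30)
  ## entries: known-fate chicks enter at age 1; marked records enter at the
  ## transmitter-failure day, always before their (unknown) death
  for (r in g$data$radio) expect_equal(r$entry, 1)
  for (m in g$data$marked) {
    expect_gte(m$entry, 1)
    expect_lt(m$entry, 30)
  }
  ## standardized sizes: mean 0, sd 1 across chicks
  mass <- vapply(c(g$data$radio, g$data$marked),
                 function(r) r$covariates[["mass"]], numeric(1))
  expect_equal(mean(mass), 0, tolerance = 1e-10)
  expect_equal(stats::sd(mass), 1, tolerance = 1e-10)
  ## standardization round-trip: the recorded (center, scale) map the
  ## per-sd effect back to the raw-scale effect
  raw_coef <- g$effect$coefficients[["mass"]] / g$effect$scale[["mass"]]
  expect_equal(raw_coef * g$effect$scale[["mass"]],
               g$effect$coefficients[["mass"]])
  expect_true(g$effect$scale[["mass"]] > 0)
})

test_that("transmitter failure drives the known/unknown fate split", {
  ## everlasting transmitters: all records known fate
  set.seed(4)
  g_all <- generate_plover_dataset(
    plover_config(n_chicks = 60, battery_mean = 400, malfunction_rate = 1e-9))
  expect_equal(length(g_all$data$marked), 0)
  ## perfect post-failure detection: marked chicks seen at every survey
  ## they are alive for
  set.seed(6)
  g_p1 <- generate_plover_dataset(
    plover_config(n_chicks = 150, detection_p = 1))
  for (m in g_p1$data$marked) {
    st <- g_p1$schedule$stimes[g_p1$schedule$stimes > m$entry]
    death <- g_p1$truth$death[m$id]
    expect_equal(m$nn, sum(st < death))
  }
  ## defaults calibrated so roughly 39% of fates are known (91 of 234)
  set.seed(8)
  frac <- mean(replicate(6, {
    g <- generate_plover_dataset(plover_config())
    mean(g$truth$known_fate)
  }))
  expect_lt(abs(frac - 91 / 234), 0.06)
})

test_that("missing sex covariates appear at the configured rates", {
  set.seed(10)
  g <- generate_plover_dataset(plover_config())
  recs <- c(g$data$radio, g$data$marked)
  n_miss_c <- sum(vapply(recs, function(r) is.na(r$covariates[["chick_sex"]]),
                         logical(1)))
  n_miss_a <- sum(vapply(recs, function(r) is.na(r$covariates[["adult_sex"]]),
                         logical(1)))
  expect_equal(n_miss_c, 44)
  expect_equal(n_miss_a, 72)
})

test_that("grid fits recover generator truth within credible intervals", {
  set.seed(20)
  g <- generate_plover_dataset(plover_config())
  fit <- eventfuse(g$data, g$schedule, family = "piecewise",
                   formula = ~ mass + habitat_agricultural, age_cuts = 4,
                   priors = prior_spec(log_rate = prior_uniform(-5, 5)),
                   control = mcmc_control(n_iter = 3000, seed = 1))
  ci <- confint(fit, level = 0.99)
  truth <- c(intercept = -2.2, age_region_2 = -0.48, mass = -0.35,
             habitat_agricultural = -0.52, p = 0.75)
  for (nm in names(truth)) {
    expect_gt(truth[[nm]], ci[nm, 1] - 0.35)
    expect_lt(truth[[nm]], ci[nm, 2] + 0.35)
  }
  ## the age drop's sign is recovered
  expect_lt(mean(as.matrix(fit$samples)[, "age_region_2"]), 0)
})

test_that("the model ladder and PH check run end to end on small data", {
  set.seed(30)
  g <- generate_plover_dataset(plover_config(n_chicks = 100))
  cm <- fit_case_models(g$data, g$schedule, formula = ~ mass,
                        impute = character(0),
                        control = mcmc_control(n_iter = 1200, seed = 2),
                        models = c("constant", "piecewise"))
  expect_equal(nrow(cm$dic_table), 2)
  expect_true(all(is.finite(cm$dic_table$DIC)))
  expect_true(all(cm$dic_table$pD > 0))
  ## PH check on the winning fit: report only eligible covariates
  fit <- cm$fits[[cm$best]]
  ph <- ph_assumption_check(fit, control = mcmc_control(n_iter = 800,
                                                        seed = 3))
  if (nrow(ph$report)) {
    expect_true(all(c("covariate", "lower", "upper", "includes_zero") %in%
                      names(ph$report)))
    expect_true(all(ph$report$lower < ph$report$upper))
  } else {
    expect_null(ph$refit)
  }
})
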