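test_that("the adaptive sampler recovers known Gaussian targets", {
  lp1 <- function(th) -0.5 * th^2
  s <- run_chains(lp1, init = 2, control = mcmc_control(n_iter = 50000,
                                                        seed = 42))
  m <- as.matrix(s)
  mce <- posterior_summary(s)$mc_error
  expect_lt(abs(mean(m)), 3 * mce)
  expect_lt(abs(stats::var(m[, 1]) - 1), 0.1)
  ## correlated 2-D Gaussian: recover the correlation
  rho <- 0.7
  Qi <- solve(matrix(c(1, rho, rho, 1), 2))
  lp2 <- function(th) -0.5 * drop(t(th) %*% Qi %*% th)
  s2 <- run_chains(lp2, init = c(0, 0),
                   control = mcmc_control(n_iter = 60000, seed = 7),
                   param_names = c("x", "y"))
  m2 <- as.matrix(s2)
  expect_lt(abs(stats::cor(m2[, 1], m2[, 2]) - rho), 0.05)
})

test_that("fixed seeds give bitwise-identical draws; chains differ", {
  lp <- function(th) -0.5 * sum(th^2)
  ctl <- mcmc_control(n_iter = 2000, n_chains = 2, seed = 5)
  s1 <- run_chains(lp, init = c(1, -1), ctl)
  s2 <- run_chains(lp, init = c(1, -1), ctl)
  expect_identical(s1$draws, s2$draws)
  expect_false(identical(s1$draws[, , 1], s1$draws[, , 2]))
})

test_that("the hit-and-run variant targets the same distribution", {
  lp <- function(th) -0.5 * sum((th - c(1, -2))^2 / c(1, 4))
  s <- run_chains(lp, init = c(0, 0),
                  control = mcmc_control(n_iter = 60000, seed = 11,
                                         algorithm = "harm"))
  m <- as.matrix(s)
  expect_lt(abs(mean(m[, 1]) - 1), 0.06)
  expect_lt(abs(mean(m[, 2]) + 2), 0.12)
  expect_lt(abs(stats::var(m[, 2]) - 4), 0.5)
})

test_that("Geweke diagnostic separates stationary from drifting chains", {
  set.seed(8)
  ## null: iid draws -- |z| < 3 in nearly all replicates
  zs <- replicate(40, geweke_z(stats::rnorm(10000)))
  expect_gte(mean(abs(zs) < 3), 0.97)
  ## alternative: a linear trend must be flagged hard
  drift <- stats::rnorm(5000) + seq(0, 3, length.out = 5000)
  expect_gt(abs(geweke_z(drift)), 5)
  ## degenerate: constant chain
  expect_error(geweke_z(rep(1, 1000)), "constant")
  expect_error(geweke_z(stats::rnorm(50)), "too short")
})

test_that("BGR scale reduction factors detect (non)convergence", {
  set.seed(13)
  make_s <- function(shift) {
    draws <- array(stats::rnorm(4000 * 2 * 3), c(4000, 2, 3),
                   dimnames = list(NULL, c("a", "b"), NULL))
    draws[, 1, 3] <- draws[, 1, 3] + shift
    eventfuse:::ef_samples_from_array(draws)
  }
  conv <- psrf(make_s(0))
  expect_true(all(conv$psrf < 1.05))
  expect_lt(conv$mpsrf, 1.1)
  split <- psrf(make_s(10))
  expect_gt(split$psrf[["a"]], 1.2)
  expect_gt(split$mpsrf, 1.2)
  one <- eventfuse:::ef_samples_from_array(
    array(stats::rnorm(100), c(100, 1, 1), list(NULL, "a", NULL)))
  expect_error(psrf(one), "2 chains")
})

test_that("DIC behaves as expected on reference cases", {
  ## point-mass posterior: pD = 0, DIC = deviance
  draws <- array(1.5, c(200, 1, 1), dimnames = list(NULL, "mu", NULL))
  s <- eventfuse:::ef_samples_from_array(draws)
  llf <- function(th) sum(stats::dnorm(c(0.2, 1.1, 2.3), th[1], 1,
                                       log = TRUE))
  d <- dic(s, llf)
  expect_equal(d$pD, 0)
  expect_equal(d$DIC, -2 * llf(1.5))
  ## Gaussian mean model with a flat prior: pD is about one parameter
  set.seed(99)
  y <- stats::rnorm(30, 2, 1)
  lp <- function(th) sum(stats::dnorm(y, th, 1, log = TRUE))
  sg <- run_chains(lp, init = 0, control = mcmc_control(n_iter = 50000,
                                                        seed = 12),
                   param_names = "mu")
  dg <- dic(sg, function(th) lp(th[1]))
  expect_lt(abs(dg$pD - 1), 0.1)
})

test_that("posterior summaries report the right moments and quantiles", {
  ## constant chain
  s <- eventfuse:::ef_samples_from_array(
    array(2, c(500, 1, 1), list(NULL, "c", NULL)))
  tab <- posterior_summary(s)
  expect_equal(tab$sd, 0)
  expect_equal(unlist(tab[, c("q025", "q500", "q975")]),
               c(q025 = 2, q500 = 2, q975 = 2))
  ## iid uniforms
  set.seed(1)
  u <- array(stats::runif(40000), c(40000, 1, 1), list(NULL, "u", NULL))
  su <- eventfuse:::ef_samples_from_array(u)
  tu <- posterior_summary(su)
  expect_equal(tu$mean, 0.5, tolerance = 0.01)
  expect_lt(abs(tu$q025 - 0.025), 0.005)
  ## batch-means MC error approaches sd/sqrt(n) for iid draws
  expect_equal(tu$mc_error, tu$sd / sqrt(40000), tolerance = 0.35)
})
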