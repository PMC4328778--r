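## Prior declarations, the intrinsic random-walk (RW1) age prior, and the
## joint log-posterior.  Out-of-support parameter values yield -Inf
## (rejection semantics), never an error.

#' Elementary prior declarations
#'
#' Small constructors for the prior families used by the models: uniform,
#' Gaussian and scaled central t.  Each returns a list with a vectorized
#' `logd(x)` function; values outside the support give `-Inf`.
#'
#' @param lo,hi Uniform bounds.
#' @param mu,sigma Gaussian mean and standard deviation.
#' @param df,scale Degrees of freedom and scale of the central t.
#' @return A list with elements `type`, the parameters, and `logd`.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  force(lo); force(hi)
  list(type = "uniform", lo = lo, hi = hi,
       logd = function(x) ifelse(x < lo | x > hi, -Inf, -log(hi - lo)))
}

#' @rdname priors
#' @export
prior_gaussian <- function(mu, sigma) {
  force(mu); force(sigma)
  list(type = "gaussian", mu = mu, sigma = sigma,
       logd = function(x) stats::dnorm(x, mu, sigma, log = TRUE))
}

#' @rdname priors
#' @export
prior_t <- function(df, scale = 1) {
  force(df); force(scale)
  list(type = "t", df = df, scale = scale,
       logd = function(x) stats::dt(x / scale, df, log = TRUE) - log(scale))
}

#' Named prior presets for hazard coefficients
#'
#' Three weakly informative families commonly compared in prior-sensitivity
#' analyses: `"uniform5"` = uniform on \[-5, 5\], `"t5"` = central t with 5
#' degrees of freedom, `"gauss224"` = Gaussian(0, 2.24).
#'
#' @param name One of `"uniform5"`, `"t5"`, `"gauss224"`.
#' @return A prior declaration as from [prior_uniform()] etc.
#' @export
prior_preset <- function(name = c("uniform5", "t5", "gauss224")) {
  switch(match.arg(name),
         uniform5 = prior_uniform(-5, 5),
         t5 = prior_t(df = 5),
         gauss224 = prior_gaussian(0, 2.24))
}

#' Prior specification for an integrated event-time model
#'
#' One prior per parameter block.  Defaults: uniform(-12, 0) on each log
#' baseline rate (daily hazards between `exp(-12)` and 1), the preset
#' uniform(-5, 5) on covariate coefficients, the Bayes-Laplace uniform(0, 1)
#' on the detection probability, uniform(0, 5) on the random-walk increment
#' standard deviation `tau`, and Gaussian(0.5, 0.05) on the probability
#' parameter of each missing-binary-covariate Bernoulli prior (constraining
#' e.g. a sex ratio to roughly 45--55%).
#'
#' @param log_rate,coef,detection,tau,impute_pi Prior declarations (see
#'   [prior_uniform()], [prior_preset()]).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(log_rate = prior_uniform(-12, 0),
                       coef = prior_preset("uniform5"),
                       detection = prior_uniform(0, 1),
                       tau = prior_uniform(0, 5),
                       impute_pi = prior_gaussian(0.5, 0.05)) {
  structure(list(log_rate = log_rate, coef = coef, detection = detection,
                 tau = tau, impute_pi = impute_pi),
            class = "prior_spec")
}

#' First-order neighborhood matrix of the age chain
#'
#' The row-standardized adjacency matrix of `k` ordered age intervals:
#' `H[i, j]` is 0 unless interval `j` immediately precedes or follows
#' interval `i`, in which case it is 1/2 for interior rows and 1 for the two
#' boundary rows (which have a single neighbor).  Every row sums to one, so
#' `I - H` is singular and the implied Gaussian random-walk prior is
#' intrinsic (improper); see [rw_age_log_prior()].
#'
#' @param k Number of age intervals (at least 2).
#' @return A `k x k` matrix.
#' @export
build_neighborhood_matrix <- function(k) {
  if (k < 2) stop("'k' must be at least 2")
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= k]
    H[i, nb] <- 1 / length(nb)
  }
  H
}

#' Intrinsic random-walk (RW1) log prior for age effects
#'
#' The first-order Gaussian Markov random field density (up to a constant)
#' penalizing squared differences of adjacent age effects:
#' \deqn{-(k-1)\log\tau - \frac{1}{2\tau^2}\sum_{i=1}^{k-1}
#'       (a_{i+1}-a_i)^2.}
#' The density is improper in the level direction (the row-standardized
#' neighborhood matrix makes `I - H` singular), so a sum-to-zero constraint
#' on the age effects is imposed for identifiability against the model
#' intercept; on that constrained subspace the density coincides with a
#' zero-mean Gaussian with generalized covariance `(I - H)^{-1} M`,
#' `M = tau^2 I` (row-standardized weights).
#'
#' @param age_effects Numeric vector of `k >= 2` age-interval effects.
#' @param tau Increment standard deviation, positive.
#' @return Log-density up to an additive constant.
#' @export
rw_age_log_prior <- function(age_effects, tau) {
  if (tau <= 0) stop("'tau' must be positive")
  k <- length(age_effects)
  if (k < 2) stop("need at least 2 age effects")
  -(k - 1) * log(tau) - sum(diff(age_effects)^2) / (2 * tau^2)
}

#' Joint log prior
#'
#' Sums the independent prior log-densities over the supplied parameter
#' blocks: log baseline rates, covariate coefficients, the detection
#' probability, the random-walk age effects with their scale `tau`, the
#' probability parameters of missing-binary-covariate priors, and the
#' Bernoulli log-masses of any imputed covariate values themselves (data
#' augmentation).  Returns `-Inf` outside the prior support.
#'
#' @param params Named list with any of the elements `log_rates`, `coef`,
#'   `p`, `age_effects` + `tau`, `impute_pi` (named probabilities), and
#'   `impute_values` (named list of 0/1 vectors, one per missing covariate,
#'   whose names match `impute_pi`).
#' @param priors A [prior_spec()].
#' @return Scalar log prior density (up to a constant), possibly `-Inf`.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  lp <- 0
  if (!is.null(params$log_rates))
    lp <- lp + sum(priors$log_rate$logd(params$log_rates))
  if (!is.null(params$coef) && length(params$coef))
    lp <- lp + sum(priors$coef$logd(params$coef))
  if (!is.null(params$p)) {
    if (params$p < 0 || params$p > 1) return(-Inf)
    lp <- lp + priors$detection$logd(params$p)
  }
  if (!is.null(params$age_effects)) {
    if (is.null(params$tau)) stop("'tau' required with age effects")
    lp <- lp + priors$tau$logd(params$tau)
    if (!is.finite(lp)) return(-Inf)
    lp <- lp + rw_age_log_prior(params$age_effects, params$tau)
  }
  if (!is.null(params$impute_pi)) {
    pi <- params$impute_pi
    if (any(pi < 0 | pi > 1)) return(-Inf)
    lp <- lp + sum(priors$impute_pi$logd(pi))
    if (!is.null(params$impute_values)) {
      for (nm in names(params$impute_values)) {
        v <- params$impute_values[[nm]]
        pr <- pi[[nm]]
        lp <- lp + sum(v * log(pr) + (1 - v) * log(1 - pr))
      }
    }
  }
  if (is.nan(lp)) -Inf else lp
}

## substitute imputed values for missing covariates, in record order
## (radio first, then marked)
impute_into_data <- function(data, impute_values) {
  if (is.null(impute_values) || !length(impute_values)) return(data)
  for (nm in names(impute_values)) {
    vals <- impute_values[[nm]]
    j <- 0L
    fill <- function(rec) {
      if (!is.null(rec$covariates) && nm %in% names(rec$covariates) &&
          is.na(rec$covariates[[nm]])) {
        j <<- j + 1L
        rec$covariates[[nm]] <- vals[j]
      }
      rec
    }
    data$radio <- lapply(data$radio, fill)
    data$marked <- lapply(data$marked, fill)
    if (j != length(vals))
      stop("length of imputed values for '", nm,
           "' does not match the number of missing entries (", j, ")")
  }
  data
}

#' Joint log posterior
#'
#' `joint_loglik + log_prior`, with imputed covariate values substituted
#' into the likelihood (data augmentation) before evaluation.  The hazard
#' spec is rebuilt from the parameter vector using `template` for its
#' structure (kind, change points, season window, origin).
#'
#' @inheritParams log_prior
#' @param data An [event_data()].
#' @param schedule A [survey_schedule()].
#' @param template A [hazard_spec()] giving the structural layout; its
#'   `log_rates` (and `age_effects`, if present in `params`) are replaced by
#'   the values in `params`.
#' @param include_detection Passed to [joint_loglik()].
#' @return Scalar log posterior density (up to a constant), `-Inf` outside
#'   the prior support.
#' @export
log_posterior <- function(params, data, schedule, template,
                          priors = prior_spec(), include_detection = FALSE) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  spec <- template
  spec$log_rates <- params$log_rates
  if (!is.null(params$age_effects)) spec$age_effects <- params$age_effects
  effect <- NULL
  if (!is.null(params$coef) && length(params$coef)) {
    if (is.null(names(params$coef))) stop("'coef' must be named")
    effect <- covariate_effect(params$coef)
  }
  data <- impute_into_data(data, params$impute_values)
  lp + joint_loglik(data, spec, p = params$p, schedule = schedule,
                    effect = effect, include_detection = include_detection)
}
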