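## The main model-fitting interface.  eventfuse() dispatches on the hazard
## template: the two-season calendar model without covariates goes through
## the compiled sufficient-statistic path, and models on a daily grid
## (constant / piecewise / random-walk age effects, with
## proportional-hazards covariates and missing binary covariates) go
## through a vectorized likelihood sampled with the generic adaptive
## Metropolis machinery.

row_logsumexp <- function(M) {
  mx <- do.call(pmax, c(as.data.frame(M), list(na.rm = FALSE)))
  mx + log(rowSums(exp(M - mx)))
}

## ---- daily-grid design -----------------------------------------------------

## Collapse a dataset whose times all sit on the integer grid
## [origin, study_end] (daily surveys) into the matrices the vectorized
## likelihood needs.  'impute' names 0/1 covariates that may contain NA.
build_grid_design <- function(data, schedule, origin, formula = NULL,
                              impute = character(0)) {
  K <- schedule$study_end - origin
  need <- seq.int(origin + 1, schedule$study_end)
  if (K < 1 || !isTRUE(all.equal(schedule$stimes, need)))
    stop("the grid path requires daily surveys at every integer time in (",
         origin, ", ", schedule$study_end, "]")
  recs <- c(data$radio, data$marked)
  n1 <- length(data$radio); n2 <- length(data$marked)
  n <- n1 + n2
  chk_int <- function(x) all(is.finite(x) == FALSE | x == floor(x))
  ## covariate matrix
  X <- NULL; xnames <- character(0)
  if (!is.null(formula)) {
    cv <- lapply(recs, function(r) as.list(r$covariates))
    df <- do.call(rbind, lapply(cv, function(l) as.data.frame(l)))
    mf <- stats::model.frame(formula, df, na.action = stats::na.pass)
    X <- stats::model.matrix(formula, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    xnames <- colnames(X)
    bad <- setdiff(xnames[colSums(is.na(X)) > 0], impute)
    if (length(bad))
      stop("missing values in covariate(s) not declared for imputation: ",
           paste(bad, collapse = ", "))
  }
  seg_idx <- function(a, b) if (b > a) seq.int(a - origin + 1, b - origin)
                            else integer(0)
  ER <- matrix(0, n1, K); DR <- matrix(0, n1, K); dead <- logical(n1)
  for (i in seq_len(n1)) {
    r <- data$radio[[i]]
    if (r$entry != floor(r$entry) || r$last_alive != floor(r$last_alive) ||
        (is.finite(r$first_dead) && r$first_dead != floor(r$first_dead)))
      stop("grid path requires integer record times (record ", i, ")")
    ER[i, seg_idx(r$entry, r$last_alive)] <- 1
    if (is.finite(r$first_dead)) {
      dead[i] <- TRUE
      DR[i, seg_idx(r$last_alive, r$first_dead)] <- 1
    }
  }
  EM <- matrix(0, max(n2, 1), K); nn <- navail <- k0 <- numeric(n2)
  for (j in seq_len(n2)) {
    r <- data$marked[[j]]
    if (is.finite(r$first_dead))
      stop("the grid path supports right-censored marked records only")
    tstar <- tstar_of(r)
    if (r$entry != floor(r$entry) || tstar != floor(tstar))
      stop("grid path requires integer record times (marked record ", j, ")")
    EM[j, seg_idx(r$entry, tstar)] <- 1
    nn[j] <- r$nn
    navail[j] <- n_avail_of(r, schedule)
    k0[j] <- tstar - origin + 1
  }
  if (n2 > 0) {
    kk <- matrix(rep(seq_len(K), each = n2), ncol = K)
    MASK <- (kk >= k0) * 1
    EXPO <- pmax(kk - k0, 0)
    mfin <- pmax(K - k0 + 1, 0)
    cs_cbind <- cbind(seq_len(n2), pmax(k0 - 1, 1))
    cs_use <- as.numeric(k0 > 1)
  } else {
    MASK <- EXPO <- matrix(0, 0, K); mfin <- numeric(0)
    cs_cbind <- cbind(integer(0), integer(0)); cs_use <- numeric(0)
  }
  UT <- upper.tri(matrix(0, K, K), diag = TRUE) * 1
  list(n1 = n1, n2 = n2, n = n, K = K, origin = origin,
       ER = ER, DR = DR, dead = dead, DRd = DR[dead, , drop = FALSE],
       EM = EM, nn = nn, navail = navail, k0 = k0,
       cs_cbind = cs_cbind, cs_use = cs_use,
       MASK = MASK, EXPO = EXPO, mfin = mfin, UT = UT,
       X = X, xnames = xnames,
       miss = lapply(stats::setNames(impute, impute),
                     function(nm) if (!is.null(X) && nm %in% xnames)
                       which(is.na(X[, nm])) else integer(0)),
       schedule = schedule)
}

## per-individual log-likelihood vector for one covariate configuration
## rho: per-interval log baseline (length K); lp: linear predictor (n);
## gam_age: optional per-interval interaction addition as an n x K matrix
grid_llvec <- function(des, rho, lp, p, gam_age = NULL) {
  erho <- exp(rho)
  ll <- numeric(des$n)
  if (des$n1 > 0) {
    i1 <- seq_len(des$n1)
    elp1 <- exp(lp[i1])
    if (is.null(gam_age)) {
      ll1 <- -elp1 * drop(des$ER %*% erho)
      HD <- elp1[des$dead] * drop(des$DRd %*% erho)
    } else {
      EG <- exp(gam_age[i1, , drop = FALSE])
      ll1 <- -elp1 * drop((des$ER * EG) %*% erho)
      HD <- elp1[des$dead] *
        drop((des$DRd * EG[des$dead, , drop = FALSE]) %*% erho)
    }
    ll1[des$dead] <- ll1[des$dead] + log1mexp(HD)
    ll[i1] <- ll1
  }
  if (des$n2 > 0) {
    i2 <- des$n1 + seq_len(des$n2)
    elp2 <- exp(lp[i2])
    if (p <= 0 && any(des$nn > 0)) return(rep(-Inf, des$n))
    if (p >= 1 && any(des$navail > des$nn)) return(rep(-Inf, des$n))
    det <- if (p > 0 && p < 1)
      des$nn * log(p) + (des$navail - des$nn) * log1p(-p)
    else if (p <= 0) 0 else des$nn * 0  # boundary cases already screened
    ## never-seen-again tails on the daily grid
    RM <- if (is.null(gam_age)) outer(elp2, erho)
          else elp2 * exp(gam_age[i2, , drop = FALSE] +
                            rep(rho, each = des$n2))
    if (is.null(gam_age)) ll2 <- -elp2 * drop(des$EM %*% erho)
    else ll2 <- -rowSums(des$EM * RM)
    C <- RM %*% des$UT
    Cstart <- C[des$cs_cbind] * des$cs_use
    W <- exp(Cstart - C)
    W_prev <- cbind(1, W[, -des$K, drop = FALSE])
    q <- 1 - p
    Qm <- (q ^ des$EXPO) * des$MASK
    tail <- rowSums((W_prev - W) * Qm) + W[, des$K] * q^des$mfin
    ll[i2] <- ll2 + det + log(pmax(tail, 1e-300))
  }
  ll
}

## enumerate missing-covariate configurations; returns list of
## list(X = imputed matrix, logw = function(pi) scalar log weight)
grid_configs <- function(des) {
  active <- names(des$miss)[vapply(des$miss, length, 1L) > 0]
  if (!length(active)) return(list(list(X = des$X, vals = NULL)))
  grid <- expand.grid(rep(list(0:1), length(active)))
  names(grid) <- active
  lapply(seq_len(nrow(grid)), function(g) {
    X <- des$X
    for (nm in active) X[des$miss[[nm]], nm] <- grid[g, nm]
    list(X = X, vals = unlist(grid[g, , drop = FALSE]))
  })
}

## ---- parameter layout ------------------------------------------------------

grid_layout <- function(des, family, n_regions, interactions = character(0)) {
  nm <- "intercept"
  if (family == "piecewise" && n_regions > 1)
    nm <- c(nm, paste0("age_region_", 2:n_regions))
  nm <- c(nm, des$xnames)
  if (length(interactions)) nm <- c(nm, paste0(interactions, ":age"))
  has_p <- des$n2 > 0
  if (has_p) nm <- c(nm, "p")
  if (family == "rw") nm <- c(nm, "tau", paste0("delta_", seq_len(des$K - 1)))
  active <- names(des$miss)[vapply(des$miss, length, 1L) > 0]
  if (length(active)) nm <- c(nm, paste0("pi_", active))
  list(names = nm, has_p = has_p, active = active,
       idx = stats::setNames(seq_along(nm), nm))
}

## ---- the fitted-model class ------------------------------------------------

#' Fit an integrated event-time survival model
#'
#' Samples the joint posterior of hazard and detection parameters for a
#' dataset combining interval-censored known-fate records with imperfectly
#' detected marked records.  Two model families are supported:
#'
#' * `family = "seasonal"`: the calendar-periodic two-rate hazard (off- and
#'   in-season daily rates, e.g. outside/inside a hunting season), no
#'   covariates; fitted through a compiled sufficient-statistic likelihood.
#' * `family = "constant"`, `"piecewise"`, `"rw"`: hazards on a daily age
#'   grid (all record times integers, daily surveys), optionally with
#'   log-linear proportional-hazards covariates, covariate-by-age
#'   interactions, missing 0/1 covariates (marginalized over Bernoulli
#'   priors whose probability parameters are estimated), and -- for
#'   `"rw"` -- a smoothed age profile under an intrinsic first-order
#'   random-walk prior with increment standard deviation `tau`.
#'
#' For the grid families the baseline is parameterized as an intercept (log
#' hazard of the first age region) plus log hazard-ratio contrasts for later
#' regions, so exponentiated coefficients are hazard ratios throughout.
#'
#' @param data An [event_data()].
#' @param schedule A [survey_schedule()].
#' @param family Model family, see above.
#' @param formula RHS-only formula for proportional-hazards covariates,
#'   evaluated against the per-record covariate sets (grid families only).
#' @param age_cuts Interior change points on the age axis for
#'   `family = "piecewise"` (e.g. `4` for a drop after the first three daily
#'   intervals).
#' @param origin Start of the age/time axis for the grid families (default
#'   1: entry at age 1 day).
#' @param interactions Character vector of covariate names whose effect is
#'   allowed to vary linearly with (standardized) age -- a proportional-
#'   hazards assumption check.
#' @param impute Names of 0/1 covariates that may contain `NA`; they are
#'   marginalized over Bernoulli priors with estimated probability
#'   parameters `pi_<name>`.
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @param season_start,season_end In-season window for
#'   `family = "seasonal"`.
#' @return An object of class `"eventfuse"` with components `samples` (an
#'   `ef_samples`), `family`, `data`, `schedule`, and the internal design;
#'   see [summary.eventfuse()], [coef.eventfuse()], [plot.eventfuse()],
#'   [predict.eventfuse()], [dic_fit()], [posterior_predictive_check()].
#' @export
eventfuse <- function(data, schedule,
                      family = c("seasonal", "constant", "piecewise", "rw"),
                      formula = NULL, age_cuts = NULL, origin = 1,
                      interactions = character(0), impute = character(0),
                      priors = prior_spec(), control = mcmc_control(),
                      season_start = 274, season_end = 365) {
  family <- match.arg(family)
  cl <- match.call()
  if (family == "seasonal") {
    if (!is.null(formula))
      stop("the seasonal family does not support covariates")
    samples <- fit_seasonal(data, schedule, control = control,
                            log_rate_bounds = c(priors$log_rate$lo,
                                                priors$log_rate$hi),
                            season_start = season_start,
                            season_end = season_end)
    out <- list(samples = samples, family = family, data = data,
                schedule = schedule, priors = priors, control = control,
                season = c(season_start, season_end), call = cl)
    class(out) <- "eventfuse"
    return(out)
  }
  des <- build_grid_design(data, schedule, origin, formula, impute)
  if (family == "piecewise") {
    if (is.null(age_cuts)) stop("'age_cuts' required for the piecewise family")
    age_cuts <- sort(as.numeric(age_cuts))
    region <- findInterval(origin + seq_len(des$K) - 0.5, age_cuts) + 1L
    n_regions <- max(region)
  } else {
    region <- rep(1L, des$K)
    n_regions <- 1L
  }
  lay <- grid_layout(des, family, n_regions, interactions)
  configs <- grid_configs(des)
  amid <- origin + seq_len(des$K) - 0.5
  age_std <- (amid - mean(amid)) / stats::sd(amid)
  npar <- length(lay$names)
  ix <- lay$idx
  nx <- length(des$xnames)
  nint <- length(interactions)
  int_cols <- if (nint) match(interactions, des$xnames) else integer(0)
  if (nint && anyNA(int_cols)) stop("'interactions' must name model covariates")

  unpack <- function(theta) {
    b0 <- theta[ix[["intercept"]]]
    contr <- if (n_regions > 1)
      c(0, theta[ix[paste0("age_region_", 2:n_regions)]]) else 0
    beta <- if (nx) theta[ix[des$xnames]] else numeric(0)
    gamma <- if (nint) theta[ix[paste0(interactions, ":age")]] else numeric(0)
    p <- if (lay$has_p) theta[ix[["p"]]] else NA_real_
    tau <- if (family == "rw") theta[ix[["tau"]]] else NA_real_
    delta <- if (family == "rw")
      theta[ix[paste0("delta_", seq_len(des$K - 1))]] else numeric(0)
    pi <- if (length(lay$active))
      stats::setNames(theta[ix[paste0("pi_", lay$active)]], lay$active)
    else numeric(0)
    age_eff <- if (family == "rw") {
      a <- cumsum(c(0, delta)); a - mean(a)
    } else numeric(0)
    rho <- b0 + contr[region] + if (family == "rw") age_eff else 0
    list(b0 = b0, contr = contr, beta = beta, gamma = gamma, p = p,
         tau = tau, delta = delta, pi = pi, age_eff = age_eff, rho = rho)
  }

  log_prior_theta <- function(pp) {
    lp <- priors$log_rate$logd(pp$b0)
    if (n_regions > 1) lp <- lp + sum(priors$coef$logd(pp$contr[-1]))
    if (nx) lp <- lp + sum(priors$coef$logd(pp$beta))
    if (nint) lp <- lp + sum(priors$coef$logd(pp$gamma))
    if (lay$has_p) {
      if (pp$p < 0 || pp$p > 1) return(-Inf)
      lp <- lp + priors$detection$logd(pp$p)
    }
    if (family == "rw") {
      lp <- lp + priors$tau$logd(pp$tau)
      if (!is.finite(lp) || pp$tau <= 0) return(-Inf)
      lp <- lp - (des$K - 1) * log(pp$tau) -
        sum(pp$delta^2) / (2 * pp$tau^2)
    }
    if (length(lay$active)) {
      if (any(pp$pi <= 0 | pp$pi >= 1)) return(-Inf)
      lp <- lp + sum(priors$impute_pi$logd(pp$pi))
    }
    if (is.nan(lp)) -Inf else lp
  }

  loglik_theta <- function(theta) {
    pp <- unpack(theta)
    llc <- vapply(configs, function(cf) {
      lp_i <- if (nx) drop(cf$X %*% pp$beta) else numeric(des$n)
      gam_age <- if (nint)
        outer(drop(cf$X[, int_cols, drop = FALSE] %*% pp$gamma), age_std)
      else NULL
      grid_llvec(des, pp$rho, lp_i, pp$p, gam_age)
    }, numeric(des$n))
    llc <- matrix(llc, nrow = des$n)
    if (length(configs) == 1L) return(sum(llc[, 1]))
    logw <- vapply(configs, function(cf)
      sum(cf$vals * log(pp$pi[names(cf$vals)]) +
            (1 - cf$vals) * log1p(-pp$pi[names(cf$vals)])), numeric(1))
    sum(row_logsumexp(sweep(llc, 2, logw, `+`)))
  }

  log_post <- function(theta) {
    pp <- unpack(theta)
    lp <- log_prior_theta(pp)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik_theta(theta)
  }

  init_fn <- function(chain) {
    th <- numeric(npar)
    th[ix[["intercept"]]] <- stats::runif(1, -4, -1)
    if (n_regions > 1)
      th[ix[paste0("age_region_", 2:n_regions)]] <-
        stats::runif(n_regions - 1, -1, 1)
    if (nx) th[ix[des$xnames]] <- stats::runif(nx, -0.5, 0.5)
    if (nint) th[ix[paste0(interactions, ":age")]] <-
      stats::runif(nint, -0.2, 0.2)
    if (lay$has_p) th[ix[["p"]]] <- stats::runif(1, 0.2, 0.9)
    if (family == "rw") {
      th[ix[["tau"]]] <- stats::runif(1, 0.2, 1.5)
      th[ix[paste0("delta_", seq_len(des$K - 1))]] <-
        stats::rnorm(des$K - 1, 0, 0.1)
    }
    if (length(lay$active))
      th[ix[paste0("pi_", lay$active)]] <- stats::runif(length(lay$active),
                                                        0.45, 0.55)
    th
  }

  samples <- run_chains(log_post, init_fn, control, param_names = lay$names)
  out <- list(samples = samples, family = family, data = data,
              schedule = schedule, priors = priors, control = control,
              design = des, layout = lay, unpack = unpack,
              loglik_theta = loglik_theta, region = region,
              n_regions = n_regions, age_cuts = age_cuts, origin = origin,
              interactions = interactions, call = cl)
  class(out) <- "eventfuse"
  out
}

## rebuild a hazard spec (and covariate effect) from one parameter vector
build_spec_from <- function(fit, theta) {
  if (fit$family == "seasonal") {
    list(spec = hazard_seasonal(theta[c("lambda1", "lambda2")],
                                fit$season[1], fit$season[2]),
         effect = NULL, p = theta[["p"]])
  } else {
    pp <- fit$unpack(theta)
    rho_regions <- if (fit$family == "piecewise") pp$b0 + pp$contr else pp$b0
    spec <- if (fit$family == "piecewise")
      hazard_spec("piecewise", log_rates = rho_regions,
                  change_points = fit$age_cuts, origin = fit$origin)
    else hazard_spec("constant", log_rates = pp$b0,
                     age_effects = if (fit$family == "rw") pp$age_eff,
                     origin = fit$origin)
    eff <- if (length(pp$beta))
      covariate_effect(stats::setNames(pp$beta, fit$design$xnames))
    list(spec = spec, effect = eff, p = pp$p)
  }
}

#' @export
print.eventfuse <- function(x, ...) {
  cat("Integrated event-time survival model (family:", x$family, ")\n")
  print(x$data)
  cm <- colMeans(as.matrix(x$samples))
  show <- cm[!grepl("^delta_", names(cm))]
  cat("Posterior means:\n")
  print(round(show, 4))
  invisible(x)
}

#' Summarize a fitted integrated survival model
#'
#' Posterior mean, sd, batch-means MC error and central quantiles per
#' parameter, plus convergence diagnostics (Geweke z per parameter; BGR
#' scale reduction factors when more than one chain was run).
#'
#' @param object An `eventfuse` fit.
#' @param ... Unused.
#' @return A list of class `"summary.eventfuse"`.
#' @export
summary.eventfuse <- function(object, ...) {
  tab <- posterior_summary(object$samples)
  gz <- tryCatch(geweke_z(object$samples), error = function(e) NULL)
  ps <- if (dim(object$samples$draws)[3] >= 2) psrf(object$samples) else NULL
  structure(list(table = tab, geweke = gz, psrf = ps,
                 family = object$family),
            class = "summary.eventfuse")
}

#' @export
print.summary.eventfuse <- function(x, ...) {
  cat("Posterior summary (family:", x$family, ")\n")
  tab <- x$table[!grepl("^delta_", rownames(x$table)), ]
  print(round(tab, 4))
  if (!is.null(x$psrf))
    cat(sprintf("Multivariate BGR scale reduction factor: %.3f\n",
                x$psrf$mpsrf))
  invisible(x)
}

#' @export
coef.eventfuse <- function(object, ...) colMeans(as.matrix(object$samples))

#' @export
confint.eventfuse <- function(object, parm, level = 0.95, ...) {
  m <- as.matrix(object$samples)
  if (!missing(parm)) m <- m[, parm, drop = FALSE]
  a <- (1 - level) / 2
  t(apply(m, 2, stats::quantile, probs = c(a, 1 - a)))
}

#' Predict survival or hazard curves from a fitted model
#'
#' Evaluates the posterior-mean hazard (optionally scaled by covariates) at
#' the requested times.
#'
#' @param object An `eventfuse` fit.
#' @param times Times (days) at which to evaluate.
#' @param newdata Optional named covariate vector.
#' @param type `"survival"` (from the first time to each time),
#'   `"hazard"`, or `"cumhaz"`.
#' @param ... Unused.
#' @return A data frame with columns `time` and the requested quantity.
#' @export
predict.eventfuse <- function(object, times, newdata = NULL,
                              type = c("survival", "hazard", "cumhaz"), ...) {
  type <- match.arg(type)
  bs <- build_spec_from(object, coef(object))
  out <- switch(type,
    hazard = vapply(times, function(t)
      hazard_at(bs$spec, t, bs$effect, newdata), numeric(1)),
    cumhaz = vapply(times, function(t)
      cumulative_hazard(bs$spec, times[1], t, bs$effect, newdata), numeric(1)),
    survival = vapply(times, function(t)
      survival_prob(bs$spec, times[1], t, bs$effect, newdata), numeric(1)))
  data.frame(time = times, value = out)
}

#' Plot a fitted integrated survival model
#'
#' For a random-walk age model, the posterior mean hazard curve over age
#' with a credible envelope; otherwise traceplots of the main parameters.
#'
#' @param x An `eventfuse` fit.
#' @param which_pars Parameters to trace (default: all non-increment).
#' @param level Credible level of the hazard envelope (default 0.9).
#' @param ... Passed to the underlying plot calls.
#' @return Invisibly, `x`.
#' @export
plot.eventfuse <- function(x, which_pars = NULL, level = 0.9, ...) {
  m <- as.matrix(x$samples)
  if (x$family == "rw") {
    ## per-draw hazard at each age interval
    K <- x$design$K
    idx_d <- grep("^delta_", colnames(m))
    b0 <- m[, "intercept"]
    haz <- t(apply(cbind(b0, m[, idx_d, drop = FALSE]), 1, function(th) {
      a <- cumsum(c(0, th[-1])); a <- a - mean(a)
      exp(th[1] + a)
    }))
    qs <- apply(haz, 2, stats::quantile,
                probs = c((1 - level) / 2, 0.5, 1 - (1 - level) / 2))
    age <- x$origin + seq_len(K) - 0.5
    plot(age, qs[2, ], type = "n", ylim = range(qs),
         xlab = "age (days)", ylab = "hazard (per day)", ...)
    polygon(c(age, rev(age)), c(qs[1, ], rev(qs[3, ])),
            col = "grey85", border = NA)
    lines(age, qs[2, ], lwd = 2)
  } else {
    if (is.null(which_pars))
      which_pars <- setdiff(colnames(m), grep("^delta_", colnames(m),
                                              value = TRUE))
    op <- par(mfrow = c(min(length(which_pars), 3),
                        ceiling(length(which_pars) / 3)), mar = c(3, 4, 2, 1))
    on.exit(par(op))
    for (nm in which_pars)
      plot(m[, nm], type = "l", ylab = nm, xlab = "", ...)
  }
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' Computes DIC (with `pD` and `Dbar`) from the fit's own likelihood,
#' evaluated on thinned posterior draws and at the posterior mean.
#'
#' @param fit An `eventfuse` fit.
#' @param thin Use every `thin`-th pooled draw for `Dbar` (default keeps
#'   about 500 draws).
#' @return As [dic()].
#' @export
dic_fit <- function(fit, thin = NULL) {
  m <- as.matrix(fit$samples)
  if (is.null(thin)) thin <- max(1L, floor(nrow(m) / 500))
  llfn <- if (fit$family == "seasonal") {
    design <- fit$samples$design
    function(theta) .loglik_seasonal_cpp(theta[[1]], theta[[2]], theta[[3]],
                                         design)
  } else {
    fit$loglik_theta
  }
  dic(fit$samples, llfn, thin = thin)
}

#' Posterior predictive check of failure times
#'
#' For each retained draw (thinned), simulates replicate failure times for
#' the individuals whose deaths were observed, conditional on their entry
#' times and on dying within the study, and compares a discrepancy
#' statistic against the observed interval-midpoint failure times.
#' `"mean_failure_age"` compares the replicate mean failure time with the
#' observed mean; `"failure_age_difference"` uses the mean per-individual
#' difference between replicated and observed failure times (reference
#' value 0).  The Bayesian p-value is the fraction of draws whose
#' replicated statistic is at least the observed one; values near 0 or 1
#' signal misfit, interior values (e.g. 0.05--0.95) are unremarkable.
#'
#' @param fit An `eventfuse` fit.
#' @param statistic `"mean_failure_age"` or `"failure_age_difference"`.
#' @param ndraws Number of (thinned) posterior draws to use.
#' @return List with `p_value`, the observed statistic, and the replicate
#'   statistics.
#' @export
posterior_predictive_check <- function(fit,
                                       statistic = c("mean_failure_age",
                                                     "failure_age_difference"),
                                       ndraws = 200) {
  statistic <- match.arg(statistic)
  dead <- Filter(function(r) is.finite(r$first_dead), fit$data$radio)
  if (!length(dead))
    stop("posterior predictive check needs individuals with known deaths")
  obs <- vapply(dead, function(r) (r$last_alive + r$first_dead) / 2,
                numeric(1))
  m <- as.matrix(fit$samples)
  idx <- unique(round(seq(1, nrow(m), length.out = min(ndraws, nrow(m)))))
  end <- fit$schedule$study_end
  rep_stat <- vapply(idx, function(i) {
    bs <- build_spec_from(fit, m[i, ])
    sim <- vapply(dead, function(r) {
      dp <- interval_death_probs(bs$spec, r$entry, end)
      scl <- if (is.null(bs$effect)) 1
             else exp(linear_predictor(bs$effect, r$covariates))
      rate <- dp$rate * scl
      len <- dp$end - dp$start
      H <- rate * len
      sb <- exp(-cumsum(c(0, H[-length(H)])))
      q <- sb * -expm1(-H)
      k <- sample.int(length(q), 1L, prob = q)  # conditional on death in study
      u <- stats::runif(1)
      x <- if (H[k] < 1e-12) u * len[k]
           else -log1p(u * expm1(-H[k])) / rate[k]
      dp$start[k] + x
    }, numeric(1))
    switch(statistic,
           mean_failure_age = mean(sim),
           failure_age_difference = mean(sim - obs))
  }, numeric(1))
  obs_stat <- switch(statistic, mean_failure_age = mean(obs),
                     failure_age_difference = 0)
  list(p_value = mean(rep_stat >= obs_stat), observed = obs_stat,
       replicates = rep_stat, statistic = statistic)
}
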