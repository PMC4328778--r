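## Posterior samplers: adaptive componentwise random-walk Metropolis (the
## default) and a hit-and-run Metropolis variant (random direction, one-D
## step).  Adaptation of proposal scales runs during burn-in only, so the
## retained chain leaves the target invariant.

#' MCMC configuration
#'
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded (and used for step-size adaptation);
#'   default half of `n_iter`.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.  Identical
#'   configuration and data give bitwise-identical draws.
#' @param algorithm `"arwm"` (adaptive componentwise random-walk Metropolis)
#'   or `"harm"` (hit-and-run Metropolis).
#' @param target_accept Acceptance rate targeted by the adaptation
#'   (componentwise proposals mix well near 0.23--0.44; default 0.35).
#' @param step0 Initial proposal standard deviation (per component).
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 10000, burn_in = floor(n_iter / 2),
                         n_chains = 1, seed = 1,
                         algorithm = c("arwm", "harm"),
                         target_accept = 0.35, step0 = 0.5) {
  algorithm <- match.arg(algorithm)
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  if (n_chains < 1) stop("'n_chains' must be at least 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 algorithm = algorithm, target_accept = target_accept,
                 step0 = step0),
            class = "mcmc_control")
}

#' Run MCMC chains on a log-posterior
#'
#' Samples from an arbitrary log target density with the configured
#' Metropolis algorithm.  Proposal scales adapt towards
#' `control$target_accept` during burn-in (diminishing adaptation) and are
#' frozen afterwards, preserving detailed balance for the retained draws.
#' A chain whose post-adaptation acceptance rate collapses below 1e-3
#' triggers a warning rather than failing silently.
#'
#' @param log_post Function mapping a numeric parameter vector to a scalar
#'   log density (`-Inf` outside the support).
#' @param init Numeric vector of initial values, a `n_chains x n_par`
#'   matrix, or a function `function(chain)` returning a vector (for
#'   dispersed starting values).  `log_post` must be finite at every initial
#'   point.
#' @param control An [mcmc_control()].
#' @param param_names Optional parameter names.
#' @return An object of class `"ef_samples"`: post-burn-in draws in an array
#'   `[iteration, parameter, chain]`, log-posterior values, and acceptance
#'   rates.
#' @export
run_chains <- function(log_post, init, control = mcmc_control(),
                       param_names = NULL) {
  get_init <- function(chain) {
    th <- if (is.function(init)) init(chain)
          else if (is.matrix(init)) init[chain, ]
          else init
    as.numeric(th)
  }
  npar <- length(get_init(1L))
  if (is.null(param_names)) {
    nm <- names(if (is.function(init)) init(1L)
                else if (is.matrix(init)) init[1L, ] else init)
    param_names <- if (!is.null(nm)) nm else paste0("par", seq_len(npar))
  }
  n_keep <- control$n_iter - control$burn_in
  draws <- array(NA_real_, c(n_keep, npar, control$n_chains),
                 dimnames = list(NULL, param_names, NULL))
  lp_keep <- matrix(NA_real_, n_keep, control$n_chains)
  accept <- matrix(0, control$n_chains, npar)

  for (chain in seq_len(control$n_chains)) {
    set.seed(control$seed + chain - 1L)
    theta <- get_init(chain)
    ll <- log_post(theta)
    if (!is.finite(ll))
      stop("log_post not finite at the initial point of chain ", chain)
    log_step <- rep(log(control$step0), npar)
    acc_post <- n_post <- 0
    if (control$algorithm == "arwm") {
      acc_count <- numeric(npar)
      for (iter in seq_len(control$n_iter)) {
        adapting <- iter <= control$burn_in
        gam <- if (adapting) min(0.25, 2 / sqrt(iter)) else 0
        for (cmp in seq_len(npar)) {
          prop <- theta
          prop[cmp] <- prop[cmp] + exp(log_step[cmp]) * stats::rnorm(1)
          llp <- log_post(prop)
          acc <- is.finite(llp) && log(stats::runif(1)) < llp - ll
          if (acc) { theta <- prop; ll <- llp }
          if (adapting) {
            log_step[cmp] <- log_step[cmp] +
              gam * ((if (acc) 1 else 0) - control$target_accept)
          } else {
            acc_count[cmp] <- acc_count[cmp] + acc
          }
        }
        if (iter > control$burn_in) {
          k <- iter - control$burn_in
          draws[k, , chain] <- theta
          lp_keep[k, chain] <- ll
        }
      }
      accept[chain, ] <- acc_count / n_keep
    } else {  # hit-and-run: random direction, scalar Metropolis step
      for (iter in seq_len(control$n_iter)) {
        adapting <- iter <= control$burn_in
        gam <- if (adapting) min(0.25, 2 / sqrt(iter)) else 0
        d <- stats::rnorm(npar)
        d <- d / sqrt(sum(d^2))
        prop <- theta + exp(log_step[1]) * stats::rnorm(1) * d
        llp <- log_post(prop)
        acc <- is.finite(llp) && log(stats::runif(1)) < llp - ll
        if (acc) { theta <- prop; ll <- llp }
        if (adapting) {
          log_step[] <- log_step[1] +
            gam * ((if (acc) 1 else 0) - control$target_accept)
        } else {
          acc_post <- acc_post + acc; n_post <- n_post + 1
        }
        if (iter > control$burn_in) {
          k <- iter - control$burn_in
          draws[k, , chain] <- theta
          lp_keep[k, chain] <- ll
        }
      }
      accept[chain, ] <- acc_post / max(n_post, 1)
    }
    if (any(accept[chain, ] < 1e-3))
      warning("chain ", chain, ": acceptance rate below 1e-3 after ",
              "adaptation; the posterior may be poorly explored")
  }
  structure(list(draws = draws, lp = lp_keep, accept = accept,
                 control = control, param_names = param_names),
            class = "ef_samples")
}

#' @export
print.ef_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior samples: %d kept iterations x %d parameters x %d chain(s)\n",
              d[1], d[2], d[3]))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat(sprintf("  mean acceptance rate: %.2f\n", mean(x$accept)))
  invisible(x)
}

#' Pool draws across chains into a matrix
#'
#' @param x An `ef_samples` object.
#' @param ... Unused.
#' @return A matrix with one column per parameter, chains stacked.
#' @export
as.matrix.ef_samples <- function(x, ...) {
  d <- dim(x$draws)
  out <- do.call(rbind, lapply(seq_len(d[3]),
                               function(ch) matrix(x$draws[, , ch], ncol = d[2])))
  colnames(out) <- x$param_names
  out
}

## internal: construct an ef_samples object from a plain array
ef_samples_from_array <- function(draws, accept = NULL, control = NULL,
                                  lp = NULL) {
  if (length(dim(draws)) == 2L) draws <- array(draws, c(dim(draws), 1L),
                                               dimnames = c(dimnames(draws),
                                                            list(NULL)))
  structure(list(draws = draws, lp = lp,
                 accept = if (is.null(accept))
                   matrix(NA_real_, dim(draws)[3], dim(draws)[2]) else accept,
                 control = control,
                 param_names = dimnames(draws)[[2]]),
            class = "ef_samples")
}
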