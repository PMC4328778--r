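## Convergence diagnostics and posterior summaries: Geweke z, the corrected
## Brooks-Gelman-Rubin scale reduction factors, DIC, and batch-means Monte
## Carlo errors.  All diagnostics are pure functions of the draws.

## accept either raw samples or a fitted model
as_ef_samples <- function(x) {
  if (inherits(x, "eventfuse")) x$samples else x
}

## spectral density at frequency zero via a Bartlett lag window,
## window length 4 * sqrt(n / 100)
spectral0 <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0)
    stop("constant chain segment: spectral variance undefined")
  K <- max(1L, floor(4 * sqrt(n / 100)))
  K <- min(K, n - 1L)
  g <- stats::acf(v, lag.max = K, type = "covariance", plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  w <- 1 - seq_len(K) / (K + 1)
  s0 <- g[1] + 2 * sum(w * g[-1])
  max(s0, g[1] * 1e-8)
}

#' Geweke stationarity diagnostic
#'
#' Compares the mean of an early window of a single chain with the mean of a
#' late window, standardized by spectral-density-at-zero variance estimates
#' of each window; approximately standard normal when the chain is
#' stationary.
#'
#' @param samples An `ef_samples` object (first chain is used) or a numeric
#'   vector / one-column-per-parameter matrix of post-burn-in draws.
#' @param first_frac,last_frac Fractions of the chain used for the early and
#'   late windows (defaults 0.1 and 0.5).
#' @return Named vector of per-parameter z-scores.
#' @export
geweke_z <- function(samples, first_frac = 0.1, last_frac = 0.5) {
  samples <- as_ef_samples(samples)
  m <- if (inherits(samples, "ef_samples"))
    matrix(samples$draws[, , 1], ncol = dim(samples$draws)[2],
           dimnames = list(NULL, samples$param_names))
  else if (is.matrix(samples)) samples
  else matrix(samples, ncol = 1)
  n <- nrow(m)
  n1 <- floor(first_frac * n)
  n2 <- floor(last_frac * n)
  if (n1 < 10 || n2 < 10)
    stop("chain too short for the Geweke windows (need >= 10 draws each)")
  apply(m, 2, function(v) {
    a <- v[seq_len(n1)]
    b <- v[seq.int(n - n2 + 1L, n)]
    (mean(a) - mean(b)) / sqrt(spectral0(a) / n1 + spectral0(b) / n2)
  })
}

#' Brooks-Gelman-Rubin scale reduction factors
#'
#' Corrected potential scale reduction factor per parameter (including the
#' sampling-variability degrees-of-freedom correction) and the multivariate
#' scale reduction factor, from two or more chains of equal length.  Values
#' approach 1 as the chains mix over the same distribution.
#'
#' @param samples An `ef_samples` object with at least two chains.
#' @return List with `psrf` (named per-parameter factors) and `mpsrf`.
#' @export
psrf <- function(samples) {
  samples <- as_ef_samples(samples)
  stopifnot(inherits(samples, "ef_samples"))
  d <- dim(samples$draws)
  n <- d[1]; npar <- d[2]; m <- d[3]
  if (m < 2) stop("at least 2 chains are required for the BGR diagnostic")
  per_param <- vapply(seq_len(npar), function(j) {
    x <- matrix(samples$draws[, j, ], n, m)
    xbar_j <- colMeans(x)
    s2_j <- apply(x, 2, stats::var)
    W <- mean(s2_j)
    B <- n * stats::var(xbar_j)
    sig2 <- (n - 1) / n * W + B / n
    Vhat <- sig2 + B / (m * n)
    xbar <- mean(xbar_j)
    var_V <- ((n - 1) / n)^2 / m * stats::var(s2_j) +
      ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
      2 * (m + 1) * (n - 1) / (m * n^2) * (n / m) *
        (stats::cov(s2_j, xbar_j^2) - 2 * xbar * stats::cov(s2_j, xbar_j))
    df <- max(2 * Vhat^2 / max(var_V, .Machine$double.eps), 1e-8)
    sqrt((df + 3) / (df + 1) * Vhat / W)
  }, numeric(1))
  names(per_param) <- samples$param_names
  ## multivariate factor from the largest eigenvalue of W^{-1} B / n
  chains <- lapply(seq_len(m), function(ch) matrix(samples$draws[, , ch],
                                                   n, npar))
  Wm <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mu <- t(vapply(chains, colMeans, numeric(npar)))
  mu <- matrix(mu, m, npar)
  Bn <- stats::cov(mu)  # = B / n
  lam1 <- tryCatch(max(Re(eigen(solve(Wm, Bn), only.values = TRUE)$values)),
                   error = function(e) NA_real_)
  mpsrf <- sqrt((n - 1) / n + (m + 1) / m * lam1)
  list(psrf = per_param, mpsrf = mpsrf)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the deviance `-2 log L`, `pD = Dbar -
#' D(posterior mean)` the effective number of parameters, and
#' `DIC = Dbar + pD`.
#'
#' @param samples An `ef_samples` object.
#' @param loglik_fn Function mapping a parameter vector (in the sampled
#'   parameterization) to the data log-likelihood.
#' @param thin Evaluate the deviance on every `thin`-th pooled draw
#'   (default 1 = all draws).
#' @return List with `DIC`, `pD`, `Dbar` and `Dhat`.
#' @export
dic <- function(samples, loglik_fn, thin = 1) {
  samples <- as_ef_samples(samples)
  m <- as.matrix(samples)
  idx <- seq(1, nrow(m), by = thin)
  dev <- vapply(idx, function(i) -2 * loglik_fn(m[i, ]), numeric(1))
  if (any(!is.finite(dev)))
    stop("nonfinite deviance at ", sum(!is.finite(dev)), " draw(s)")
  Dbar <- mean(dev)
  theta_bar <- colMeans(m)
  Dhat <- -2 * loglik_fn(theta_bar)
  if (!is.finite(Dhat)) {
    stop("nonfinite deviance at the posterior mean (parameters: ",
         paste(samples$param_names, collapse = ", "), ")")
  }
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior summary table
#'
#' Mean, standard deviation, batch-means Monte Carlo error, and the 0.025,
#' 0.5 and 0.975 quantiles of each parameter, pooled over chains.
#'
#' @param samples An `ef_samples` object (or a draws matrix).
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(samples) {
  samples <- as_ef_samples(samples)
  m <- if (inherits(samples, "ef_samples")) as.matrix(samples)
       else as.matrix(samples)
  nch <- if (inherits(samples, "ef_samples")) dim(samples$draws)[3] else 1L
  n <- nrow(m) / nch
  mc_err <- apply(m, 2, function(v) {
    per_chain <- vapply(seq_len(nch), function(ch) {
      x <- v[seq.int((ch - 1) * n + 1, ch * n)]
      b <- max(1L, floor(sqrt(length(x))))
      nb <- floor(length(x) / b)
      bm <- colMeans(matrix(x[seq_len(nb * b)], b, nb))
      if (nb < 2) return(NA_real_)
      stats::var(bm) / nb
    }, numeric(1))
    sqrt(mean(per_chain) / nch)
  })
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  data.frame(mean = colMeans(m), sd = apply(m, 2, stats::sd),
             mc_error = mc_err,
             q025 = qs[, 1], q500 = qs[, 2], q975 = qs[, 3],
             row.names = colnames(m))
}
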