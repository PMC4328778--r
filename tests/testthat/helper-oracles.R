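## Independent oracles used across the suite.  These deliberately use
## different mechanisms from the package internals: adaptive quadrature for
## integrals, exhaustive enumeration for detection histories, dense
## generalized-inverse linear algebra for the random-walk prior, and grid
## search / grid integration for posterior quantities.

## adaptive-quadrature cumulative hazard; 'breaks' marks known rate
## discontinuities so each smooth piece is integrated separately
quad_cumhaz <- function(spec, t0, t1, effect = NULL, covariates = NULL,
                        breaks = NULL) {
  if (t1 == t0) return(0)
  pts <- sort(unique(c(t0, t1, breaks[breaks > t0 & breaks < t1])))
  sum(vapply(seq_len(length(pts) - 1), function(i)
    stats::integrate(function(u) hazard_at(spec, u, effect, covariates),
                     pts[i], pts[i + 1], subdivisions = 2000L,
                     rel.tol = 1e-12, abs.tol = 1e-13)$value, numeric(1)))
}

## every observable detection history of one marked animal on a short
## schedule, with its likelihood; conservation requires the sum to be 1
enumerate_marked_histories <- function(spec, p, schedule, entry,
                                       covariates = NULL, effect = NULL) {
  st <- schedule$stimes[schedule$stimes > entry]
  m <- length(st)
  hists <- as.matrix(expand.grid(rep(list(0:1), m)))
  lik <- apply(hists, 1, function(h) {
    nn <- sum(h)
    last_seen <- if (nn > 0) st[max(which(h == 1))] else NA
    rec <- mark_record(entry, last_seen = last_seen, history = h,
                       covariates = covariates)
    exp(loglik_marked(rec, spec, p, schedule, effect))
  })
  list(histories = hists, lik = lik, total = sum(lik))
}

## fine-grid discrete-time likelihood of a right-censored marked record:
## sum over death bins (and the survive-past-study outcome) of
## P(death in bin) * P(observed detection history | death time)
discrete_marked_lik <- function(rec, spec, p, schedule, h = 0.05) {
  stopifnot(!is.finite(rec$first_dead))
  st <- schedule$stimes[schedule$stimes > rec$entry]
  hist <- rec$history
  stopifnot(length(hist) == length(st))
  bins <- seq(rec$entry, schedule$study_end, by = h)
  if (bins[length(bins)] < schedule$study_end)
    bins <- c(bins, schedule$study_end)
  S <- vapply(bins, function(t)
    exp(-quad_cumhaz(spec, rec$entry, t, covariates = rec$covariates)),
    numeric(1))
  det_prob_given_death <- function(death) {
    ## surveys the animal was alive for (strictly before death)
    avail <- st < death
    if (any(hist == 1 & !avail)) return(0)
    prod(ifelse(avail, ifelse(hist == 1, p, 1 - p), 1))
  }
  tot <- 0
  for (b in seq_len(length(bins) - 1)) {
    pd <- S[b] - S[b + 1]
    mid <- (bins[b] + bins[b + 1]) / 2
    tot <- tot + pd * det_prob_given_death(mid)
  }
  ## survived past the study end
  tot + S[length(S)] * det_prob_given_death(Inf)
}

## dense oracle for the intrinsic RW1 log density on the sum-to-zero
## subspace: age | tau ~ N(0, generalized inverse of R / tau^2) with the
## RW1 structure matrix R (diag 1, 2, ..., 2, 1; off-diagonals -1)
dense_rw1_logdens <- function(age, tau) {
  k <- length(age)
  R <- diag(c(1, rep(2, k - 2), 1))
  for (i in seq_len(k - 1)) R[i, i + 1] <- R[i + 1, i] <- -1
  Q <- R / tau^2
  ev <- eigen(Q, symmetric = TRUE)
  pos <- ev$values > 1e-10
  ## log density wrt Lebesgue measure on the (k-1)-dim subspace
  -0.5 * (k - 1) * log(2 * pi) + 0.5 * sum(log(ev$values[pos])) -
    0.5 * drop(t(age) %*% Q %*% age)
}

## 1-D grid search for the posterior mode / MLE of a single log-rate
grid_opt_1d <- function(f, lo, hi, n = 4001) {
  x <- seq(lo, hi, length.out = n)
  y <- vapply(x, f, numeric(1))
  x[which.max(y)]
}

## small deterministic toy dataset on a weekly grid
toy_dataset <- function() {
  sched <- survey_schedule(c(7, 14, 21, 28), study_end = 28)
  radio <- list(radio_record(0, 14, 21), radio_record(3, 28),
                radio_record(0, 7, 14))
  marked <- list(
    mark_record(0, last_seen = 14, history = c(1, 1, 0, 0)),
    mark_record(7, last_seen = NA, history = c(0, 0, 0)),
    mark_record(0, last_seen = 21, history = c(0, 1, 1, 0)))
  list(data = event_data(radio, marked), schedule = sched)
}
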