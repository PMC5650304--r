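# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: naive double loops, explicit product limits,
# brute-force grids.

make_surv <- function(time, event, ids = NULL, endpoint = "survival") {
  ids <- ids %||% sprintf("s%02d", seq_along(time))
  survsig::survival_table(ids, time, event, endpoint = endpoint)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive Cox partial log-likelihood: explicit loop over event times with
# Efron or Breslow tie handling.
naive_partial_loglik <- function(beta, x, time, event, ties = "efron") {
  x <- as.matrix(x)
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t0 & event == 1)
    risk <- which(time >= t0)
    d <- length(d_idx)
    ll <- ll + sum(eta[d_idx])
    if (ties == "breslow" || d == 1) {
      ll <- ll - d * log(sum(exp(eta[risk])))
    } else {
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sum(exp(eta[risk])) - (l / d) * sum(exp(eta[d_idx])))
      }
    }
  }
  ll
}

# Brute-force maximizer of the single-covariate partial likelihood over a
# beta grid (Breslow; callers supply untied event times, where Breslow and
# Efron coincide).
grid_cox_beta <- function(x, time, event, lo = -10, hi = 10, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  E <- exp(outer(x, grid))
  ll <- numeric(length(grid))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * grid - log(colSums(E[risk, , drop = FALSE]))
  }
  grid[which.max(ll)]
}

# Explicit product-limit curve: survival at each unique event time.
naive_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Two-group log-rank chi-square via direct O-E summation over event times.
naive_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  oe <- 0; v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    atrisk <- time >= t0
    n <- sum(atrisk); n1 <- sum(atrisk & group == 1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Binary AUC by exhaustive pair counting (ties get half credit).
pair_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
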