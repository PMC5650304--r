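# Cox partial-likelihood machinery, Kaplan-Meier estimation, log-rank
# testing and time-dependent ROC.  Fitting is delegated to the survival
# package's C engine (coxph.fit); held-out evaluation of the partial
# log-likelihood at frozen coefficients — the quantity the forward-selection
# procedure ranks genes by — is computed directly here.

#' Cox partial log-likelihood at fixed coefficients
#'
#' Direct evaluation of the partial log-likelihood
#' `sum over events of [eta_i - log(sum over risk set of exp(eta_j))]`
#' at a given coefficient vector, with Efron or Breslow handling of tied
#' event times.  No fitting is performed.  With no observed events the
#' partial likelihood is an empty product and 0 is returned.
#'
#' @param beta Coefficient vector (length = number of covariate columns).
#' @param x Covariate matrix, samples in rows.
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return The partial log-likelihood (a scalar, <= 0 when events exist and
#'   covariates are finite).
#' @export
partial_loglik <- function(beta, x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  stopifnot(length(beta) == ncol(x), nrow(x) == length(time),
            length(time) == length(event))
  if (sum(event) == 0) return(0)
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)  # invariant shift for numerical stability
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; eta <- eta[ord]
  r <- exp(eta)
  risk_cum <- rev(cumsum(rev(r)))  # sum of r over {j : time_j >= time_i}
  ll <- 0
  for (t0 in unique(time[event == 1])) {
    first <- match(t0, time)
    d_idx <- which(time == t0 & event == 1)
    d <- length(d_idx)
    ll <- ll + sum(eta[d_idx])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(risk_cum[first])
    } else {
      sd_ <- sum(r[d_idx])
      ll <- ll - sum(log(risk_cum[first] - (seq_len(d) - 1) / d * sd_))
    }
  }
  ll
}

# Low-overhead Cox fit used in resampling loops: returns list(coef, loglik,
# var, converged) or NULL when the fit is degenerate.  Coefficients of
# monotone-separation (divergent) fits are capped at |beta| <= cap and the
# log-likelihood re-evaluated at the capped value.
cox_fit_ <- function(x, time, event, ties = "efron", cap = 15) {
  storage.mode(x) <- "double"
  n <- nrow(x)
  fit <- tryCatch(suppressWarnings(
    survival::coxph.fit(x, survival::Surv(time, event), strata = NULL,
                        offset = NULL, init = NULL,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100),
                        weights = NULL, method = ties,
                        rownames = as.character(seq_len(n)))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
  beta <- fit$coefficients
  converged <- is.null(fit$fail) && all(abs(beta) <= cap)
  if (any(abs(beta) > cap)) {
    beta <- pmin(pmax(beta, -cap), cap)
    ll <- partial_loglik(beta, x, time, event, ties)
  } else {
    ll <- fit$loglik[2]
  }
  list(coef = beta, loglik = ll, loglik_null = fit$loglik[1],
       var = fit$var, converged = converged)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood by Newton iteration (the survival
#' package's fitting engine) with the chosen treatment of tied event times.
#' Fits with monotone likelihood (complete separation of a covariate, under
#' which the coefficient diverges) are not errors: the coefficient is capped
#' at `|beta| <= 15`, the log-likelihood re-evaluated there, and the fit
#' flagged as non-converged — so screening thousands of genes never aborts.
#'
#' @param x Covariate matrix (samples x covariates) or a single numeric
#'   vector; column names become covariate ids.
#' @param survival A [survival_table()] (or data frame with `time`/`event`),
#'   rows aligned with `x`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `"cox_fit"`: `ids`, `coef`, `se`, `p`
#'   (Wald), `loglik` (maximized partial log-likelihood), `loglik_null`,
#'   `converged`, `n`, `n_event`, `ties`.
#' @export
fit_cox <- function(x, survival, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  time <- survival$time; event <- survival$event
  if (nrow(x) != length(time)) stop_("covariates and survival rows differ")
  if (sum(event) < 1) stop_("no observed events: cannot fit a Cox model")
  const <- apply(x, 2, function(v) max(v) == min(v))
  if (any(const)) {
    stop_("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  }
  fit <- cox_fit_(x, time, event, ties)
  if (is.null(fit)) stop_("Cox fit failed (degenerate inputs)")
  se <- sqrt(pmax(diag(as.matrix(fit$var)), 0))
  p <- 2 * stats::pnorm(-abs(fit$coef / se))
  p[!is.finite(p)] <- 1
  structure(list(ids = colnames(x), coef = stats::setNames(fit$coef, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 p = stats::setNames(p, colnames(x)),
                 loglik = fit$loglik, loglik_null = fit$loglik_null,
                 converged = fit$converged, n = nrow(x),
                 n_event = sum(event), ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  print(data.frame(coef = x$coef, se = x$se, p = signif(x$p, 3)))
  cat("partial log-likelihood:", format(x$loglik),
      if (!x$converged) " (capped: monotone likelihood)" else "", "\n")
  invisible(x)
}

#' Held-out partial log-likelihood of a frozen fit
#'
#' Evaluates the Cox partial log-likelihood of new data at the coefficients
#' of an existing fit, without refitting — the validation-set score that
#' drives robust likelihood-based forward selection.  A held-out set with
#' zero events has an empty risk-set sum; 0 is returned with a warning.
#'
#' @param fit A [fit_cox()] result.
#' @param x Covariate matrix for the held-out samples; columns must include
#'   the fit's covariate ids (matched by name).
#' @param survival Held-out [survival_table()] aligned with `x`.
#' @return The held-out partial log-likelihood.
#' @export
heldout_loglik <- function(fit, x, survival) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, fit$ids))
  miss <- setdiff(fit$ids, colnames(x))
  if (length(miss) > 0) stop_("held-out data lacks covariate(s): ",
                              paste(miss, collapse = ", "))
  x <- as.matrix(x)[, fit$ids, drop = FALSE]
  if (sum(survival$event) == 0) {
    warning("held-out set has no events; partial log-likelihood is 0")
    return(0)
  }
  partial_loglik(fit$coef, x, survival$time, survival$event, fit$ties)
}

#' Akaike information criterion for a fitted gene model
#'
#' `AIC = 2 * nloglik + 2 * n_genes`: the Cox model has no intercept, so
#' the parameter count equals the number of genes in the model.
#'
#' @param nloglik Negative maximized partial log-likelihood.
#' @param n_genes Number of genes (coefficients) in the model.
#' @return The AIC (smaller is better).
#' @export
compute_aic <- function(nloglik, n_genes) {
  stopifnot(is.numeric(nloglik), n_genes >= 0)
  2 * nloglik + 2 * n_genes
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with the standard
#' convention that censoring at an event time is processed after the event.
#'
#' @param survival A [survival_table()].
#' @return An object of class `"km_curve"`: `time` (unique observed times),
#'   `surv`, `n_risk`, `n_event`, `n_censor`, plus the endpoint/unit labels.
#' @export
km_curve <- function(survival) {
  if (nrow(survival) == 0) stop_("empty survival table")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(survival))
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n_censor = sf$n.censor,
                 endpoint = attr(survival, "endpoint"),
                 unit = attr(survival, "unit")),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve (", x$endpoint %||% "survival", ", ",
      x$unit %||% "?", "): ", sum(x$n_event), " events over ",
      length(x$time), " time points\n", sep = "")
  invisible(x)
}

#' Log-rank test of survival differences between groups
#'
#' The standard k-group log-rank chi-square: observed minus expected event
#' counts per group accumulated over event times, with hypergeometric
#' variance, referred to a chi-square distribution with k - 1 degrees of
#' freedom.
#'
#' @param survival A [survival_table()].
#' @param groups Group label per sample (factor or vector), aligned with
#'   the table's rows.  Every group must be non-empty.
#' @return An object of class `"logrank_test"`: `chisq`, `df`, `p`,
#'   `observed` and `expected` per group, `n` per group.
#' @export
logrank_test <- function(survival, groups) {
  groups <- factor(groups)
  if (length(groups) != nrow(survival)) stop_("groups and survival rows differ")
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop_("need >= 2 non-empty groups")
  }
  if (sum(survival$event) < 1) stop_("no observed events")
  d <- data.frame(time = survival$time, event = survival$event, g = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- nlevels(groups) - 1L
  structure(list(chisq = sd_$chisq, df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 observed = stats::setNames(sd_$obs, levels(groups)),
                 expected = stats::setNames(sd_$exp, levels(groups)),
                 n = stats::setNames(as.integer(table(groups)), levels(groups))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chisq = ", format(x$chisq), " on ", x$df,
      " df, p = ", format(x$p), "\n", sep = "")
  print(data.frame(n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)))
  invisible(x)
}

# Kaplan-Meier survival probability at t0 within a subgroup; carries the
# last value beyond the last observed time.
km_surv_at_ <- function(time, event, t0) {
  s <- 1
  for (t1 in sort(unique(time[event == 1 & time <= t0]))) {
    s <- s * (1 - sum(time == t1 & event == 1) / sum(time >= t1))
  }
  s
}

#' Time-dependent ROC AUC for a survival risk score
#'
#' Cumulative-case / dynamic-control time-dependent ROC at a horizon `t`:
#' cases are samples with an event by `t`, controls are samples surviving
#' beyond `t`, and both rates are estimated with Kaplan-Meier weights
#' (the survivalROC "KM" estimator): for each score cutoff `c`,
#' `TPR(c) = (1 - S(t | score > c)) * P(score > c) / (1 - S(t))` and
#' `FPR(c) = S(t | score > c) * P(score > c) / S(t)`, with `S` the
#' product-limit estimate.  The AUC is the trapezoidal area under the
#' resulting curve.  Without censoring this reduces to the ordinary binary
#' AUC of the score against event-by-horizon status.
#'
#' @param score Numeric risk score per sample (higher = riskier).
#' @param survival A [survival_table()] aligned with `score`.
#' @param horizon Evaluation time; must lie within the observed time range
#'   and admit at least one case and one control.
#' @return The AUC in `[0, 1]`.
#' @export
td_roc_auc <- function(score, survival, horizon) {
  time <- survival$time; event <- survival$event
  stopifnot(length(score) == length(time))
  if (any(!is.finite(score))) stop_("scores must be finite")
  if (horizon < min(time) || horizon > max(time)) {
    stop_("horizon outside the observed time range")
  }
  if (sum(event == 1 & time <= horizon) == 0) stop_("no cases by the horizon")
  if (sum(time > horizon) == 0) stop_("no controls beyond the horizon")
  s_all <- km_surv_at_(time, event, horizon)
  if (s_all >= 1 || s_all <= 0) stop_("degenerate case/control split at the horizon")
  cuts <- sort(unique(score))
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    sel <- score > cuts[i]
    p_c <- mean(sel)
    s_c <- if (any(sel)) km_surv_at_(time[sel], event[sel], horizon) else 1
    tpr[i] <- (1 - s_c) * p_c / (1 - s_all)
    fpr[i] <- s_c * p_c / s_all
  }
  xx <- c(1, fpr, 0); yy <- c(1, tpr, 0)
  xx <- pmin(pmax(xx, 0), 1); yy <- pmin(pmax(yy, 0), 1)
  ord <- order(xx, yy)
  xx <- xx[ord]; yy <- yy[ord]
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}
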