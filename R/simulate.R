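# Synthetic survival cohorts with a planted prognostic signature.
#
# The generator emulates the kind of discovery cohort the pipeline is built
# for: a few hundred tumour samples, thousands of log-scale expression
# values, a small signature of positively and negatively acting genes whose
# standardized expression drives a proportional-hazards model, and two
# right-censored endpoints (survival and recurrence) over the same linear
# predictor.

#' Configuration for [simulate_cohort()]
#'
#' Defaults emulate a 432-sample discovery cohort with a 9-gene signature of
#' 7 positive- and 2 negative-impact genes, each with log-hazard effect 0.8
#' per standard deviation of expression, an exponential baseline hazard of
#' 0.02 events per month, and uniform censoring calibrated so that roughly
#' 65% of follow-up is censored.
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes (background genes carry no effect).
#' @param n_signature Planted signature size.
#' @param n_positive,n_negative Signature genes with adverse high / adverse
#'   low expression; must sum to `n_signature`.
#' @param beta Log-hazard effect per signature gene (scalar or length
#'   `n_signature`), applied to standardized expression; must be >= 0 (the
#'   direction comes from the sign).
#' @param baseline_hazard Exponential baseline event rate (per time unit)
#'   for the survival endpoint.
#' @param baseline_hazard_recurrence Baseline rate for the recurrence
#'   endpoint (same linear predictor, independent draw).
#' @param censoring_target Target fraction of censored samples, in `[0, 1)`.
#'   Censoring times are uniform on `(0, c_max)` with `c_max` calibrated
#'   numerically against the cohort's realized linear predictors.
#' @param baseline_shape Weibull shape of the baseline hazard; 1 (default)
#'   gives the exponential model.
#' @param mean_range,sd_range Per-gene background mean and standard
#'   deviation are drawn uniformly from these intervals (log-scale units).
#' @param signature_correlation Optional equicorrelation among signature
#'   genes (default 0, i.e. independent genes).
#' @param probes_per_gene When > 1, a probe-level matrix is also generated
#'   (each probe = gene profile + independent noise) together with a probe
#'   map, to exercise probe collapsing.
#' @param probe_noise_sd Standard deviation of per-probe noise.
#' @param seed RNG seed; with a fixed seed the cohort is bit-reproducible.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples = 432L, n_genes = 2000L,
                              n_signature = 9L, n_positive = 7L,
                              n_negative = 2L, beta = 0.8,
                              baseline_hazard = 0.02,
                              baseline_hazard_recurrence = 0.03,
                              censoring_target = 0.65,
                              baseline_shape = 1,
                              mean_range = c(5, 10), sd_range = c(0.6, 1.4),
                              signature_correlation = 0,
                              probes_per_gene = 1L, probe_noise_sd = 0.25,
                              seed = NULL) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_signature = as.integer(n_signature),
              n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              beta = as.numeric(beta),
              baseline_hazard = baseline_hazard,
              baseline_hazard_recurrence = baseline_hazard_recurrence,
              censoring_target = censoring_target,
              baseline_shape = baseline_shape,
              mean_range = mean_range, sd_range = sd_range,
              signature_correlation = signature_correlation,
              probes_per_gene = as.integer(probes_per_gene),
              probe_noise_sd = probe_noise_sd, seed = seed)
  if (cfg$n_positive + cfg$n_negative != cfg$n_signature) {
    stop_("n_positive + n_negative must equal n_signature")
  }
  if (cfg$n_signature > cfg$n_genes) stop_("n_signature must be <= n_genes")
  if (any(cfg$beta < 0)) stop_("beta must be >= 0 (direction is carried by the sign)")
  if (!length(cfg$beta) %in% c(1L, cfg$n_signature)) {
    stop_("beta must be scalar or one value per signature gene")
  }
  if (cfg$baseline_hazard <= 0 || cfg$baseline_hazard_recurrence <= 0) {
    stop_("baseline hazards must be > 0")
  }
  if (cfg$censoring_target < 0 || cfg$censoring_target >= 1) {
    stop_("censoring_target must be in [0, 1)")
  }
  if (cfg$n_samples < 2 || cfg$n_genes < 1) stop_("cohort must have >= 2 samples, >= 1 gene")
  class(cfg) <- "simulation_config"
  cfg
}

# Calibrate the upper bound of uniform censoring so that the expected
# censored fraction, given the realized per-sample rates, hits the target.
# P(censored | rate r) under C ~ U(0, m) is (1 - exp(-r m)) / (r m) for the
# exponential model; for Weibull shape a the integral is taken numerically.
calibrate_censoring_ <- function(rates, target, shape = 1) {
  if (target <= 0) return(Inf)
  cens_frac <- function(m) {
    if (shape == 1) {
      mean((1 - exp(-rates * m)) / (rates * m))
    } else {
      # P(T > c) = exp(-(r c)^a); average survival of T over C ~ U(0, m)
      mean(vapply(rates, function(r) {
        stats::integrate(function(u) exp(-(r * u)^shape), 0, m)$value / m
      }, numeric(1)))
    }
  }
  hi <- 1
  while (cens_frac(hi) > target && hi < 1e12) hi <- hi * 2
  stats::uniroot(function(m) cens_frac(m) - target, c(1e-9, hi),
                 tol = 1e-8)$root
}

draw_endpoint_ <- function(eta, rate, target, shape) {
  n <- length(eta)
  # proportional hazards on the baseline: h(t) = shape * r^shape * t^(shape-1)
  # with per-sample scale r = rate * exp(eta / shape); shape 1 = exponential.
  r <- rate * exp(eta / shape)
  if (shape == 1) {
    t_event <- stats::rexp(n, rate = r)
  } else {
    t_event <- (-log(stats::runif(n)))^(1 / shape) / r
  }
  cmax <- calibrate_censoring_(r, target, shape)
  cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

#' Simulate an expression + survival cohort with a planted signature
#'
#' Each gene's expression is Normal with its own mean and standard deviation
#' (independent across genes unless a signature correlation is requested).
#' The per-sample log-hazard is `sum(sign_g * beta_g * z_g)` over signature
#' genes, where `z_g` is the gene's expression standardized by its true mean
#' and sd.  Event times follow the configured baseline hazard scaled by
#' `exp(log-hazard)`; censoring times are drawn independently and the
#' observed time is the minimum.  The recurrence endpoint reuses the same
#' linear predictor with its own baseline rate and censoring draw.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_cohort"` with elements `expression`
#'   (gene x sample matrix), `survival` and `recurrence` ([survival_table()]
#'   objects in months), `truth` (planted gene ids, signs, betas, and the
#'   per-sample linear predictor), `config`, and — when `probes_per_gene > 1`
#'   — `probe_expression` and `probe_map`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples; g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  sample_ids <- sprintf("S%04d", seq_len(n))

  mu <- stats::runif(g, config$mean_range[1], config$mean_range[2])
  sd_g <- stats::runif(g, config$sd_range[1], config$sd_range[2])

  z <- matrix(stats::rnorm(g * n), nrow = g)
  sig_idx <- sort(sample.int(g, config$n_signature))
  rho <- config$signature_correlation
  if (rho > 0 && config$n_signature > 1) {
    shared <- stats::rnorm(n)
    z[sig_idx, ] <- sqrt(rho) * matrix(shared, nrow = config$n_signature,
                                       ncol = n, byrow = TRUE) +
      sqrt(1 - rho) * z[sig_idx, ]
  }
  expr <- z * sd_g + mu
  dimnames(expr) <- list(gene_ids, sample_ids)

  signs <- sample(c(rep(1L, config$n_positive), rep(-1L, config$n_negative)))
  betas <- rep(config$beta, length.out = config$n_signature)
  eta <- drop(crossprod(z[sig_idx, , drop = FALSE], signs * betas))

  sv <- draw_endpoint_(eta, config$baseline_hazard, config$censoring_target,
                       config$baseline_shape)
  rc <- draw_endpoint_(eta, config$baseline_hazard_recurrence,
                       config$censoring_target, config$baseline_shape)

  out <- list(
    expression = expr,
    survival = survival_table(sample_ids, sv$time, sv$event,
                              endpoint = "survival", unit = "months"),
    recurrence = survival_table(sample_ids, rc$time, rc$event,
                                endpoint = "recurrence", unit = "months"),
    truth = list(genes = gene_ids[sig_idx],
                 signs = stats::setNames(signs, gene_ids[sig_idx]),
                 betas = stats::setNames(betas, gene_ids[sig_idx]),
                 linear_predictor = stats::setNames(eta, sample_ids)),
    gene_means = stats::setNames(mu, gene_ids),
    gene_sds = stats::setNames(sd_g, gene_ids),
    config = config
  )

  if (config$probes_per_gene > 1L) {
    k <- config$probes_per_gene
    probe_ids <- as.vector(t(outer(gene_ids, seq_len(k),
                                   function(a, b) paste0(a, "_p", b))))
    pm <- expr[rep(seq_len(g), each = k), , drop = FALSE] +
      matrix(stats::rnorm(g * k * n, sd = config$probe_noise_sd), nrow = g * k)
    dimnames(pm) <- list(probe_ids, sample_ids)
    out$probe_expression <- pm
    out$probe_map <- data.frame(probe_id = probe_ids,
                                gene_symbol = rep(gene_ids, each = k),
                                stringsAsFactors = FALSE)
  }
  class(out) <- "synthetic_cohort"
  out
}

#' Draw an independent cohort from an existing cohort's generative truth
#'
#' Re-draws a fresh sample of patients under the discovery cohort's frozen
#' generative model: same gene identities, per-gene means and standard
#' deviations, same planted signature (genes, signs, betas) and the same
#' baseline hazards and censoring target.  This is the synthetic analogue
#' of an independent validation cohort.  `beta_scale = 0` removes the
#' planted signal entirely, giving a pure-noise cohort for calibration
#' checks; intermediate values attenuate it (as a weaker replication
#' cohort would).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_samples Validation cohort size (default: same as discovery).
#' @param seed RNG seed for the new draw.
#' @param beta_scale Multiplier on the planted effect sizes (default 1).
#' @return A `synthetic_cohort` whose sample ids are prefixed `"V"`.
#' @export
simulate_validation_cohort <- function(cohort, n_samples = NULL, seed = NULL,
                                       beta_scale = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  n <- as.integer(n_samples %||% cfg$n_samples)
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- names(cohort$gene_means)
  g <- length(gene_ids)
  sample_ids <- sprintf("V%04d", seq_len(n))
  z <- matrix(stats::rnorm(g * n), nrow = g)
  sig_idx <- match(cohort$truth$genes, gene_ids)
  rho <- cfg$signature_correlation
  if (rho > 0 && length(sig_idx) > 1) {
    shared <- stats::rnorm(n)
    z[sig_idx, ] <- sqrt(rho) * matrix(shared, nrow = length(sig_idx),
                                       ncol = n, byrow = TRUE) +
      sqrt(1 - rho) * z[sig_idx, ]
  }
  expr <- z * cohort$gene_sds + cohort$gene_means
  dimnames(expr) <- list(gene_ids, sample_ids)
  eta <- drop(crossprod(z[sig_idx, , drop = FALSE],
                        cohort$truth$signs * cohort$truth$betas * beta_scale))
  sv <- draw_endpoint_(eta, cfg$baseline_hazard, cfg$censoring_target,
                       cfg$baseline_shape)
  rc <- draw_endpoint_(eta, cfg$baseline_hazard_recurrence,
                       cfg$censoring_target, cfg$baseline_shape)
  out <- list(
    expression = expr,
    survival = survival_table(sample_ids, sv$time, sv$event,
                              endpoint = "survival", unit = "months"),
    recurrence = survival_table(sample_ids, rc$time, rc$event,
                                endpoint = "recurrence", unit = "months"),
    truth = list(genes = cohort$truth$genes,
                 signs = cohort$truth$signs,
                 betas = cohort$truth$betas * beta_scale,
                 linear_predictor = stats::setNames(eta, sample_ids)),
    gene_means = cohort$gene_means,
    gene_sds = cohort$gene_sds,
    config = cfg
  )
  class(out) <- "synthetic_cohort"
  out
}

#' Fraction of censored follow-up in a cohort or survival table
#'
#' @param x A `synthetic_cohort` or a [survival_table()].
#' @return For a survival table, the censored fraction; for a cohort, a
#'   named vector with one entry per endpoint.
#' @export
empirical_censoring_rate <- function(x) {
  if (inherits(x, "survival_table")) {
    if (nrow(x) == 0) stop_("empty survival table")
    return(mean(x$event == 0))
  }
  if (inherits(x, "synthetic_cohort")) {
    return(c(survival = mean(x$survival$event == 0),
             recurrence = mean(x$recurrence$event == 0)))
  }
  stop_("x must be a survival_table or synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$expression), "samples x",
      nrow(x$expression), "genes\n")
  cat("  planted signature:", length(x$truth$genes), "genes (",
      sum(x$truth$signs > 0), "positive /", sum(x$truth$signs < 0),
      "negative ), beta =", paste(unique(x$truth$betas), collapse = ", "), "\n")
  cr <- empirical_censoring_rate(x)
  cat(sprintf("  censoring: survival %.2f, recurrence %.2f\n", cr[1], cr[2]))
  invisible(x)
}
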