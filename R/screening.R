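# Candidate-gene screening (expression filter + univariate Cox) and robust
# likelihood-based forward selection with subsample stability counting.
#
# Forward selection ranks candidate genes by their mean held-out partial
# log-likelihood over random train/validation partitions, appends the best
# gene, and records the full-cohort negative log-likelihood and AIC of the
# growing model; the selected model is the prefix minimizing AIC.  The
# stability layer repeats the whole selection on random subsamples and
# keeps the most frequent gene combination.

#' Filter dim and flat genes
#'
#' Keeps genes whose expression is both reasonably high and reasonably
#' variable: row median above `median_fraction` times the cohort reference
#' median (the median of per-gene medians), and row variance above
#' `variance_fraction` times the reference variance (the median of per-gene
#' variances).  Both reference statistics are computed once on the input
#' matrix.
#'
#' @param expression Genes x samples matrix.
#' @param median_fraction,variance_fraction Fractions in (0, 1); default
#'   0.20 each.
#' @param reference `"median"` (default) or `"mean"`: the summary used for
#'   the cohort reference level of the per-gene medians and variances.
#' @return The filtered matrix, with attribute `"filter"` recording the
#'   thresholds applied.
#' @export
expression_filter <- function(expression, median_fraction = 0.20,
                              variance_fraction = 0.20,
                              reference = c("median", "mean")) {
  reference <- match.arg(reference)
  check_expression(expression)
  if (ncol(expression) < 2) stop_("need >= 2 samples to assess variance")
  if (median_fraction <= 0 || median_fraction >= 1 ||
      variance_fraction <= 0 || variance_fraction >= 1) {
    stop_("filter fractions must lie in (0, 1)")
  }
  med <- apply(expression, 1, stats::median)
  v <- apply(expression, 1, stats::var)
  ref <- if (reference == "median") stats::median else mean
  med_thr <- median_fraction * ref(med)
  var_thr <- variance_fraction * ref(v)
  keep <- med > med_thr & v > var_thr
  if (!any(keep)) stop_("expression filter removed every gene")
  out <- expression[keep, , drop = FALSE]
  attr(out, "filter") <- list(median_threshold = med_thr,
                              variance_threshold = var_thr,
                              n_removed = sum(!keep))
  out
}

#' Univariate Cox screen for seed genes
#'
#' Fits one single-gene Cox model per gene and flags genes with Wald
#' p < `alpha` as seed genes for forward selection.  Degenerate genes
#' (constant expression) and divergent monotone-likelihood fits are flagged
#' and assigned p = 1 rather than aborting the screen.
#'
#' @param expression Genes x samples matrix (normally the
#'   [expression_filter()] output).
#' @param survival A [survival_table()] covering the matrix's samples.
#' @param alpha Seed-gene significance threshold (default 0.05).
#' @param ties Ties method passed to the Cox fits.
#' @return A `data.frame` of class `"screen_table"`, sorted by ascending p:
#'   columns `gene`, `coef`, `se`, `p`, `seed`, `flagged`.
#' @export
univariate_screen <- function(expression, survival, alpha = 0.05,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_expression(expression)
  survival <- align_survival(expression, survival)
  if (sum(survival$event) < 1) stop_("no observed events")
  time <- survival$time; event <- survival$event
  res <- lapply(rownames(expression), function(g) {
    x <- expression[g, ]
    if (max(x) == min(x)) {
      return(data.frame(gene = g, coef = NA_real_, se = NA_real_, p = 1,
                        flagged = TRUE))
    }
    fit <- cox_fit_(matrix(x, ncol = 1), time, event, ties)
    if (is.null(fit)) {
      return(data.frame(gene = g, coef = NA_real_, se = NA_real_, p = 1,
                        flagged = TRUE))
    }
    se <- sqrt(max(fit$var[1, 1], 0))
    p <- if (fit$converged) 2 * stats::pnorm(-abs(fit$coef / se)) else 1
    if (!is.finite(p)) p <- 1
    data.frame(gene = g, coef = fit$coef, se = se, p = p,
               flagged = !fit$converged)
  })
  tab <- do.call(rbind, res)
  tab$seed <- tab$p < alpha
  tab <- tab[order(tab$p), c("gene", "coef", "se", "p", "seed", "flagged")]
  rownames(tab) <- NULL
  if (!any(tab$seed)) {
    stop_("no seed genes at alpha = ", alpha,
          "; consider a larger alpha or stronger data")
  }
  attr(tab, "alpha") <- alpha
  class(tab) <- c("screen_table", "data.frame")
  tab
}

#' Partition and resampling settings for robust forward selection
#'
#' @param holdout_fraction Fraction of samples held out for validation in
#'   each random partition (default 1/3; training size is
#'   `round(n * (1 - p))`, validation the remainder).
#' @param n_inner Number of random partitions averaged per selection step
#'   (default 10).
#' @param subsample Subsample size drawn (without replacement) by each
#'   outer stability iteration (default 300).
#' @param n_outer Number of outer stability iterations (default 1000).
#' @param seed Optional master seed; outer iteration `i` derives its own
#'   child stream from it, so `n_outer` can change without perturbing
#'   earlier iterations.
#' @return A list of class `"partition_spec"`.
#' @export
partition_spec <- function(holdout_fraction = 1 / 3, n_inner = 10L,
                           subsample = 300L, n_outer = 1000L, seed = NULL) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_("holdout_fraction must lie in (0, 1)")
  }
  if (n_inner < 1 || n_outer < 1) stop_("n_inner and n_outer must be >= 1")
  structure(list(holdout_fraction = holdout_fraction,
                 n_inner = as.integer(n_inner),
                 subsample = as.integer(subsample),
                 n_outer = as.integer(n_outer), seed = seed),
            class = "partition_spec")
}

# Draw one train/validation partition with >= 1 training event; indices of
# the training samples are returned.  Errors after max_tries failures.
draw_partition_ <- function(n, n_train, event, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    tr <- sample.int(n, n_train)
    if (sum(event[tr]) >= 1) return(tr)
  }
  stop_("could not draw a training partition containing an event")
}

#' Robust likelihood-based forward selection
#'
#' Greedy model growth: at each step, every remaining candidate gene is
#' appended to the current model, the enlarged model is fitted on the
#' training part of `n_inner` fresh random partitions, its partial
#' log-likelihood is evaluated on the corresponding validation parts at the
#' frozen training coefficients, and the candidate with the largest mean
#' held-out log-likelihood wins the step.  For each step the full-cohort
#' fit of the selected model is recorded as `nloglik` (negative maximized
#' partial log-likelihood) together with `aic = 2 * nloglik + 2 * step`;
#' the selected model is the prefix with the smallest AIC.
#'
#' @param expression Genes x samples matrix restricted to the seed genes.
#' @param survival A [survival_table()] covering the samples.
#' @param partition A [partition_spec()]; `subsample`/`n_outer` are ignored
#'   here (see [stability_select()]).
#' @param max_steps Maximum number of forward steps (default 20, capped at
#'   the number of genes).
#' @param ties Ties method for the Cox fits.
#' @return A `data.frame` of class `"selection_trace"`: columns `step`,
#'   `gene`, `nloglik`, `aic`, `mean_heldout`, with attribute `"selected"`
#'   holding the min-AIC gene prefix.
#' @export
forward_select <- function(expression, survival, partition = partition_spec(),
                           max_steps = 20L, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_expression(expression)
  survival <- align_survival(expression, survival)
  if (nrow(expression) < 1) stop_("no candidate genes")
  if (sum(survival$event) < 1) stop_("no observed events")
  if (!is.null(partition$seed)) set.seed(partition$seed)
  xmat <- t(expression)  # samples x genes
  n <- nrow(xmat)
  time <- survival$time; event <- survival$event
  n_train <- round(n * (1 - partition$holdout_fraction))
  if (n_train < 2 || n_train >= n) stop_("holdout fraction incompatible with cohort size")
  genes <- colnames(xmat)
  model <- integer(0)
  remaining <- seq_along(genes)
  n_steps <- min(as.integer(max_steps), length(genes))
  trace <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    parts <- lapply(seq_len(partition$n_inner), function(j) {
      draw_partition_(n, n_train, event)
    })
    means <- vapply(remaining, function(g) {
      cols <- c(model, g)
      lls <- vapply(parts, function(tr) {
        xt <- xmat[tr, cols, drop = FALSE]
        if (any(apply(xt, 2, function(v) max(v) == min(v)))) return(NA_real_)
        fit <- cox_fit_(xt, time[tr], event[tr], ties)
        if (is.null(fit)) return(NA_real_)
        partial_loglik(fit$coef, xmat[-tr, cols, drop = FALSE],
                       time[-tr], event[-tr], ties)
      }, numeric(1))
      if (all(is.na(lls))) -Inf else mean(lls, na.rm = TRUE)
    }, numeric(1))
    if (all(!is.finite(means))) stop_("all candidate fits failed at step ", s)
    best <- which.max(means)
    model <- c(model, remaining[best])
    full <- cox_fit_(xmat[, model, drop = FALSE], time, event, ties)
    if (is.null(full)) stop_("full-cohort fit failed at step ", s)
    trace[[s]] <- data.frame(step = s, gene = genes[model[s]],
                             nloglik = -full$loglik,
                             aic = compute_aic(-full$loglik, s),
                             mean_heldout = means[best])
    remaining <- remaining[-best]
  }
  out <- do.call(rbind, trace)
  rownames(out) <- NULL
  attr(out, "selected") <- out$gene[seq_len(select_model_size(out$aic))]
  attr(out, "ties") <- ties
  class(out) <- c("selection_trace", "data.frame")
  out
}

#' Pick the model size minimizing AIC
#'
#' @param aics AIC values of the nested models in step order.
#' @return The 1-based index of the minimum; exact ties resolve toward the
#'   smaller model.
#' @export
select_model_size <- function(aics) {
  if (length(aics) == 0) stop_("empty AIC list")
  which.min(aics)  # which.min returns the first (smallest-index) minimum
}

#' Stability selection over random subsamples
#'
#' Runs [forward_select()] on `n_outer` random subsamples (drawn without
#' replacement, each required to contain at least one event) and tallies
#' the selected gene sets order-insensitively.  The most frequent gene
#' combination is the modal set; per-gene marginal selection frequencies
#' are reported as a diagnostic.  Samples are canonicalized by id order
#' before any drawing, and each outer iteration uses a child seed derived
#' from the master seed, so results are reproducible and insensitive to
#' input sample order and to later changes of `n_outer`.
#'
#' @param expression Genes x samples matrix restricted to seed genes.
#' @param survival Matching [survival_table()].
#' @param partition A [partition_spec()]; `subsample`, `n_outer` and `seed`
#'   are used here, the rest is passed to each inner [forward_select()].
#' @param max_steps Per-run forward-selection step cap.
#' @param ties Ties method for the Cox fits.
#' @return A list of class `"stability_result"`: `sets` (named frequency
#'   vector, names are `|`-joined sorted gene ids), `modal_set`,
#'   `modal_frequency`, `per_gene` marginal frequencies,
#'   `iteration_sets` (the per-iteration selected set keys, in order),
#'   `n_outer`, `seed`.
#' @export
stability_select <- function(expression, survival, partition = partition_spec(),
                             max_steps = 20L, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_expression(expression)
  expression <- expression[, order(colnames(expression)), drop = FALSE]
  survival <- align_survival(expression, survival)
  n <- ncol(expression)
  m <- partition$subsample
  if (m > n) stop_("subsample size ", m, " exceeds cohort size ", n)
  master <- partition$seed %||% sample.int(.Machine$integer.max, 1)
  keys <- character(partition$n_outer)
  sets <- vector("list", partition$n_outer)
  inner <- partition
  inner$seed <- NULL
  for (i in seq_len(partition$n_outer)) {
    set.seed(child_seed(master, i))
    idx <- NULL
    for (try in seq_len(100L)) {
      cand <- sort(sample.int(n, m))
      if (sum(survival$event[cand]) >= 1) { idx <- cand; break }
    }
    if (is.null(idx)) stop_("could not draw a subsample containing an event")
    tr <- forward_select(expression[, idx, drop = FALSE],
                         survival[idx, , drop = FALSE],
                         partition = inner, max_steps = max_steps, ties = ties)
    sel <- sort(attr(tr, "selected"))
    sets[[i]] <- sel
    keys[i] <- paste(sel, collapse = "|")
  }
  freq <- table(keys)
  freq <- freq[order(-as.integer(freq), names(freq))]  # ties: lexicographic
  modal_key <- names(freq)[1]
  per_gene <- sort(table(unlist(sets)), decreasing = TRUE)
  structure(list(sets = stats::setNames(as.integer(freq), names(freq)),
                 modal_set = strsplit(modal_key, "|", fixed = TRUE)[[1]],
                 modal_frequency = as.integer(freq[1]),
                 per_gene = stats::setNames(as.integer(per_gene),
                                            names(per_gene)),
                 iteration_sets = keys,
                 n_outer = partition$n_outer, seed = master),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability selection over", x$n_outer, "subsamples\n")
  cat("  modal set (frequency ", x$modal_frequency, "/", x$n_outer, "): ",
      paste(x$modal_set, collapse = ", "), "\n", sep = "")
  cat("  distinct sets:", length(x$sets), "\n")
  invisible(x)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward-selection trace (", nrow(x), " steps; min-AIC model = ",
      length(attr(x, "selected")), " genes)\n", sep = "")
  print.data.frame(x, digits = 6)
  invisible(x)
}
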