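# From signature genes to a patient-level risk classifier: unsupervised
# two-cluster structure, per-gene prognostic direction (impact sign),
# median-dichotomized activation counts, the ">= k active genes" threshold
# sweep, and frozen-model validation on an independent cohort.

#' Two-cluster grouping of samples on signature-gene expression
#'
#' Agglomerative hierarchical clustering of samples on Euclidean distance
#' over the signature genes, with the tree cut at two clusters.  When
#' survival data are supplied, cluster 1 is relabelled to be the cluster
#' with worse survival (more observed than expected events under the
#' log-rank decomposition); otherwise cluster 1 is the larger cluster.
#'
#' @param expression Genes x samples matrix restricted to the signature.
#' @param survival Optional [survival_table()] used to orient the labels.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return A list of class `"cluster_assignment"`: `labels` (named 1/2 per
#'   sample), `worse_cluster` (always 1), `basis` (`"survival"` or
#'   `"size"`), `linkage`, `distance`.
#' @export
cluster_samples <- function(expression, survival = NULL,
                            linkage = c("complete", "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  check_expression(expression)
  if (ncol(expression) < 2) stop_("need >= 2 samples to cluster")
  hc <- stats::hclust(stats::dist(t(expression), method = "euclidean"),
                      method = linkage)
  labels <- stats::cutree(hc, k = 2)
  basis <- "size"
  if (!is.null(survival)) {
    sv <- align_survival(expression, survival)
    if (sum(sv$event) >= 1 && length(unique(labels)) == 2) {
      lr <- logrank_test(sv, labels)
      worse <- which.max(lr$observed - lr$expected)
      if (worse == 2) labels <- 3L - labels
      basis <- "survival"
    }
  }
  if (basis == "size" && sum(labels == 2) > sum(labels == 1)) {
    labels <- 3L - labels
  }
  structure(list(labels = labels, worse_cluster = 1L, basis = basis,
                 linkage = linkage, distance = "euclidean"),
            class = "cluster_assignment")
}

#' Assign a prognostic direction to each signature gene
#'
#' Positive-impact genes are adverse when highly expressed; negative-impact
#' genes are adverse when lowly expressed.  Two rules are offered:
#' `"cox-sign"` (default) takes the sign of the gene's univariate Cox
#' coefficient; `"cluster-contrast"` sets +1 when the gene's mean
#' expression is higher in the worse-survival cluster of a two-cluster
#' grouping.  Exact ties resolve to +1 with a warning.
#'
#' @param expression Genes x samples matrix containing the signature genes.
#' @param genes Signature gene ids.
#' @param survival A [survival_table()]; required by both methods (it
#'   orients the clusters under `"cluster-contrast"`).
#' @param method `"cox-sign"` or `"cluster-contrast"`.
#' @param clusters Optional precomputed [cluster_samples()] result for
#'   `"cluster-contrast"`.
#' @param ties Ties method for the Cox fits under `"cox-sign"`.
#' @return Named vector of +1 / -1 per gene.
#' @export
assign_signs <- function(expression, genes, survival = NULL,
                         method = c("cox-sign", "cluster-contrast"),
                         clusters = NULL, ties = "efron") {
  method <- match.arg(method)
  check_expression(expression)
  miss <- setdiff(genes, rownames(expression))
  if (length(miss) > 0) stop_("genes absent from matrix: ", paste(miss, collapse = ", "))
  sub <- expression[genes, , drop = FALSE]
  if (method == "cox-sign") {
    if (is.null(survival)) stop_("method 'cox-sign' requires survival data")
    sv <- align_survival(sub, survival)
    signs <- vapply(genes, function(g) {
      fit <- fit_cox(sub[g, ], sv, ties = ties)
      unname(sign(fit$coef[1]))
    }, numeric(1))
  } else {
    if (is.null(clusters)) {
      if (is.null(survival)) {
        stop_("method 'cluster-contrast' requires survival data (or precomputed clusters)")
      }
      clusters <- cluster_samples(sub, survival)
    }
    worse <- clusters$labels == clusters$worse_cluster
    signs <- vapply(genes, function(g) {
      sign(mean(sub[g, worse]) - mean(sub[g, !worse]))
    }, numeric(1))
  }
  if (any(signs == 0)) {
    warning("tied contrast for gene(s) ", paste(genes[signs == 0], collapse = ", "),
            "; resolved to +1")
    signs[signs == 0] <- 1
  }
  stats::setNames(as.integer(signs), genes)
}

#' Construct a frozen signature model
#'
#' The classifier the pipeline produces: a gene list, a prognostic
#' direction per gene, a per-gene expression cutoff (by default the
#' cohort median), and the activation threshold `k` at or above which a
#' patient is called high risk.
#'
#' @param genes Signature gene ids.
#' @param signs Named +1/-1 per gene.
#' @param cutoffs Named numeric cutoffs per gene, or an expression matrix
#'   from which per-gene medians are taken.
#' @param k Activation threshold (1 <= k <= number of genes); may be left
#'   `NULL` until [threshold_sweep()] chooses it.
#' @return A list of class `"signature_model"`.
#' @export
signature_model <- function(genes, signs, cutoffs, k = NULL) {
  genes <- as.character(genes)
  if (is.matrix(cutoffs)) {
    check_expression(cutoffs)
    miss <- setdiff(genes, rownames(cutoffs))
    if (length(miss) > 0) {
      stop_("gene(s) missing from cutoff matrix: ", paste(miss, collapse = ", "))
    }
    cutoffs <- apply(cutoffs[genes, , drop = FALSE], 1, stats::median)
  }
  signs <- signs[genes]; cutoffs <- cutoffs[genes]
  if (any(is.na(signs)) || !all(signs %in% c(-1L, 1L))) {
    stop_("signs must be +1/-1 for every gene")
  }
  if (any(!is.finite(cutoffs))) stop_("cutoffs must be finite for every gene")
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1 || k > length(genes)) stop_("k must lie in 1..", length(genes))
  }
  structure(list(genes = genes, signs = signs, cutoffs = cutoffs, k = k),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Signature model:", length(x$genes), "genes, threshold k =",
      x$k %||% NA, "\n")
  print(data.frame(gene = x$genes,
                   impact = ifelse(x$signs > 0, "positive", "negative"),
                   cutoff = round(x$cutoffs, 4)), row.names = FALSE)
  invisible(x)
}

#' Per-sample activation counts
#'
#' A positive-impact gene is active in a sample when its expression is
#' strictly above the cutoff; a negative-impact gene when strictly below.
#' The activation count is the number of active signature genes; a sample
#' sitting exactly at every cutoff has count 0.
#'
#' @param expression Genes x samples matrix containing the model's genes.
#' @param model A [signature_model()].
#' @return Named integer vector of counts per sample.
#' @export
activation_scores <- function(expression, model) {
  check_expression(expression)
  miss <- setdiff(model$genes, rownames(expression))
  if (length(miss) > 0) stop_("model gene(s) missing from matrix: ",
                              paste(miss, collapse = ", "))
  sub <- expression[model$genes, , drop = FALSE]
  up <- sub > model$cutoffs      # cutoffs recycle down rows (genes)
  dn <- sub < model$cutoffs
  active <- (model$signs > 0) * up + (model$signs < 0) * dn
  stats::setNames(as.integer(colSums(active)), colnames(sub))
}

#' Sweep the activation threshold k
#'
#' For each candidate `k`, samples with activation count `>= k` form the
#' high-risk group and the rest the low-risk group; a log-rank test
#' compares the two.  Thresholds producing an empty group are reported as
#' `NA`.  The chosen `k` is the threshold with the smallest log-rank p
#' (ties toward smaller `k`) among *eligible* thresholds — those leaving
#' at least a `min_group` fraction of samples in each arm.  The guard
#' exists because the log-rank chi-square is badly anti-conservative for
#' near-empty groups (a couple of extreme-count samples failing early can
#' dominate every balanced split), and a risk classifier whose high-risk
#' arm holds a handful of patients does not transfer; if no threshold is
#' eligible the guard is dropped.  A resampling check re-chooses `k` on
#' random subsamples (each containing at least one event) and reports the
#' modal choice as a stability diagnostic.
#'
#' @param counts Named activation counts from [activation_scores()].
#' @param survival Matching [survival_table()].
#' @param k_range Candidate thresholds (default `1:max(counts)` capped
#'   below at 1).
#' @param min_group Minimum fraction of samples required in each risk arm
#'   for a threshold to be eligible (default 0.05).
#' @param n_resample Number of stability subsamples (default 25; 0 skips
#'   the check).
#' @param resample_fraction Subsample fraction for the stability check.
#' @return A list of class `"threshold_sweep"`: `table` (k, group sizes,
#'   chisq, p), `chosen_k`, `modal_k`, `logrank` (the test at the chosen
#'   k).
#' @export
threshold_sweep <- function(counts, survival, k_range = NULL,
                            min_group = 0.05, n_resample = 25L,
                            resample_fraction = 0.8) {
  sv <- survival[match(names(counts), survival$sample_id), , drop = FALSE]
  if (any(is.na(sv$time))) stop_("counts and survival cover different samples")
  if (is.null(k_range)) k_range <- seq_len(max(max(counts), 1))
  sweep_once <- function(counts, sv) {
    m <- ceiling(min_group * length(counts))
    rows <- lapply(k_range, function(k) {
      high <- counts >= k
      if (!any(high) || all(high)) {
        return(data.frame(k = k, n_high = sum(high), n_low = sum(!high),
                          eligible = FALSE, chisq = NA_real_, p = NA_real_))
      }
      lr <- logrank_test(sv, ifelse(high, "high", "low"))
      data.frame(k = k, n_high = sum(high), n_low = sum(!high),
                 eligible = sum(high) >= m && sum(!high) >= m,
                 chisq = lr$chisq, p = lr$p)
    })
    do.call(rbind, rows)
  }
  pick_k <- function(tab) {
    p <- ifelse(tab$eligible, tab$p, NA_real_)
    if (all(is.na(p))) p <- tab$p  # no eligible threshold: drop the guard
    if (all(is.na(p))) return(NA_integer_)
    tab$k[which.min(p)]  # NA never wins; ties go to the smaller k
  }
  tab <- sweep_once(counts, sv)
  if (all(is.na(tab$p))) stop_("no threshold yields two non-empty groups")
  chosen <- pick_k(tab)
  modal_k <- NA_integer_
  if (n_resample > 0) {
    n <- length(counts)
    m <- max(2L, round(resample_fraction * n))
    picks <- vapply(seq_len(n_resample), function(b) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, m)
        if (sum(sv$event[idx]) >= 1) break
      }
      t2 <- sweep_once(counts[idx], sv[idx, , drop = FALSE])
      if (all(is.na(t2$p))) NA_integer_ else as.integer(pick_k(t2))
    }, integer(1))
    picks <- picks[!is.na(picks)]
    if (length(picks) > 0) {
      tt <- table(picks)
      modal_k <- as.integer(names(tt)[which.max(tt)])
    }
  }
  high <- counts >= chosen
  structure(list(table = tab, chosen_k = as.integer(chosen),
                 modal_k = modal_k,
                 logrank = logrank_test(sv, ifelse(high, "high", "low"))),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Activation-threshold sweep (chosen k =", x$chosen_k,
      "; modal k over resamples =", x$modal_k, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classify samples with a frozen signature model
#'
#' @param expression Genes x samples matrix containing the model's genes.
#' @param model A [signature_model()] with `k` set.
#' @param recompute_cutoffs If `TRUE`, per-gene median cutoffs are
#'   recomputed within this cohort (signs and `k` stay frozen) — the
#'   default for cross-platform transfer; `FALSE` applies the model's
#'   stored cutoffs unchanged.
#' @return A `data.frame` of class `"risk_assignment"`: `sample_id`,
#'   `count`, `label` (`"high"`/`"low"`).
#' @export
classify_samples <- function(expression, model, recompute_cutoffs = FALSE) {
  if (is.null(model$k)) stop_("model has no activation threshold k")
  if (recompute_cutoffs) {
    model <- signature_model(model$genes, model$signs, expression, k = model$k)
  }
  counts <- activation_scores(expression, model)
  out <- data.frame(sample_id = names(counts), count = as.integer(counts),
                    label = ifelse(counts >= model$k, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- model$k
  class(out) <- c("risk_assignment", "data.frame")
  out
}

#' Validate a frozen model on an independent cohort
#'
#' Applies a frozen signature (gene list, impact signs, threshold `k`) to a
#' new cohort.  By default per-gene median cutoffs are recomputed within
#' the validation cohort — absolute expression cutoffs do not transfer
#' across platforms — while signs and `k` stay frozen; set
#' `recompute_cutoffs = FALSE` to carry the discovery cutoffs over.  Each
#' supplied endpoint gets its own Kaplan-Meier comparison of the high- and
#' low-risk groups.
#'
#' @param expression Validation genes x samples matrix.
#' @param survivals A [survival_table()] or named list of them (e.g.
#'   `list(survival = ..., recurrence = ...)`).
#' @param model A frozen [signature_model()].
#' @param recompute_cutoffs See [classify_samples()]; default `TRUE`.
#' @return A list of class `"external_validation"`: `assignment` (the
#'   [classify_samples()] table) and `tests`, a named list with a
#'   `logrank_test` per endpoint (endpoints whose samples are absent are
#'   skipped with a warning).
#' @export
validate_external <- function(expression, survivals, model,
                              recompute_cutoffs = TRUE) {
  if (inherits(survivals, "survival_table")) {
    survivals <- stats::setNames(list(survivals),
                                 attr(survivals, "endpoint") %||% "survival")
  }
  assignment <- classify_samples(expression, model,
                                 recompute_cutoffs = recompute_cutoffs)
  tests <- list()
  for (ep in names(survivals)) {
    sv <- survivals[[ep]]
    idx <- match(assignment$sample_id, sv$sample_id)
    if (all(is.na(idx))) {
      warning("endpoint '", ep, "' covers none of the cohort samples; skipped")
      next
    }
    ok <- !is.na(idx)
    tests[[ep]] <- logrank_test(sv[idx[ok], , drop = FALSE],
                                assignment$label[ok])
  }
  structure(list(assignment = assignment, tests = tests, k = model$k),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation at k =", x$k, "\n")
  cat("  high:", sum(x$assignment$label == "high"),
      " low:", sum(x$assignment$label == "low"), "\n")
  for (ep in names(x$tests)) {
    cat(sprintf("  %s: log-rank chisq %.3f, p = %.4g\n", ep,
                x$tests[[ep]]$chisq, x$tests[[ep]]$p))
  }
  invisible(x)
}

#' Pairwise Pearson correlation of signature genes
#'
#' @param expression Genes x samples matrix restricted to the signature
#'   (>= 3 samples).  Constant genes yield `NA` correlations; the diagonal
#'   is always 1.
#' @return Symmetric correlation matrix.
#' @export
gene_correlation <- function(expression) {
  check_expression(expression)
  if (ncol(expression) < 3) stop_("need >= 3 samples for correlation")
  cc <- suppressWarnings(stats::cor(t(expression), method = "pearson"))
  diag(cc) <- 1
  cc
}
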