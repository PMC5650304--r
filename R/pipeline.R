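# End-to-end orchestration: discovery (filter -> screen -> selection ->
# signs -> threshold sweep -> frozen model) as one function, plus a
# config-driven staged runner used by the command-line wrapper.

#' Discover a prognostic signature and build the risk classifier
#'
#' Runs the whole discovery pipeline on one cohort: expression filter,
#' univariate Cox screen, robust likelihood-based forward selection
#' (optionally wrapped in subsample stability counting), impact-sign
#' assignment, median cutoffs, and the activation-threshold sweep.  The
#' result is a frozen [signature_model()] ready for
#' [validate_external()].
#'
#' @param expression Genes x samples matrix (log-scale, normalized).
#' @param survival A [survival_table()] for the discovery endpoint.
#' @param median_fraction,variance_fraction Filter fractions
#'   ([expression_filter()]).
#' @param alpha Seed-gene threshold ([univariate_screen()]).
#' @param partition A [partition_spec()] for selection.
#' @param max_steps Forward-selection step cap.
#' @param stability If `TRUE` (default) the signature is the modal gene
#'   set of [stability_select()]; if `FALSE`, the min-AIC prefix of a
#'   single [forward_select()] run on the full cohort.
#' @param sign_method Sign rule for [assign_signs()].
#' @param k Optional pinned activation threshold; `NULL` (default) lets
#'   [threshold_sweep()] choose it.
#' @param ties Ties method for all Cox fits.
#' @param seed Seed applied before any resampling.
#' @return A list of class `"signature_fit"`: `screen`, `trace` (when
#'   `stability = FALSE`), `stability` (otherwise), `signs`, `model`,
#'   `sweep`, `assignment` (discovery-cohort risk calls), `n_filtered`.
#' @export
discover_signature <- function(expression, survival,
                               median_fraction = 0.20,
                               variance_fraction = 0.20,
                               alpha = 0.05,
                               partition = partition_spec(),
                               max_steps = 20L,
                               stability = TRUE,
                               sign_method = c("cox-sign", "cluster-contrast"),
                               k = NULL,
                               ties = c("efron", "breslow"),
                               seed = NULL) {
  sign_method <- match.arg(sign_method)
  ties <- match.arg(ties)
  if (!is.null(seed)) set.seed(seed)
  filt <- expression_filter(expression, median_fraction, variance_fraction)
  screen <- univariate_screen(filt, survival, alpha = alpha, ties = ties)
  seeds <- screen$gene[screen$seed]
  seed_mat <- filt[seeds, , drop = FALSE]
  out <- list(screen = screen, n_filtered = nrow(filt))
  if (stability) {
    if (is.null(partition$seed) && !is.null(seed)) partition$seed <- seed
    stab <- stability_select(seed_mat, survival, partition = partition,
                             max_steps = max_steps, ties = ties)
    signature <- stab$modal_set
    out$stability <- stab
  } else {
    tr <- forward_select(seed_mat, survival, partition = partition,
                         max_steps = max_steps, ties = ties)
    signature <- attr(tr, "selected")
    out$trace <- tr
  }
  signs <- assign_signs(expression, signature, survival,
                        method = sign_method, ties = ties)
  model <- signature_model(signature, signs, expression, k = NULL)
  counts <- activation_scores(expression, model)
  sweep <- threshold_sweep(counts, survival)
  model$k <- if (is.null(k)) sweep$chosen_k else as.integer(k)
  out$signs <- signs
  out$model <- model
  out$sweep <- sweep
  out$assignment <- classify_samples(expression, model)
  class(out) <- "signature_fit"
  out
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Prognostic signature fit\n")
  cat("  genes after filter:", x$n_filtered,
      "; seed genes:", sum(x$screen$seed), "\n")
  cat("  signature:", paste(x$model$genes, collapse = ", "), "\n")
  cat("  impact signs:", paste(ifelse(x$model$signs > 0, "+", "-"),
                               collapse = " "), "\n")
  cat("  activation threshold k =", x$model$k,
      sprintf("(log-rank p = %.3g at k)", x$sweep$logrank$p), "\n")
  invisible(x)
}

#' Run pipeline stages from a configuration list
#'
#' Config-driven staged runner behind the command-line wrapper.  Stages:
#' `"simulate"` (write a synthetic cohort), `"screen"` (filter +
#' univariate screen), `"select"` (forward/stability selection),
#' `"model"` (signs, cutoffs, threshold sweep -> model JSON),
#' `"classify"` (risk assignment on the discovery cohort) and
#' `"validate"` (frozen model on a second cohort).  Each stage writes its
#' artifact into `outdir` plus a shared `manifest.json` recording the
#' seed, the config echo and md5 checksums of every file written, so a
#' rerun with the same config is byte-reproducible and attributable.
#'
#' @param config Named list; recognized fields: `stages` (character
#'   vector, default all applicable), `expression`, `clinical`,
#'   `probe_map`, `validation_expression`, `validation_clinical` (paths),
#'   `seed`, `outdir`, `simulate` (list passed to [simulation_config()]),
#'   `filter` (`median_fraction`, `variance_fraction`), `alpha`,
#'   `partition` (list passed to [partition_spec()]), `max_steps`,
#'   `stability`, `sign_method`, `k`, `ties`, `collapse_rule`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir %||% "survsig-output"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||%
    c(if (!is.null(config$simulate) || is.null(config$expression)) "simulate",
      "screen", "select", "model", "classify",
      if (!is.null(config$validation_expression)) "validate")
  files <- character(0)
  note <- function(tag, path) files[tag] <<- path

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop_("[", name, "] ", conditionMessage(e))
    })
  }

  mat <- NULL; clin <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- do.call(simulation_config,
                     c(config$simulate %||% list(), list(seed = seed)))
      cohort <- simulate_cohort(cfg)
      written <- write_cohort(cohort, outdir)
      for (tag in names(written)) note(paste0("simulate:", tag), written[[tag]])
      mat <<- cohort$expression
      clin <<- list(survival = cohort$survival, recurrence = cohort$recurrence)
    })
  }
  load_inputs <- function() {
    if (is.null(mat)) {
      if (is.null(config$expression)) stop_("config field 'expression' is required")
      m <- read_expression(config$expression)
      if (!is.null(config$probe_map)) {
        m <- collapse_probes(m, read_probe_map(config$probe_map),
                             rule = config$collapse_rule %||% "maxvar")
      }
      mat <<- m
    }
    if (is.null(clin)) {
      if (is.null(config$clinical)) stop_("config field 'clinical' is required")
      clin <<- read_clinical(config$clinical)
    }
  }

  fit <- NULL
  if (any(c("screen", "select", "model", "classify") %in% stages)) {
    run_stage("screen", load_inputs)
    run_stage("pipeline", function() {
      part <- do.call(partition_spec,
                      c(config$partition %||% list(), list(seed = seed)))
      fit <<- discover_signature(
        mat, clin$survival,
        median_fraction = config$filter$median_fraction %||% 0.20,
        variance_fraction = config$filter$variance_fraction %||% 0.20,
        alpha = config$alpha %||% 0.05,
        partition = part,
        max_steps = config$max_steps %||% 20L,
        stability = config$stability %||% TRUE,
        sign_method = config$sign_method %||% "cox-sign",
        k = config$k, ties = config$ties %||% "efron", seed = seed)
    })
    if ("screen" %in% stages) {
      p <- file.path(outdir, "screen.tsv")
      write_results(fit$screen, p); note("screen", p)
    }
    if ("select" %in% stages) {
      if (!is.null(fit$trace)) {
        p <- file.path(outdir, "selection_trace.tsv")
        write_results(fit$trace, p); note("select:trace", p)
      }
      if (!is.null(fit$stability)) {
        p <- file.path(outdir, "stability_sets.tsv")
        write_tsv_(data.frame(set = names(fit$stability$sets),
                              frequency = fit$stability$sets), p)
        note("select:stability", p)
      }
    }
    if ("model" %in% stages) {
      fit$model$metadata <- list(seed = seed,
                                 package_version = as.character(utils::packageVersion("survsig")))
      p <- file.path(outdir, "model.json")
      write_results(fit$model, p); note("model", p)
      p <- file.path(outdir, "threshold_sweep.tsv")
      write_tsv_(fit$sweep$table, p); note("model:sweep", p)
    }
    if ("classify" %in% stages) {
      p <- file.path(outdir, "risk_assignment.tsv")
      write_results(fit$assignment, p); note("classify", p)
    }
  }

  if ("validate" %in% stages) {
    run_stage("validate", function() {
      if (is.null(config$validation_expression) || is.null(config$validation_clinical)) {
        stop_("config fields 'validation_expression'/'validation_clinical' are required")
      }
      vmat <- read_expression(config$validation_expression)
      vclin <- read_clinical(config$validation_clinical)
      model <- if (!is.null(fit)) fit$model else
        read_signature_model(config$model %||% file.path(outdir, "model.json"))
      val <- validate_external(vmat, vclin, model)
      p <- file.path(outdir, "validation_assignment.tsv")
      write_results(val$assignment, p); note("validate:assignment", p)
      tests <- lapply(val$tests, function(t) list(chisq = t$chisq, df = t$df, p = t$p))
      p <- file.path(outdir, "validation_tests.json")
      jsonlite::write_json(tests, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note("validate:tests", p)
    })
  }

  manifest <- list(seed = seed, stages = stages,
                   config = config[setdiff(names(config), "outdir")],
                   files = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
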