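# Reading, validating and writing the cohort tables the pipeline consumes:
# tab-delimited expression matrices, probe -> gene maps, clinical follow-up,
# and the serialized pipeline outputs.

#' Read a tab-delimited expression matrix
#'
#' Reads a TSV with one header row of identifiers and one id column, and
#' returns a validated genes x samples numeric matrix.  Values are taken
#' as-is: the pipeline assumes they are already normalized and on a
#' continuous (typically log) scale.
#'
#' Validation is strict: duplicate row or column identifiers, non-numeric
#' cells and missing values are all hard errors (imputation is deliberately
#' out of scope), with offending ids or cell coordinates named in the
#' message.
#'
#' @param path Path to a tab-delimited text file.  The first column holds
#'   row identifiers; the header holds column identifiers.
#' @param orientation `"genes"` if rows are genes (the default layout),
#'   `"samples"` if rows are samples; the returned matrix is always
#'   genes x samples.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @seealso [collapse_probes()], [read_clinical()]
#' @export
read_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop_("expected an id column plus at least one data column in ", path)
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup) > 0) {
    stop_("duplicate row identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  dup <- unique(col_ids[duplicated(col_ids)])
  if (length(dup) > 0) {
    stop_("duplicate column identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_("non-numeric or missing value at row '", row_ids[i], "', column '",
          col_ids[j], "' in ", path, " (", nrow(bad), " offending cell(s))")
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples") vals <- t(vals)
  check_expression(vals)
  vals
}

#' Read a probe-to-gene map
#'
#' @param path Two-column TSV (`probe_id`, `gene_symbol`).  Probes without a
#'   gene symbol should simply be absent from the file.
#' @return A data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop_("probe map must have two columns (probe_id, gene_symbol)")
  map <- data.frame(probe_id = df[[1]], gene_symbol = df[[2]],
                    stringsAsFactors = FALSE)
  dup <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(dup) > 0) stop_("duplicate probe ids in map: ", paste(dup, collapse = ", "))
  map
}

#' Construct a per-sample follow-up table
#'
#' The basic survival container used throughout the package: one row per
#' sample with a non-negative follow-up time and a binary event indicator
#' (1 = event observed, 0 = censored).  The endpoint label and time unit are
#' carried as attributes and never converted implicitly; mixing cohorts
#' followed in months with cohorts followed in days is the caller's
#' responsibility to notice.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (logical accepted).
#' @param endpoint Label such as `"survival"` or `"recurrence"`.
#' @param unit Time unit label, e.g. `"months"` or `"days"`.
#' @return A `data.frame` of class `"survival_table"` with columns
#'   `sample_id`, `time`, `event` and attributes `endpoint` and `unit`.
#' @export
survival_table <- function(sample_id, time, event, endpoint = "survival",
                           unit = "months") {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(sample_id) != length(time) || length(time) != length(event)) {
    stop_("sample_id, time and event must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop_("duplicate sample ids: ",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (any(!is.finite(time)) || any(time < 0)) stop_("times must be finite and >= 0")
  if (!all(event %in% c(0L, 1L))) stop_("event must be 0/1")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "endpoint") <- endpoint
  attr(out, "unit") <- unit
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read a clinical follow-up table
#'
#' Expects a TSV with columns `sample_id`, `time`, `event`, and optionally
#' `time_recurrence` / `event_recurrence` for a second endpoint.
#'
#' @param path Path to the clinical TSV.
#' @param unit Time unit recorded on the returned tables.
#' @return A named list of [survival_table()] objects: always `survival`,
#'   plus `recurrence` when the optional columns are present.
#' @export
read_clinical <- function(path, unit = "months") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) stop_("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  out <- list(survival = survival_table(df$sample_id, df$time, df$event,
                                        endpoint = "survival", unit = unit))
  if (all(c("time_recurrence", "event_recurrence") %in% colnames(df))) {
    out$recurrence <- survival_table(df$sample_id, df$time_recurrence,
                                     df$event_recurrence,
                                     endpoint = "recurrence", unit = unit)
  }
  out
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes absent from the map are dropped (the standard "remove non-matched
#' probes" step); multiple probes mapping to one gene are combined by the
#' chosen rule.  The default keeps, per gene, the probe with the largest
#' variance across samples — a deterministic rule that preserves the dynamic
#' range survival screening depends on; `"mean"` averages the probe rows
#' element-wise.
#'
#' @param expression Numeric probe x sample matrix with probe rownames.
#' @param map Probe map as returned by [read_probe_map()], or any data frame
#'   with columns `probe_id` and `gene_symbol`.
#' @param rule `"maxvar"` (default) or `"mean"`.
#' @return A gene x sample matrix with unique gene rownames.
#' @export
collapse_probes <- function(expression, map, rule = c("maxvar", "mean")) {
  rule <- match.arg(rule)
  check_expression(expression, "probe matrix")
  idx <- match(rownames(expression), map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop_("no probes left after mapping: all probes unmatched")
  sub <- expression[keep, , drop = FALSE]
  genes <- map$gene_symbol[idx[keep]]
  ug <- unique(genes)
  out <- matrix(NA_real_, nrow = length(ug), ncol = ncol(sub),
                dimnames = list(ug, colnames(sub)))
  if (rule == "maxvar") {
    v <- apply(sub, 1, stats::var)
    for (g in ug) {
      rows <- which(genes == g)
      out[g, ] <- sub[rows[which.max(v[rows])], ]
    }
  } else {
    for (g in ug) {
      rows <- which(genes == g)
      out[g, ] <- colMeans(sub[rows, , drop = FALSE])
    }
  }
  out
}

#' Write a pipeline result to disk
#'
#' Tabular results (screen tables, selection traces, risk assignments) are
#' written as TSV; a [signature_model()] is written as a JSON document that
#' [read_signature_model()] reloads without loss.
#'
#' @param x A pipeline result object.
#' @param path Output file path.
#' @param ... Passed to methods.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

write_tsv_ <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_("cannot write to ", path)
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, ...) write_tsv_(as.data.frame(x), path)

#' @export
write_results.selection_trace <- function(x, path, ...) {
  write_tsv_(as.data.frame(x)[, c("gene", "nloglik", "aic", "step", "mean_heldout")], path)
}

#' @export
write_results.risk_assignment <- function(x, path, ...) {
  write_tsv_(as.data.frame(x)[, c("sample_id", "count", "label")], path)
}

#' @export
write_results.signature_model <- function(x, path, ...) {
  doc <- list(
    type = "signature_model",
    genes = x$genes,
    signs = as.integer(x$signs),
    cutoffs = as.numeric(x$cutoffs),
    k = as.integer(x$k),
    metadata = x$metadata %||% list()
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_("cannot write to ", path)
  invisible(path)
}

#' Reload a signature model written by [write_results()]
#'
#' @param path Path to the model JSON.
#' @return A [signature_model()] object.
#' @export
read_signature_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "signature_model")) stop_(path, " is not a signature model document")
  m <- signature_model(genes = doc$genes,
                       signs = stats::setNames(doc$signs, doc$genes),
                       cutoffs = stats::setNames(doc$cutoffs, doc$genes),
                       k = doc$k)
  m$metadata <- doc$metadata
  m
}

#' Write a synthetic cohort as the pipeline's external file formats
#'
#' Writes the expression TSV (probe-level when the cohort carries probes, so
#' that collapsing is exercised downstream), the clinical TSV with both
#' endpoints, the probe map if present, and the planted truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  mat <- cohort$probe_expression %||% cohort$expression
  ep <- file.path(dir, "expression.tsv")
  write_tsv_(data.frame(gene_id = rownames(mat), mat, check.names = FALSE), ep)
  files["expression"] <- ep
  cl <- data.frame(sample_id = cohort$survival$sample_id,
                   time = cohort$survival$time, event = cohort$survival$event,
                   time_recurrence = cohort$recurrence$time,
                   event_recurrence = cohort$recurrence$event)
  cp <- file.path(dir, "clinical.tsv")
  write_tsv_(cl, cp)
  files["clinical"] <- cp
  if (!is.null(cohort$probe_map)) {
    pp <- file.path(dir, "probe_map.tsv")
    write_tsv_(cohort$probe_map, pp)
    files["probe_map"] <- pp
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["truth"] <- tp
  invisible(files)
}
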