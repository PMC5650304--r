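# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ <- function(...) stop(..., call. = FALSE)

#' Derive a child RNG seed from a master seed and an iteration index.
#'
#' Keeps iteration i reproducible regardless of how many iterations are run,
#' so enlarging an outer loop never perturbs earlier draws.  Seeds stay below
#' 2^31 - 1.
#' @noRd
child_seed <- function(master, i) {
  s <- (as.double(master) + 48271 * as.double(i)) %% 2147483646
  as.integer(s) + 1L
}

#' Align a survival table to the columns of an expression matrix.
#'
#' Returns the survival table restricted and reordered to the matrix's
#' sample ids; errors if any matrix sample lacks follow-up.
#' @noRd
align_survival <- function(expression, survival) {
  ids <- colnames(expression)
  miss <- setdiff(ids, survival$sample_id)
  if (length(miss) > 0) {
    stop_("no follow-up for sample(s): ", paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) ", ..." else "")
  }
  survival[match(ids, survival$sample_id), , drop = FALSE]
}

#' Check that a matrix looks like genes x samples expression.
#' @noRd
check_expression <- function(x, what = "expression") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_(what, " must be a numeric matrix (genes in rows, samples in columns)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_(what, " must carry gene rownames and sample colnames")
  }
  invisible(x)
}
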