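# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
ho_stop <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "holonet_error"), ...)
}

#' Check that a matrix looks like an expression matrix
#' @noRd
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    ho_stop(sprintf("`%s` must be a numeric matrix (transcripts x samples)", arg),
            "holonet_input_error")
  }
  if (any(x < 0)) {
    ho_stop(sprintf("`%s` contains negative values", arg), "holonet_input_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    ho_stop(sprintf("`%s` must have transcript rownames and sample colnames", arg),
            "holonet_input_error")
  }
  invisible(x)
}

#' Check a sample design table
#' @noRd
check_design <- function(design) {
  need <- c("sample_id", "treatment", "replicate", "is_control")
  if (!all(need %in% names(design))) {
    ho_stop(sprintf("design must have columns: %s", paste(need, collapse = ", ")),
            "holonet_design_error")
  }
  if (anyDuplicated(design[, c("treatment", "replicate")])) {
    ho_stop("design has duplicated (treatment, replicate) pairs", "holonet_design_error")
  }
  if (sum(unique(design$treatment[design$is_control])) == 0 ||
      length(unique(design$treatment[design$is_control])) != 1) {
    ho_stop("design must contain exactly one control nitrate level", "holonet_design_error")
  }
  invisible(design)
}

#' Derive a child seed for a pipeline stage
#'
#' Stable integer derivation so each stage of a pipeline run is
#' independently reproducible from one global seed.
#' @noRd
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + stage_index * 16807) %% 2147483587L)
}
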