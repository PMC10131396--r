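# Per-compartment differential expression against the control, DET calling
# with Venn partitioning, and the ordination input transform.

#' Counts per million
#'
#' Library-size normalisation: `cpm[i, j] = count[i, j] / colsum[j] * 1e6`,
#' so every column of the result sums to one million (when the library is
#' non-empty).
#'
#' @param counts Numeric matrix of raw counts, transcripts x samples, with
#'   dimnames.
#' @return CPM matrix with the same dimnames.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
#' cpm(m)
#' @export
cpm <- function(counts) {
  check_expression_matrix(counts, "counts")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    ho_stop(sprintf("zero library size in sample(s): %s",
                    paste(colnames(counts)[libs == 0], collapse = ", ")),
            "holonet_degenerate_library")
  }
  sweep(counts, 2, libs, `/`) * 1e6
}

#' Row-wise Welch's t-test on log2(CPM + 1)
#'
#' The default two-group test for [pairwise_de()]: per transcript, Welch's
#' unequal-variance t on `log2(CPM + 1)`. Degenerate rows (zero variance in
#' both groups) get p = 1 when the means agree and p = 0 otherwise.
#'
#' @param a,b CPM matrices (transcripts x samples) for the two groups,
#'   matching rows.
#' @return Vector of two-sided p-values, one per transcript.
#' @export
welch_log2_test <- function(a, b) {
  x <- log2(a + 1)
  y <- log2(b + 1)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
  unname(p)
}

#' Pairwise differential expression of one treatment against control
#'
#' Computes, per transcript, `logFC = log2((mean treatment CPM + prior) /
#' (mean control CPM + prior))` and a p-value from a pluggable two-group
#' test (default: [welch_log2_test()]). A transcript is flagged significant
#' when `logFC > lfc_threshold` or `logFC < -lfc_threshold` (strict) and
#' `p <= p_threshold` (inclusive).
#'
#' @param cpm_mat CPM matrix (transcripts x samples).
#' @param design Sample design (see [generate_design()]).
#' @param treatment Nitrate level to compare against the control; must not be
#'   the control itself.
#' @param test Function `(treatment_cpm, control_cpm) -> p-values`.
#' @param prior Pseudo-CPM added to both group means before the ratio, to
#'   stabilise fold changes at zeros.
#' @param lfc_threshold Absolute log2 fold-change cut (strict inequality).
#' @param p_threshold P-value cut (inclusive).
#' @return Tibble: `transcript_id`, `comparison`, `logFC`, `p_value`,
#'   `significant`.
#' @export
pairwise_de <- function(cpm_mat, design, treatment,
                        test = welch_log2_test,
                        prior = 1,
                        lfc_threshold = 1,
                        p_threshold = 1e-4) {
  check_expression_matrix(cpm_mat, "cpm_mat")
  check_design(design)
  ctl_ids <- design$sample_id[design$is_control]
  trt_ids <- design$sample_id[design$treatment == treatment & !design$is_control]
  if (length(trt_ids) < 2 || length(ctl_ids) < 2) {
    ho_stop(sprintf("treatment %s vs control needs >= 2 replicates per group", treatment),
            "holonet_design_error")
  }
  a <- cpm_mat[, trt_ids, drop = FALSE]
  b <- cpm_mat[, ctl_ids, drop = FALSE]
  logfc <- log2((rowMeans(a) + prior) / (rowMeans(b) + prior))
  p <- test(a, b)
  tibble::tibble(
    transcript_id = rownames(cpm_mat),
    comparison = sprintf("control-%g", treatment),
    logFC = unname(logfc),
    p_value = p,
    significant = (logfc > lfc_threshold | logfc < -lfc_threshold) & p <= p_threshold
  )
}

#' Default DET p-value threshold for a compartment
#'
#' Coral and Symbiodiniaceae transcripts use 1e-4; prokaryotic transcripts
#' use the laxer 1e-3.
#' @param compartment One of `"coral"`, `"symbiodiniaceae"`, `"prokaryote"`.
#' @return A p-value threshold.
#' @export
det_p_threshold <- function(compartment) {
  switch(compartment,
         coral = 1e-4,
         symbiodiniaceae = 1e-4,
         prokaryote = 1e-3,
         ho_stop(sprintf("unknown compartment '%s'", compartment),
                 "holonet_input_error"))
}

#' Call differentially expressed transcripts (DETs) across comparisons
#'
#' A transcript differentially expressed in at least one treatment-vs-control
#' comparison is a DET. Significance is re-evaluated here from `logFC` and
#' `p_value` with the compartment's thresholds, so upstream flags cannot
#' disagree with the stated rule. Returns the union set, the Venn partition
#' of the union across comparisons, and up/down counts per comparison.
#'
#' @param de_results A list of tibbles from [pairwise_de()] (one per
#'   comparison) or one row-bound tibble.
#' @param compartment Compartment label; sets the default `p_threshold` via
#'   [det_p_threshold()].
#' @param p_threshold,lfc_threshold Override thresholds.
#' @return An object of class `det_set`: list with `compartment`,
#'   `per_comparison` (named list of transcript id vectors), `union`,
#'   `venn_counts` (named integer vector keyed by comparison combination),
#'   `up_down` (tibble comparison/up/down) and `thresholds`.
#' @export
call_dets <- function(de_results, compartment,
                      p_threshold = det_p_threshold(compartment),
                      lfc_threshold = 1) {
  de <- if (is.data.frame(de_results)) de_results else dplyr::bind_rows(de_results)
  if (nrow(de) == 0) {
    out <- list(compartment = compartment, per_comparison = list(),
                union = character(), venn_counts = integer(0),
                up_down = tibble::tibble(comparison = character(),
                                         up = integer(), down = integer()),
                thresholds = c(p = p_threshold, lfc = lfc_threshold))
    class(out) <- "det_set"
    return(out)
  }
  de$significant <- (de$logFC > lfc_threshold | de$logFC < -lfc_threshold) &
    de$p_value <= p_threshold
  comps <- unique(de$comparison)
  per_comparison <- lapply(comps, function(cmp) {
    de$transcript_id[de$comparison == cmp & de$significant]
  })
  names(per_comparison) <- comps
  union_set <- sort(unique(unlist(per_comparison)))

  # Venn partition: each union member keyed by the set of comparisons it is
  # significant in
  membership <- vapply(union_set, function(tid) {
    paste(comps[vapply(per_comparison, function(s) tid %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  venn_counts <- if (length(membership)) {
    tab <- table(membership)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)

  up_down <- dplyr::bind_rows(lapply(comps, function(cmp) {
    d <- de[de$comparison == cmp & de$significant, , drop = FALSE]
    tibble::tibble(comparison = cmp,
                   up = sum(d$logFC > 0), down = sum(d$logFC < 0))
  }))

  out <- list(compartment = compartment, per_comparison = per_comparison,
              union = union_set, venn_counts = venn_counts, up_down = up_down,
              thresholds = c(p = p_threshold, lfc = lfc_threshold))
  class(out) <- "det_set"
  out
}

#' @export
print.det_set <- function(x, ...) {
  cat(sprintf("DET set (%s): %d transcripts in union, thresholds |logFC| > %g, p <= %g\n",
              x$compartment, length(x$union), x$thresholds["lfc"], x$thresholds["p"]))
  for (cmp in names(x$per_comparison)) {
    cat(sprintf("  %s: %d significant\n", cmp, length(x$per_comparison[[cmp]])))
  }
  invisible(x)
}

#' Ordination input transform
#'
#' `sqrt(log2(CPM + 1))`: the square-root of log2 counts per million (offset
#' by one so zeros map to zero), the input scale used for Bray-Curtis
#' ordination of DET expression.
#'
#' @param cpm_mat CPM matrix.
#' @return Transformed matrix of the same shape.
#' @export
ordination_transform <- function(cpm_mat) {
  if (any(cpm_mat < 0)) ho_stop("CPM values must be nonnegative", "holonet_input_error")
  sqrt(log2(cpm_mat + 1))
}

#' Bray-Curtis sample dissimilarity
#'
#' `d(u, v) = sum|u - v| / sum(u + v)` between sample columns; values lie in
#' `[0, 1]`, with 0 for identical samples and 1 for disjoint supports.
#'
#' @param mat Nonnegative matrix, features x samples (typically the output of
#'   [ordination_transform()]).
#' @return Square symmetric dissimilarity matrix (samples x samples).
#' @export
bray_curtis <- function(mat) {
  if (any(mat < 0)) ho_stop("Bray-Curtis requires nonnegative input", "holonet_input_error")
  d <- as.matrix(vegan::vegdist(t(mat), method = "bray"))
  dimnames(d) <- list(colnames(mat), colnames(mat))
  d
}
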