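# Repeated random-subset L1-penalized linear mixed-model selection linking
# transcript expression to symbiont physiology.
#
# The model: response = intercept + X beta + u_group + eps, with a random
# intercept per aquarium-replicate batch (u ~ N(0, tau2)) and an L1 penalty
# on the fixed effects. Fitting alternates (a) coordinate descent with
# soft-thresholding on the whitened fixed-effect problem with (b) exact
# profiled-ML variance-component updates; convergence when the largest coefficient
# change drops below `tol` (default 1e-6) or after `max_iter` iterations.

# The numerical core lives in src/plmm.cpp: coordinate descent with
# soft-thresholding on the whitened problem, alternating with an exact
# profiled-ML variance-component update (1-D search over tau2/sigma2).
# This thin wrapper exists so the grid driver and tests have one R-side
# entry point.
.plmm_fit <- function(y, xs, gi, lambda, max_iter = 500, tol = 1e-6,
                      start = NULL) {
  .plmm_fit_cpp(as.numeric(y), unname(as.matrix(xs)), as.integer(gi),
                lambda, as.integer(max_iter), tol, start)
}

# Fit over a lambda grid and keep the BIC-minimizing fit.
.plmm_fit_grid <- function(y, xs, gi, lambda = NULL,
                           grid_fractions = c(0.5, 0.25, 0.1, 0.05, 0.02),
                           max_iter = 500, tol = 1e-6) {
  if (!is.null(lambda)) {
    fit <- .plmm_fit(y, xs, gi, lambda, max_iter, tol)
    fit$lambda <- lambda
    fit$lambda_grid <- lambda
    return(fit)
  }
  lam_max <- max(abs(crossprod(xs, y - mean(y))))
  grid <- sort(lam_max * grid_fractions, decreasing = TRUE)
  best <- NULL
  start <- NULL
  for (lam in grid) {
    fit <- .plmm_fit(y, xs, gi, lam, max_iter, tol, start = start)
    fit$lambda <- lam
    start <- list(b0 = fit$intercept, beta = fit$beta,
                  sigma2 = fit$sigma2, tau2 = fit$tau2)
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  best$lambda_grid <- grid
  best
}

#' Fit an L1-penalized linear mixed model with a random intercept
#'
#' Minimises the penalized objective: residual sum of squares under a
#' random-intercept-per-group Gaussian model plus `lambda * sum(|beta|)` on
#' the fixed effects. Predictors are standardized to zero mean and unit
#' variance before penalization (coefficients are reported on that scale);
#' constant predictors are dropped with a warning. When `lambda` is `NULL`,
#' it is chosen by minimising BIC over a small fixed grid of fractions of
#' the smallest all-zero penalty.
#'
#' @param y Numeric response vector (natural scale).
#' @param x Numeric predictor matrix, samples x predictors (at most a
#'   handful of columns; the repeated-selection procedure feeds blocks of
#'   10).
#' @param group Grouping factor/vector (aquarium replicate batch); needs at
#'   least 2 levels.
#' @param lambda L1 penalty weight (>= 0), or `NULL` for BIC selection.
#' @param grid_fractions Fractions of `lambda_max` forming the BIC grid.
#' @param max_iter,tol Convergence controls: stop when the largest
#'   coefficient change is below `tol`, error after `max_iter` iterations.
#' @return Object of class `penalized_lmm`: list with `coefficients` (named,
#'   standardized scale), `intercept`, `random_effects` (predicted group
#'   intercepts), `mean_abs_random` (mean absolute predicted random
#'   intercept), `sigma2`, `tau2`, `lambda`, `lambda_grid`, `bic`,
#'   `n_iter`, `converged` and `dropped` (constant predictors removed).
#' @export
fit_penalized_lmm <- function(y, x, group, lambda = NULL,
                              grid_fractions = c(0.5, 0.25, 0.1, 0.05, 0.02),
                              max_iter = 500, tol = 1e-6) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x) || length(group) != nrow(x)) {
    ho_stop("y, rows of x, and group must align", "holonet_input_error")
  }
  if (!is.null(lambda) && lambda < 0) {
    ho_stop("lambda must be >= 0", "holonet_input_error")
  }
  gi <- as.integer(factor(group))
  if (max(gi) < 2) ho_stop("need >= 2 groups", "holonet_input_error")

  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  keep <- sds > 0
  xs <- scale(x[, keep, drop = FALSE])
  fit <- .plmm_fit_grid(y, xs, gi, lambda, grid_fractions, max_iter, tol)
  if (!fit$converged) {
    ho_stop(sprintf("penalized LMM did not converge in %d iterations (lambda = %g)",
                    max_iter, fit$lambda),
            "holonet_nonconvergence", n_iter = fit$n_iter, lambda = fit$lambda)
  }
  out <- list(
    coefficients = stats::setNames(fit$beta, colnames(x)[keep]),
    intercept = fit$intercept,
    random_effects = stats::setNames(fit$u, levels(factor(group))),
    mean_abs_random = mean(abs(fit$u)),
    sigma2 = fit$sigma2, tau2 = fit$tau2,
    lambda = fit$lambda, lambda_grid = fit$lambda_grid,
    bic = fit$bic, n_iter = fit$n_iter, converged = fit$converged,
    dropped = dropped
  )
  class(out) <- "penalized_lmm"
  out
}

#' @export
print.penalized_lmm <- function(x, ...) {
  cat(sprintf("Penalized LMM: lambda = %.4g, %d/%d nonzero coefficients, tau2 = %.4g, sigma2 = %.4g\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients),
              x$tau2, x$sigma2))
  invisible(x)
}

#' Repeated random-subset penalized mixed-model selection
#'
#' The selection procedure: in each of `n_runs` runs, transcripts are
#' randomly permuted and partitioned into consecutive blocks of `n_per_fit`
#' (a final short block is fitted as-is, so every transcript gets exactly
#' one estimate per run). Each block is fitted with the penalized mixed
#' model; a transcript scores a hit in a run when its absolute fixed-effect
#' estimate exceeds the mean absolute predicted random intercept of its
#' block's fit. Transcripts whose hit count exceeds `threshold_runs` are
#' retained; the conventional thresholds are more than 95 runs (of 100) for
#' coral and more than 70 for prokaryotic predictors.
#'
#' @param response Numeric physiology vector over samples.
#' @param predictors Expression matrix, transcripts x samples (CPM); the
#'   procedure fits on standardized log2(CPM + 1).
#' @param group Aquarium-replicate batch per sample.
#' @param n_per_fit Transcripts per model fit (default 10).
#' @param n_runs Number of repeated runs (default 100).
#' @param threshold_runs Retention threshold: retained iff hit count >
#'   `threshold_runs` (default 95).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param log_transform Apply log2(x + 1) to predictors first (default TRUE).
#' @param lambda Fixed penalty, or `NULL` for per-fit BIC selection.
#' @param response_name Label stored in the result.
#' @return Object of class `selection_result`: list with `response`,
#'   `table` (tibble transcript_id, retention_count, retained, sign,
#'   mean_estimate), `n_runs`, `threshold_runs`, `n_per_fit`, `seed`.
#' @export
repeated_selection <- function(response, predictors, group,
                               n_per_fit = 10, n_runs = 100,
                               threshold_runs = 95, seed = 1,
                               log_transform = TRUE, lambda = NULL,
                               response_name = "response") {
  if (n_runs < 1 || n_per_fit < 1) {
    ho_stop("n_runs and n_per_fit must be >= 1", "holonet_parameter_error")
  }
  check_expression_matrix(predictors, "predictors")
  if (length(response) != ncol(predictors) || length(group) != ncol(predictors)) {
    ho_stop("response and group must align with predictor samples",
            "holonet_input_error")
  }
  gi <- as.integer(factor(group))
  if (max(gi) < 2) ho_stop("need >= 2 groups", "holonet_input_error")

  xmat <- t(if (log_transform) log2(predictors + 1) else predictors)
  sds <- apply(xmat, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d constant transcript(s) from selection", sum(!keep)))
  }
  xs <- scale(xmat[, keep, drop = FALSE])
  ids <- colnames(xs)
  p <- ncol(xs)

  counts <- stats::setNames(rep(0L, p), ids)
  est_sum <- stats::setNames(rep(0, p), ids)
  hit_n <- stats::setNames(rep(0L, p), ids)

  set.seed(seed)
  for (run in seq_len(n_runs)) {
    perm <- sample.int(p)
    starts <- seq(1, p, by = n_per_fit)
    for (s in starts) {
      idx <- perm[s:min(s + n_per_fit - 1, p)]
      fit <- .plmm_fit_grid(response, xs[, idx, drop = FALSE], gi, lambda)
      mar <- mean(abs(fit$u))
      hits <- abs(fit$beta) > mar
      if (any(hits)) {
        hit_ids <- ids[idx[hits]]
        counts[hit_ids] <- counts[hit_ids] + 1L
        est_sum[hit_ids] <- est_sum[hit_ids] + fit$beta[hits]
        hit_n[hit_ids] <- hit_n[hit_ids] + 1L
      }
    }
  }

  mean_est <- unname(ifelse(hit_n > 0, est_sum / pmax(hit_n, 1L), 0))
  tbl <- tibble::tibble(
    transcript_id = ids,
    retention_count = unname(as.integer(counts)),
    retained = unname(counts > threshold_runs),
    sign = ifelse(unname(hit_n) == 0, NA_character_,
                  ifelse(mean_est >= 0, "positive", "negative")),
    mean_estimate = mean_est
  )
  out <- list(response = response_name, table = tbl, n_runs = n_runs,
              threshold_runs = threshold_runs, n_per_fit = n_per_fit,
              seed = seed)
  class(out) <- "selection_result"
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection for %s: %d/%d transcripts retained (> %d of %d runs)\n",
              x$response, sum(x$table$retained), nrow(x$table),
              x$threshold_runs, x$n_runs))
  invisible(x)
}

#' Summarise retained transcripts across responses
#'
#' One row per retained (response, transcript) pair, ordered by response then
#' transcript id, with the sign and mean estimate over hit runs.
#'
#' @param results A `selection_result` or list of them.
#' @return Long tibble: `response`, `transcript_id`, `sign`,
#'   `mean_estimate`, `retention_count`.
#' @export
summarize_selection <- function(results) {
  if (inherits(results, "selection_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    tb <- r$table[r$table$retained, , drop = FALSE]
    if (nrow(tb) == 0) return(NULL)
    tibble::tibble(response = r$response, transcript_id = tb$transcript_id,
                   sign = tb$sign, mean_estimate = tb$mean_estimate,
                   retention_count = tb$retention_count)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(response = character(), transcript_id = character(),
                          sign = character(), mean_estimate = numeric(),
                          retention_count = integer()))
  }
  out[order(out$response, out$transcript_id), , drop = FALSE]
}
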