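# Cross-compartment Spearman correlation networks, size-adjusted
# betweenness centrality, and core-transcript extraction.

#' Two-sided p-value for Spearman's rho (t approximation)
#'
#' Large-sample approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. `|rho| = 1` maps to p = 0.
#'
#' @param rho Spearman correlation(s).
#' @param n Number of paired samples (>= 4).
#' @return Two-sided p-value(s).
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 4) ho_stop("need >= 4 samples for the t approximation", "holonet_input_error")
  p <- rep(0, length(rho))
  ok <- abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p
}

#' Spearman rank correlation of a single pair
#'
#' Midrank-based Spearman coefficient, the single-pair counterpart of the
#' matrix computation in [correlate_pairs()]. With distinct values this
#' equals the classical rank-difference form `1 - 6 * sum(d^2) / (n (n^2 -
#' 1))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Spearman's rho.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))  # -0.5
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    ho_stop("x and y must have equal length >= 3", "holonet_input_error")
  }
  stats::cor(rank(x), rank(y))
}

#' Spearman correlations for all cross-compartment transcript pairs
#'
#' Correlates every transcript of one compartment with every transcript of
#' another, across matched samples, using Spearman's rank correlation with
#' midranks for ties and the two-sided t approximation for p-values.
#' Expression is log2(x + 1)-transformed first; rho is invariant to that
#' monotone transform, but the transform is recorded for reproducibility of
#' tie handling. Transcripts with zero rank variance (constant expression)
#' cannot be correlated: their pairs are excluded from the edge table with a
#' warning, but still count toward `n_pairs_tested = |A| x |B|`.
#'
#' @param expr_a,expr_b Expression matrices (transcripts x samples; typically
#'   CPM restricted to each compartment's DET set) with identical, aligned
#'   sample columns and >= 4 samples.
#' @param compartment_a,compartment_b Compartment labels attached to the
#'   respective transcripts.
#' @param log_transform Apply log2(x + 1) before ranking (default TRUE).
#' @return An object of class `correlation_pairs`: list with `pairs` (tibble
#'   transcript_a, compartment_a, transcript_b, compartment_b, rho, p_value,
#'   sign), `n_pairs_tested`, `n_samples` and `excluded` (constant
#'   transcripts).
#' @export
correlate_pairs <- function(expr_a, expr_b,
                            compartment_a = "coral",
                            compartment_b = "symbiodiniaceae",
                            log_transform = TRUE) {
  check_expression_matrix(expr_a, "expr_a")
  check_expression_matrix(expr_b, "expr_b")
  if (!identical(colnames(expr_a), colnames(expr_b))) {
    ho_stop("expr_a and expr_b must have identical, aligned sample columns",
            "holonet_input_error")
  }
  n <- ncol(expr_a)
  if (n < 4) ho_stop("need >= 4 matched samples", "holonet_input_error")
  n_pairs_tested <- nrow(expr_a) * nrow(expr_b)

  a <- if (log_transform) log2(expr_a + 1) else expr_a
  b <- if (log_transform) log2(expr_b + 1) else expr_b

  const_a <- apply(a, 1, function(z) length(unique(z)) == 1)
  const_b <- apply(b, 1, function(z) length(unique(z)) == 1)
  excluded <- c(rownames(a)[const_a], rownames(b)[const_b])
  if (length(excluded)) {
    warning(sprintf(
      "excluding %d constant transcript(s) with undefined rank correlation: %s",
      length(excluded), paste(excluded, collapse = ", ")))
  }
  a <- a[!const_a, , drop = FALSE]
  b <- b[!const_b, , drop = FALSE]

  if (nrow(a) == 0 || nrow(b) == 0) {
    pairs <- tibble::tibble(transcript_a = character(), compartment_a = character(),
                            transcript_b = character(), compartment_b = character(),
                            rho = numeric(), p_value = numeric(), sign = character())
  } else {
    rho <- stats::cor(t(a), t(b), method = "spearman")
    pairs <- tibble::tibble(
      transcript_a = rep(rownames(a), times = nrow(b)),
      compartment_a = compartment_a,
      transcript_b = rep(rownames(b), each = nrow(a)),
      compartment_b = compartment_b,
      rho = as.vector(rho)
    )
    pairs$p_value <- spearman_pvalue(pairs$rho, n)
    pairs$sign <- ifelse(pairs$rho >= 0, "positive", "negative")
  }

  out <- list(pairs = pairs, n_pairs_tested = n_pairs_tested,
              n_samples = n, excluded = excluded,
              compartments = c(compartment_a, compartment_b))
  class(out) <- "correlation_pairs"
  out
}

#' Canonical network name for a compartment pair
#' @noRd
network_name_for <- function(compartments) {
  key <- paste(sort(compartments), collapse = "|")
  switch(key,
         "coral|symbiodiniaceae" = "coral-algal",
         "prokaryote|symbiodiniaceae" = "algal-prokaryotic",
         "coral|prokaryote" = "coral-prokaryotic",
         paste(compartments, collapse = "-"))
}

#' Build a bipartite co-expression network from tested pairs
#'
#' Retains pairs with `p <= alpha` as network edges. Nodes are the
#' transcripts incident to at least one retained edge; the proportion of
#' significant correlations is `|edges| / n_pairs_tested`.
#'
#' @param pairs A `correlation_pairs` object from [correlate_pairs()].
#' @param alpha Edge significance level (default 0.05, uncorrected).
#' @param name Network name; defaults to the canonical name for the
#'   compartment pair (`"coral-algal"`, `"algal-prokaryotic"`,
#'   `"coral-prokaryotic"`).
#' @return Object of class `bipartite_network`: list with `name`, `nodes`
#'   (tibble transcript_id/compartment), `edges`, `n_pairs_tested`,
#'   `proportion_significant` and `alpha`.
#' @export
build_network <- function(pairs, alpha = 0.05, name = NULL) {
  if (!inherits(pairs, "correlation_pairs")) {
    ho_stop("pairs must come from correlate_pairs()", "holonet_input_error")
  }
  edges <- pairs$pairs[pairs$pairs$p_value <= alpha, , drop = FALSE]
  nodes <- dplyr::bind_rows(
    tibble::tibble(transcript_id = edges$transcript_a,
                   compartment = edges$compartment_a),
    tibble::tibble(transcript_id = edges$transcript_b,
                   compartment = edges$compartment_b)
  )
  nodes <- dplyr::distinct(nodes)
  nodes <- nodes[order(nodes$transcript_id), , drop = FALSE]
  out <- list(
    name = name %||% network_name_for(pairs$compartments),
    nodes = nodes,
    edges = edges,
    n_pairs_tested = pairs$n_pairs_tested,
    proportion_significant = nrow(edges) / pairs$n_pairs_tested,
    alpha = alpha
  )
  class(out) <- "bipartite_network"
  out
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges of %d pairs tested (%.2f%% significant at p <= %g)\n",
              x$name, nrow(x$nodes), nrow(x$edges), x$n_pairs_tested,
              100 * x$proportion_significant, x$alpha))
  invisible(x)
}

#' Size-adjusted betweenness centrality
#'
#' Shortest-path betweenness on the unweighted network graph, divided by the
#' number of transcripts included in the network, so hub scores are
#' comparable across networks of different sizes. An alternative
#' normalisation by the number of non-incident vertex pairs
#' `(N - 1)(N - 2) / 2` is available.
#'
#' @param network A `bipartite_network`.
#' @param normalization `"node_count"` (default: divide by N) or
#'   `"pair_count"` (divide by `(N - 1)(N - 2) / 2`).
#' @return Tibble: `transcript_id`, `compartment`, `betweenness` (raw) and
#'   `adjusted_betweenness`; isolated and degree-1 nodes score 0.
#' @export
adjusted_betweenness <- function(network,
                                 normalization = c("node_count", "pair_count")) {
  normalization <- match.arg(normalization)
  if (!inherits(network, "bipartite_network")) {
    ho_stop("network must come from build_network()", "holonet_input_error")
  }
  nodes <- network$nodes
  if (nrow(nodes) == 0) {
    return(tibble::tibble(transcript_id = character(), compartment = character(),
                          betweenness = numeric(), adjusted_betweenness = numeric()))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("transcript_a", "transcript_b")],
    directed = FALSE,
    vertices = nodes$transcript_id
  )
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  n_nodes <- nrow(nodes)
  denom <- if (normalization == "node_count") n_nodes else
    max((n_nodes - 1) * (n_nodes - 2) / 2, 1)
  tibble::tibble(
    transcript_id = nodes$transcript_id,
    compartment = nodes$compartment,
    betweenness = unname(raw[nodes$transcript_id]),
    adjusted_betweenness = unname(raw[nodes$transcript_id]) / denom
  )
}

#' Core transcripts of a network
#'
#' The top-k transcripts by adjusted betweenness centrality (ties broken by
#' transcript id, ascending). If the network has fewer than k nodes, all are
#' returned.
#'
#' @param network A `bipartite_network` with at least one node.
#' @param k Number of core transcripts (default 20).
#' @param normalization Passed to [adjusted_betweenness()].
#' @return Tibble of the ranked core transcripts with a `rank` column.
#' @export
core_transcripts <- function(network, k = 20,
                             normalization = c("node_count", "pair_count")) {
  ab <- adjusted_betweenness(network, normalization)
  if (nrow(ab) == 0) {
    ho_stop("network has no nodes", "holonet_input_error")
  }
  ord <- order(-ab$adjusted_betweenness, ab$transcript_id)
  out <- ab[ord, , drop = FALSE][seq_len(min(k, nrow(ab))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
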