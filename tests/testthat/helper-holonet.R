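# Shared fixtures, built in code. The default simulation is cached per test
# file run so several tests can share one realisation.

tiny_design <- function(n_reps = 4) generate_design(n_reps)

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- generate_design(4)
      sim <- generate_counts(
        design,
        n_transcripts = c(coral = 60, symbiodiniaceae = 50, prokaryote = 50),
        de_fraction = 0.1, effect_size_log2 = 2, seed = 11
      )
      cache <<- list(design = design, sim = sim,
                     cpms = lapply(sim$counts, cpm))
    }
    cache
  }
})

# Spearman rho for a single pair via the rank-difference route (midranks),
# used as a cross-check against the matrix path.
rank_rho <- function(x, y) stats::cor(rank(x), rank(y))

# Permutation oracle for the Spearman p-value.
perm_spearman_p <- function(x, y, B = 10000) {
  r_obs <- stats::cor(x, y, method = "spearman")
  ym <- replicate(B, sample(y))
  r_perm <- as.vector(stats::cor(x, ym, method = "spearman"))
  mean(abs(r_perm) >= abs(r_obs) - 1e-12)
}

# Build a correlation_pairs object with prescribed p-values, for exercising
# build_network arithmetic on known inputs.
manual_pairs <- function(edges, n_pairs_tested, n_samples = 20) {
  structure(list(pairs = edges, n_pairs_tested = n_pairs_tested,
                 n_samples = n_samples, excluded = character(),
                 compartments = c(edges$compartment_a[1], edges$compartment_b[1])),
            class = "correlation_pairs")
}
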