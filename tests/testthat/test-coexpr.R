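test_that("pair counting is the product of DET set sizes and rho matches the rank formula", {
  set.seed(1)
  a <- matrix(stats::rnorm(5 * 8, 8, 1), 5, 8,
              dimnames = list(paste0("c", 1:5), paste0("s", 1:8)))
  b <- matrix(stats::rnorm(3 * 8, 8, 1), 3, 8,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:8)))
  cp <- correlate_pairs(2^a, 2^b, "coral", "prokaryote")
  expect_equal(cp$n_pairs_tested, 15)
  expect_equal(nrow(cp$pairs), 15)
  # every rho agrees with the midrank route computed pair by pair
  for (k in seq_len(nrow(cp$pairs))) {
    x <- log2(2^a[cp$pairs$transcript_a[k], ] + 1)
    y <- log2(2^b[cp$pairs$transcript_b[k], ] + 1)
    expect_equal(cp$pairs$rho[k], rank_rho(x, y), tolerance = 1e-12)
  }
  expect_true(all(cp$pairs$sign == ifelse(cp$pairs$rho >= 0, "positive", "negative")))
})

test_that("perfect concordance gives rho 1 with a vanishing p-value", {
  x <- matrix(1:6, 1, 6, dimnames = list("a", paste0("s", 1:6)))
  y <- matrix((1:6) * 3 + 2, 1, 6, dimnames = list("b", paste0("s", 1:6)))
  cp <- correlate_pairs(x, y)
  expect_equal(cp$pairs$rho, 1)
  expect_equal(cp$pairs$p_value, 0)
})

test_that("constant transcripts are excluded with a warning but still counted as tested", {
  x <- matrix(c(1:6, rep(2, 6)), 2, 6, byrow = TRUE,
              dimnames = list(c("a", "flat"), paste0("s", 1:6)))
  y <- matrix(6:1, 1, 6, dimnames = list("b", paste0("s", 1:6)))
  expect_warning(cp <- correlate_pairs(x, y), "flat")
  expect_equal(cp$n_pairs_tested, 2)
  expect_equal(nrow(cp$pairs), 1)
})

test_that("network retains only significant edges and reports the significant proportion", {
  set.seed(2)
  n <- 40
  edges <- tibble::tibble(
    transcript_a = sprintf("c%02d", 1:n), compartment_a = "coral",
    transcript_b = sprintf("p%02d", 1:n), compartment_b = "prokaryote",
    rho = stats::runif(n, -1, 1))
  edges$p_value <- c(rep(0.01, 10), rep(0.5, n - 10))
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  net <- build_network(manual_pairs(edges, n_pairs_tested = 200))
  expect_equal(nrow(net$edges), 10)
  expect_equal(net$proportion_significant, 0.05)
  expect_equal(net$name, "coral-prokaryotic")

  edges$p_value <- 1
  empty <- build_network(manual_pairs(edges, 200))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$proportion_significant, 0)
  expect_equal(nrow(adjusted_betweenness(empty)), 0)
})

test_that("adjusted betweenness matches hand-enumerated path counts", {
  # path A - B - C: B lies on the single shortest path, 3 nodes in network
  edges <- tibble::tibble(
    transcript_a = c("A", "C"), compartment_a = "coral",
    transcript_b = c("B", "B"), compartment_b = "symbiodiniaceae",
    rho = 0.9, p_value = 0.01, sign = "positive")
  net <- build_network(manual_pairs(edges, 10))
  ab <- adjusted_betweenness(net)
  expect_equal(ab$betweenness[ab$transcript_id == "B"], 1)
  expect_equal(ab$adjusted_betweenness[ab$transcript_id == "B"], 1 / 3)
  expect_equal(ab$adjusted_betweenness[ab$transcript_id == "A"], 0)

  # star: hub h with k leaves -> adjusted(h) = k(k-1)/2 / (k+1)
  k <- 7
  edges <- tibble::tibble(
    transcript_a = sprintf("leaf%02d", 1:k), compartment_a = "coral",
    transcript_b = "hub", compartment_b = "symbiodiniaceae",
    rho = 0.9, p_value = 0.01, sign = "positive")
  star <- build_network(manual_pairs(edges, 100))
  ab <- adjusted_betweenness(star)
  expect_equal(ab$adjusted_betweenness[ab$transcript_id == "hub"],
               (k * (k - 1) / 2) / (k + 1))
  # alternative normalisation by non-incident pairs
  ab2 <- adjusted_betweenness(star, normalization = "pair_count")
  expect_equal(ab2$adjusted_betweenness[ab2$transcript_id == "hub"], 1)
})

test_that("betweenness is invariant under transcript relabeling", {
  set.seed(3)
  n <- 15
  edges <- tibble::tibble(
    transcript_a = sprintf("a%02d", sample(1:6, n, TRUE)), compartment_a = "coral",
    transcript_b = sprintf("b%02d", sample(1:6, n, TRUE)), compartment_b = "prokaryote",
    rho = 0.5, p_value = 0.01, sign = "positive")
  edges <- dplyr::distinct(edges)
  net1 <- build_network(manual_pairs(edges, 100))
  relab <- edges
  relab$transcript_a <- sub("a", "x", relab$transcript_a)
  relab$transcript_b <- sub("b", "y", relab$transcript_b)
  net2 <- build_network(manual_pairs(relab, 100))
  ab1 <- adjusted_betweenness(net1)
  ab2 <- adjusted_betweenness(net2)
  ab2$transcript_id <- sub("x", "a", sub("y", "b", ab2$transcript_id))
  m <- match(ab1$transcript_id, ab2$transcript_id)
  expect_equal(ab1$adjusted_betweenness, ab2$adjusted_betweenness[m])
})

test_that("core transcripts rank by centrality with a lexicographic tie-break", {
  edges <- tibble::tibble(
    transcript_a = c("A", "C"), compartment_a = "coral",
    transcript_b = c("B", "B"), compartment_b = "symbiodiniaceae",
    rho = 0.9, p_value = 0.01, sign = "positive")
  net <- build_network(manual_pairs(edges, 10))
  core <- core_transcripts(net, k = 20)
  expect_equal(nrow(core), 3)           # k larger than the network
  expect_equal(core$transcript_id[1], "B")
  expect_equal(core$transcript_id[2:3], c("A", "C"))  # equal scores: id order
  expect_equal(core$rank, 1:3)
})

test_that("a planted hub with many partners ranks first", {
  set.seed(4)
  n_samp <- 20
  hub <- stats::rnorm(n_samp)
  partners <- t(sapply(1:30, function(i) hub + stats::rnorm(n_samp, 0, 0.3)))
  noise <- matrix(stats::rnorm(20 * n_samp), 20, n_samp)
  a <- rbind(matrix(hub, 1), noise)
  rownames(a) <- c("hub", sprintf("anoise%02d", 1:20))
  b <- rbind(partners, matrix(stats::rnorm(10 * n_samp), 10, n_samp))
  rownames(b) <- c(sprintf("partner%02d", 1:30), sprintf("bnoise%02d", 1:10))
  colnames(a) <- colnames(b) <- paste0("s", 1:n_samp)
  cp <- correlate_pairs(2^a, 2^b, "coral", "prokaryote")
  net <- build_network(cp)
  core <- core_transcripts(net, k = 5)
  expect_equal(core$transcript_id[1], "hub")
})

test_that("under the null the significant-edge proportion approximates alpha", {
  set.seed(5)
  props <- replicate(10, {
    a <- matrix(stats::rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("a", 1:30), paste0("s", 1:20)))
    b <- matrix(stats::rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("b", 1:30), paste0("s", 1:20)))
    build_network(correlate_pairs(2^a, 2^b))$proportion_significant
  })
  expect_equal(mean(props), 0.05, tolerance = 0.35)
})
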