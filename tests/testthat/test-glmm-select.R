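sim_xy <- function(n = 20, p = 10, beta = NULL, noise = 0.5, re_sd = 0.5,
                   seed = 1) {
  set.seed(seed)
  g <- rep(1:4, length.out = n)
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, paste0("t", 1:p)))
  eff <- if (is.null(beta)) rep(0, p) else beta
  y <- as.vector(scale(x) %*% eff) + stats::rnorm(n, 0, noise) +
    stats::rnorm(4, 0, re_sd)[g]
  list(y = y, x = x, g = g)
}

test_that("extreme penalty shrinks every fixed effect to exactly zero", {
  d <- sim_xy(beta = c(2, rep(0, 9)))
  f <- fit_penalized_lmm(d$y, d$x, d$g, lambda = 1e8)
  expect_true(all(f$coefficients == 0))
  expect_equal(sum(abs(f$random_effects) > 0), 4)
})

test_that("with no penalty and no noise the fit reduces to the OLS slope", {
  set.seed(2)
  x <- matrix(stats::rnorm(20), 20, 1, dimnames = list(NULL, "t1"))
  y <- 3 * x[, 1] + 1
  f <- fit_penalized_lmm(y, x, rep(1:4, each = 5), lambda = 0)
  ols <- unname(stats::coef(stats::lm(y ~ scale(x[, 1])))[2])
  expect_equal(unname(f$coefficients), ols, tolerance = 1e-6)
  expect_lt(f$sigma2, 1e-8)
})

test_that("the unpenalized fit matches lme4's maximum-likelihood estimates", {
  skip_if_not_installed("lme4")
  d <- sim_xy(beta = c(2, -1, rep(0, 8)), seed = 7)
  f <- fit_penalized_lmm(d$y, d$x[, 1:3], d$g, lambda = 0)
  df <- data.frame(y = d$y, xs = I(scale(d$x[, 1:3])), g = d$g)
  lf <- lme4::lmer(y ~ xs + (1 | g), data = df, REML = FALSE)
  expect_equal(unname(f$coefficients), unname(lme4::fixef(lf)[-1]),
               tolerance = 1e-4)
  expect_equal(f$intercept, unname(lme4::fixef(lf)[1]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$tau2, vc$vcov[1], tolerance = 1e-3)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-3)
})

test_that("the penalized solution satisfies the lasso KKT conditions and beats glmnet's solution on its own objective", {
  skip_if_not_installed("glmnet")
  d <- sim_xy(beta = c(2, -1, rep(0, 8)), seed = 11)
  lam <- 4
  f <- fit_penalized_lmm(d$y, d$x, d$g, lambda = lam)
  # whiten at the fitted variance components and check stationarity
  gi <- d$g; nj <- tabulate(gi, 4)
  theta <- 1 - sqrt(f$sigma2 / (f$sigma2 + nj * f$tau2))
  xs <- scale(d$x)
  xbar <- apply(xs, 2, function(cl) as.numeric(tapply(cl, gi, mean)))
  xtil <- xs - xbar[gi, ] * theta[gi]
  ybar <- as.numeric(tapply(d$y, gi, mean))
  ytil <- d$y - theta[gi] * ybar[gi]
  ctil <- 1 - theta[gi]
  res <- as.vector(ytil - ctil * f$intercept - xtil %*% f$coefficients)
  grad <- as.vector(crossprod(xtil, res))
  nz <- f$coefficients != 0
  expect_equal(grad[nz], unname(lam * sign(f$coefficients[nz])),
               tolerance = 1e-4)
  expect_true(all(abs(grad[!nz]) <= lam + 1e-6))

  # objective value no worse than glmnet's lasso solution on the same
  # whitened problem
  obj <- function(b0, b) 0.5 * sum((ytil - ctil * b0 - xtil %*% b)^2) +
    lam * sum(abs(b))
  gf <- glmnet::glmnet(cbind(ctil, xtil), ytil, intercept = FALSE,
                       standardize = FALSE,
                       penalty.factor = c(0, rep(1, ncol(xtil))),
                       lambda = lam / length(d$y))
  gb <- as.vector(gf$beta)
  expect_lte(obj(f$intercept, f$coefficients), obj(gb[1], gb[-1]) + 1e-6)
})

test_that("constant predictors are dropped with a warning and invalid inputs error", {
  d <- sim_xy()
  xbad <- cbind(d$x, flat = 5)
  expect_warning(f <- fit_penalized_lmm(d$y, xbad, d$g), "flat")
  expect_false("flat" %in% names(f$coefficients))
  expect_error(fit_penalized_lmm(d$y, d$x, rep(1, 20)),
               class = "holonet_input_error")
  expect_error(fit_penalized_lmm(d$y, d$x, d$g, lambda = -1),
               class = "holonet_input_error")
  expect_error(repeated_selection(d$y, t(d$x), d$g, n_runs = 0),
               class = "holonet_parameter_error")
})

test_that("a strongly planted predictor dominates the estimates across simulations", {
  wins <- replicate(30, {
    d <- sim_xy(beta = c(2, rep(0, 9)), noise = 0.5, seed = sample.int(1e6, 1))
    f <- fit_penalized_lmm(d$y, d$x, d$g)
    names(which.max(abs(f$coefficients))) == "t1"
  })
  expect_gt(mean(wins), 0.9)
})

test_that("repeated selection is deterministic, bounded, and monotone in the threshold", {
  sim <- small_sim()
  ph <- generate_physiology(sim$design, sim$cpms, seed = 5)
  preds <- sim$cpms$prokaryote[1:20, ]
  r1 <- repeated_selection(ph$physiology$p_n, preds, sim$design$replicate,
                           n_runs = 20, threshold_runs = 19, seed = 9)
  r2 <- repeated_selection(ph$physiology$p_n, preds, sim$design$replicate,
                           n_runs = 20, threshold_runs = 19, seed = 9)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$retention_count >= 0 &
                    r1$table$retention_count <= 20))
  # monotonicity: a lower threshold can only grow the retained set
  lo <- r1$table$transcript_id[r1$table$retention_count > 10]
  hi <- r1$table$transcript_id[r1$table$retention_count > 19]
  expect_true(all(hi %in% lo))
})

test_that("a planted driver with a strong effect is retained in every run", {
  sim <- small_sim()
  drv <- "coral_t0007"
  spec <- make_driver_spec(sim$cpms, "photosynthesis", "coral", drv,
                           target_sd = 0.3 * 0.8)
  ph <- generate_physiology(sim$design, sim$cpms, spec,
                            random_effect_sd = 0.01, noise_sd = 0.01, seed = 6)
  preds <- sim$cpms$coral[1:30, ]
  stopifnot(drv %in% rownames(preds))
  rs <- repeated_selection(ph$physiology$p_n, preds, sim$design$replicate,
                           n_runs = 30, threshold_runs = 28, seed = 10)
  row <- rs$table[rs$table$transcript_id == drv, ]
  expect_equal(row$retention_count, 30L)
  expect_true(row$retained)
  expect_equal(row$sign, "positive")
})

test_that("selection summaries collect retained transcripts with reproducible ordering", {
  empty <- summarize_selection(list())
  expect_equal(nrow(empty), 0)

  sim <- small_sim()
  spec <- dplyr::bind_rows(
    make_driver_spec(sim$cpms, "density", "coral", "coral_t0003",
                     target_sd = 0.3 * 1.75e4),
    make_driver_spec(sim$cpms, "density", "coral", "coral_t0011",
                     target_sd = 0.3 * 1.75e4, signs = -1))
  ph <- generate_physiology(sim$design, sim$cpms, spec,
                            random_effect_sd = 0.01, noise_sd = 0.01, seed = 8)
  preds <- sim$cpms$coral[1:15, ]
  rs <- repeated_selection(ph$physiology$density, preds, sim$design$replicate,
                           n_runs = 20, threshold_runs = 18, seed = 12,
                           response_name = "density")
  smry <- summarize_selection(rs)
  expect_true(all(c("coral_t0003", "coral_t0011") %in% smry$transcript_id))
  expect_equal(smry$sign[smry$transcript_id == "coral_t0003"], "positive")
  expect_equal(smry$sign[smry$transcript_id == "coral_t0011"], "negative")
  smry2 <- summarize_selection(rs)
  expect_identical(smry, smry2)
})
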