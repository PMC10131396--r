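random_params <- function(seed) {
  set.seed(seed)
  symbiosis_params(
    r = stats::runif(1, 0.5, 1.5), K = stats::runif(1, 0.5, 2),
    gamma1 = stats::runif(1, 0, 1), gamma2 = stats::runif(1, 0, 0.5),
    a1 = stats::runif(1, 0, 0.3), a2 = stats::runif(1, 0, 0.3),
    g1 = stats::runif(1, 0.3, 1.2), g2 = stats::runif(1, 0.3, 1.2),
    b1 = stats::runif(1, 0, 0.3), b2 = stats::runif(1, 0, 0.3),
    d1 = stats::runif(1, 0.1, 0.5), d2 = stats::runif(1, 0.1, 0.5),
    e1 = stats::runif(1, 0.5, 3), e2 = stats::runif(1, 0.5, 3),
    c1 = stats::runif(1, 0, 0.5), c2 = stats::runif(1, 0, 0.5))
}

# independent re-statement of the printed rate equations, written in
# expanded form so transcription slips in either copy would disagree
rates_oracle <- function(st, p) {
  H <- st[1]; S <- st[2]; B <- st[3]
  cap <- p$K + p$gamma1 * S + p$gamma2 * S * B
  dH <- p$r * H - p$r * H * H / cap - p$a1 * S * H - p$a2 * B * H
  dS <- p$g1 * H * S + p$g1 * H * S * p$b1 * B -
    p$d1 * S - p$d1 * S * p$e1 * S - p$d1 * S * p$c1 * B
  dB <- p$g2 * H * B + p$g2 * H * B * p$b2 * S -
    p$d2 * B - p$d2 * B * p$e2 * B - p$d2 * B * p$c2 * S
  c(dH, dS, dB)
}

test_that("rate equations reduce to logistic growth without symbionts and match an independent evaluation", {
  p <- example_symbiosis_params("coexistence")
  d <- symbiosis_derivatives(c(0.4, 0, 0), p)
  expect_equal(d[1], p$r * 0.4 * (1 - 0.4 / p$K))
  expect_equal(d[2:3], c(0, 0))
  expect_equal(symbiosis_derivatives(c(p$K, 0, 0), p), c(0, 0, 0))

  for (s in 1:25) {
    pp <- random_params(s)
    st <- stats::runif(3, 0, 3)
    expect_equal(symbiosis_derivatives(st, pp), rates_oracle(st, pp),
                 tolerance = 1e-12)
  }
})

test_that("coordinate planes are invariant", {
  for (s in 1:10) {
    pp <- random_params(100 + s)
    st <- stats::runif(3, 0, 3)
    expect_equal(symbiosis_derivatives(c(0, st[2], st[3]), pp)[1], 0)
    expect_equal(symbiosis_derivatives(c(st[1], 0, st[3]), pp)[2], 0)
    expect_equal(symbiosis_derivatives(c(st[1], st[2], 0), pp)[3], 0)
  }
})

test_that("the analytic Jacobian agrees with central finite differences", {
  for (s in 1:10) {
    pp <- random_params(200 + s)
    st <- stats::runif(3, 0.1, 2)
    J <- symbiosis_jacobian(st, pp)
    h <- 1e-6
    Jnum <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- h
      Jnum[, j] <- (symbiosis_derivatives(st + e, pp) -
                      symbiosis_derivatives(st - e, pp)) / (2 * h)
    }
    expect_equal(J, Jnum, tolerance = 1e-5)
  }
})

test_that("integration respects the logistic limit, nonnegativity, and tolerance refinement", {
  p <- example_symbiosis_params("coexistence")
  tr <- simulate_symbiosis(p, c(0.05, 0, 0), t_end = 60)
  expect_equal(tr$H[nrow(tr)], p$K, tolerance = 1e-3)
  expect_equal(tr$S[nrow(tr)], 0)

  tr2 <- simulate_symbiosis(p, c(0.5, 0.4, 0.3), t_end = 50)
  expect_true(all(tr2$H >= 0 & tr2$S >= 0 & tr2$B >= 0))

  end1 <- simulate_symbiosis(p, c(0.5, 0.4, 0.3), t_end = 30)[200, ]
  end2 <- simulate_symbiosis(p, c(0.5, 0.4, 0.3), t_end = 30,
                             rtol = 5e-9, atol = 5e-11)[200, ]
  expect_equal(unlist(end1[c("H", "S", "B")]), unlist(end2[c("H", "S", "B")]),
               tolerance = 1e-6)

  expect_error(simulate_symbiosis(p, c(-1, 0, 0), 10),
               class = "holonet_parameter_error")
})

test_that("boundary densities follow the closed form and its invasion threshold", {
  p <- example_symbiosis_params("coexistence")
  expect_equal(boundary_lambda(p, 1, p$d1 / p$g1), 0)   # g H = d: threshold
  pp <- symbiosis_params(r = 1, K = 1, gamma1 = 0, gamma2 = 0, a1 = 0, a2 = 0,
                         g1 = 1, g2 = 1, b1 = 0, b2 = 0, d1 = 0.5, d2 = 0.5,
                         e1 = 0.5, e2 = 1, c1 = 0, c2 = 0)
  expect_equal(boundary_lambda(pp, 1, 1), 2)            # direct substitution
})

test_that("equilibrium finding returns the origin, the coral-only point, and consistent boundary states", {
  found_boundary <- 0
  for (s in 1:20) {
    pp <- random_params(300 + s)
    eqs <- find_equilibria(pp)
    expect_true(any(eqs$kind == "trivial"))
    co <- eqs[eqs$kind == "coral-only", ]
    expect_equal(co$H, pp$K, tolerance = 1e-8)
    expect_true(all(eqs$residual < 1e-8))
    ca <- eqs[eqs$kind == "coral-algal", ]
    if (nrow(ca) > 0) {
      found_boundary <- found_boundary + 1
      # solver's S* equals the closed form evaluated at its coral biomass
      expect_equal(ca$S, ca$lambda_1, tolerance = 1e-6)
    }
  }
  expect_gt(found_boundary, 5)
})

test_that("stability labels agree with long-horizon simulation from perturbed starts", {
  for (rg in c("mutualism", "parasitism", "coexistence")) {
    p <- example_symbiosis_params(rg)
    eqs <- find_equilibria(p)
    st <- eqs[eqs$stability == "stable", ]
    expect_gte(nrow(st), 1)
    eq <- unlist(st[1, c("H", "S", "B")])
    start <- pmax(eq + c(0.01, -0.01, 0.01) * (eq + 0.05), 0)
    tr <- simulate_symbiosis(p, start, t_end = 400)
    expect_equal(unname(unlist(tr[nrow(tr), c("H", "S", "B")])),
                 unname(eq), tolerance = 1e-4)
  }
})

test_that("nullclines match the boundary line and vanish at interior equilibria", {
  p <- example_symbiosis_params("parasitism")
  iso <- isoclines(p, plane = "HS", fixed = 0, xmax = 2, ymax = 3)
  sline <- iso[iso$rate == "S", ]
  expect_gt(nrow(sline), 10)
  pred <- (1 / p$e1) * ((p$g1 / p$d1) * sline$x - 1)
  keep <- pred >= 0 & pred <= 3
  expect_equal(sline$y[keep], pred[keep], tolerance = 1e-6)

  # per-capita rates vanish at a coexistence equilibrium
  eqs <- find_equilibria(p)
  cx <- eqs[eqs$kind == "coexistence" & eqs$stability == "stable", ]
  st <- unlist(cx[1, c("H", "S", "B")])
  expect_equal(symbiosis_derivatives(st, p) / st, c(0, 0, 0),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(isoclines(p, xmax = -1), class = "holonet_parameter_error")
})

test_that("regimes are classified as designed: benefit, cost, and competition structure", {
  expect_equal(classify_regime(example_symbiosis_params("mutualism"))$association,
               "mutualism")
  pr <- classify_regime(example_symbiosis_params("parasitism"))
  expect_equal(pr$association, "parasitism")
  expect_lt(pr$h_star, 1)
  expect_equal(classify_regime(example_symbiosis_params("coexistence"))$coexistence,
               "coexistence")
  ex <- classify_regime(example_symbiosis_params("exclusion"))
  expect_false(ex$coexistence == "coexistence")

  # pure-cost construction: gamma = 0 with persisting symbionts is parasitic
  p0 <- symbiosis_params(r = 1, K = 1, gamma1 = 0, gamma2 = 0, a1 = 0.2,
                         a2 = 0.05, g1 = 1, g2 = 0.6, b1 = 0, b2 = 0,
                         d1 = 0.3, d2 = 0.4, e1 = 1, e2 = 1,
                         c1 = 0.1, c2 = 0.1)
  cl0 <- classify_regime(p0)
  expect_equal(cl0$association, "parasitism")
  expect_lt(cl0$h_star, p0$K)
})

test_that("parameter validation rejects non-positive death terms", {
  expect_error(symbiosis_params(r = 1, K = 1, gamma1 = 0, gamma2 = 0, a1 = 0,
                                a2 = 0, g1 = 1, g2 = 1, b1 = 0, b2 = 0,
                                d1 = 0, d2 = 0.5, e1 = 1, e2 = 1,
                                c1 = 0, c2 = 0),
               class = "holonet_parameter_error")
  expect_error(symbiosis_params(r = -1, K = 1, gamma1 = 0, gamma2 = 0, a1 = 0,
                                a2 = 0, g1 = 1, g2 = 1, b1 = 0, b2 = 0,
                                d1 = 0.3, d2 = 0.5, e1 = 1, e2 = 1,
                                c1 = 0, c2 = 0),
               class = "holonet_parameter_error")
})
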