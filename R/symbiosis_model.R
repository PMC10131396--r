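# Tripartite coral-Symbiodiniaceae-prokaryote dynamical model.
#
# State (H, S, B): coral biomass, Symbiodiniaceae community density,
# prokaryotic community density. Rates:
#   dH/dt = r H (1 - H / (K + gamma1 S + gamma2 S B)) - a1 S H - a2 B H
#   dS/dt = g1 H S (1 + b1 B) - d1 S (1 + e1 S + c1 B)
#   dB/dt = g2 H B (1 + b2 S) - d2 B (1 + e2 B + c2 S)
# Coral grows logistically with a capacity raised by its partners'
# contributions (gamma terms) and pays linear costs (a terms); each microbial
# partner grows with host biomass, gains from the other partner (b terms),
# and dies at density-dependent rates (d, e) with interference competition
# between the two microbial compartments (c terms).

#' Construct and validate symbiosis model parameters
#'
#' @param r Coral independent growth rate.
#' @param K Environmental carrying capacity of the coral.
#' @param gamma1,gamma2 Benefits Symbiodiniaceae / prokaryotes provide to
#'   the coral (capacity increments).
#' @param a1,a2 Costs of Symbiodiniaceae / prokaryotes to the coral.
#' @param g1,g2 Independent growth rates of Symbiodiniaceae / prokaryotes.
#' @param b1,b2 Benefits each microbial partner receives from the other.
#' @param d1,d2 Independent death rates (> 0).
#' @param e1,e2 Density-dependent death rates (> 0; boundary equilibrium
#'   formulas divide by them).
#' @param c1,c2 Competition between Symbiodiniaceae and prokaryotes.
#' @return Named list of class `symbiosis_params`.
#' @export
symbiosis_params <- function(r, K, gamma1, gamma2, a1, a2, g1, g2,
                             b1, b2, d1, d2, e1, e2, c1, c2) {
  p <- list(r = r, K = K, gamma1 = gamma1, gamma2 = gamma2, a1 = a1, a2 = a2,
            g1 = g1, g2 = g2, b1 = b1, b2 = b2, d1 = d1, d2 = d2,
            e1 = e1, e2 = e2, c1 = c1, c2 = c2)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    ho_stop("all symbiosis parameters must be finite and nonnegative",
            "holonet_parameter_error")
  }
  if (p$d1 <= 0 || p$d2 <= 0 || p$e1 <= 0 || p$e2 <= 0 || p$K <= 0) {
    ho_stop("d1, d2, e1, e2 and K must be strictly positive",
            "holonet_parameter_error")
  }
  class(p) <- "symbiosis_params"
  p
}

#' Illustrative parameter sets spanning the model's regimes
#'
#' Named example parameterizations (not estimates from any dataset) chosen
#' to land in the mutualism, parasitism, coexistence and competitive
#' exclusion regimes of the model.
#'
#' @param regime One of `"mutualism"`, `"parasitism"`, `"coexistence"`,
#'   `"exclusion"`.
#' @return A `symbiosis_params` object.
#' @export
example_symbiosis_params <- function(regime = c("mutualism", "parasitism",
                                                "coexistence", "exclusion")) {
  regime <- match.arg(regime)
  switch(regime,
    # strong capacity benefit, low cost: coral equilibrates above K
    mutualism = symbiosis_params(
      r = 1, K = 1, gamma1 = 0.8, gamma2 = 0.2, a1 = 0.05, a2 = 0.05,
      g1 = 0.5, g2 = 0.5, b1 = 0.1, b2 = 0.1, d1 = 0.3, d2 = 0.35,
      e1 = 3, e2 = 1, c1 = 0.2, c2 = 0.2),
    # no benefit, pure cost: symbionts persist but drag H below K
    parasitism = symbiosis_params(
      r = 1, K = 1, gamma1 = 0, gamma2 = 0, a1 = 0.25, a2 = 0.1,
      g1 = 1, g2 = 0.8, b1 = 0.05, b2 = 0.05, d1 = 0.3, d2 = 0.35,
      e1 = 1, e2 = 1, c1 = 0.2, c2 = 0.2),
    # moderate benefits and mild competition: interior equilibrium
    coexistence = symbiosis_params(
      r = 1, K = 1, gamma1 = 2, gamma2 = 0.5, a1 = 0.1, a2 = 0.05,
      g1 = 0.8, g2 = 0.7, b1 = 0.1, b2 = 0.1, d1 = 0.3, d2 = 0.3,
      e1 = 1, e2 = 1, c1 = 0.3, c2 = 0.3),
    # fierce mutual interference: one microbial partner excluded
    exclusion = symbiosis_params(
      r = 1, K = 1, gamma1 = 1, gamma2 = 0.2, a1 = 0.1, a2 = 0.1,
      g1 = 0.8, g2 = 0.7, b1 = 0, b2 = 0, d1 = 0.3, d2 = 0.3,
      e1 = 0.5, e2 = 0.5, c1 = 8, c2 = 8)
  )
}

#' Right-hand side of the symbiosis model
#'
#' Exact algebraic evaluation of the three rate equations at a state. On the
#' coordinate planes (any compartment at zero) the corresponding rate
#' component vanishes, so the planes are invariant.
#'
#' @param state Numeric vector `c(H, S, B)` (nonnegative).
#' @param params A `symbiosis_params` object.
#' @return Numeric vector `c(dH, dS, dB)`.
#' @export
symbiosis_derivatives <- function(state, params) {
  H <- state[[1]]; S <- state[[2]]; B <- state[[3]]
  p <- params
  D <- p$K + p$gamma1 * S + p$gamma2 * S * B
  if (D == 0) ho_stop("singular capacity: K + gamma1*S + gamma2*S*B = 0",
                      "holonet_numerical_error")
  c(
    p$r * H * (1 - H / D) - p$a1 * S * H - p$a2 * B * H,
    p$g1 * H * S * (1 + p$b1 * B) - p$d1 * S * (1 + p$e1 * S + p$c1 * B),
    p$g2 * H * B * (1 + p$b2 * S) - p$d2 * B * (1 + p$e2 * B + p$c2 * S)
  )
}

#' Analytic Jacobian of the symbiosis model
#'
#' @inheritParams symbiosis_derivatives
#' @return 3x3 Jacobian matrix of the rate equations at `state`.
#' @export
symbiosis_jacobian <- function(state, params) {
  H <- state[[1]]; S <- state[[2]]; B <- state[[3]]
  p <- params
  D <- p$K + p$gamma1 * S + p$gamma2 * S * B
  j11 <- p$r * (1 - 2 * H / D) - p$a1 * S - p$a2 * B
  j12 <- p$r * H^2 * (p$gamma1 + p$gamma2 * B) / D^2 - p$a1 * H
  j13 <- p$r * H^2 * (p$gamma2 * S) / D^2 - p$a2 * H
  j21 <- p$g1 * S * (1 + p$b1 * B)
  j22 <- p$g1 * H * (1 + p$b1 * B) - p$d1 * (1 + 2 * p$e1 * S + p$c1 * B)
  j23 <- p$g1 * H * S * p$b1 - p$d1 * S * p$c1
  j31 <- p$g2 * B * (1 + p$b2 * S)
  j32 <- p$g2 * H * B * p$b2 - p$d2 * B * p$c2
  j33 <- p$g2 * H * (1 + p$b2 * S) - p$d2 * (1 + 2 * p$e2 * B + p$c2 * S)
  matrix(c(j11, j21, j31, j12, j22, j32, j13, j23, j33), 3, 3)
}

#' Integrate the symbiosis model
#'
#' Adaptive-step integration (deSolve's `lsoda`) from a nonnegative initial
#' state. Tiny negative excursions within solver tolerance are clipped to
#' zero in the returned trajectory.
#'
#' @param params A `symbiosis_params`.
#' @param initial Numeric `c(H, S, B)`, nonnegative.
#' @param t_end End time (> 0).
#' @param times Output times (default 200 points over `[0, t_end]`).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return Tibble with columns `time`, `H`, `S`, `B`.
#' @export
simulate_symbiosis <- function(params, initial, t_end, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  if (t_end <= 0) ho_stop("t_end must be > 0", "holonet_parameter_error")
  if (any(initial < 0)) ho_stop("initial state must be nonnegative",
                                "holonet_parameter_error")
  times <- times %||% seq(0, t_end, length.out = 200)
  rhs <- function(t, y, parms) list(symbiosis_derivatives(y, params))
  sol <- deSolve::ode(y = c(H = initial[[1]], S = initial[[2]], B = initial[[3]]),
                      times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    ho_stop("ODE integration failed (possible stiffness); see deSolve diagnostics",
            "holonet_numerical_error")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  for (cc in c("H", "S", "B")) out[[cc]][out[[cc]] < 0 & out[[cc]] > -10 * atol] <- 0
  out
}

#' Boundary partner density at a given coral biomass
#'
#' The closed-form boundary density `lambda_i = (1 / e_i) ((g_i / d_i) *
#' H_bar - 1)` of microbial compartment `i` (1 = Symbiodiniaceae, 2 =
#' prokaryotes) evaluated at a boundary coral biomass `H_bar` (the coral
#' biomass when the other compartment is absent). Negative values signal
#' that the compartment cannot invade at that coral biomass.
#'
#' @param params A `symbiosis_params`.
#' @param i Microbial compartment: 1 (Symbiodiniaceae) or 2 (prokaryote).
#' @param H_bar Boundary coral biomass.
#' @return The boundary density (may be negative).
#' @export
boundary_lambda <- function(params, i, H_bar) {
  if (!i %in% c(1, 2)) ho_stop("i must be 1 or 2", "holonet_parameter_error")
  g <- if (i == 1) params$g1 else params$g2
  d <- if (i == 1) params$d1 else params$d2
  e <- if (i == 1) params$e1 else params$e2
  (1 / e) * ((g / d) * H_bar - 1)
}

# Boundary coral biomass values H_bar on the plane where one microbial
# compartment is absent, found by scanning the 1D reduced system for sign
# changes and polishing with uniroot. absent = "B": coral-algal plane (B = 0,
# S > 0); absent = "S": coral-prokaryote plane.
boundary_coral_biomass <- function(params, absent = c("B", "S"),
                                   h_max = NULL, n_grid = 2000) {
  absent <- match.arg(absent)
  p <- params
  if (absent == "B") {
    h_min <- p$d1 / p$g1     # below this the partner density is negative
    dens <- function(H) (1 / p$e1) * ((p$g1 / p$d1) * H - 1)
    g <- function(H) {
      S <- dens(H)
      p$r * (1 - H / (p$K + p$gamma1 * S)) - p$a1 * S
    }
  } else {
    h_min <- p$d2 / p$g2
    dens <- function(H) (1 / p$e2) * ((p$g2 / p$d2) * H - 1)
    g <- function(H) {
      B <- dens(H)
      p$r * (1 - H / p$K) - p$a2 * B
    }
  }
  h_max <- h_max %||% max(4 * p$K, 4 * h_min)
  hs <- seq(h_min * (1 + 1e-9) + 1e-12, h_max, length.out = n_grid)
  vals <- vapply(hs, g, numeric(1))
  roots <- numeric(0)
  sgn <- sign(vals)
  for (k in seq_len(n_grid - 1)) {
    if (is.finite(vals[k]) && is.finite(vals[k + 1]) && sgn[k] * sgn[k + 1] < 0) {
      rt <- stats::uniroot(g, c(hs[k], hs[k + 1]), tol = 1e-12)$root
      roots <- c(roots, rt)
    } else if (vals[k] == 0) {
      roots <- c(roots, hs[k])
    }
  }
  roots[dens(roots) > 0]
}

# Newton iteration with the analytic Jacobian; returns the root or NULL.
.newton_root <- function(params, start, tol = 1e-12, max_iter = 100) {
  x <- start
  for (k in seq_len(max_iter)) {
    f <- symbiosis_derivatives(x, params)
    if (max(abs(f)) < tol) return(x)
    J <- symbiosis_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    x <- x - step
    if (any(!is.finite(x)) || max(abs(x)) > 1e6) return(NULL)
  }
  if (max(abs(symbiosis_derivatives(x, params))) < tol) x else NULL
}

#' Find and classify equilibria of the symbiosis model
#'
#' Assembles the trivial and coral-only fixed points, solves the boundary
#' planes (one microbial compartment absent) via their 1D reductions, and
#' searches for interior (coexistence) equilibria by multistart Newton
#' iteration with the analytic Jacobian. Each equilibrium is classified by
#' the sign of the largest real part of the Jacobian eigenvalues
#' (`stable` / `unstable` / `marginal` at tolerance 1e-8), and the boundary
#' invasion densities `lambda_1`, `lambda_2` (see [boundary_lambda()]) are
#' recorded at its coral biomass.
#'
#' @param params A `symbiosis_params`.
#' @param tol Residual tolerance for accepting a fixed point.
#' @param dedupe_tol Equilibria closer than this (absolute) are merged.
#' @return Tibble: `H`, `S`, `B`, `kind` (`trivial`, `coral-only`,
#'   `coral-algal`, `coral-prokaryote`, `coexistence`), `stability`,
#'   `max_re_eigen`, `residual`, `lambda_1`, `lambda_2`.
#' @export
find_equilibria <- function(params, tol = 1e-9, dedupe_tol = 1e-6) {
  p <- params
  eqs <- list(c(0, 0, 0), c(p$K, 0, 0))

  for (H in boundary_coral_biomass(p, "B")) {
    eqs <- c(eqs, list(c(H, boundary_lambda(p, 1, H), 0)))
  }
  for (H in boundary_coral_biomass(p, "S")) {
    eqs <- c(eqs, list(c(H, 0, boundary_lambda(p, 2, H))))
  }

  # multistart Newton for interior roots, seeded from combinations of the
  # boundary solutions and coarse fractions of K
  h_seeds <- unique(c(p$K * c(0.3, 0.7, 1, 1.5, 2.5),
                      vapply(eqs, `[[`, numeric(1), 1)))
  s_seeds <- unique(c(0.2, 0.8, 2, pmax(vapply(eqs, `[[`, numeric(1), 2), 0.1)))
  b_seeds <- unique(c(0.2, 0.8, 2, pmax(vapply(eqs, `[[`, numeric(1), 3), 0.1)))
  for (H0 in h_seeds) for (S0 in s_seeds) for (B0 in b_seeds) {
    if (H0 <= 0 || S0 <= 0 || B0 <= 0) next
    rt <- .newton_root(p, c(H0, S0, B0))
    if (is.null(rt)) next
    if (any(rt < -1e-8)) next
    rt <- pmax(rt, 0)
    eqs <- c(eqs, list(rt))
  }

  # dedupe and keep genuine fixed points
  keep <- list()
  for (e in eqs) {
    if (max(abs(symbiosis_derivatives(e, p))) > max(tol, 1e-9)) next
    dup <- any(vapply(keep, function(k) max(abs(k - e)) < dedupe_tol, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- e
  }

  zt <- 1e-7
  rows <- lapply(keep, function(e) {
    J <- symbiosis_jacobian(e, p)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    kind <- if (e[1] < zt && e[2] < zt && e[3] < zt) "trivial"
    else if (e[2] < zt && e[3] < zt) "coral-only"
    else if (e[3] < zt && e[2] >= zt) "coral-algal"
    else if (e[2] < zt && e[3] >= zt) "coral-prokaryote"
    else "coexistence"
    tibble::tibble(
      H = e[1], S = e[2], B = e[3], kind = kind,
      stability = if (mre < -1e-8) "stable" else if (mre > 1e-8) "unstable" else "marginal",
      max_re_eigen = mre,
      residual = max(abs(symbiosis_derivatives(e, p))),
      lambda_1 = boundary_lambda(p, 1, e[1]),
      lambda_2 = boundary_lambda(p, 2, e[1])
    )
  })
  dplyr::bind_rows(rows)
}

#' Nullcline point sets in a coordinate plane
#'
#' Zero-level curves of the per-capita rate of each compartment, restricted
#' to a plane with the third variable fixed. The coordinate axes are
#' trivially nullclines of their own variable and are omitted; the curves
#' returned are the non-trivial (per-capita) branches, suitable for
#' phase-plane plots. Curves are located by sign-change scanning with
#' linear interpolation on a regular grid.
#'
#' @param params A `symbiosis_params`.
#' @param plane `"HS"` (B fixed), `"HB"` (S fixed) or `"SB"` (H fixed).
#' @param fixed Value of the third variable (default 0).
#' @param xmax,ymax Upper grid bounds for the two free variables.
#' @param n Grid resolution per axis.
#' @return Tibble: `rate` (which compartment's nullcline), `x`, `y`, with
#'   the plane's axis names in attributes `xvar`/`yvar`.
#' @export
isoclines <- function(params, plane = c("HS", "HB", "SB"), fixed = 0,
                      xmax = 3, ymax = 3, n = 201) {
  plane <- match.arg(plane)
  if (xmax <= 0 || ymax <= 0) ho_stop("grid bounds must be positive",
                                      "holonet_parameter_error")
  p <- params
  percap <- list(
    H = function(H, S, B) p$r * (1 - H / (p$K + p$gamma1 * S + p$gamma2 * S * B)) -
      p$a1 * S - p$a2 * B,
    S = function(H, S, B) p$g1 * H * (1 + p$b1 * B) -
      p$d1 * (1 + p$e1 * S + p$c1 * B),
    B = function(H, S, B) p$g2 * H * (1 + p$b2 * S) -
      p$d2 * (1 + p$e2 * B + p$c2 * S)
  )
  vars <- strsplit(plane, "")[[1]]
  assemble <- function(x, y) {
    st <- stats::setNames(c(x, y, fixed), c(vars, setdiff(c("H", "S", "B"), vars)))
    st[c("H", "S", "B")]
  }
  xs <- seq(0, xmax, length.out = n)
  ys <- seq(0, ymax, length.out = n)
  rows <- list()
  for (rate in c("H", "S", "B")) {
    f <- function(x, y) {
      st <- assemble(x, y)
      percap[[rate]](st[["H"]], st[["S"]], st[["B"]])
    }
    pts_x <- numeric(0); pts_y <- numeric(0)
    # scan along y for each x
    for (x in xs) {
      v <- vapply(ys, function(y) f(x, y), numeric(1))
      ch <- which(v[-n] * v[-1] < 0)
      for (k in ch) {
        w <- v[k] / (v[k] - v[k + 1])
        pts_x <- c(pts_x, x)
        pts_y <- c(pts_y, ys[k] + w * (ys[k + 1] - ys[k]))
      }
      z <- which(v == 0)
      pts_x <- c(pts_x, rep(x, length(z))); pts_y <- c(pts_y, ys[z])
    }
    if (length(pts_x)) {
      rows[[rate]] <- tibble::tibble(rate = rate, x = pts_x, y = pts_y)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "xvar") <- vars[1]
  attr(out, "yvar") <- vars[2]
  attr(out, "fixed") <- stats::setNames(fixed, setdiff(c("H", "S", "B"), vars))
  out
}

#' Classify the symbiosis regime of a parameter set
#'
#' Two labels derived from the stable equilibria: (i) the coral-algal
#' association is *mutualistic* when a stable equilibrium with
#' Symbiodiniaceae present has coral biomass above the symbiont-free
#' capacity `K`, and *parasitic* when below it; (ii) the microbial partners
#' *coexist* when a stable equilibrium has both S and B positive, otherwise
#' the excluded partner is named. With multiple stable equilibria all are
#' reported and basins are flagged as unresolved.
#'
#' @param params A `symbiosis_params`.
#' @param tol Density threshold below which a compartment counts as absent.
#' @return List: `association` (`"mutualism"`, `"parasitism"` or
#'   `"no-symbiosis"`), `coexistence` (`"coexistence"`,
#'   `"prokaryote-excluded"`, `"symbiodiniaceae-excluded"` or
#'   `"both-absent"`), `h_star`, `K`, `bistable`, `equilibria` (the full
#'   table).
#' @export
classify_regime <- function(params, tol = 1e-7) {
  eqs <- find_equilibria(params)
  stable <- eqs[eqs$stability == "stable", , drop = FALSE]
  with_s <- stable[stable$S > tol, , drop = FALSE]
  association <- if (nrow(with_s) == 0) "no-symbiosis"
  else if (max(with_s$H) > params$K) "mutualism" else "parasitism"
  h_star <- if (nrow(with_s)) max(with_s$H) else NA_real_
  coexist <- if (any(stable$S > tol & stable$B > tol)) "coexistence"
  else if (any(stable$S > tol)) "prokaryote-excluded"
  else if (any(stable$B > tol)) "symbiodiniaceae-excluded"
  else "both-absent"
  list(association = association, coexistence = coexist,
       h_star = h_star, K = params$K,
       bistable = nrow(stable) > 1, equilibria = eqs)
}
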