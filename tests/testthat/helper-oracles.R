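# Independent oracles used to cross-check the closed-form solutions.
# These deliberately avoid the code paths they validate.

# Supply-coupled assimilation as the root of A = f(Ca - A/g_tot),
# found by bracketed root-finding rather than the quadratic formula.
coupled_oracle <- function(ca, g_s, g_m, a_sat, ce, omega, gamma) {
  g_tot <- g_s * g_m / (g_s + g_m)
  p <- nrh_params(a_sat, ce, omega, gamma, basis = "Cm")
  g <- function(a) a - nrh_assimilation(ca - a / g_tot, p)
  lo <- -a_sat - ce * max(gamma - ca, 0) - 10
  stats::uniroot(g, lower = lo, upper = a_sat, tol = 1e-13)$root
}

# Lower root of the light-response quadratic by bisection on the
# quadratic itself.
light_oracle <- function(ppfd, y_ll, ga_sat, m) {
  q <- function(ga) m * ga^2 - (y_ll * ppfd + ga_sat) * ga +
    y_ll * ppfd * ga_sat
  lo <- 0; hi <- min(ga_sat, y_ll * ppfd)
  if (q(lo) == 0) return(lo)
  stats::uniroot(q, lower = lo - 1e-9, upper = hi, tol = 1e-13)$root
}

# Coarse grid search over the four NRH parameters; returns the smallest
# sum of squared residuals found on the grid.
nrh_grid_sse <- function(driver, a, a_sat_grid, ce_grid, omega_grid,
                         gamma_grid) {
  best <- Inf
  for (as in a_sat_grid) for (ce in ce_grid)
    for (om in omega_grid) for (ga in gamma_grid) {
      p <- nrh_params(as, ce, om, ga)
      sse <- sum((nrh_assimilation(driver, p) - a)^2)
      if (sse < best) best <- sse
    }
  best
}

light_grid_sse <- function(ppfd, a, y_grid, ga_grid, m_grid) {
  best <- Inf
  for (y in y_grid) for (g in ga_grid) for (m in m_grid) {
    p <- light_params(y, g, m)
    sse <- sum((light_assimilation(ppfd, p) - a)^2)
    if (sse < best) best <- sse
  }
  best
}

# Random valid parameter draws for property tests (seeded by caller).
draw_supply_inputs <- function(n) {
  data.frame(
    ca = runif(n, 120, 800),
    g_s = runif(n, 0.02, 1),
    g_m = runif(n, 0.02, 1),
    a_sat = runif(n, 5, 40),
    ce = runif(n, 0.02, 0.3),
    omega = runif(n, 0.05, 0.99),
    gamma = runif(n, 20, 60)
  )
}

healthy_supply_state <- function() {
  ps_state("healthy operational", "supply",
           c(ca = 420, g_s = 0.063, g_m = 0.35, a_sat = 26, ce = 0.18,
             omega = 0.54, gamma = 45))
}
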