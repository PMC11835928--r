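# Closed-form model layer: hyperbolas, supply chain, coupled solution,
# flattening, mechanistic conversion.

healthy_ci <- nrh_params(26, 0.12, 0.7, 45, basis = "Ci")
healthy_cm <- nrh_params(26, 0.18, 0.54, 45, basis = "Cm")

test_that("CO2-response hyperbola returns the lower physical root", {
  expect_equal(nrh_assimilation(420, healthy_ci), 20.7,
               tolerance = 0.05 / 20.7)
  expect_equal(nrh_assimilation(24, healthy_ci), -2.59,
               tolerance = 0.01 / 2.59)
  # zero exactly at the compensation point, for any valid curve
  expect_equal(nrh_assimilation(45, healthy_ci), 0)
  expect_equal(nrh_assimilation(45, nrh_params(13, 0.3, 0.95, 45)), 0)
  # saturates from below and increases strictly
  cc <- seq(0, 5000, by = 25)
  a <- nrh_assimilation(cc, healthy_ci)
  expect_true(all(diff(a) > 0))
  expect_true(all(a <= healthy_ci$a_sat))
  expect_equal(nrh_assimilation(1e7, healthy_ci), 26, tolerance = 1e-4)
  # lower-root envelope: never above the initial-slope line either
  expect_true(all(a <= healthy_ci$ce * (cc - healthy_ci$gamma) + 1e-9))
})

test_that("curvature edge cases use the analytic limits", {
  # omega = 0: rectangular hyperbola a_sat*x/(x + a_sat)
  p0 <- nrh_params(20, 0.1, 0, 40)
  x <- 0.1 * (300 - 40)
  expect_equal(nrh_assimilation(300, p0), 20 * x / (x + 20))
  # omega = 1: Blackman response, min of the two envelopes
  p1 <- nrh_params(20, 0.1, 1, 40)
  expect_equal(nrh_assimilation(c(100, 2000), p1),
               pmin(0.1 * (c(100, 2000) - 40), 20))
})

test_that("light-response hyperbola matches its quadratic", {
  p <- light_params(0.05, 25, 0.7)
  expect_equal(light_assimilation(0, p), 0)
  expect_equal(light_assimilation(1e6, p), 25, tolerance = 0.01 / 25)
  expect_equal(light_assimilation(500, p),
               light_oracle(500, 0.05, 25, 0.7), tolerance = 1e-9)
  ppfd <- seq(0, 3000, by = 20)
  expect_true(all(diff(light_assimilation(ppfd, p)) > 0))
})

test_that("total conductance is the series combination", {
  expect_equal(total_conductance(conductances(0.063, 0.35)),
               0.063 * 0.35 / (0.063 + 0.35))
  expect_equal(total_conductance(conductances(0.2, 0.2)), 0.1)
  expect_equal(total_conductance(conductances(0.063, 1e6)), 0.063,
               tolerance = 1e-6)
  g <- conductances(0.1, 0.4)
  expect_lt(total_conductance(g), min(g$g_s, g$g_m))
  expect_error(conductances(-0.1, 0.3), "positive")
})

test_that("mesophyll supply function and its inverse behave", {
  expect_equal(cm_from_ci(420, 20.7, 0.35), 420 - 20.7 / 0.35)
  expect_equal(round(cm_from_ci(420, 20.7, 0.35)), 361)
  expect_equal(cm_from_ci(24, -2.59, 0.35), 24 + 2.59 / 0.35)
  expect_equal(cm_from_ci(150, 0, 0.35), 150)
  # below compensation the gradient reverses
  expect_gt(cm_from_ci(24, -2.59, 0.35), 24)
  expect_error(cm_from_ci(10, 20, 0.35), "negative")
})

test_that("operational stomatal conductance follows the CO2 gradient", {
  expect_equal(operational_gs(operational_point(13.9, 200, 420)),
               0.063, tolerance = 0.01)
  expect_equal(operational_gs(operational_point(11, 220, 420)), 0.055)
  expect_equal(operational_gs(operational_point(0, 300, 420)), 0)
  expect_error(operational_point(10, 420, 420), "exceed")
})

test_that("coupled supply-demand solution hits the worked examples", {
  expect_equal(
    coupled_assimilation(420, conductances(0.063, 0.35), healthy_cm),
    13.9, tolerance = 0.15 / 13.9)
  treated_cm <- nrh_params(19, 0.14, 0.54, 45, basis = "Cm")
  expect_equal(
    coupled_assimilation(420, conductances(0.055, 0.25), treated_cm),
    11, tolerance = 0.15 / 11)
  # unhindered diffusion reduces to the bare demand curve at Ca
  expect_equal(
    coupled_assimilation(420, conductances(1e6, 1e6), healthy_cm),
    nrh_assimilation(420, healthy_cm), tolerance = 1e-7)
  expect_equal(nrh_assimilation(420, healthy_cm), 21.5,
               tolerance = 0.1 / 21.5)
  expect_error(coupled_assimilation(420, conductances(0.1, 0.3),
                                    healthy_ci), "Cm-based")
})

test_that("coupled solution equals the bracketing oracle on random draws", {
  set.seed(42)
  d <- draw_supply_inputs(1000)
  for (i in seq_len(nrow(d))) {
    p <- nrh_params(d$a_sat[i], d$ce[i], d$omega[i], d$gamma[i],
                    basis = "Cm")
    a <- coupled_assimilation(d$ca[i], conductances(d$g_s[i], d$g_m[i]),
                              p)
    o <- coupled_oracle(d$ca[i], d$g_s[i], d$g_m[i], d$a_sat[i],
                        d$ce[i], d$omega[i], d$gamma[i])
    expect_equal(a, o, tolerance = 1e-8)
  }
})

test_that("coupled solution is monotone in its drivers", {
  set.seed(7)
  d <- draw_supply_inputs(200)
  bump <- 1.05
  for (i in seq_len(nrow(d))) {
    g <- conductances(d$g_s[i], d$g_m[i])
    p <- nrh_params(d$a_sat[i], d$ce[i], d$omega[i], d$gamma[i],
                    basis = "Cm")
    a0 <- coupled_assimilation(d$ca[i], g, p)
    expect_gte(coupled_assimilation(d$ca[i] * bump, g, p), a0)
    expect_gte(coupled_assimilation(
      d$ca[i], conductances(d$g_s[i] * bump, d$g_m[i]), p), a0)
    expect_gte(coupled_assimilation(
      d$ca[i], conductances(d$g_s[i], d$g_m[i] * bump), p), a0)
    p2 <- nrh_params(d$a_sat[i] * bump, d$ce[i], d$omega[i],
                     d$gamma[i], basis = "Cm")
    if (d$ca[i] > d$gamma[i])
      expect_gte(coupled_assimilation(d$ca[i], g, p2), a0 - 1e-12)
  }
})

test_that("flattening reproduces the treated-plant estimate", {
  mu <- 26 / 0.12
  fl <- flattened_ce(11, 220, mu, 0.7, 45)
  expect_equal(fl$ce, 0.088, tolerance = 0.01)
  expect_equal(fl$a_sat, 19.1, tolerance = 0.01)
  # the flattened curve passes exactly through the operational point
  p <- nrh_params(fl$a_sat, fl$ce, 0.7, 45)
  expect_equal(nrh_assimilation(220, p), 11, tolerance = 1e-6 / 11)
  # independent bisection on CE with a_sat = mu*ce imposed
  f <- function(ce) nrh_assimilation(
    220, nrh_params(mu * ce, ce, 0.7, 45)) - 11
  ce_bis <- uniroot(f, c(1e-6, 1), tol = 1e-12)$root
  expect_equal(fl$ce, ce_bis, tolerance = 1e-8)
})

test_that("flattening is self-consistent and degenerates gracefully", {
  p <- nrh_params(26, 0.12, 0.7, 45)
  a <- nrh_assimilation(300, p)
  fl <- flattened_ce(a, 300, 26 / 0.12, 0.7, 45)
  expect_equal(fl$ce, 0.12, tolerance = 1e-10)
  expect_lt(flattened_ce(1e-8, 300, 26 / 0.12, 0.7, 45)$ce, 1e-7)
  # for omega <= 1 the inner radicand is provably non-negative, so the
  # unreachable-point guard can only trip on out-of-range curvature
  expect_error(flattened_ce(20, 45 + 26 / 0.12, 26 / 0.12, 1.2, 45),
               "not reachable")
  expect_error(flattened_ce(-1, 300, 26 / 0.12, 0.7, 45), "positive")
  expect_error(flattened_ce(10, 30, 26 / 0.12, 0.7, 45), "exceed")
})

test_that("mechanistic parameters convert to the empirical set", {
  p3 <- mechanistic_to_empirical(60, 500, 104, 0, "C3", gamma = 45)
  expect_equal(p3$ce, 0.12)
  expect_equal(p3$a_sat, 26)
  expect_equal(p3$omega, 0.7)
  p4 <- mechanistic_to_empirical(120, 80, 110, 1, "C4", gamma = 3)
  expect_equal(p4$a_sat, 19)
  expect_error(mechanistic_to_empirical(60, 500, 8, 5, "C3",
                                        gamma = 45), "respiration")
})
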