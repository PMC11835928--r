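# The named analysis recipes on the embedded worked-example plants.

healthy <- load_fixture("healthy")
treated <- load_fixture("treated")

test_that("stomatal limitation matches the closed form and the example", {
  res <- stomatal_limitation(healthy$fits$ci, healthy$operational)
  expect_equal(res$summary$L_stomatal, 0.33, tolerance = 0.01 / 0.33)
  expect_equal(res$summary$a_potential, 20.7, tolerance = 0.1 / 20.7)
  # telescoping: identical to direct evaluation at the two Ci values
  a_op <- nrh_assimilation(200, healthy$fits$ci)
  a_ca <- nrh_assimilation(420, healthy$fits$ci)
  expect_equal(res$summary$L_stomatal, (a_ca - a_op) / a_ca,
               tolerance = 1e-10)
  # a plant already at Ci = Ca has nothing to gain
  none <- stomatal_limitation(healthy$fits$ci,
                              operational_point(20.7, 420 - 1e-9, 420))
  expect_equal(none$summary$L_stomatal, 0, tolerance = 1e-9)
})

test_that("diffusional limitation lifts the whole chain", {
  res <- diffusional_limitation(healthy$fits$cm, healthy$g, ca = 420)
  expect_equal(res$summary$a_potential, 21.5, tolerance = 0.1 / 21.5)
  expect_equal(res$summary$L_diffusional, 0.36, tolerance = 0.012)
  # closed form: (A_free - A_op)/A_free with A from the coupled model
  a_op <- coupled_assimilation(420, healthy$g, healthy$fits$cm)
  a_free <- nrh_assimilation(420, healthy$fits$cm)
  expect_equal(res$summary$L_diffusional, (a_free - a_op) / a_free,
               tolerance = 1e-3)
  # already-free diffusion leaves nothing to lift
  none <- diffusional_limitation(healthy$fits$cm,
                                 conductances(1e6, 1e6), ca = 420,
                                 g_high = 1e6 + 1)
  expect_lt(abs(none$summary$L_diffusional), 1e-6)
})

test_that("stomatal/non-stomatal analysis splits the treated shortfall", {
  res <- stomatal_nonstomatal(healthy$fits$ci, treated$operational,
                              treated_fit = treated$fits$ci)
  expect_equal(res$summary$a_intermediate, 15.2,
               tolerance = 0.1 / 15.2)
  expect_equal(res$summary$L_stomatal, 0.20, tolerance = 0.01 / 0.20)
  expect_equal(res$summary$L_nonstomatal, 0.26,
               tolerance = 0.01 / 0.26)
  expect_equal(res$summary$a_potential, 20.7, tolerance = 0.1 / 20.7)
})

test_that("flattening stands in when the treated curve is unmeasured", {
  res <- stomatal_nonstomatal(healthy$fits$ci, treated$operational)
  # flattened estimate reproduces the printed treated fit
  expect_equal(res$summary$treated_params$ce, 0.09, tolerance = 0.02)
  expect_equal(res$summary$treated_params$a_sat, 19, tolerance = 0.01)
  expect_equal(res$summary$L_stomatal, 0.20, tolerance = 0.01 / 0.20)
  # a "treated" plant identical to the healthy one has no
  # non-stomatal limitation
  op_h <- operational_point(nrh_assimilation(200, healthy$fits$ci),
                            200, 420)
  same <- stomatal_nonstomatal(healthy$fits$ci, op_h,
                               treated_fit = healthy$fits$ci)
  expect_equal(same$summary$L_nonstomatal, 0, tolerance = 1e-9)
})

test_that("single-transition and two-tier variants agree", {
  two <- stomatal_nonstomatal(healthy$fits$ci, treated$operational,
                              treated_fit = treated$fits$ci)
  one <- stomatal_nonstomatal(healthy$fits$ci, treated$operational,
                              treated_fit = treated$fits$ci,
                              variant = "single")
  tol <- abs(two$closure) + abs(one$closure) +
    1e-3 * abs(two$delta_omega)
  expect_equal(one$summary$L_stomatal, two$summary$L_stomatal,
               tolerance = tol)
  expect_equal(one$summary$L_nonstomatal, two$summary$L_nonstomatal,
               tolerance = tol)
  expect_equal(one$omega_end, two$omega_end, tolerance = 1e-6)
})

test_that("treatment contributions reconcile with the endpoint change", {
  res <- treatment_contributions(
    list(fit = healthy$fits$cm, g = healthy$g),
    list(fit = treated$fits$cm, g = treated$g), ca = 420)
  s <- res$summary
  # all components of the imposed treatment reduce assimilation
  expect_lt(s$xi_stomatal, 0)
  expect_lt(s$xi_mesophyll, 0)
  expect_lt(s$xi_non_diffusional, 0)
  expect_equal(s$xi_diffusional + s$xi_non_diffusional,
               s$a_treated - s$a_healthy,
               tolerance = 1e-2 * abs(res$delta_omega))
  expect_equal(s$a_healthy, 13.9, tolerance = 0.15 / 13.9)
  expect_equal(s$a_treated, 11, tolerance = 0.15 / 11)
  # no treatment, no contributions
  expect_error(treatment_contributions(
    list(fit = healthy$fits$cm, g = healthy$g),
    list(fit = healthy$fits$cm, g = healthy$g), ca = 420),
    "no input changes")
})

test_that("control analysis normalises shares and obeys the identity", {
  st <- healthy_supply_state()
  ctl <- control_analysis(st, c("g_s", "g_m", "a_sat", "ce"))
  expect_equal(sum(ctl$rho), 1, tolerance = 1e-6)
  # log-derivative identity eta = S * a / f at small i
  f0 <- state_assimilation(st)
  expect_equal(ctl$elasticity, ctl$sensitivity * ctl$value / f0,
               tolerance = 1e-4)
  # the stomatal elasticity at the healthy operational state is about
  # one half: marginally, half of any relative g_s change reaches A
  expect_equal(ctl$elasticity[ctl$input == "g_s"], 0.5,
               tolerance = 0.1)
  # shares respond to i only at second order
  ctl2 <- control_analysis(st, c("g_s", "g_m", "a_sat", "ce"),
                           i = 1e-5)
  expect_equal(ctl$rho, ctl2$rho, tolerance = 1e-3)
})

test_that("light limitation mirrors the CO2 machinery", {
  p <- light_params(0.05, 25, 0.7)
  res <- light_limitation(p, ppfd_op = 400, ppfd_max = 1800)
  ga_op <- light_assimilation(400, p)
  ga_max <- light_assimilation(1800, p)
  expect_equal(res$summary$L_light, (ga_max - ga_op) / ga_max,
               tolerance = 1e-10)
  # no shading, no limitation; full darkness loses everything
  expect_equal(light_limitation(p, 1800, 1800 + 1e-9)$summary$L_light,
               0, tolerance = 1e-9)
  expect_equal(light_limitation(p, 0, 1800)$summary$L_light, 1)
})

test_that("light/non-light variants split shading from downregulation", {
  hp <- light_params(0.05, 25, 0.7)
  tp <- light_params(0.04, 18, 0.7)
  two <- light_nonlight(hp, tp, ppfd_op = 350, ppfd_max = 1800)
  expect_gt(two$summary$L_light, 0)
  expect_gt(two$summary$L_nonlight, 0)
  expect_equal(two$summary$ga_intermediate, light_assimilation(1800, tp))
  # identical plants: the non-light share vanishes
  same <- light_nonlight(hp, hp, ppfd_op = 350, ppfd_max = 1800)
  expect_equal(same$summary$L_nonlight, 0, tolerance = 1e-9)
  # totals agree between variants within the finite-interval error
  one <- light_nonlight(hp, tp, ppfd_op = 350, ppfd_max = 1800,
                        variant = "single")
  expect_equal(one$summary$L_light + one$summary$L_nonlight,
               two$summary$L_light + two$summary$L_nonlight,
               tolerance = 1e-3)
})

test_that("path-dependent orderings bracket the simultaneous path", {
  h <- list(fit = healthy$fits$cm, g = healthy$g)
  t2 <- list(fit = treated$fits$cm, g = treated$g)
  sim <- treatment_contributions(h, t2, ca = 420)
  sf <- path_dependent_contributions(h, t2, ca = 420,
                                     order = "stomata-first")
  bf <- path_dependent_contributions(h, t2, ca = 420,
                                     order = "biochemistry-first")
  for (cls in c("xi_diffusional", "xi_non_diffusional")) {
    lo <- min(sf$summary[[cls]], bf$summary[[cls]])
    hi <- max(sf$summary[[cls]], bf$summary[[cls]])
    expect_gte(sim$summary[[cls]], lo - 1e-6)
    expect_lte(sim$summary[[cls]], hi + 1e-6)
    # the spread between orderings stays on the order of +/-20% of
    # the independent path
    expect_lt(hi - lo, 0.6 * abs(sim$summary[[cls]]))
  }
  # each ordering's total reconciles with the endpoint change (two
  # inputs move per leg, so closure is finite but shrinks in K)
  expect_lt(abs(sf$closure), 1e-3 * abs(sf$delta_omega))
  expect_lt(abs(bf$closure), 1e-3 * abs(bf$delta_omega))
  # additive models are path-independent: orders agree exactly
  f <- function(v) 2 * v$p + 3 * v$q
  seq_pq <- function(first) run_transition(ps_transition(list(
    ps_state("s1", f, c(p = 1, q = 5)),
    ps_state("mid", f, if (first == "p") c(p = 4, q = 5) else
      c(p = 1, q = 0)),
    ps_state("s2", f, c(p = 4, q = 0))), K = 8), control = FALSE)
  expect_equal(seq_pq("p")$contributions$xi_total,
               seq_pq("q")$contributions$xi_total)
})
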