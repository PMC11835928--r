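# The named restriction analyses: each composes the empirical models
# with the K-interval engine into one documented recipe.

# attach analysis-level summary entries onto a contribution_table
as_analysis <- function(res, analysis, summary) {
  res$analysis <- analysis
  res$summary <- summary
  res
}

sum_limitation <- function(res, inputs) {
  df <- res$contributions
  sum(df$limitation[df$input %in% inputs])
}

sum_xi <- function(res, inputs) {
  df <- res$contributions
  sum(df$xi_total[df$input %in% inputs])
}

#' Stomatal limitation of a single plant
#'
#' Quantifies the assimilation a leaf foregoes because its stomata admit
#' less CO2 than free diffusion would: a single transition on the
#' Ci-based response curve from the operational substomatal CO2
#' (`Ci = Ci_op`) to the hypothetical state where intercellular spaces
#' see ambient CO2 directly (`Ci = Ca`, i.e. stomatal conductance made
#' arbitrarily high). Setting `Ci = Ca` on the demand curve is exactly
#' the infinite-conductance limit, so no sentinel conductance value
#' enters the calculation.
#'
#' @param fit A Ci-based [nrh_params()] object (or a `fit_result`).
#' @param op The plant's [operational_point()].
#' @param K Intervals; default 1000.
#' @return A `contribution_table` whose `summary` holds `L_stomatal`
#'   (the limitation attributed to `Ci`), `a_operational`, and
#'   `a_potential`.
#' @export
#' @examples
#' fx <- load_fixture("healthy")
#' stomatal_limitation(fx$fits$ci, fx$operational)
stomatal_limitation <- function(fit, op, K = 1000) {
  params <- fit_params(fit, basis = "Ci")
  stopifnot(inherits(op, "operational_point"))
  base <- c(a_sat = params$a_sat, ce = params$ce, omega = params$omega,
            gamma = params$gamma)
  tr <- ps_transition(list(
    ps_state("operational", "aci", c(c = op$ci_op, base)),
    ps_state("Ci = Ca", "aci", c(c = op$ca, base))
  ), K = K)
  res <- run_transition(tr)
  as_analysis(res, "stomatal_limitation", list(
    L_stomatal = sum_limitation(res, "c"),
    a_operational = res$omega_start,
    a_potential = res$omega_end))
}

#' Diffusional limitation of a single plant
#'
#' Lifts the whole CO2 diffusion pathway at once: a single transition on
#' the supply-coupled model from the operational stomatal and mesophyll
#' conductances to arbitrarily high values, so the carboxylation sites
#' see ambient CO2 (`Cm -> Ca`). Uses the Cm-based curve parameters.
#'
#' The transition runs on the resistance scale (`r = 1/g` for each leg
#' of the diffusion chain): resistances in series add, so scaling them
#' linearly keeps the path smooth all the way to the free-diffusion
#' state and the closure residual vanishing in `K`. A linear path in
#' conductance would cross almost the whole physiological range inside
#' the first interval of the sentinel and leave a finite-interval error
#' that no `K` can remove. The per-input rows are reported against
#' `r_s` and `r_m`; their contributions are the stomatal and mesophyll
#' components.
#'
#' @param fit A Cm-based [nrh_params()] (or `fit_result`).
#' @param g Operational [conductances()].
#' @param ca Ambient CO2 mole fraction (umol mol-1).
#' @param g_high Sentinel "arbitrarily high" conductance
#'   (mol m-2 s-1); the default 1e6 makes the coupled solution agree
#'   with the uncoupled curve at `Ca` to well below 1e-6 umol m-2 s-1.
#' @param K Intervals; default 1000.
#' @return A `contribution_table`; `summary` holds `L_diffusional`
#'   (limitation summed over `g_s` and `g_m`), `L_stomatal`,
#'   `L_mesophyll`, `a_operational` and `a_potential`.
#' @export
diffusional_limitation <- function(fit, g, ca, g_high = 1e6, K = 1000) {
  params <- fit_params(fit, basis = "Cm")
  stopifnot(inherits(g, "conductances"))
  base <- c(ca = ca, a_sat = params$a_sat, ce = params$ce,
            omega = params$omega, gamma = params$gamma)
  tr <- ps_transition(list(
    ps_state("operational", "supply_r",
             c(r_s = 1 / g$g_s, r_m = 1 / g$g_m, base)),
    ps_state("free diffusion", "supply_r",
             c(r_s = 1 / g_high, r_m = 1 / g_high, base))
  ), K = K)
  res <- run_transition(tr)
  as_analysis(res, "diffusional_limitation", list(
    L_diffusional = sum_limitation(res, c("r_s", "r_m")),
    L_stomatal = sum_limitation(res, "r_s"),
    L_mesophyll = sum_limitation(res, "r_m"),
    a_operational = res$omega_start,
    a_potential = res$omega_end))
}

#' Stomatal and non-stomatal limitation of a treated plant
#'
#' Separates how much of a treated plant's shortfall below the healthy
#' plant's potential is stomatal and how much is not. If the treated
#' plant's own response curve was not measured, it is estimated by
#' flattening the healthy curve through the treated operational point
#' ([flattened_ce()]), holding `omega`, `gamma` and the ratio
#' `mu = A_SAT/CE` fixed (an actual `mu`, if known, should be passed).
#'
#' Two variants are offered. The **two-tier** path (default) lifts the
#' stomatal barrier first (`Ci -> Ca` on the treated curve) and then
#' drives the curve parameters to the healthy ones at constant `Ca`.
#' The **single** path runs one transition on the supply-coupled model
#' in which stomatal conductance rises from its operational value to
#' `g_high` while the parameters move to the healthy ones; because the
#' conductance path completes within the first intervals, the two
#' variants agree to within the closure tolerance.
#'
#' @param healthy_fit Ci-based [nrh_params()] of the healthy plant.
#' @param op Treated plant's [operational_point()].
#' @param treated_fit Optional Ci-based [nrh_params()] for the treated
#'   plant; when `NULL` the flattening estimate is used.
#' @param mu Optional `A_SAT/CE` ratio for flattening; defaults to the
#'   healthy fit's ratio.
#' @param variant `"two-tier"` or `"single"`.
#' @param g_high Sentinel conductance for the single variant.
#' @param K Intervals per leg.
#' @return A `contribution_table`; `summary` holds `L_stomatal` (the
#'   g_s-attributed share), `L_nonstomatal` (summed parameter
#'   limitations), `a_operational`, `a_intermediate` (two-tier only),
#'   `a_potential`, and the treated-curve parameters used.
#' @export
#' @examples
#' healthy <- load_fixture("healthy")
#' treated <- load_fixture("treated")
#' stomatal_nonstomatal(healthy$fits$ci, treated$operational,
#'                      treated_fit = treated$fits$ci)
stomatal_nonstomatal <- function(healthy_fit, op, treated_fit = NULL,
                                 mu = NULL,
                                 variant = c("two-tier", "single"),
                                 g_high = 1e6, K = 1000) {
  variant <- match.arg(variant)
  healthy <- fit_params(healthy_fit, basis = "Ci")
  stopifnot(inherits(op, "operational_point"))
  if (is.null(treated_fit)) {
    if (is.null(mu)) mu <- healthy$a_sat / healthy$ce
    fl <- flattened_ce(op$a_op, op$ci_op, mu, healthy$omega,
                       healthy$gamma)
    treated <- nrh_params(fl$a_sat, fl$ce, healthy$omega,
                          healthy$gamma, basis = "Ci")
  } else {
    treated <- fit_params(treated_fit, basis = "Ci")
  }

  tpar <- c(a_sat = treated$a_sat, ce = treated$ce,
            omega = treated$omega, gamma = treated$gamma)
  hpar <- c(a_sat = healthy$a_sat, ce = healthy$ce,
            omega = healthy$omega, gamma = healthy$gamma)

  if (variant == "two-tier") {
    st1 <- ps_state("treated operational", "aci", c(c = op$ci_op, tpar))
    st2 <- ps_state("Ci = Ca, treated curve", "aci", c(c = op$ca, tpar))
    st3 <- ps_state("healthy potential", "aci", c(c = op$ca, hpar))
    res <- run_transition(ps_transition(list(st1, st2, st3), K = K))
    L_st <- sum_limitation(res, "c")
    a_int <- state_assimilation(st2)
  } else {
    gs_op <- op$a_op / (op$ca - op$ci_op)
    st1 <- ps_state("treated operational", "supply",
                    c(ca = op$ca, g_s = gs_op, g_m = g_high, tpar))
    st3 <- ps_state("healthy potential", "supply",
                    c(ca = op$ca, g_s = g_high, g_m = g_high, hpar))
    res <- run_transition(ps_transition(list(st1, st3), K = K))
    L_st <- sum_limitation(res, "g_s")
    a_int <- NA_real_
  }
  nonstom <- setdiff(res$contributions$input, c("c", "g_s", "g_m"))
  as_analysis(res, "stomatal_nonstomatal", list(
    L_stomatal = L_st,
    L_nonstomatal = sum_limitation(res, nonstom),
    a_operational = res$omega_start,
    a_intermediate = a_int,
    a_potential = res$omega_end,
    treated_params = treated,
    variant = variant))
}

#' Stomatal, mesophyll and non-diffusional contributions of a treatment
#'
#' Partitions the change in operational assimilation between a healthy
#' and a treated plant into its stomatal, mesophyll, and biochemical
#' components in a single transition on the supply-coupled model:
#' `g_s`, `g_m`, `A_SAT` and `CE` all move linearly between the two
#' plants' values. If the treated plant's mesophyll conductance is
#' unknown, pass `g_high` for it in `treated$g` (and Ci-based parameter
#' sets), which reduces the diffusional term to its stomatal component.
#'
#' @param healthy,treated Lists with elements `fit` (Cm-based
#'   [nrh_params()]) and `g` ([conductances()]).
#' @param ca Ambient CO2 mole fraction, shared by both states.
#' @param K Intervals; default 1000.
#' @return A `contribution_table`; `summary` holds the per-class totals
#'   `xi_stomatal`, `xi_mesophyll`, `xi_diffusional`,
#'   `xi_non_diffusional`, and the start/end assimilation rates.
#' @export
#' @examples
#' h <- load_fixture("healthy"); t <- load_fixture("treated")
#' treatment_contributions(list(fit = h$fits$cm, g = h$g),
#'                         list(fit = t$fits$cm, g = t$g), ca = 420)
treatment_contributions <- function(healthy, treated, ca, K = 1000) {
  hfit <- fit_params(healthy$fit, basis = "Cm")
  tfit <- fit_params(treated$fit, basis = "Cm")
  stopifnot(inherits(healthy$g, "conductances"),
            inherits(treated$g, "conductances"))
  if (hfit$omega != tfit$omega || hfit$gamma != tfit$gamma)
    warning("omega/gamma differ between plants and will be ",
            "interpolated as additional inputs")
  st1 <- ps_state("healthy operational", "supply", c(
    ca = ca, g_s = healthy$g$g_s, g_m = healthy$g$g_m,
    a_sat = hfit$a_sat, ce = hfit$ce, omega = hfit$omega,
    gamma = hfit$gamma))
  st2 <- ps_state("treated operational", "supply", c(
    ca = ca, g_s = treated$g$g_s, g_m = treated$g$g_m,
    a_sat = tfit$a_sat, ce = tfit$ce, omega = tfit$omega,
    gamma = tfit$gamma))
  res <- run_transition(ps_transition(list(st1, st2), K = K))
  as_analysis(res, "treatment_contributions", list(
    xi_stomatal = sum_xi(res, "g_s"),
    xi_mesophyll = sum_xi(res, "g_m"),
    xi_diffusional = sum_xi(res, c("g_s", "g_m")),
    xi_non_diffusional = sum_xi(res,
      setdiff(res$contributions$input, c("g_s", "g_m"))),
    a_healthy = res$omega_start,
    a_treated = res$omega_end))
}

#' Control analysis at a single state
#'
#' Evaluates the model at a state and with each input in turn multiplied
#' by `(1 + i)`, reporting the absolute sensitivity `S`, the elasticity
#' `eta`, and each input's share `rho` of the summed marginal response
#' (the shares sum to one by construction).
#'
#' @param state A [ps_state()] object.
#' @param inputs Character vector of input names to perturb; defaults to
#'   every input of the state except the compensation point and, for the
#'   supply model, the ambient CO2 driver (i.e. `g_s`, `g_m`, `A_SAT`,
#'   `CE`, `omega`).
#' @param i Relative increment, default 1e-4.
#' @return A data frame of class `control_analysis` with columns
#'   `input`, `value`, `xi`, `sensitivity`, `elasticity`, `rho`.
#' @export
#' @examples
#' fx <- load_fixture("healthy")
#' st <- ps_state("healthy operational", "supply",
#'   c(ca = 420, g_s = 0.063, g_m = 0.35, a_sat = 26, ce = 0.18,
#'     omega = 0.54, gamma = 45))
#' control_analysis(st, c("g_s", "g_m", "a_sat", "ce"))
control_analysis <- function(state, inputs = NULL, i = 1e-4) {
  stopifnot(inherits(state, "ps_state"))
  if (!is.finite(i) || i <= 0) stop("'i' must be positive",
                                    call. = FALSE)
  if (is.null(inputs))
    inputs <- setdiff(names(state$inputs), c("gamma", "ca", "c",
                                             "ppfd"))
  bad <- setdiff(inputs, names(state$inputs))
  if (length(bad))
    stop("unknown input(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  f <- model_function(state$model)
  v <- state$inputs
  f0 <- f(as.list(v))
  rows <- lapply(inputs, function(nm) {
    vp <- v; vp[nm] <- v[nm] * (1 + i)
    xi <- f(as.list(vp)) - f0
    data.frame(
      input = nm, value = unname(v[nm]), xi = unname(xi),
      sensitivity = unname(xi / (v[nm] * i)),
      elasticity = if (v[nm] > 0 && f0 > 0 && f0 + xi > 0)
        unname((log(f0 + xi) - log(f0)) / log(1 + i)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$rho <- out$xi / sum(out$xi)
  structure(out, class = c("control_analysis", "data.frame"),
            i = i, f0 = f0)
}

#' Light limitation (or light contribution)
#'
#' A single transition of PPFD on the light-response hyperbola, from the
#' operational to the maximum light level. With `ppfd_max` set to the
#' hypothetical unshaded maximum this is a limitation analysis; with two
#' real light levels it quantifies the light contribution between them.
#' All quantities are on the gross-assimilation basis of the light
#' model.
#'
#' @param fit A [light_params()] object (or `fit_result`).
#' @param ppfd_op Operational PPFD (umol photons m-2 s-1).
#' @param ppfd_max Reference (maximum) PPFD.
#' @param K Intervals; default 1000.
#' @return A `contribution_table`; `summary` holds `L_light`,
#'   `ga_operational`, `ga_potential`.
#' @export
light_limitation <- function(fit, ppfd_op, ppfd_max, K = 1000) {
  params <- fit_params_light(fit)
  base <- c(y_ll = params$y_ll, ga_sat = params$ga_sat, m = params$m)
  tr <- ps_transition(list(
    ps_state("operational light", "light", c(ppfd = ppfd_op, base)),
    ps_state("full light", "light", c(ppfd = ppfd_max, base))
  ), K = K)
  res <- run_transition(tr)
  as_analysis(res, "light_limitation", list(
    L_light = sum_limitation(res, "ppfd"),
    ga_operational = res$omega_start,
    ga_potential = res$omega_end))
}

#' Light and non-light limitations of a treated plant
#'
#' Distinguishes the direct effect of shading from the downregulation of
#' biochemical potential in a treated plant. The two-tier variant lifts
#' the light limitation first (PPFD to `ppfd_max` on the treated light
#' curve) and then drives the curve parameters to the healthy ones; the
#' single variant moves PPFD and parameters in one leg.
#'
#' @param healthy_fit Healthy plant's [light_params()].
#' @param treated_fit Treated plant's [light_params()].
#' @param ppfd_op Treated plant's operational PPFD.
#' @param ppfd_max Unshaded reference PPFD.
#' @param variant `"two-tier"` or `"single"`.
#' @param K Intervals per leg.
#' @return A `contribution_table`; `summary` holds `L_light`,
#'   `L_nonlight`, `ga_operational`, `ga_intermediate` (two-tier),
#'   `ga_potential`.
#' @export
light_nonlight <- function(healthy_fit, treated_fit, ppfd_op, ppfd_max,
                           variant = c("two-tier", "single"),
                           K = 1000) {
  variant <- match.arg(variant)
  healthy <- fit_params_light(healthy_fit)
  treated <- fit_params_light(treated_fit)
  tpar <- c(y_ll = treated$y_ll, ga_sat = treated$ga_sat,
            m = treated$m)
  hpar <- c(y_ll = healthy$y_ll, ga_sat = healthy$ga_sat,
            m = healthy$m)
  st1 <- ps_state("treated, shaded", "light", c(ppfd = ppfd_op, tpar))
  st3 <- ps_state("healthy, full light", "light",
                  c(ppfd = ppfd_max, hpar))
  if (variant == "two-tier") {
    st2 <- ps_state("treated, full light", "light",
                    c(ppfd = ppfd_max, tpar))
    res <- run_transition(ps_transition(list(st1, st2, st3), K = K))
    ga_int <- state_assimilation(st2)
  } else {
    res <- run_transition(ps_transition(list(st1, st3), K = K))
    ga_int <- NA_real_
  }
  as_analysis(res, "light_nonlight", list(
    L_light = sum_limitation(res, "ppfd"),
    L_nonlight = sum_limitation(res,
      setdiff(res$contributions$input, "ppfd")),
    ga_operational = res$omega_start,
    ga_intermediate = ga_int,
    ga_potential = res$omega_end,
    variant = variant))
}

#' Path-dependent contribution variants (for comparison only)
#'
#' Classical contribution analyses assumed stomata respond before the
#' biochemistry, or the reverse; both orderings are provided here solely
#' to demonstrate their spread around the simultaneous (independent)
#' path of [treatment_contributions()]. Path-dependent orderings are
#' not recommended for inference: during a real treatment all
#' characteristics respond concurrently.
#'
#' @inheritParams treatment_contributions
#' @param order `"stomata-first"` or `"biochemistry-first"`.
#' @return A `contribution_table` (two legs); `summary` as in
#'   [treatment_contributions()], plus the ordering.
#' @export
path_dependent_contributions <- function(healthy, treated, ca,
                                         order = c("stomata-first",
                                                   "biochemistry-first"),
                                         K = 1000) {
  order <- match.arg(order)
  hfit <- fit_params(healthy$fit, basis = "Cm")
  tfit <- fit_params(treated$fit, basis = "Cm")
  h <- c(ca = ca, g_s = healthy$g$g_s, g_m = healthy$g$g_m,
         a_sat = hfit$a_sat, ce = hfit$ce, omega = hfit$omega,
         gamma = hfit$gamma)
  t2 <- c(ca = ca, g_s = treated$g$g_s, g_m = treated$g$g_m,
          a_sat = tfit$a_sat, ce = tfit$ce, omega = tfit$omega,
          gamma = tfit$gamma)
  mid <- h
  first <- if (order == "stomata-first") c("g_s", "g_m") else
    c("a_sat", "ce", "omega", "gamma")
  mid[first] <- t2[first]
  res <- run_transition(ps_transition(list(
    ps_state("healthy operational", "supply", h),
    ps_state(paste0("after ", order, " leg"), "supply", mid),
    ps_state("treated operational", "supply", t2)
  ), K = K))
  as_analysis(res, "path_dependent_contributions", list(
    xi_stomatal = sum_xi(res, "g_s"),
    xi_mesophyll = sum_xi(res, "g_m"),
    xi_diffusional = sum_xi(res, c("g_s", "g_m")),
    xi_non_diffusional = sum_xi(res,
      setdiff(res$contributions$input, c("g_s", "g_m"))),
    order = order,
    a_healthy = res$omega_start,
    a_treated = res$omega_end))
}

# accept nrh_params or fit_result; check basis
fit_params <- function(fit, basis) {
  if (inherits(fit, "fit_result")) fit <- fit$params
  if (!inherits(fit, "nrh_params"))
    stop("expected an nrh_params or fit_result object", call. = FALSE)
  if (fit$basis != basis)
    stop("expected a ", basis, "-based parameter set, got ",
         fit$basis, call. = FALSE)
  fit
}

fit_params_light <- function(fit) {
  if (inherits(fit, "fit_result")) fit <- fit$params
  if (!inherits(fit, "light_params"))
    stop("expected a light_params or fit_result object", call. = FALSE)
  fit
}
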