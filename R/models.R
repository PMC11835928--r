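# Empirical photosynthesis models: non-rectangular hyperbolas for the CO2
# and light responses, the diffusional supply chain, the coupled
# supply--demand solution, and the curve-flattening estimator.

#' Non-rectangular hyperbola parameters for a CO2-response curve
#'
#' Bundles the four empirical parameters of the non-rectangular hyperbola
#' (NRH) that describes the response of net assimilation `A` to CO2 mole
#' fraction, either in the substomatal cavity (`Ci` basis) or at the
#' mesophyll carboxylation sites (`Cm` basis).
#'
#' @param a_sat CO2-saturated assimilation rate `A_SAT`
#'   (umol m-2 s-1); must be positive.
#' @param ce Initial slope (carboxylation efficiency) `CE`
#'   (mol m-2 s-1); must be positive.
#' @param omega Curvature of the hyperbola, dimensionless, in (0, 1].
#'   `omega = 0` is accepted and treated as the rectangular-hyperbola
#'   limit.
#' @param gamma CO2 compensation point: the x-intercept of the curve
#'   (umol mol-1); must be non-negative.
#' @param basis Which CO2 mole fraction the curve is expressed against:
#'   `"Ci"` or `"Cm"`.
#'
#' @return An object of class `nrh_params`.
#' @seealso [nrh_assimilation()], [fit_nrh()]
#' @export
#' @examples
#' healthy <- nrh_params(26, 0.12, 0.7, 45, basis = "Ci")
#' nrh_assimilation(420, healthy)
nrh_params <- function(a_sat, ce, omega, gamma, basis = c("Ci", "Cm")) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(a_sat), is.numeric(ce), is.numeric(omega),
            is.numeric(gamma))
  if (!is.finite(a_sat) || a_sat <= 0)
    stop("'a_sat' must be a positive, finite rate", call. = FALSE)
  if (!is.finite(ce) || ce <= 0)
    stop("'ce' must be a positive, finite slope", call. = FALSE)
  if (!is.finite(omega) || omega < 0 || omega > 1)
    stop("'omega' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("'gamma' must be non-negative", call. = FALSE)
  structure(
    list(a_sat = a_sat, ce = ce, omega = omega, gamma = gamma,
         basis = basis),
    class = "nrh_params"
  )
}

#' @export
print.nrh_params <- function(x, ...) {
  cat("Non-rectangular hyperbola (", x$basis, " basis)\n", sep = "")
  cat(sprintf("  A_SAT = %g umol m-2 s-1\n  CE    = %g mol m-2 s-1\n",
              x$a_sat, x$ce))
  cat(sprintf("  omega = %g\n  Gamma = %g umol mol-1\n", x$omega, x$gamma))
  invisible(x)
}

#' Light-response curve parameters
#'
#' Parameters of the non-rectangular hyperbola describing the dependence
#' of gross assimilation on photosynthetic photon flux density (PPFD).
#'
#' @param y_ll Initial quantum yield `Y(CO2)_LL`
#'   (umol CO2 umol photons-1); positive.
#' @param ga_sat Light-saturated gross assimilation `GA_SAT`
#'   (umol m-2 s-1); positive.
#' @param m Curvature, dimensionless, in (0, 1] (0 accepted as the
#'   rectangular limit).
#'
#' @return An object of class `light_params`.
#' @seealso [light_assimilation()], [fit_light()]
#' @export
light_params <- function(y_ll, ga_sat, m) {
  if (!is.finite(y_ll) || y_ll <= 0)
    stop("'y_ll' must be positive", call. = FALSE)
  if (!is.finite(ga_sat) || ga_sat <= 0)
    stop("'ga_sat' must be positive", call. = FALSE)
  if (!is.finite(m) || m < 0 || m > 1)
    stop("'m' must lie in [0, 1]", call. = FALSE)
  structure(list(y_ll = y_ll, ga_sat = ga_sat, m = m),
            class = "light_params")
}

#' @export
print.light_params <- function(x, ...) {
  cat("Light-response hyperbola\n")
  cat(sprintf("  Y(CO2)_LL = %g umol CO2 umol photons-1\n", x$y_ll))
  cat(sprintf("  GA_SAT    = %g umol m-2 s-1\n  m         = %g\n",
              x$ga_sat, x$m))
  invisible(x)
}

#' Stomatal and mesophyll conductances to CO2
#'
#' @param g_s Stomatal conductance to CO2 (mol m-2 s-1); positive.
#' @param g_m Mesophyll conductance to CO2 (mol m-2 s-1); positive.
#' @return An object of class `conductances`.
#' @export
conductances <- function(g_s, g_m) {
  if (!is.finite(g_s) || g_s <= 0)
    stop("'g_s' must be positive", call. = FALSE)
  if (!is.finite(g_m) || g_m <= 0)
    stop("'g_m' must be positive", call. = FALSE)
  structure(list(g_s = g_s, g_m = g_m), class = "conductances")
}

#' Operational gas-exchange point
#'
#' The condition a leaf attains under its growth environment: measured
#' net assimilation, substomatal CO2, and ambient CO2 (plus, optionally,
#' the mesophyll CO2 mole fraction).
#'
#' @param a_op Net assimilation (umol m-2 s-1).
#' @param ci_op Substomatal CO2 mole fraction (umol mol-1).
#' @param ca Ambient CO2 mole fraction (umol mol-1).
#' @param cm_op Optional CO2 mole fraction at the carboxylation sites
#'   (umol mol-1).
#' @return An object of class `operational_point`.
#' @export
operational_point <- function(a_op, ci_op, ca, cm_op = NULL) {
  stopifnot(is.finite(a_op), is.finite(ci_op), is.finite(ca))
  if (a_op > 0 && ca <= ci_op)
    stop("'ca' must exceed 'ci_op' when assimilation is positive",
         call. = FALSE)
  if (!is.null(cm_op)) {
    stopifnot(is.finite(cm_op))
    if (a_op > 0 && cm_op > ci_op)
      stop("'cm_op' cannot exceed 'ci_op' when assimilation is positive",
           call. = FALSE)
  }
  structure(list(a_op = a_op, ci_op = ci_op, ca = ca, cm_op = cm_op),
            class = "operational_point")
}

# Lower root of omega*A^2 - (x + asat)*A + asat*x = 0 where
# x = ce*(c - gamma) (or y_ll*ppfd for the light response). Vectorised.
# The lower root is the physical branch: A <= a_sat and A <= x.
nrh_lower_root <- function(x, a_sat, omega) {
  n <- max(length(x), length(a_sat), length(omega))
  x <- rep_len(x, n); a_sat <- rep_len(a_sat, n); omega <- rep_len(omega, n)
  b <- x + a_sat
  disc <- b^2 - 4 * omega * a_sat * x
  tiny <- disc < 0 & disc > -1e-9 * pmax(b^2, 1)
  disc[tiny] <- 0
  if (any(disc < 0))
    stop("negative discriminant in hyperbola: parameters are corrupted ",
         "(requires a_sat > 0, 0 <= omega <= 1)", call. = FALSE)
  out <- numeric(n)
  rect <- omega < 1e-12
  if (any(rect)) {
    if (any(b[rect] <= 0))
      stop("rectangular-hyperbola limit undefined: x + a_sat <= 0",
           call. = FALSE)
    out[rect] <- a_sat[rect] * x[rect] / b[rect]
  }
  out[!rect] <- (b[!rect] - sqrt(disc[!rect])) / (2 * omega[!rect])
  out
}

#' Assimilation from the CO2-response hyperbola
#'
#' Evaluates the non-rectangular hyperbola at CO2 mole fraction `c`,
#' returning the lower (physical) root of its quadratic form. `A` is zero
#' exactly at `c = gamma`, negative below it, strictly increasing in `c`,
#' and approaches `a_sat` as `c` grows. At `omega = 0` the analytic
#' rectangular-hyperbola limit is used.
#'
#' @param c CO2 mole fraction (umol mol-1), on the curve's basis
#'   (`Ci` or `Cm`); may be a vector. Values below `gamma` are permitted
#'   and yield negative assimilation.
#' @param params An [nrh_params()] object.
#' @return Net assimilation (umol m-2 s-1), same length as `c`.
#' @export
#' @examples
#' p <- nrh_params(26, 0.12, 0.7, 45)
#' nrh_assimilation(c(24, 200, 420), p)
nrh_assimilation <- function(c, params) {
  stopifnot(inherits(params, "nrh_params"))
  if (any(!is.finite(c)))
    stop("'c' must be finite", call. = FALSE)
  nrh_lower_root(params$ce * (c - params$gamma), params$a_sat,
                 params$omega)
}

#' Gross assimilation from the light-response hyperbola
#'
#' Lower root of the light-response quadratic
#' `m*GA^2 - (y_ll*PPFD + ga_sat)*GA + y_ll*PPFD*ga_sat = 0`.
#' `GA` is zero at zero light and saturates at `ga_sat`.
#'
#' @param ppfd Photosynthetic photon flux density
#'   (umol photons m-2 s-1), non-negative; may be a vector.
#' @param params A [light_params()] object.
#' @return Gross assimilation (umol m-2 s-1).
#' @export
light_assimilation <- function(ppfd, params) {
  stopifnot(inherits(params, "light_params"))
  if (any(!is.finite(ppfd) | ppfd < 0))
    stop("'ppfd' must be finite and non-negative", call. = FALSE)
  nrh_lower_root(params$y_ll * ppfd, params$ga_sat, params$m)
}

#' Total conductance of the CO2 diffusion pathway
#'
#' Series combination of stomatal and mesophyll conductances,
#' `g_Tot = g_s * g_m / (g_s + g_m)`. Always smaller than either leg.
#'
#' @param g A [conductances()] object.
#' @return Total conductance (mol m-2 s-1).
#' @export
total_conductance <- function(g) {
  stopifnot(inherits(g, "conductances"))
  g$g_s * g$g_m / (g$g_s + g$g_m)
}

#' Mesophyll CO2 mole fraction from the supply function
#'
#' `Cm = Ci - A / g_m`: the draw-down across the mesophyll at flux `A`.
#' Below the compensation point (`A < 0`) `Cm` exceeds `Ci`.
#'
#' @param ci Substomatal CO2 mole fraction (umol mol-1); vectorised.
#' @param a Net assimilation (umol m-2 s-1); vectorised.
#' @param g_m Mesophyll conductance (mol m-2 s-1), positive scalar.
#' @return Mesophyll CO2 mole fraction (umol mol-1).
#' @export
cm_from_ci <- function(ci, a, g_m) {
  if (!is.finite(g_m) || g_m <= 0)
    stop("'g_m' must be positive", call. = FALSE)
  cm <- ci - a / g_m
  if (any(cm < 0))
    stop("computed Cm is negative: check 'g_m' and units", call. = FALSE)
  cm
}

#' Operational stomatal conductance from the CO2 gradient
#'
#' `g_s = A_op / (Ca - Ci_op)`: the conductance implied by the measured
#' operational point.
#'
#' @param op An [operational_point()] object.
#' @return Stomatal conductance to CO2 (mol m-2 s-1).
#' @export
#' @examples
#' operational_gs(operational_point(13.9, 200, 420)) # 0.063
operational_gs <- function(op) {
  stopifnot(inherits(op, "operational_point"))
  if (op$ca == op$ci_op)
    stop("'ca' equals 'ci_op': conductance is undefined", call. = FALSE)
  op$a_op / (op$ca - op$ci_op)
}

#' Assimilation with the demand curve coupled to the CO2 supply chain
#'
#' Solves the intersection of the Cm-based demand hyperbola with the
#' diffusional supply function `Cm = Ca - A/g_Tot`. Substituting the
#' supply function into the hyperbola's quadratic form gives, with
#' `r = 1/g_Tot`,
#' \deqn{(\omega + CE\,r)\,A^2 - [CE(C_a-\Gamma) + A_{SAT}(1 + CE\,r)]\,A
#'       + A_{SAT}\,CE\,(C_a-\Gamma) = 0,}
#' of which the lower root is returned. As both conductances grow the
#' solution reduces to [nrh_assimilation()] at `Ca`.
#'
#' @param ca Ambient CO2 mole fraction (umol mol-1); vectorised.
#' @param g A [conductances()] object.
#' @param params An [nrh_params()] object on the `Cm` basis.
#' @return Net assimilation (umol m-2 s-1).
#' @export
#' @examples
#' p <- nrh_params(26, 0.18, 0.54, 45, basis = "Cm")
#' coupled_assimilation(420, conductances(0.063, 0.35), p) # ~13.8
coupled_assimilation <- function(ca, g, params) {
  stopifnot(inherits(g, "conductances"), inherits(params, "nrh_params"))
  if (params$basis != "Cm")
    stop("'params' must be Cm-based for the coupled solution",
         call. = FALSE)
  coupled_lower_root(ca, g$g_s, g$g_m, params$a_sat, params$ce,
                     params$omega, params$gamma)
}

# Vectorised core of the supply-coupled quadratic; shared with the
# framework's model registry.
coupled_lower_root <- function(ca, g_s, g_m, a_sat, ce, omega, gamma) {
  if (any(g_s <= 0) || any(g_m <= 0))
    stop("conductances must be positive", call. = FALSE)
  r <- (g_s + g_m) / (g_s * g_m)       # 1 / g_Tot
  x <- ce * (ca - gamma)
  a2 <- omega + ce * r                 # > 0 even at omega = 0
  b <- x + a_sat * (1 + ce * r)
  disc <- b^2 - 4 * a2 * a_sat * x
  tiny <- disc < 0 & disc > -1e-9 * pmax(b^2, 1)
  disc[tiny] <- 0
  if (any(disc < 0))
    stop("no real root for the supply-coupled quadratic; ",
         "check parameters", call. = FALSE)
  (b - sqrt(disc)) / (2 * a2)
}

#' Flatten a CO2-response curve through an operational point
#'
#' Estimates the initial slope `CE'` of a plant whose response curve was
#' not measured, by forcing the healthy curve through the plant's
#' operational point `(c, a)` while holding the curvature `omega`, the
#' compensation point `gamma`, and the ratio `mu = A_SAT/CE` fixed.
#' Solving the hyperbola for `CE` under `A_SAT = mu * CE` gives
#' \deqn{CE' = \frac{A(\mu + C - \Gamma)
#'   + \sqrt{[A(\Gamma - C - \mu)]^2 - 4\omega A^2 \mu (C-\Gamma)}}
#'   {2\mu(C-\Gamma)},}
#' the positive branch. The flattened curve
#' `(mu*CE', CE', omega, gamma)` passes through `(c, a)` exactly.
#'
#' @param a Measured net assimilation at the operational point
#'   (umol m-2 s-1), positive.
#' @param c CO2 mole fraction at the operational point (umol mol-1),
#'   above `gamma`.
#' @param mu Ratio `A_SAT/CE` to preserve (umol mol-1), positive.
#' @param omega,gamma Curvature and compensation point held fixed.
#' @return A list with components `ce` (`CE'`, mol m-2 s-1) and
#'   `a_sat` (`A_SAT' = mu * CE'`).
#' @export
#' @examples
#' flattened_ce(11, 220, mu = 26 / 0.12, omega = 0.7, gamma = 45)
flattened_ce <- function(a, c, mu, omega, gamma) {
  if (!is.finite(a) || a <= 0)
    stop("'a' must be positive", call. = FALSE)
  if (!is.finite(c) || c <= gamma)
    stop("'c' must exceed 'gamma'", call. = FALSE)
  if (!is.finite(mu) || mu <= 0)
    stop("'mu' must be positive", call. = FALSE)
  rad <- (a * (gamma - c - mu))^2 - 4 * omega * a^2 * mu * (c - gamma)
  if (rad < 0)
    stop("point (", c, ", ", a, ") is not reachable by any curve with ",
         "mu = ", mu, ", omega = ", omega, ", gamma = ", gamma,
         call. = FALSE)
  ce <- (a * (mu + c - gamma) + sqrt(rad)) / (2 * mu * (c - gamma))
  list(ce = ce, a_sat = mu * ce)
}

#' Approximate empirical parameters from mechanistic ones
#'
#' Converts enzyme-level parameters into the empirical hyperbola:
#' `CE = V_MAX / K` (carboxylase maximum rate over its O2-adjusted
#' Michaelis-Menten constant), and `A_SAT = J/4 - R_L` for C3 leaves or
#' `A_SAT = J_ATP/5.5 - R_L` for C4 leaves. The curvature defaults to
#' 0.7; the compensation point is supplied by the caller (typically a
#' literature value). For a closer conversion, generate a synthetic
#' response curve from the mechanistic model and refit it with
#' [fit_nrh()] (see [synthesize_curve()]).
#'
#' @param v_max Carboxylase maximum rate (umol m-2 s-1).
#' @param k Michaelis-Menten constant (umol mol-1), positive.
#' @param j Electron-transport rate (C3) or ATP-production rate (C4)
#'   (umol m-2 s-1).
#' @param r_l Light respiration (umol m-2 s-1).
#' @param pathway `"C3"` or `"C4"`.
#' @param gamma Compensation point to carry over (umol mol-1).
#' @param omega Curvature; defaults to 0.7.
#' @param basis Basis of the resulting curve; defaults to `"Cm"`.
#' @return An [nrh_params()] object.
#' @export
mechanistic_to_empirical <- function(v_max, k, j, r_l = 0,
                                     pathway = c("C3", "C4"),
                                     gamma, omega = 0.7, basis = "Cm") {
  pathway <- match.arg(pathway)
  stopifnot(v_max >= 0, j >= 0, r_l >= 0)
  if (!is.finite(k) || k <= 0)
    stop("'k' must be positive", call. = FALSE)
  a_sat <- if (pathway == "C3") j / 4 - r_l else j / 5.5 - r_l
  if (a_sat <= 0)
    stop("respiration exceeds the electron-transport-supported rate: ",
         "A_SAT would be non-positive", call. = FALSE)
  nrh_params(a_sat = a_sat, ce = v_max / k, omega = omega, gamma = gamma,
             basis = basis)
}
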