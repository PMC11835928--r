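# Least-squares estimation of response-curve parameters, curve
# transformation between the Ci and Cm bases, and synthetic-curve
# generation.

#' Gas-exchange response curve
#'
#' Ordered (driver, assimilation) observations with metadata. The driver
#' is substomatal CO2 (`Ci`), mesophyll CO2 (`Cm`), or light (`PPFD`).
#' Points are sorted by driver; duplicated driver values are rejected.
#'
#' @param driver Numeric driver values.
#' @param a Net (or, for light curves, gross) assimilation
#'   (umol m-2 s-1).
#' @param kind `"Ci"`, `"Cm"`, or `"PPFD"`.
#' @param plant Optional plant label.
#' @param ca Optional ambient CO2 (umol mol-1).
#' @param g_m Optional mesophyll conductance (mol m-2 s-1).
#' @return An object of class `response_curve` (a data frame with
#'   columns `driver` and `a` plus attributes).
#' @export
response_curve <- function(driver, a, kind = c("Ci", "Cm", "PPFD"),
                           plant = NULL, ca = NULL, g_m = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(driver), is.numeric(a),
            length(driver) == length(a))
  if (any(!is.finite(driver)) || any(!is.finite(a)))
    stop("curve values must be finite", call. = FALSE)
  ord <- order(driver)
  driver <- driver[ord]; a <- a[ord]
  if (anyDuplicated(driver))
    stop("duplicated driver values in curve", call. = FALSE)
  structure(data.frame(driver = driver, a = a),
            kind = kind, plant = plant, ca = ca, g_m = g_m,
            class = c("response_curve", "data.frame"))
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve (%s driver, %d points%s)\n",
              attr(x, "kind"), nrow(x),
              if (is.null(attr(x, "plant"))) "" else
                paste0(", plant: ", attr(x, "plant"))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

curve_kind <- function(curve) attr(curve, "kind")

# residual sum of squares of an NRH parameter vector against a curve
nrh_sse <- function(par, driver, a) {
  pred <- nrh_lower_root(par[["ce"]] * (driver - par[["gamma"]]),
                         par[["a_sat"]], par[["omega"]])
  sum((pred - a)^2)
}

#' Fit the CO2-response hyperbola to a curve
#'
#' Estimates `(A_SAT, CE, omega, Gamma)` by nonlinear least squares
#' (Levenberg-Marquardt with box bounds). Starting values follow simple
#' curve geometry: `Gamma` from linear interpolation of the sign change
#' in `A`, `CE` from the slope of the two lowest-driver points, `A_SAT`
#' from 1.05 x the largest observed `A`, and `omega = 0.7`. On
#' non-convergence the fit is restarted from three jittered starts; a
#' still-unconverged result is returned flagged, never silently.
#'
#' @param curve A [response_curve()] with a `Ci` or `Cm` driver and at
#'   least 5 points.
#' @param fix_gamma,fix_omega Optional fixed values for the compensation
#'   point and curvature (both are commonly held fixed when comparing
#'   treatments, on the rationale that they reflect enzymatic
#'   properties).
#' @param start Optional named list overriding the starting values.
#' @return An object of class `fit_result`: `params` ([nrh_params()]),
#'   `rmse` (umol m-2 s-1), `converged`, and `fixed` (named logical).
#' @export
#' @examples
#' fx <- load_fixture("healthy")
#' fit_nrh(fx$curves$aci)
fit_nrh <- function(curve, fix_gamma = NULL, fix_omega = NULL,
                    start = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  kind <- curve_kind(curve)
  if (!kind %in% c("Ci", "Cm"))
    stop("fit_nrh() needs a Ci- or Cm-driven curve", call. = FALSE)
  driver <- curve$driver; a <- curve$a
  if (length(driver) < 5)
    stop("at least 5 points are required for fitting", call. = FALSE)
  if (length(unique(a)) == 1)
    stop("degenerate curve: all assimilation values equal",
         call. = FALSE)

  pos <- driver[a > 0]
  gamma_hi <- if (length(pos)) min(pos) else max(driver)
  start0 <- list(
    a_sat = 1.05 * max(a),
    ce = {
      s <- (a[2] - a[1]) / (driver[2] - driver[1])
      if (is.finite(s) && s > 0) s else 0.1
    },
    omega = 0.7,
    gamma = guess_gamma(driver, a)
  )
  if (!is.null(start)) start0[names(start)] <- start
  if (start0$a_sat <= 0) start0$a_sat <- 1

  fixed <- c(a_sat = FALSE, ce = FALSE,
             omega = !is.null(fix_omega), gamma = !is.null(fix_gamma))
  if (fixed[["omega"]]) start0$omega <- fix_omega
  if (fixed[["gamma"]]) start0$gamma <- fix_gamma

  lower <- c(a_sat = 1e-6, ce = 1e-8, omega = 1e-6, gamma = 0)
  upper <- c(a_sat = 10 * max(abs(a)), ce = 10, omega = 1,
             gamma = max(gamma_hi, 1e-6))
  free <- names(fixed)[!fixed]
  start_free <- unlist(start0[free])
  start_free <- pmin(pmax(start_free, lower[free]), upper[free])

  resid_fun <- function(p) {
    par <- as.list(p)
    if (fixed[["omega"]]) par$omega <- fix_omega
    if (fixed[["gamma"]]) par$gamma <- fix_gamma
    nrh_lower_root(par$ce * (driver - par$gamma), par$a_sat,
                   par$omega) - a
  }
  fit <- lm_multistart(resid_fun, start_free, lower[free], upper[free])

  par <- as.list(fit$par)
  if (fixed[["omega"]]) par$omega <- fix_omega
  if (fixed[["gamma"]]) par$gamma <- fix_gamma
  params <- nrh_params(par$a_sat, par$ce, min(par$omega, 1),
                       max(par$gamma, 0), basis = kind)
  new_fit_result(params, sqrt(mean(resid_fun(fit$par)^2)),
                 fit$converged, fixed)
}

# gamma start: linear interpolation of the sign change in A
guess_gamma <- function(driver, a) {
  i <- which(a[-length(a)] <= 0 & a[-1] > 0)
  if (length(i)) {
    i <- i[1]
    driver[i] - a[i] * (driver[i + 1] - driver[i]) / (a[i + 1] - a[i])
  } else if (all(a > 0)) {
    max(min(driver) / 2, 0)
  } else {
    min(driver)
  }
}

# Levenberg-Marquardt with up to 3 deterministically jittered restarts.
lm_multistart <- function(resid_fun, start, lower, upper) {
  jitters <- list(1, c(0.7, 1.3)[seq_along(start) %% 2 + 1],
                  c(1.4, 0.6)[seq_along(start) %% 2 + 1], 0.85)
  best <- NULL
  for (j in jitters) {
    s <- pmin(pmax(start * j, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse)
      best <- list(par = stats::coef(fit), sse = sse, converged = conv)
    if (conv && (is.null(best) || sse <= best$sse)) break
  }
  if (is.null(best))
    stop("least-squares optimisation failed from all starts",
         call. = FALSE)
  best
}

new_fit_result <- function(params, rmse, converged, fixed) {
  structure(list(params = params, rmse = rmse, converged = converged,
                 fixed = fixed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$params)
  cat(sprintf("  RMSE = %.4g umol m-2 s-1; converged: %s\n", x$rmse,
              x$converged))
  if (any(x$fixed))
    cat("  fixed:", paste(names(x$fixed)[x$fixed], collapse = ", "),
        "\n")
  invisible(x)
}

#' Fit the light-response hyperbola to a curve
#'
#' Same scheme as [fit_nrh()] for the parameters
#' `(Y(CO2)_LL, GA_SAT, m)` of the light response. The curve passes
#' through the origin by construction, so no intercept is estimated.
#'
#' @param curve A [response_curve()] with a `PPFD` driver, >= 5 points.
#' @param start Optional named list of starting values.
#' @return A `fit_result` whose `params` is a [light_params()] object.
#' @export
fit_light <- function(curve, start = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  if (curve_kind(curve) != "PPFD")
    stop("fit_light() needs a PPFD-driven curve", call. = FALSE)
  ppfd <- curve$driver; a <- curve$a
  if (length(ppfd) < 5)
    stop("at least 5 points are required for fitting", call. = FALSE)
  if (length(unique(a)) == 1)
    stop("degenerate curve: all assimilation values equal",
         call. = FALSE)

  low <- ppfd > 0
  start0 <- list(
    y_ll = {
      s <- max(a[low][1] / ppfd[low][1], 1e-4)
      if (is.finite(s)) s else 0.05
    },
    ga_sat = 1.05 * max(a), m = 0.7)
  if (!is.null(start)) start0[names(start)] <- start

  lower <- c(y_ll = 1e-8, ga_sat = 1e-6, m = 1e-6)
  upper <- c(y_ll = 1, ga_sat = 10 * max(abs(a)), m = 1)
  s0 <- pmin(pmax(unlist(start0), lower), upper)

  resid_fun <- function(p)
    nrh_lower_root(p[["y_ll"]] * ppfd, p[["ga_sat"]], p[["m"]]) - a
  fit <- lm_multistart(resid_fun, s0, lower, upper)
  params <- light_params(fit$par[["y_ll"]], fit$par[["ga_sat"]],
                         min(fit$par[["m"]], 1))
  new_fit_result(params, sqrt(mean(resid_fun(fit$par)^2)),
                 fit$converged,
                 c(y_ll = FALSE, ga_sat = FALSE, m = FALSE))
}

#' Transform a Ci-based curve to the Cm basis
#'
#' Applies the mesophyll supply function pointwise,
#' `Cm = Ci - A/g_m`, leaving assimilation values unchanged.
#'
#' @param curve A `Ci`-driven [response_curve()].
#' @param g_m Mesophyll conductance (mol m-2 s-1).
#' @return A `Cm`-driven [response_curve()].
#' @export
curve_to_cm <- function(curve, g_m) {
  stopifnot(inherits(curve, "response_curve"))
  if (curve_kind(curve) != "Ci")
    stop("curve_to_cm() needs a Ci-driven curve", call. = FALSE)
  response_curve(cm_from_ci(curve$driver, curve$a, g_m), curve$a,
                 kind = "Cm", plant = attr(curve, "plant"),
                 ca = attr(curve, "ca"), g_m = g_m)
}

#' Generate a synthetic response curve from known parameters
#'
#' Evaluates the model on a driver grid and adds optional Gaussian
#' noise. With `sd = 0` the curve is exact model output, so
#' `fit_nrh(synthesize_curve(p, grid))` recovers `p` (a property the
#' test suite exercises); with noise, the same seed always reproduces
#' the same curve. Also used for the mechanistic-conversion pathway:
#' synthesise a curve from converted parameters, then refit.
#'
#' @param params An [nrh_params()] or [light_params()] object.
#' @param grid Driver values (non-empty).
#' @param sd Gaussian noise standard deviation (umol m-2 s-1), >= 0.
#' @param seed Optional integer seed; the global RNG state is left
#'   untouched.
#' @param plant Optional plant label for the curve.
#' @return A [response_curve()].
#' @export
synthesize_curve <- function(params, grid, sd = 0, seed = NULL,
                             plant = NULL) {
  if (!length(grid)) stop("'grid' must be non-empty", call. = FALSE)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (inherits(params, "nrh_params")) {
    a <- nrh_assimilation(grid, params)
    kind <- params$basis
  } else if (inherits(params, "light_params")) {
    a <- light_assimilation(grid, params)
    kind <- "PPFD"
  } else {
    stop("'params' must be nrh_params or light_params", call. = FALSE)
  }
  if (sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(grid), 0, sd) else
      withr::with_seed(seed, stats::rnorm(length(grid), 0, sd))
    a <- a + noise
  }
  response_curve(grid, a, kind = kind, plant = plant)
}
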