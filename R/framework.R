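# The generalised restriction engine: states, K-interval transitions,
# and the marginal/total/relative contribution, limitation, sensitivity
# and elasticity metrics. Agnostic to which photosynthesis model
# supplies f: built-in models are referenced by name, and any function
# taking a named input list can serve as f.

.model_inputs <- list(
  aci      = c("c", "a_sat", "ce", "omega", "gamma"),
  supply   = c("ca", "g_s", "g_m", "a_sat", "ce", "omega", "gamma"),
  supply_r = c("ca", "r_s", "r_m", "a_sat", "ce", "omega", "gamma"),
  light    = c("ppfd", "y_ll", "ga_sat", "m")
)

# Returns a vectorised f(inputs) -> numeric for a model selector.
# `inputs` is a named list of equal-length numeric vectors.
model_function <- function(model) {
  if (is.function(model)) return(model)
  switch(
    model,
    aci = function(v)
      nrh_lower_root(v$ce * (v$c - v$gamma), v$a_sat, v$omega),
    supply = function(v)
      coupled_lower_root(v$ca, v$g_s, v$g_m, v$a_sat, v$ce, v$omega,
                         v$gamma),
    supply_r = function(v)
      coupled_lower_root(v$ca, 1 / v$r_s, 1 / v$r_m, v$a_sat, v$ce,
                         v$omega, v$gamma),
    light = function(v)
      nrh_lower_root(v$y_ll * v$ppfd, v$ga_sat, v$m),
    stop("unknown model '", model, "'; use \"aci\", \"supply\", ",
         "\"light\", or a function", call. = FALSE)
  )
}

#' Define a photosynthetic state
#'
#' A state is a named, complete set of model inputs (environmental
#' drivers plus plant characteristics) at which the selected model can be
#' evaluated. Built-in models: `"aci"` (CO2-response hyperbola with
#' driver `c`), `"supply"` (demand curve coupled to the stomatal and
#' mesophyll supply chain, driver `ca`), `"supply_r"` (the same model
#' parameterised by the resistances `r_s = 1/g_s` and `r_m = 1/g_m`,
#' so that transitions scale the diffusion chain linearly in the space
#' where its legs add), and `"light"` (light-response hyperbola, driver
#' `ppfd`). A custom model may be given as a function taking a named
#' list of input vectors and returning assimilation.
#'
#' @param name Label for the state (e.g. `"operational"`).
#' @param model Model selector: `"aci"`, `"supply"`, `"light"`, or a
#'   function.
#' @param inputs Named numeric vector or list of all inputs the model
#'   needs. For built-in models the required names are checked.
#' @return An object of class `ps_state`.
#' @export
#' @examples
#' st <- ps_state("operational", "supply",
#'   c(ca = 420, g_s = 0.063, g_m = 0.35, a_sat = 26, ce = 0.18,
#'     omega = 0.54, gamma = 45))
#' state_assimilation(st)
ps_state <- function(name, model, inputs) {
  inputs <- unlist(inputs)
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("all state inputs must be named", call. = FALSE)
  if (any(!is.finite(inputs)))
    stop("state inputs must be finite", call. = FALSE)
  if (is.character(model)) {
    req <- .model_inputs[[model]]
    if (is.null(req))
      stop("unknown model '", model, "'", call. = FALSE)
    missing <- setdiff(req, names(inputs))
    if (length(missing))
      stop("state '", name, "' lacks input(s) required by model '",
           model, "': ", paste(missing, collapse = ", "), call. = FALSE)
  }
  st <- structure(list(name = name, model = model, inputs = inputs),
                  class = "ps_state")
  # the model must evaluate without error at the state
  val <- state_assimilation(st)
  if (!is.finite(val))
    stop("model does not evaluate to a finite value at state '", name,
         "'", call. = FALSE)
  st
}

#' Evaluate the model at a state
#'
#' @param state A [ps_state()] object.
#' @return The model output (assimilation, umol m-2 s-1).
#' @export
state_assimilation <- function(state) {
  stopifnot(inherits(state, "ps_state"))
  f <- model_function(state$model)
  unname(f(as.list(state$inputs)))
}

#' Define a transition across two or more states
#'
#' An ordered path along which every input scales linearly between
#' consecutive states, each leg divided into `K` equal intervals.
#'
#' @param states List of [ps_state()] objects, length >= 2, sharing the
#'   same model and input names.
#' @param K Intervals per leg, integer >= 1. The default of 1000 keeps
#'   the finite-interval error of the forward-difference contributions
#'   negligible for smooth models.
#' @return An object of class `ps_transition`.
#' @seealso [run_transition()]
#' @export
ps_transition <- function(states, K = 1000) {
  if (!is.list(states) || length(states) < 2)
    stop("'states' must be a list of at least two states", call. = FALSE)
  lapply(states, function(s) stopifnot(inherits(s, "ps_state")))
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K))
    stop("'K' must be a positive integer", call. = FALSE)
  nm1 <- sort(names(states[[1]]$inputs))
  for (s in states[-1]) {
    if (!identical(sort(names(s$inputs)), nm1))
      stop("all states must share the same input names", call. = FALSE)
    if (!identical(s$model, states[[1]]$model))
      stop("all states must share the same model", call. = FALSE)
  }
  structure(list(states = states, K = as.integer(K)),
            class = "ps_transition")
}

#' Linear interpolation of inputs inside a leg
#'
#' Input values at interval `k` of the leg from state `m` to state
#' `m + 1`: `a_k = a_m + (k/K) (a_{m+1} - a_m)` for every input.
#'
#' @param state_from,state_to The two adjacent states.
#' @param k Interval index, `0 <= k <= K`.
#' @param K Number of intervals in the leg.
#' @return Named numeric vector of interpolated inputs.
#' @export
interpolate_inputs <- function(state_from, state_to, k, K) {
  stopifnot(inherits(state_from, "ps_state"),
            inherits(state_to, "ps_state"))
  if (k < 0 || k > K)
    stop("'k' must lie in [0, K]", call. = FALSE)
  a <- state_from$inputs
  b <- state_to$inputs[names(a)]
  a + (k / K) * (b - a)
}

#' Marginal contribution of one input over one interval
#'
#' The forward variant advances input `input` from its interval-`k` to
#' its interval-`k+1` value while all other inputs stay at `k`:
#' `xi = f(a_{k+1}, b_k) - f(a_k, b_k)`. The alternate variant
#' (`xi'`) holds the others at `k+1` instead. The two converge as `K`
#' grows; the forward form is the default throughout the package.
#'
#' @param transition A [ps_transition()] object.
#' @param input Input name.
#' @param m Leg index (1 = first leg).
#' @param k Interval index within the leg, `0 <= k <= K-1`.
#' @param variant `"forward"` or `"alternate"`.
#' @return Marginal contribution (umol m-2 s-1).
#' @export
marginal_contribution <- function(transition, input, m, k,
                                  variant = c("forward", "alternate")) {
  variant <- match.arg(variant)
  stopifnot(inherits(transition, "ps_transition"))
  K <- transition$K
  if (m < 1 || m >= length(transition$states))
    stop("'m' must index a leg of the transition", call. = FALSE)
  if (k < 0 || k > K - 1)
    stop("'k' must lie in [0, K-1]", call. = FALSE)
  s1 <- transition$states[[m]]; s2 <- transition$states[[m + 1]]
  if (!input %in% names(s1$inputs))
    stop("unknown input '", input, "'", call. = FALSE)
  f <- model_function(s1$model)
  vk  <- interpolate_inputs(s1, s2, k, K)
  vk1 <- interpolate_inputs(s1, s2, k + 1, K)
  base <- if (variant == "forward") vk else vk1
  pert <- base; pert[input] <- vk1[input]
  ref  <- base; ref[input]  <- vk[input]
  unname(f(as.list(pert)) - f(as.list(ref)))
}

# Evaluate f over the rows of an input matrix (columns = inputs).
eval_rows <- function(f, mat) {
  f(lapply(seq_len(ncol(mat)), function(j) mat[, j]) |>
      stats::setNames(colnames(mat)))
}

#' Run a transition: contribution table and control series
#'
#' Walks every leg of the transition in `K` linear intervals and, for
#' each input that changes, accumulates its forward marginal
#' contributions into the total contribution `Xi` (umol m-2 s-1). From
#' the totals it derives the relative contribution
#' `rho = Xi / (Omega_end - Omega_start)` and the limitation
#' `L = Xi / Omega_end`, and reports per-interval sensitivities
#' `S = xi / delta_a` and elasticities
#' `eta = delta ln f / delta ln a`. The closure residual
#' `sum(Xi) - (Omega_end - Omega_start)` measures the finite-interval
#' error; it shrinks as `K` grows and is zero to machine precision when
#' a single input changes (the forward differences then telescope).
#'
#' Division-by-zero conditions are flagged, never silent: `rho` is `NA`
#' with `flags$rho_undefined = TRUE` when the output does not change,
#' and `L` is `NA` with `flags$limitation_undefined = TRUE` when the
#' final output is zero.
#'
#' @param transition A [ps_transition()] object.
#' @param K Override the transition's interval count.
#' @param variant `"forward"` (default) or `"alternate"` marginal
#'   contributions; the alternate form is provided for convergence
#'   demonstrations.
#' @param control Logical; also compute the per-interval sensitivity and
#'   elasticity series (default `TRUE`).
#' @return An object of class `contribution_table`: a list with
#'   `contributions` (data frame: input, delta, xi_total, rho,
#'   limitation), `omega_start`, `omega_end`, `delta_omega`, `closure`,
#'   `flags`, `K`, `variant`, and (optionally) `control`, a data frame of
#'   per-interval series.
#' @export
#' @examples
#' p <- c(a_sat = 26, ce = 0.12, omega = 0.7, gamma = 45)
#' tr <- ps_transition(list(
#'   ps_state("operational", "aci", c(c = 200, p)),
#'   ps_state("potential", "aci", c(c = 420, p))))
#' run_transition(tr)
run_transition <- function(transition, K = NULL,
                           variant = c("forward", "alternate"),
                           control = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(transition, "ps_transition"))
  K <- if (is.null(K)) transition$K else as.integer(K)
  if (K < 1) stop("'K' must be >= 1", call. = FALSE)
  states <- transition$states
  f <- model_function(states[[1]]$model)
  input_names <- names(states[[1]]$inputs)

  # inputs changing anywhere along the path, in state-I declaration order
  changing <- input_names[vapply(input_names, function(nm) {
    vals <- vapply(states, function(s) s$inputs[[nm]], numeric(1))
    any(vals != vals[1])
  }, logical(1))]
  if (!length(changing))
    stop("no input changes along the transition", call. = FALSE)

  xi_tot <- stats::setNames(numeric(length(changing)), changing)
  ctrl <- if (control) vector("list", length(states) - 1) else NULL

  for (m in seq_len(length(states) - 1)) {
    a1 <- states[[m]]$inputs
    a2 <- states[[m + 1]]$inputs[names(a1)]
    frac <- (0:K) / K
    # (K+1) x n matrix of interpolated inputs
    grid <- outer(frac, a2 - a1) + matrix(a1, K + 1, length(a1),
                                          byrow = TRUE)
    colnames(grid) <- names(a1)
    f_base <- eval_rows(f, grid)
    leg_ctrl <- NULL
    for (nm in changing) {
      if (a1[[nm]] == a2[[nm]]) next   # xi = 0 over this whole leg
      pert <- grid[1:K, , drop = FALSE]
      pert[, nm] <- grid[2:(K + 1), nm]
      f_pert <- eval_rows(f, pert)
      xi <- f_pert - f_base[1:K]
      if (variant == "alternate") {
        back <- grid[2:(K + 1), , drop = FALSE]
        back[, nm] <- grid[1:K, nm]
        xi <- f_base[2:(K + 1)] - eval_rows(f, back)
      }
      xi_tot[nm] <- xi_tot[nm] + sum(xi)
      if (control) {
        da <- grid[2:(K + 1), nm] - grid[1:K, nm]
        a_k <- grid[1:K, nm]; a_k1 <- grid[2:(K + 1), nm]
        f_base_k <- f_base[1:K]
        eta <- rep(NA_real_, K)
        ok <- a_k > 0 & a_k1 > 0 & f_base_k > 0 & f_pert > 0
        eta[ok] <- (log(f_pert[ok]) - log(f_base_k[ok])) /
          (log(a_k1[ok]) - log(a_k[ok]))
        leg_ctrl <- rbind(leg_ctrl, data.frame(
          leg = m, k = 0:(K - 1), input = nm, value = a_k,
          sensitivity = xi / da, elasticity = eta))
      }
    }
    if (control) ctrl[[m]] <- leg_ctrl
  }

  omega_start <- state_assimilation(states[[1]])
  omega_end <- state_assimilation(states[[length(states)]])
  delta <- omega_end - omega_start
  closure <- sum(xi_tot) - delta

  flags <- list(rho_undefined = delta == 0,
                limitation_undefined = omega_end == 0)
  rho <- if (flags$rho_undefined) rep(NA_real_, length(xi_tot)) else
    xi_tot / delta
  lim <- if (flags$limitation_undefined) rep(NA_real_, length(xi_tot)) else
    xi_tot / omega_end

  deltas <- vapply(changing, function(nm)
    states[[length(states)]]$inputs[[nm]] - states[[1]]$inputs[[nm]],
    numeric(1))

  out <- list(
    contributions = data.frame(
      input = changing, delta = unname(deltas),
      xi_total = unname(xi_tot), rho = unname(rho),
      limitation = unname(lim)),
    omega_start = omega_start, omega_end = omega_end,
    delta_omega = delta, closure = closure, flags = flags,
    K = K, variant = variant,
    model = if (is.character(states[[1]]$model)) states[[1]]$model else
      "custom",
    states = vapply(states, function(s) s$name, character(1))
  )
  if (control) out$control <- do.call(rbind, ctrl)
  class(out) <- "contribution_table"
  out
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Restriction analysis (model: ", x$model, ", K = ", x$K, ")\n",
      sep = "")
  cat("  path: ", paste(x$states, collapse = " -> "), "\n", sep = "")
  cat(sprintf("  A start = %.4f, A end = %.4f, dA = %.4f (umol m-2 s-1)\n",
              x$omega_start, x$omega_end, x$delta_omega))
  df <- x$contributions
  df$xi_total <- signif(df$xi_total, 6)
  df$rho <- signif(df$rho, 4)
  df$limitation <- signif(df$limitation, 4)
  print(df, row.names = FALSE)
  cat(sprintf("  closure residual = %.3g\n", x$closure))
  if (isTRUE(x$flags$rho_undefined))
    cat("  note: output unchanged; rho undefined\n")
  if (isTRUE(x$flags$limitation_undefined))
    cat("  note: final output is zero; limitation undefined\n")
  invisible(x)
}

#' Finite-difference sensitivity of the model at a state
#'
#' `S = [f(a + increment, b) - f(a, b)] / increment`: the absolute
#' control coefficient of the output with respect to one input.
#'
#' @param state A [ps_state()] object.
#' @param input Input name.
#' @param increment Finite perturbation of the input (its own units);
#'   non-zero.
#' @return Sensitivity, output units per input units.
#' @export
sensitivity <- function(state, input, increment) {
  stopifnot(inherits(state, "ps_state"))
  if (!input %in% names(state$inputs))
    stop("unknown input '", input, "'", call. = FALSE)
  if (!is.finite(increment) || increment == 0)
    stop("'increment' must be non-zero", call. = FALSE)
  f <- model_function(state$model)
  v <- state$inputs
  vp <- v; vp[input] <- v[input] + increment
  unname((f(as.list(vp)) - f(as.list(v))) / increment)
}

#' Finite-difference elasticity of the model at a state
#'
#' The relative (log-log) control coefficient,
#' `eta = [ln f(a(1+i), b) - ln f(a, b)] / ln(1+i)`, evaluated with a
#' small relative increment `i`. Requires the input and both model
#' values to be positive.
#'
#' @param state A [ps_state()] object.
#' @param input Input name.
#' @param i Relative increment (dimensionless), positive; default 1e-4.
#' @return Elasticity (dimensionless).
#' @export
elasticity <- function(state, input, i = 1e-4) {
  stopifnot(inherits(state, "ps_state"))
  if (!input %in% names(state$inputs))
    stop("unknown input '", input, "'", call. = FALSE)
  if (!is.finite(i) || i <= 0)
    stop("'i' must be positive", call. = FALSE)
  f <- model_function(state$model)
  v <- state$inputs
  a <- v[[input]]
  if (a <= 0)
    stop("elasticity undefined: input '", input, "' is not positive",
         call. = FALSE)
  f0 <- f(as.list(v))
  vp <- v; vp[input] <- a * (1 + i)
  f1 <- f(as.list(vp))
  if (f0 <= 0 || f1 <= 0)
    stop("elasticity undefined: model output is not positive",
         call. = FALSE)
  unname((log(f1) - log(f0)) / log(1 + i))
}
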