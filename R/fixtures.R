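# Embedded worked-example dataset: one healthy and one hypothetically
# treated plant, with operational points, A/Ci and derived A/Cm response
# curves, mesophyll conductances, and the fitted hyperbola parameters on
# both bases. Values are transcribed from the published synthetic table;
# the concatenated print layout is expanded into explicit columns.

# healthy plant, g_m = 0.35 mol m-2 s-1
.fx_healthy <- list(
  operational = c(a_op = 13.9, ci_op = 200, cm_op = 160, ca = 420),
  g_s = 0.063,   # A_op / (Ca - Ci_op)
  g_m = 0.35,
  aci = data.frame(
    #        A      Ci    Cm   (printed columns)
    a  = c(-2.59, -1.22, 0.60, 3.00, 6.15, 10.1, 14.4, 17.9, 20.7),
    ci = c(   24,    35,   50,   71,  101,  145,  210,  294,  420),
    cm = c(   32,    38,   48,   62,   84,  116,  166,  243,  361)
  ),
  fits = list(
    ci = c(a_sat = 26, ce = 0.12, omega = 0.70, gamma = 45),
    cm = c(a_sat = 26, ce = 0.18, omega = 0.54, gamma = 45)
  )
)

# treated plant (reduced photosynthetic potential), g_m = 0.25
.fx_treated <- list(
  operational = c(a_op = 11, ci_op = 220, cm_op = 176, ca = 420),
  g_s = 0.055,   # printed operational stomatal conductance
  g_m = 0.25,
  aci = data.frame(
    a  = c(-1.91, -0.90, 0.44, 2.21, 4.53, 7.42, 10.6, 13.2, 15.2),
    ci = c(   24,    35,   50,   71,  101,  145,  210,  294,  420),
    cm = c(   32,    39,   48,   62,   83,  115,  164,  242,  359)
  ),
  fits = list(
    ci = c(a_sat = 19, ce = 0.09, omega = 0.70, gamma = 45),
    cm = c(a_sat = 19, ce = 0.14, omega = 0.54, gamma = 45)
  )
)

#' Load an embedded worked-example plant
#'
#' Returns the embedded gas-exchange dataset for one of the two
#' worked-example plants: `"healthy"` (untreated) or `"treated"`
#' (subjected to a hypothetical treatment reducing photosynthetic
#' potential). Each fixture carries the operational point, the measured
#' A/Ci response, the A/Cm response derived with the plant's mesophyll
#' conductance, the operational conductances, and the hyperbola
#' parameters fitted on both bases.
#'
#' @param name `"healthy"` or `"treated"`.
#' @return A list of class `table2_plant` with elements `operational`
#'   (an [operational_point()]), `curves` (`aci` and `acm`
#'   [response_curve()]s), `g` (a [conductances()] object), and `fits`
#'   (`ci` and `cm` [nrh_params()]).
#' @export
#' @examples
#' fx <- load_fixture("healthy")
#' fx$fits$ci
load_fixture <- function(name) {
  fixtures <- list(healthy = .fx_healthy, treated = .fx_treated)
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(fixtures))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(fixtures), collapse = ", "),
         call. = FALSE)
  raw <- fixtures[[name]]
  op <- raw$operational
  structure(list(
    name = name,
    operational = operational_point(op[["a_op"]], op[["ci_op"]],
                                    op[["ca"]], op[["cm_op"]]),
    curves = list(
      aci = response_curve(raw$aci$ci, raw$aci$a, kind = "Ci",
                           plant = name, ca = op[["ca"]],
                           g_m = raw$g_m),
      acm = response_curve(raw$aci$cm, raw$aci$a, kind = "Cm",
                           plant = name, ca = op[["ca"]],
                           g_m = raw$g_m)
    ),
    g = conductances(raw$g_s, raw$g_m),
    fits = list(
      ci = do.call(nrh_params, c(as.list(raw$fits$ci),
                                 list(basis = "Ci"))),
      cm = do.call(nrh_params, c(as.list(raw$fits$cm),
                                 list(basis = "Cm")))
    )
  ), class = "table2_plant")
}

#' @export
print.table2_plant <- function(x, ...) {
  cat("Worked-example plant: ", x$name, "\n", sep = "")
  cat(sprintf("  operational: A = %g, Ci = %g, Ca = %g (Cm = %g)\n",
              x$operational$a_op, x$operational$ci_op,
              x$operational$ca, x$operational$cm_op))
  cat(sprintf("  g_s = %g, g_m = %g mol m-2 s-1\n", x$g$g_s, x$g$g_m))
  cat(sprintf("  Ci-based fit: A_SAT %g, CE %g, omega %g, Gamma %g\n",
              x$fits$ci$a_sat, x$fits$ci$ce, x$fits$ci$omega,
              x$fits$ci$gamma))
  cat(sprintf("  Cm-based fit: A_SAT %g, CE %g, omega %g, Gamma %g\n",
              x$fits$cm$a_sat, x$fits$cm$ce, x$fits$cm$omega,
              x$fits$cm$gamma))
  invisible(x)
}
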