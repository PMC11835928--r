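# CSV readers/writers for curves and reports, and YAML configuration
# parsing for scripted analyses.

#' Read a response curve from CSV
#'
#' Expects a two-column CSV whose header names the driver kind (`Ci`,
#' `Cm`, or `PPFD`) and the assimilation column `A`, e.g. `Ci,A`.
#' The dialect is fixed: comma separator, period decimal point, UTF-8.
#' Files using comma decimals are rejected with an explicit message
#' rather than silently misread.
#'
#' @param path Path to the CSV file.
#' @return A [response_curve()].
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  kinds <- c("Ci", "Cm", "PPFD")
  kind <- intersect(kinds, names(df))
  if (length(kind) != 1)
    stop("curve CSV must have exactly one driver column named one of ",
         paste(kinds, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  if (!"A" %in% names(df))
    stop("curve CSV is missing the required column 'A'", call. = FALSE)
  to_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & nzchar(x))) {
      if (any(grepl(",", x, fixed = TRUE)))
        stop("column '", col, "' uses comma decimals; the CSV dialect ",
             "is fixed to period decimal point and comma separator",
             call. = FALSE)
      stop("column '", col, "' contains non-numeric values",
           call. = FALSE)
    }
    v
  }
  response_curve(to_num(df[[kind]], kind), to_num(df[["A"]], "A"),
                 kind = kind)
}

#' Write a response curve to CSV
#'
#' Inverse of [read_curve_csv()]: the driver column is named after the
#' curve's kind. Values round-trip at full double precision.
#'
#' @param curve A [response_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  df <- data.frame(driver = curve$driver, A = curve$a)
  names(df)[1] <- curve_kind(curve)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis report to CSV and JSON
#'
#' Emits two files: `<stem>_metrics.csv` with the per-input totals
#' (contribution, relative contribution, limitation) and
#' `<stem>.json` with the full report -- states, overall outputs,
#' closure residual, summary quantities, and the per-interval
#' sensitivity/elasticity series when present. The JSON schema carries a
#' `schema_version` field.
#'
#' @param result A `contribution_table` (as returned by
#'   [run_transition()] or any analysis function).
#' @param stem Output path stem (no extension).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(result, stem) {
  stopifnot(inherits(result, "contribution_table"))
  csv <- paste0(stem, "_metrics.csv")
  json <- paste0(stem, ".json")
  utils::write.csv(result$contributions, csv, row.names = FALSE,
                   fileEncoding = "UTF-8")
  payload <- list(
    schema_version = "1.0",
    analysis = if (is.null(result$analysis)) "transition" else
      result$analysis,
    model = result$model,
    states = result$states,
    K = result$K,
    variant = result$variant,
    omega_start = result$omega_start,
    omega_end = result$omega_end,
    delta_omega = result$delta_omega,
    closure = result$closure,
    flags = result$flags,
    summary = lapply(result$summary, function(x)
      if (inherits(x, "nrh_params")) unclass(x) else x),
    contributions = result$contributions,
    control = result$control
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")
  invisible(c(csv, json))
}

# ---- analysis configuration ------------------------------------------

.config_analyses <- c("stomatal", "diffusional", "stomnon", "contrib",
                      "control", "light", "lightnon", "pathdep",
                      "transition")

#' Read and validate an analysis configuration
#'
#' Parses a YAML configuration describing one analysis run. Every
#' configuration names the `analysis` (one of `stomatal`,
#' `diffusional`, `stomnon`, `contrib`, `control`, `light`, `lightnon`,
#' `pathdep`, `transition`) and may set `K`, `g_high`, `i`, and `seed`;
#' the remaining blocks depend on the analysis (e.g. `params`, `op`,
#' `healthy`/`treated`, `state`, or `states`). Validation is structural
#' and happens before any computation.
#'
#' @param path Path to the YAML file.
#' @return A validated list of class `analysis_config`.
#' @seealso [run_config()]
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path))
    stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.list(cfg) || is.null(cfg$analysis))
    stop("config must be a mapping with an 'analysis' key",
         call. = FALSE)
  if (!cfg$analysis %in% .config_analyses)
    stop("unknown analysis '", cfg$analysis, "'; available: ",
         paste(.config_analyses, collapse = ", "), call. = FALSE)
  for (key in c("K", "g_high", "i", "seed"))
    if (!is.null(cfg[[key]]) && !is.numeric(cfg[[key]]))
      stop("config key '", key, "' must be numeric", call. = FALSE)
  need <- switch(cfg$analysis,
    stomatal = c("params", "op"),
    diffusional = c("params", "g", "ca"),
    stomnon = c("healthy_params", "op"),
    contrib = c("healthy", "treated", "ca"),
    pathdep = c("healthy", "treated", "ca", "order"),
    control = "state",
    light = c("light_params", "ppfd_op", "ppfd_max"),
    lightnon = c("healthy_light", "treated_light", "ppfd_op",
                 "ppfd_max"),
    transition = c("model", "states"))
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config for '", cfg$analysis, "' is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(cfg, class = "analysis_config")
}

cfg_nrh <- function(block, basis) {
  nrh_params(block$a_sat, block$ce, block$omega, block$gamma,
             basis = basis)
}

cfg_side <- function(block) {
  list(fit = cfg_nrh(block$params, "Cm"),
       g = conductances(block$g_s, block$g_m))
}

#' Run an analysis from a configuration
#'
#' Dispatches a validated configuration (see [read_analysis_config()])
#' to the corresponding analysis function.
#'
#' @param cfg An `analysis_config` (or a list that validates as one).
#' @return The analysis result (`contribution_table` or
#'   `control_analysis`).
#' @export
run_config <- function(cfg) {
  if (!inherits(cfg, "analysis_config")) cfg <- validate_config(cfg)
  K <- if (is.null(cfg$K)) 1000 else cfg$K
  g_high <- if (is.null(cfg$g_high)) 1e6 else cfg$g_high
  i <- if (is.null(cfg$i)) 1e-4 else cfg$i
  op <- function(b) operational_point(b$a_op, b$ci_op, b$ca, b$cm_op)
  switch(cfg$analysis,
    stomatal = stomatal_limitation(cfg_nrh(cfg$params, "Ci"),
                                   op(cfg$op), K = K),
    diffusional = diffusional_limitation(
      cfg_nrh(cfg$params, "Cm"),
      conductances(cfg$g$g_s, cfg$g$g_m), ca = cfg$ca,
      g_high = g_high, K = K),
    stomnon = stomatal_nonstomatal(
      cfg_nrh(cfg$healthy_params, "Ci"), op(cfg$op),
      treated_fit = if (!is.null(cfg$treated_params))
        cfg_nrh(cfg$treated_params, "Ci"),
      mu = cfg$mu,
      variant = if (is.null(cfg$variant)) "two-tier" else cfg$variant,
      g_high = g_high, K = K),
    contrib = treatment_contributions(cfg_side(cfg$healthy),
                                      cfg_side(cfg$treated),
                                      ca = cfg$ca, K = K),
    pathdep = path_dependent_contributions(cfg_side(cfg$healthy),
                                           cfg_side(cfg$treated),
                                           ca = cfg$ca,
                                           order = cfg$order, K = K),
    control = control_analysis(
      ps_state(if (is.null(cfg$state$name)) "state" else
        cfg$state$name, cfg$state$model, unlist(cfg$state$inputs)),
      inputs = cfg$inputs, i = i),
    light = light_limitation(
      light_params(cfg$light_params$y_ll, cfg$light_params$ga_sat,
                   cfg$light_params$m),
      ppfd_op = cfg$ppfd_op, ppfd_max = cfg$ppfd_max, K = K),
    lightnon = light_nonlight(
      light_params(cfg$healthy_light$y_ll, cfg$healthy_light$ga_sat,
                   cfg$healthy_light$m),
      light_params(cfg$treated_light$y_ll, cfg$treated_light$ga_sat,
                   cfg$treated_light$m),
      ppfd_op = cfg$ppfd_op, ppfd_max = cfg$ppfd_max,
      variant = if (is.null(cfg$variant)) "two-tier" else cfg$variant,
      K = K),
    transition = run_transition(ps_transition(
      lapply(cfg$states, function(s)
        ps_state(if (is.null(s$name)) "state" else s$name,
                 cfg$model, unlist(s$inputs))),
      K = K))
  )
}
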