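#' Pipeline run configuration
#'
#' One object describing a full analysis: the input (a CSV path or a
#' [dgp_config()] to simulate from), the response and candidate regressors,
#' lag-scan depth, bounds-test simulation settings, the ECM order (explicit
#' or `"auto"` = the SBC consensus lag for both `p` and every `q`), the
#' shock scenarios, and a single global seed from which every stage derives
#' its own stream.
#'
#' @param input a CSV file path or a `dgp_config`.
#' @param response response column name.
#' @param regressors candidate regressor names (default: all other columns).
#' @param p_max lag-scan depth for [lag_criteria()].
#' @param bounds_case deterministic case of the bounds test.
#' @param bounds_n_sim replications for the simulated critical bounds.
#' @param order `"auto"` or a list `list(p = , q = )` as in
#'   [fit_ecm_ardl()].
#' @param contemporaneous passed to [fit_ecm_ardl()].
#' @param scenarios list of [shock_scenario()] objects (scenario seeds are
#'   re-derived from the global seed).
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   all artifacts there.
#' @param seed global integer seed.
#' @param force continue past failed gates (with a warning) instead of
#'   halting.
#' @param verbose print stage progress.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, response, regressors = NULL, p_max = 4L,
                       bounds_case = "iii", bounds_n_sim = 5000L,
                       order = "auto", contemporaneous = TRUE,
                       scenarios = list(), output_dir = NULL, seed = 1L,
                       force = FALSE, verbose = FALSE) {
  is_path <- is.character(input) && length(input) == 1L
  is_dgp <- inherits(input, "dgp_config")
  if (!xor(is_path, is_dgp))
    stop("input must be exactly one of: a CSV path, a dgp_config", call. = FALSE)
  if (is_dgp && missing(response)) response <- input$response_name
  if (!is.null(regressors) && response %in% regressors)
    stop("response must not be among the regressors", call. = FALSE)
  if (!identical(order, "auto") &&
      !(is.list(order) && all(c("p", "q") %in% names(order))))
    stop("order must be \"auto\" or list(p =, q =)", call. = FALSE)
  for (s in scenarios)
    if (!inherits(s, "shock_scenario"))
      stop("scenarios must be shock_scenario objects", call. = FALSE)
  structure(list(input = input, response = response, regressors = regressors,
                 p_max = as.integer(p_max), bounds_case = bounds_case,
                 bounds_n_sim = as.integer(bounds_n_sim), order = order,
                 contemporaneous = contemporaneous, scenarios = scenarios,
                 output_dir = output_dir, seed = as.integer(seed),
                 force = force, verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Schema-validated: unknown keys raise an error naming the key. Scenario
#' entries take the same fields as [shock_scenario()]; the input is either
#' `csv: <path>` or `dgp: <path to a YAML written by [write_dgp_config()]>`.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("csv", "dgp", "response", "regressors", "p_max", "bounds_case",
             "bounds_n_sim", "order", "contemporaneous", "scenarios",
             "output_dir", "seed", "force", "verbose")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!xor(is.null(x$csv), is.null(x$dgp)))
    stop("configuration needs exactly one of 'csv' or 'dgp'", call. = FALSE)
  input <- if (!is.null(x$csv)) x$csv else read_dgp_config(x$dgp)
  scenarios <- lapply(x$scenarios, function(s) do.call(shock_scenario, s))
  order <- if (is.null(x$order) || identical(x$order, "auto")) "auto"
           else list(p = x$order$p, q = unlist(x$order$q))
  args <- list(input = input, order = order, scenarios = scenarios)
  for (f in c("response", "regressors", "p_max", "bounds_case", "bounds_n_sim",
              "contemporaneous", "output_dir", "seed", "force", "verbose"))
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  do.call(run_config, args)
}

#' Run the full fire-climate attribution pipeline
#'
#' Executes the staged protocol with its two hard gates: (1) read or
#' simulate the monthly panel; (2) classify every variable's order of
#' integration — any `I(2)+` variable halts the run, because the ARDL bounds
#' framework requires all series integrated below order two; (3) select the
#' lag order by the five information criteria; (4) estimate the
#' error-correction ARDL; (5) bounds F-test against freshly simulated
#' critical bounds — a non-cointegrated verdict halts before any long-run
#' interpretation or simulation; (6) residual diagnostics and recursive
#' CUSUM; (7) shock-response simulations. All per-stage randomness derives
#' from the global seed, and all artifacts are written to `output_dir` when
#' set.
#'
#' @param config a [run_config()].
#' @return object of class `run_report` with sections `panel`, `unit_roots`,
#'   `lag_selection`, `ecm`, `bounds`, `long_run`, `diagnostics`, `cusum`,
#'   `simulations`, the gate decisions, and `halted`/`halt_reason`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[fireardl] ", ...)
  report <- list(seed = config$seed, gates = list(), halted = FALSE,
                 halt_reason = NULL)
  class(report) <- "run_report"

  ## stage 1: data
  if (inherits(config$input, "dgp_config")) {
    dgp <- config$input
    dgp$seed <- config$seed + 101L          # stage-derived stream
    say("simulating synthetic panel (n = ", dgp$n_months, ")")
    panel <- simulate_fire_panel(dgp)
  } else {
    say("reading panel from ", config$input)
    panel <- read_panel(config$input)
  }
  regressors <- config$regressors
  if (is.null(regressors)) regressors <- setdiff(panel_vars(panel), config$response)
  report$panel <- panel
  report$response <- config$response
  report$regressors <- regressors

  ## stage 2: unit roots + I(2) gate
  say("unit-root classification")
  ur <- classify_integration(panel, c(config$response, regressors))
  report$unit_roots <- ur
  bad <- names(ur$verdicts)[ur$verdicts == "I(2)+"]
  gate_ok <- length(bad) == 0L
  report$gates$integration <- list(
    passed = gate_ok,
    detail = if (gate_ok) "all variables I(0) or I(1)"
             else paste0("variable(s) ", paste(bad, collapse = ", "),
                         " classified I(2)+; series should not be I(2)"))
  if (!gate_ok && !config$force) {
    report$halted <- TRUE
    report$halt_reason <- report$gates$integration$detail
    finish_report(report, config)
    return(report)
  }
  if (!gate_ok) warning("forcing past failed integration gate: ",
                        report$gates$integration$detail, call. = FALSE)

  ## stage 3: lag selection
  say("lag selection (p_max = ", config$p_max, ")")
  lags <- lag_criteria(panel, p_max = config$p_max,
                       vars = c(config$response, regressors))
  report$lag_selection <- lags

  ## stage 4: ECM estimation
  if (identical(config$order, "auto")) {
    p_use <- max(0L, lags$consensus_lag - 1L)  # one level lag is implicit
    q_use <- max(1L, lags$consensus_lag)
  } else {
    p_use <- config$order$p
    q_use <- config$order$q
  }
  say("ECM fit (p = ", p_use, ")")
  fit <- fit_ecm_ardl(panel, config$response, regressors,
                      p = p_use, q = q_use,
                      contemporaneous = config$contemporaneous)
  report$ecm <- fit

  ## stage 5: bounds test + cointegration gate
  say("bounds critical values (", config$bounds_n_sim, " replications)")
  cv <- bounds_critical_values(n = nrow(panel), k = length(regressors),
                               case = config$bounds_case,
                               n_sim = config$bounds_n_sim,
                               seed = config$seed + 202L)
  bt <- bounds_f_test(fit, cv)
  report$bounds <- bt
  gate_ok <- bt$decision == "cointegrated"
  report$gates$cointegration <- list(
    passed = gate_ok,
    detail = paste0("bounds decision: ", bt$decision,
                    " (F = ", format(bt$F_statistic, digits = 4), ")"))
  if (!gate_ok && !config$force) {
    report$halted <- TRUE
    report$halt_reason <- paste0(report$gates$cointegration$detail,
                                 "; long-run interpretation unwarranted")
    finish_report(report, config)
    return(report)
  }
  if (!gate_ok) warning("forcing past failed cointegration gate: ",
                        report$gates$cointegration$detail, call. = FALSE)

  ## stage 6: long-run multipliers, diagnostics, stability
  report$long_run <- long_run_multipliers(fit)
  say("diagnostics and CUSUM")
  report$diagnostics <- residual_diagnostics(fit)
  report$cusum <- cusum_stability(fit)

  ## stage 7: shock simulations
  report$simulations <- list()
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    sc$seed <- config$seed + 300L + i
    say("simulating ", sc$shock_persistence, " shock to ", sc$regressor)
    nm <- paste0(sc$regressor, ifelse(sc$shock_sign > 0, "_pos", "_neg"))
    report$simulations[[nm]] <- simulate_response(fit, panel, sc)
  }
  finish_report(report, config)
  report
}

finish_report <- function(report, config) {
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("fireardl pipeline report (seed ", x$seed, ")\n", sep = "")
  for (g in names(x$gates))
    cat("  gate ", g, ": ", if (x$gates[[g]]$passed) "passed" else "FAILED",
        " - ", x$gates[[g]]$detail, "\n", sep = "")
  if (x$halted) {
    cat("  HALTED: ", x$halt_reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("  consensus lag:", x$lag_selection$consensus_lag, "\n")
  cat("  ECT coefficient:", format(x$ecm$ect_coefficient, digits = 4),
      " R2:", format(x$ecm$r.squared, digits = 3), "\n")
  cat("  bounds F:", format(x$bounds$F_statistic, digits = 4),
      "->", x$bounds$decision, "\n")
  cat("  CUSUM crossed:", x$cusum$crossed, "\n")
  if (length(x$simulations))
    for (nm in names(x$simulations))
      cat("  shift[", nm, "]: ",
          format(x$simulations[[nm]]$equilibrium_shift$estimate, digits = 4),
          "\n", sep = "")
  invisible(x)
}

#' Machine-readable summary of a pipeline run
#'
#' Flat named list of the report's headline numbers, suitable for JSON
#' serialisation; deterministic given the configuration and seed.
#'
#' @param report a `run_report`.
#' @return named list.
#' @export
report_summary <- function(report) {
  out <- list(seed = report$seed,
              halted = report$halted,
              halt_reason = report$halt_reason,
              gates = lapply(report$gates, function(g)
                list(passed = g$passed, detail = g$detail)),
              integration_verdicts = as.list(report$unit_roots$verdicts))
  if (report$halted) return(out)
  out$consensus_lag <- report$lag_selection$consensus_lag
  out$ecm_order <- paste0("(", report$ecm$orders$p, ",",
                          paste(report$ecm$orders$q, collapse = ","), ")")
  out$ect_coefficient <- report$ecm$ect_coefficient
  out$r_squared <- report$ecm$r.squared
  out$adj_r_squared <- report$ecm$adj.r.squared
  out$durbin_watson <- report$ecm$durbin_watson
  out$bounds_f <- report$bounds$F_statistic
  out$bounds_decision <- report$bounds$decision
  if (!is.null(report$long_run))
    out$long_run <- stats::setNames(as.list(report$long_run$estimate),
                                    report$long_run$regressor)
  if (!is.null(report$cusum)) out$cusum_crossed <- report$cusum$crossed
  if (length(report$simulations))
    out$equilibrium_shifts <- lapply(report$simulations, function(s)
      list(estimate = s$equilibrium_shift$estimate,
           significant = as.list(s$equilibrium_shift$significant)))
  out
}

#' Write all report artifacts to a directory
#'
#' One CSV per section (panel, unit roots, lag selection, bounds,
#' coefficients, long-run multipliers, diagnostics, CUSUM trace, one fan per
#' scenario) plus `summary.json`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_panel(report$panel, p("panel.csv"))
  if (!is.null(report$unit_roots))
    write_unit_root_report(report$unit_roots, p("unit_roots.csv"))
  if (!is.null(report$lag_selection))
    utils::write.csv(as.data.frame(report$lag_selection),
                     p("lag_selection.csv"), row.names = FALSE)
  if (!is.null(report$ecm))
    utils::write.csv(ecm_coefficient_table(report$ecm),
                     p("ecm_coefficients.csv"), row.names = FALSE)
  if (!is.null(report$bounds))
    utils::write.csv(cbind(F_statistic = report$bounds$F_statistic,
                           report$bounds$critical_bounds,
                           decision = report$bounds$decision),
                     p("bounds.csv"), row.names = FALSE)
  if (!is.null(report$long_run))
    utils::write.csv(report$long_run, p("long_run_multipliers.csv"),
                     row.names = FALSE)
  if (!is.null(report$diagnostics))
    utils::write.csv(report$diagnostics$table, p("diagnostics.csv"),
                     row.names = FALSE)
  if (!is.null(report$cusum))
    utils::write.csv(as.data.frame(report$cusum), p("cusum.csv"),
                     row.names = FALSE)
  for (nm in names(report$simulations))
    write_fan(report$simulations[[nm]], p(paste0("fan_", nm, ".csv")))
  jsonlite::write_json(report_summary(report), p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
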