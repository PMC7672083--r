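#' Classify the order of integration of every panel variable
#'
#' Runs all four tests (ADF, PP, KPSS, DF-GLS) on each variable in levels and
#' in first differences, then applies a majority rule at the 5% level across
#' ADF, PP, DF-GLS and the direction-inverted KPSS: a form is judged
#' stationary when at least three of the four tests agree (ties resolved
#' conservatively toward the higher integration order). A variable is I(0) if
#' its level is stationary, I(1) if only its first difference is, and
#' `"I(2)+"` otherwise — in which case downstream ARDL estimation must not
#' proceed.
#'
#' @param panel a `monthly_panel`.
#' @param vars variables to classify (default all).
#' @param deterministic deterministic specification passed to every test.
#' @param max_lag,bandwidth optional nuisance settings forwarded to the tests.
#' @return object of class `unit_root_report`: a list with `table` (one row
#'   per variable x test x form: statistic, nuisance setting, 1%/5%
#'   decisions) and `verdicts` (named character vector of `"I(0)"`, `"I(1)"`,
#'   `"I(2)+"`).
#' @export
classify_integration <- function(panel, vars = panel_vars(panel),
                                 deterministic = "constant",
                                 max_lag = NULL, bandwidth = NULL) {
  stopifnot(inherits(panel, "monthly_panel"))
  rows <- list()
  verdicts <- character(0)
  for (v in vars) {
    y <- panel_matrix(panel, v)[, 1L]
    forms <- list(level = y, diff = diff(y))
    results <- list()
    for (f in names(forms)) {
      x <- forms[[f]]
      results[[f]] <- list(
        ADF = adf_test(x, max_lag = max_lag, deterministic = deterministic),
        PP = pp_test(x, bandwidth = bandwidth, deterministic = deterministic),
        KPSS = kpss_test(x, bandwidth = bandwidth, deterministic = deterministic),
        `DF-GLS` = dfgls_test(x, max_lag = max_lag, deterministic = deterministic))
      for (tname in names(results[[f]])) {
        r <- results[[f]][[tname]]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, test = tname, form = f,
          statistic = r$statistic, setting = r$nuisance,
          reject_1pct = r$reject_1pct, reject_5pct = r$reject_5pct,
          stringsAsFactors = FALSE)
      }
    }
    verdicts[v] <- integration_verdict(results)
  }
  structure(list(table = do.call(rbind, rows), verdicts = verdicts,
                 deterministic = deterministic),
            class = "unit_root_report")
}

# stationarity votes at the 5% level with KPSS inverted; >= 3 of 4 wins
stationary_by_majority <- function(tests) {
  votes <- c(tests$ADF$reject_5pct, tests$PP$reject_5pct,
             tests$`DF-GLS`$reject_5pct, !tests$KPSS$reject_5pct)
  sum(votes) >= 3L
}

integration_verdict <- function(results) {
  if (!all(c("level", "diff") %in% names(results)))
    stop("incomplete report: need all tests at level and first difference",
         call. = FALSE)
  for (f in c("level", "diff"))
    if (!all(c("ADF", "PP", "KPSS", "DF-GLS") %in% names(results[[f]])))
      stop("incomplete report: missing test results at ", f, call. = FALSE)
  if (stationary_by_majority(results$level)) "I(0)"
  else if (stationary_by_majority(results$diff)) "I(1)"
  else "I(2)+"
}

#' @export
print.unit_root_report <- function(x, ...) {
  cat("Unit-root report (", x$deterministic, " specification)\n", sep = "")
  for (v in names(x$verdicts)) cat("  ", v, ": ", x$verdicts[[v]], "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.unit_root_report <- function(x, ...) {
  tab <- x$table
  tab$verdict <- x$verdicts[tab$variable]
  tab
}

#' Write a unit-root report as tidy CSV
#'
#' One row per (variable, test, form) with the statistic, the nuisance
#' setting (lags or bandwidth), the 1%/5% decisions and the per-variable
#' integration verdict.
#'
#' @param report a `unit_root_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_root_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
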