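## Unit-root and stationarity tests: ADF, Phillips-Perron, KPSS, DF-GLS.
##
## All four tests operate on a single numeric series with a constant-only or
## constant-plus-trend deterministic specification and report star-level
## decisions at 1% and 5% against embedded asymptotic critical values.

## ---- shared internals ------------------------------------------------------

# least squares via QR; returns coefficients, standard errors, residuals,
# and the t-ratio of a requested column
ols_qr <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular design matrix in test regression", call. = FALSE)
  coef <- qr.coef(qx, y)
  resid <- as.numeric(y - X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  Rinv <- chol2inv(qr.R(qx))
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  piv <- qx$pivot
  xtx_inv[piv, piv] <- Rinv
  list(coef = coef, se = sqrt(sigma2 * diag(xtx_inv)), resid = resid,
       sigma2 = sigma2, df = df, xtx_inv = xtx_inv)
}

check_series <- function(series, min_n = 20L) {
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  if (length(series) < min_n)
    stop("series too short: ", length(series), " < ", min_n, call. = FALSE)
  if (stats::var(series) < 1e-24)
    stop("degenerate input: series has zero variance", call. = FALSE)
  as.numeric(series)
}

schwert_lag <- function(n) as.integer(floor(12 * (n / 100)^0.25))

default_bandwidth <- function(n) as.integer(floor(4 * (n / 100)^(2 / 9)))

# Bartlett-kernel long-run variance of a (mean-zero) residual series
bartlett_lrv <- function(u, bandwidth) {
  n <- length(u)
  g0 <- sum(u^2) / n
  if (bandwidth < 1L) return(g0)
  acc <- g0
  for (j in seq_len(bandwidth)) {
    gj <- sum(u[(j + 1):n] * u[1:(n - j)]) / n
    acc <- acc + 2 * (1 - j / (bandwidth + 1)) * gj
  }
  acc
}

# Dickey-Fuller style regression of dy_t on [deterministics, y_{t-1},
# dy_{t-1..p}]; returns the t-ratio on y_{t-1} and the full regression
df_regression <- function(y, p, deterministic = c("constant", "trend", "none")) {
  deterministic <- match.arg(deterministic)
  n <- length(y)
  dy <- diff(y)
  idx <- (p + 2):n                      # rows of y usable as response Delta y_t
  target <- dy[idx - 1L]
  X <- cbind(y_lag = y[idx - 1L])
  if (p > 0L)
    for (i in seq_len(p)) X <- cbind(X, dy[idx - 1L - i])
  colnames(X) <- c("y_lag", if (p > 0L) paste0("d_lag", seq_len(p)))
  if (deterministic == "constant") X <- cbind(const = 1, X)
  if (deterministic == "trend")    X <- cbind(const = 1, trend = idx, X)
  fit <- ols_qr(X, target)
  k <- which(colnames(X) == "y_lag")
  list(fit = fit, t_statistic = fit$coef[[k]] / fit$se[[k]],
       gamma = fit$coef[[k]], se_gamma = fit$se[[k]],
       n_eff = length(target), X = X, y = target,
       deterministic = deterministic, p = p)
}

# Schwarz-criterion lag choice on a common estimation sample
select_df_lag <- function(y, max_lag, deterministic) {
  n <- length(y)
  dy <- diff(y)
  idx <- (max_lag + 2):n
  target <- dy[idx - 1L]
  n_eff <- length(target)
  base <- switch(deterministic,
                 none = NULL,
                 constant = matrix(1, n_eff, 1),
                 trend = cbind(1, idx))
  bics <- vapply(0:max_lag, function(p) {
    X <- cbind(base, y[idx - 1L])
    if (p > 0L) for (i in seq_len(p)) X <- cbind(X, dy[idx - 1L - i])
    res <- qr.resid(qr(X), target)
    n_eff * log(sum(res^2) / n_eff) + ncol(X) * log(n_eff)
  }, numeric(1))
  (0:max_lag)[which.min(bics)]
}

## ---- embedded asymptotic critical values (1%, 5%, 10%) ---------------------

df_critical_values <- function(deterministic) {
  switch(deterministic,
         none = c(`1%` = -2.58, `5%` = -1.95, `10%` = -1.62),
         constant = c(`1%` = -3.43, `5%` = -2.86, `10%` = -2.57),
         trend = c(`1%` = -3.96, `5%` = -3.41, `10%` = -3.13))
}

dfgls_critical_values <- function(deterministic) {
  switch(deterministic,
         constant = c(`1%` = -2.58, `5%` = -1.95, `10%` = -1.62),
         trend = c(`1%` = -3.48, `5%` = -2.89, `10%` = -2.57))
}

kpss_critical_values <- function(deterministic) {
  switch(deterministic,
         constant = c(`1%` = 0.739, `5%` = 0.463, `10%` = 0.347),
         trend = c(`1%` = 0.216, `5%` = 0.146, `10%` = 0.119))
}

p_value_band <- function(statistic, cv, lower_tail = TRUE) {
  if (lower_tail) {
    if (statistic < cv[["1%"]]) "< 0.01"
    else if (statistic < cv[["5%"]]) "0.01-0.05"
    else if (statistic < cv[["10%"]]) "0.05-0.10"
    else "> 0.10"
  } else {
    if (statistic > cv[["1%"]]) "< 0.01"
    else if (statistic > cv[["5%"]]) "0.01-0.05"
    else if (statistic > cv[["10%"]]) "0.05-0.10"
    else "> 0.10"
  }
}

new_urtest <- function(test, statistic, cv, lower_tail, nuisance, nuisance_name,
                       deterministic, n, null, regression = NULL) {
  structure(list(test = test, statistic = statistic,
                 critical_values = cv,
                 reject_1pct = if (lower_tail) statistic < cv[["1%"]]
                               else statistic > cv[["1%"]],
                 reject_5pct = if (lower_tail) statistic < cv[["5%"]]
                               else statistic > cv[["5%"]],
                 p_value_band = p_value_band(statistic, cv, lower_tail),
                 nuisance = nuisance, nuisance_name = nuisance_name,
                 deterministic = deterministic, n = n, null = null,
                 regression = regression),
            class = "fire_urtest")
}

#' @export
print.fire_urtest <- function(x, ...) {
  cat(x$test, "test (", x$deterministic, "), H0:", x$null, "\n")
  cat("  statistic:", format(x$statistic, digits = 4),
      " [", x$nuisance_name, "=", x$nuisance, ", n =", x$n, "]\n")
  cat("  critical values:",
      paste(names(x$critical_values),
            format(x$critical_values, digits = 3), collapse = "  "), "\n")
  cat("  reject H0 at 5%:", x$reject_5pct,
      " at 1%:", x$reject_1pct,
      "  p-value band:", x$p_value_band, "\n")
  invisible(x)
}

## ---- the four tests --------------------------------------------------------

#' Augmented Dickey-Fuller test
#'
#' Tests the null of a unit root (\eqn{\rho = 1} in
#' \eqn{y_t = a + \rho y_{t-1} + \varepsilon_t}) against the stationary
#' alternative \eqn{\rho < 1}, augmenting the test regression with lagged
#' differences to absorb higher-order autocorrelation. The lag order is
#' chosen by minimising the Schwarz criterion over `0..max_lag` on a common
#' estimation sample; `max_lag` defaults to Schwert's rule
#' \eqn{\lfloor 12 (n/100)^{1/4} \rfloor}.
#'
#' @param series numeric vector, no missing values, non-constant.
#' @param max_lag maximum augmentation lag scanned.
#' @param deterministic `"constant"` (default, matching a model with an
#'   intercept and no trend) or `"trend"`.
#' @return a `fire_urtest` with the t-statistic on the lagged level, 1%/5%
#'   decisions against Dickey-Fuller critical values, a coarse p-value band,
#'   and the underlying test regression (coefficients, residuals, lag order).
#' @export
adf_test <- function(series, max_lag = NULL,
                     deterministic = c("constant", "trend")) {
  deterministic <- match.arg(deterministic)
  y <- check_series(series)
  n <- length(y)
  if (is.null(max_lag)) max_lag <- schwert_lag(n)
  if (n < max_lag + 10L)
    stop("series too short for max_lag = ", max_lag, call. = FALSE)
  p <- select_df_lag(y, max_lag, deterministic)
  reg <- df_regression(y, p, deterministic)
  cv <- df_critical_values(deterministic)
  regression <- list(intercept = if (deterministic == "none") 0
                     else reg$fit$coef[["const"]],
                     rho_minus_1 = reg$gamma,
                     lag_coefficients = if (p > 0L)
                       reg$fit$coef[paste0("d_lag", seq_len(p))] else numeric(0),
                     residuals = reg$fit$resid,
                     t_statistic = reg$t_statistic,
                     lags_used = p,
                     deterministic_spec = deterministic)
  new_urtest("ADF", reg$t_statistic, cv, lower_tail = TRUE,
             nuisance = p, nuisance_name = "lags",
             deterministic = deterministic, n = n,
             null = "unit root", regression = regression)
}

#' Phillips-Perron test
#'
#' The \eqn{Z_t} statistic: a Dickey-Fuller regression with no lag
#' augmentation whose t-ratio is corrected non-parametrically with a
#' Newey-West (Bartlett kernel) long-run variance, making the test robust to
#' unspecified serial correlation and heteroskedasticity in the errors.
#' Default bandwidth \eqn{\lfloor 4 (n/100)^{2/9} \rfloor}.
#'
#' @inheritParams adf_test
#' @param bandwidth Bartlett-kernel truncation lag.
#' @return a `fire_urtest` (same decision reporting as [adf_test()]).
#' @export
pp_test <- function(series, bandwidth = NULL,
                    deterministic = c("constant", "trend")) {
  deterministic <- match.arg(deterministic)
  y <- check_series(series)
  n <- length(y)
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(n)
  reg <- df_regression(y, 0L, deterministic)
  u <- reg$fit$resid
  n_eff <- reg$n_eff
  g0 <- sum(u^2) / n_eff
  lam2 <- bartlett_lrv(u, bandwidth)
  s <- sqrt(reg$fit$sigma2)
  z_t <- sqrt(g0 / lam2) * reg$t_statistic -
    (lam2 - g0) / (2 * sqrt(lam2)) * (n_eff * reg$se_gamma / s)
  new_urtest("PP", z_t, df_critical_values(deterministic), lower_tail = TRUE,
             nuisance = bandwidth, nuisance_name = "bandwidth",
             deterministic = deterministic, n = n, null = "unit root")
}

#' KPSS stationarity test
#'
#' Tests the null of (level or trend) stationarity: the LM statistic
#' \eqn{n^{-2} \sum_t S_t^2 / \hat\lambda^2} where \eqn{S_t} are partial sums
#' of the demeaned (or detrended) series and \eqn{\hat\lambda^2} is a
#' Bartlett-kernel long-run variance. The decision direction is inverted
#' relative to the other tests: rejection indicates non-stationarity.
#'
#' @inheritParams pp_test
#' @return a `fire_urtest`; `reject_5pct = TRUE` means stationarity rejected.
#' @export
kpss_test <- function(series, bandwidth = NULL,
                      deterministic = c("constant", "trend")) {
  deterministic <- match.arg(deterministic)
  y <- check_series(series)
  n <- length(y)
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(n)
  e <- if (deterministic == "constant") y - mean(y)
       else stats::lm.fit(cbind(1, seq_len(n)), y)$residuals
  S <- cumsum(e)
  lam2 <- bartlett_lrv(e, bandwidth)
  stat <- sum(S^2) / (n^2 * lam2)
  new_urtest("KPSS", stat, kpss_critical_values(deterministic),
             lower_tail = FALSE, nuisance = bandwidth,
             nuisance_name = "bandwidth", deterministic = deterministic,
             n = n, null = "stationarity")
}

#' DF-GLS (Elliott-Rothenberg-Stock) unit-root test
#'
#' Locally GLS-demeans (or detrends) the series with the standard
#' non-centrality constants (-7 constant-only, -13.5 with trend), then runs an
#' ADF-type regression with no deterministic terms on the detrended series.
#' More powerful than ADF for roots near unity in small samples.
#'
#' @inheritParams adf_test
#' @return a `fire_urtest` with the detrended-regression details.
#' @export
dfgls_test <- function(series, max_lag = NULL,
                       deterministic = c("constant", "trend")) {
  deterministic <- match.arg(deterministic)
  y <- check_series(series)
  n <- length(y)
  if (is.null(max_lag)) max_lag <- schwert_lag(n)
  if (n < max_lag + 10L)
    stop("series too short for max_lag = ", max_lag, call. = FALSE)
  cbar <- if (deterministic == "constant") -7 else -13.5
  abar <- 1 + cbar / n
  z <- if (deterministic == "constant") matrix(1, n, 1)
       else cbind(1, seq_len(n))
  ya <- c(y[1L], y[-1L] - abar * y[-n])
  za <- rbind(z[1L, , drop = FALSE],
              z[-1L, , drop = FALSE] - abar * z[-n, , drop = FALSE])
  beta <- qr.coef(qr(za), ya)
  yd <- as.numeric(y - z %*% beta)
  if (stats::var(yd) < 1e-20)
    stop("degenerate input: series is exactly deterministic after GLS detrending",
         call. = FALSE)
  p <- select_df_lag(yd, max_lag, "none")
  reg <- df_regression(yd, p, "none")
  regression <- list(intercept = 0,
                     rho_minus_1 = reg$gamma,
                     lag_coefficients = if (p > 0L)
                       reg$fit$coef[paste0("d_lag", seq_len(p))] else numeric(0),
                     residuals = reg$fit$resid,
                     t_statistic = reg$t_statistic,
                     lags_used = p,
                     deterministic_spec = deterministic,
                     detrended = yd)
  new_urtest("DF-GLS", reg$t_statistic, dfgls_critical_values(deterministic),
             lower_tail = TRUE, nuisance = p, nuisance_name = "lags",
             deterministic = deterministic, n = n,
             null = "unit root", regression = regression)
}

#' Monte-Carlo finite-sample Dickey-Fuller critical values
#'
#' Optional refinement of the embedded asymptotic tables: simulates the null
#' distribution of the Dickey-Fuller t-statistic for a driftless random walk
#' of length `n` and returns empirical 1%/5%/10% quantiles.
#'
#' @param n series length.
#' @param deterministic `"constant"` or `"trend"`.
#' @param n_sim number of replications.
#' @param seed integer seed.
#' @return named numeric vector of critical values.
#' @export
simulate_df_critical_values <- function(n, deterministic = c("constant", "trend"),
                                        n_sim = 10000L, seed = 1L) {
  deterministic <- match.arg(deterministic)
  set.seed(seed)
  stats_ <- vapply(seq_len(n_sim), function(i) {
    y <- cumsum(stats::rnorm(n))
    df_regression(y, 0L, deterministic)$t_statistic
  }, numeric(1))
  q <- stats::quantile(stats_, c(0.01, 0.05, 0.10), names = FALSE, type = 7)
  stats::setNames(q, c("1%", "5%", "10%"))
}
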