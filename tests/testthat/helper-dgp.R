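# Shared test fixtures: known-truth data-generating processes and
# independent brute-force oracles.

# Three-regressor cointegrated DGP: x1 is a random walk carrying the
# long-run relation (theta = 2), x2 an unrelated random walk, x3 a
# stationary AR(0.7). Intercept 0.5, innovation sd 0.2, response sd 0.1.
coint_dgp <- function(seed, n = 240, adjustment = -0.6, noise_sd = 0.1) {
  dgp_config(
    n_months = n,
    variable_specs = data.frame(
      name = c("x1", "x2", "x3"), order = c(1, 1, 0),
      seasonal_amplitude = 0, innovation_sd = 0.2, ar = c(0, 0, 0.7)),
    cointegration_vector = c(x1 = 2),
    adjustment_speed = adjustment,
    response_innovation_sd = noise_sd,
    intercept = 0.5,
    seed = seed)
}

# Single-regressor DGP (random-walk regressor, theta = 2, adjustment -0.5)
single_dgp <- function(seed, n = 240, theta = 2, adjustment = -0.5,
                       noise_sd = 0.1) {
  dgp_config(
    n_months = n,
    variable_specs = data.frame(name = "wind", order = 1,
                                seasonal_amplitude = 0,
                                innovation_sd = 0.2, ar = 0),
    cointegration_vector = c(wind = theta),
    adjustment_speed = adjustment,
    response_innovation_sd = noise_sd,
    intercept = 0.5,
    seed = seed)
}

# Panel of mutually independent driftless random walks (no cointegration)
rw_panel <- function(seed, n = 216, k = 3) {
  set.seed(seed)
  vals <- as.data.frame(matrix(rnorm(n * (k + 1)), n, k + 1))
  names(vals) <- c("y", paste0("x", seq_len(k)))
  monthly_panel(as.data.frame(lapply(vals, cumsum)))
}

# Response simulated with caller-supplied innovations and/or a
# time-varying intercept (for structural-break and serially-correlated
# error experiments); regressors come from the config's own stream.
gen_response_custom <- function(cfg, innovations = NULL,
                                intercept_path = NULL) {
  reg <- generate_regressors(cfg)
  X <- panel_matrix(reg, cfg$variable_specs$name)
  n <- nrow(X)
  if (is.null(innovations)) {
    set.seed(cfg$seed + 1L)
    innovations <- rnorm(n, 0, cfg$response_innovation_sd)
  }
  a <- if (is.null(intercept_path)) rep(cfg$intercept, n) else intercept_path
  eq <- as.numeric(X %*% cfg$theta)
  y <- numeric(n)
  y[1] <- eq[1] - cfg$intercept / cfg$adjustment_speed
  for (t in 2:n)
    y[t] <- y[t - 1] + a[t] + cfg$adjustment_speed * (y[t - 1] - eq[t - 1]) +
      innovations[t]
  vals <- cbind(as.data.frame(X), area_burned = y)
  monthly_panel(vals)
}

# ---- independent oracles (normal equations, explicit designs) -------------

# Dickey-Fuller t-ratio by explicitly building the design matrix and
# solving the normal equations (independent of the package's QR path).
bf_df_tstat <- function(y, p, deterministic = c("constant", "trend", "none")) {
  deterministic <- match.arg(deterministic)
  n <- length(y)
  dy <- diff(y)
  idx <- (p + 2):n
  X <- cbind(y[idx - 1])
  if (p > 0) for (i in seq_len(p)) X <- cbind(X, dy[idx - 1 - i])
  if (deterministic == "constant") X <- cbind(1, X)
  if (deterministic == "trend") X <- cbind(1, idx, X)
  yv <- dy[idx - 1]
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% yv)
  e <- yv - X %*% b
  s2 <- sum(e^2) / (length(yv) - ncol(X))
  pos <- ncol(X) - p                      # column of y_{t-1}
  b[pos] / sqrt(s2 * solve(XtX)[pos, pos])
}

# GLS local detrending with the standard non-centrality constants,
# written directly from the quasi-differencing formulas.
bf_gls_detrend <- function(y, deterministic = c("constant", "trend")) {
  deterministic <- match.arg(deterministic)
  n <- length(y)
  cbar <- if (deterministic == "constant") -7 else -13.5
  abar <- 1 + cbar / n
  z <- if (deterministic == "constant") matrix(1, n, 1) else cbind(1, 1:n)
  ya <- c(y[1], y[-1] - abar * y[-n])
  za <- rbind(z[1, , drop = FALSE],
              z[-1, , drop = FALSE] - abar * z[-n, , drop = FALSE])
  beta <- solve(t(za) %*% za, t(za) %*% ya)
  as.numeric(y - z %*% beta)
}

# AR(1) draw of length n (stationary start), for size/power experiments
ar1_series <- function(n, rho, sd = 1) {
  if (rho == 0) return(rnorm(n, 0, sd))
  as.numeric(arima.sim(list(ar = rho), n, sd = sd))
}
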