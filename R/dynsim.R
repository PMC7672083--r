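#' Counterfactual shock scenario
#'
#' Configuration of a single-regressor counterfactual: at scenario time
#' `shock_time` the shocked regressor is moved by
#' `shock_sign x shock_magnitude x (its sample standard deviation)`, either
#' permanently (a sustained level shift, the default — responses then settle
#' at a new equilibrium) or as a one-period pulse. `burn_in` periods are
#' simulated and discarded before scenario time 1 so the recursion forgets
#' its starting state; the shock clock starts after burn-in.
#'
#' @param regressor name of the shocked regressor.
#' @param shock_sign +1 or -1.
#' @param shock_magnitude shock size in multiples of the regressor's sample
#'   standard deviation (default 1).
#' @param shock_time scenario period of the shock (default 10).
#' @param shock_persistence `"permanent"` (default) or `"pulse"`.
#' @param scenario_length number of scenario periods (default 30; must
#'   exceed `shock_time + 5`).
#' @param n_simulations number of stochastic replications (default 5000).
#' @param burn_in discarded initial simulated periods (default 20).
#' @param percentiles fan band coverages in percent (default 75, 90, 95).
#' @param seed integer seed.
#' @return object of class `shock_scenario`.
#' @export
shock_scenario <- function(regressor, shock_sign = 1, shock_magnitude = 1,
                           shock_time = 10L,
                           shock_persistence = c("permanent", "pulse"),
                           scenario_length = 30L, n_simulations = 5000L,
                           burn_in = 20L, percentiles = c(75, 90, 95),
                           seed = 1L) {
  shock_persistence <- match.arg(shock_persistence)
  if (!shock_sign %in% c(-1, 1)) stop("shock_sign must be +1 or -1", call. = FALSE)
  if (shock_magnitude < 0) stop("shock_magnitude must be non-negative", call. = FALSE)
  if (shock_time < 1L) stop("shock_time must be at least 1", call. = FALSE)
  if (scenario_length <= shock_time + 5L)
    stop("scenario_length must exceed shock_time + 5", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be non-negative", call. = FALSE)
  structure(list(regressor = regressor, shock_sign = shock_sign,
                 shock_magnitude = shock_magnitude,
                 shock_time = as.integer(shock_time),
                 shock_persistence = shock_persistence,
                 scenario_length = as.integer(scenario_length),
                 n_simulations = as.integer(n_simulations),
                 burn_in = as.integer(burn_in),
                 percentiles = sort(percentiles), seed = as.integer(seed)),
            class = "shock_scenario")
}

#' Stochastic simulation of the fitted ECM under a shock
#'
#' Simulates the estimated error-correction recursion forward
#' `n_simulations` times: each replication draws a coefficient vector from
#' the multivariate normal centred at the estimates with the fit covariance,
#' holds every regressor at its sample mean, starts the response at the
#' point-estimate equilibrium, iterates through the burn-in and scenario
#' periods adding i.i.d. normal innovations with the residual standard
#' deviation, and applies the configured shock to the single shocked
#' regressor at `shock_time`. The fan is the per-period mean and equal-tailed
#' empirical percentile bands across replications; the equilibrium shift is
#' the terminal-window (last 5 periods) mean response relative to the
#' pre-shock mean, judged significant at a band level when the band excludes
#' the pre-shock mean over the whole terminal window.
#'
#' The simulation presumes a valid level relationship (the fit should have
#' passed the bounds test) and refuses to run when \eqn{\delta_0 \ge 0},
#' which would make the recursion divergent.
#'
#' @param fit an [fit_ecm_ardl()] fit.
#' @param panel the `monthly_panel` the fit was estimated on (source of the
#'   regressor means and the shock's standard deviation).
#' @param scenario a [shock_scenario()].
#' @param include_parameter_uncertainty draw coefficients from their
#'   sampling distribution (default `TRUE`; `FALSE` fixes them at the
#'   estimates).
#' @param include_residual_noise add the residual-scale innovations
#'   (default `TRUE`).
#' @return object of class `simulation_fan`: `fan` data.frame (time, mean,
#'   lo/hi per percentile), `pre_shock_mean`, `equilibrium_shift`
#'   (estimate + per-level significance), and the scenario.
#' @export
simulate_response <- function(fit, panel, scenario,
                              include_parameter_uncertainty = TRUE,
                              include_residual_noise = TRUE) {
  stopifnot(inherits(fit, "ecm_fit"), inherits(panel, "monthly_panel"),
            inherits(scenario, "shock_scenario"))
  if (!scenario$regressor %in% fit$regressors)
    stop("shocked regressor '", scenario$regressor, "' not in the fit",
         call. = FALSE)
  if (fit$ect_coefficient >= 0)
    stop("non-negative error-correction coefficient (",
         format(fit$ect_coefficient, digits = 4),
         "): recursion risks divergence, refusing to simulate", call. = FALSE)

  cf <- stats::coef(fit$lm)
  npar <- length(cf)
  n_sim <- scenario$n_simulations
  set.seed(scenario$seed)
  B <- if (include_parameter_uncertainty)
    MASS::mvrnorm(n_sim, mu = cf, Sigma = fit$vcov)
  else matrix(cf, n_sim, npar, byrow = TRUE, dimnames = list(NULL, names(cf)))
  resid_sd <- sqrt(fit$sigma2)
  total <- scenario$burn_in + scenario$scenario_length
  E <- if (include_residual_noise && resid_sd > 0)
    matrix(stats::rnorm(n_sim * total, 0, resid_sd), n_sim, total)
  else matrix(0, n_sim, total)

  xbar <- colMeans(panel_matrix(panel, fit$regressors))
  shock <- scenario$shock_sign * scenario$shock_magnitude *
    stats::sd(panel_matrix(panel, scenario$regressor)[, 1L])
  shock_abs <- scenario$burn_in + scenario$shock_time

  # regressor level paths (common to all replications) and the implied
  # difference path of the shocked regressor
  xlev <- matrix(xbar, total, length(xbar), byrow = TRUE,
                 dimnames = list(NULL, fit$regressors))
  dx <- numeric(total)
  j <- scenario$regressor
  if (scenario$shock_persistence == "permanent") {
    xlev[shock_abs:total, j] <- xbar[[j]] + shock
    dx[shock_abs] <- shock
  } else {
    xlev[shock_abs, j] <- xbar[[j]] + shock
    dx[shock_abs] <- shock
    if (shock_abs < total) dx[shock_abs + 1L] <- -shock
  }

  a0 <- B[, "(Intercept)"]
  d0 <- B[, "lag_y"]
  Dlev <- B[, paste0("lag_", fit$regressors), drop = FALSE]
  p <- fit$orders$p
  A <- if (p > 0L) B[, paste0("d_y_l", seq_len(p)), drop = FALSE] else NULL
  # short-run terms of the shocked regressor (others have zero differences)
  q_j <- fit$orders$q[[j]]
  beta_lags <- if (q_j > 0L) {
    if (fit$orders$contemporaneous) 0:(q_j - 1L) else seq_len(q_j)
  } else integer(0)
  Bj <- if (length(beta_lags))
    B[, paste0("d_", j, "_l", beta_lags), drop = FALSE] else NULL

  # start every replication at the point-estimate equilibrium
  y0 <- -(cf[["(Intercept)"]] +
            sum(cf[paste0("lag_", fit$regressors)] * xbar)) / cf[["lag_y"]]
  y_prev <- rep(y0, n_sim)
  dy_hist <- if (p > 0L) matrix(0, n_sim, p) else NULL
  Y <- matrix(NA_real_, n_sim, scenario$scenario_length)
  for (t in seq_len(total)) {
    dy <- a0 + d0 * y_prev + as.numeric(Dlev %*% xlev[t, ]) + E[, t]
    if (p > 0L) dy <- dy + rowSums(A * dy_hist)
    if (length(beta_lags)) {
      dxv <- vapply(beta_lags, function(l)
        if (t - l >= 1L) dx[t - l] else 0, numeric(1))
      dy <- dy + as.numeric(Bj %*% dxv)
    }
    y_prev <- y_prev + dy
    if (p > 0L)
      dy_hist <- cbind(dy, dy_hist[, -p, drop = FALSE])
    if (t > scenario$burn_in) Y[, t - scenario$burn_in] <- y_prev
  }

  mean_path <- colMeans(Y)
  fan <- data.frame(time = seq_len(scenario$scenario_length), mean = mean_path)
  for (P in scenario$percentiles) {
    tail_p <- (1 - P / 100) / 2
    qs <- apply(Y, 2L, stats::quantile, probs = c(tail_p, 1 - tail_p),
                names = FALSE)
    fan[[sprintf("lo%g", P)]] <- qs[1L, ]
    fan[[sprintf("hi%g", P)]] <- qs[2L, ]
  }
  pre <- mean(mean_path[seq_len(scenario$shock_time - 1L)])
  last5 <- (scenario$scenario_length - 4L):scenario$scenario_length
  shift <- mean(mean_path[last5]) - pre
  signif <- vapply(scenario$percentiles, function(P) {
    lo <- fan[[sprintf("lo%g", P)]][last5]
    hi <- fan[[sprintf("hi%g", P)]][last5]
    all(lo > pre | hi < pre)
  }, logical(1))
  structure(list(fan = fan, pre_shock_mean = pre,
                 equilibrium_shift = list(
                   estimate = shift,
                   significant = stats::setNames(signif,
                                                 sprintf("%g%%",
                                                         scenario$percentiles))),
                 scenario = scenario,
                 theta_shock = shock),
            class = "simulation_fan")
}

#' @export
print.simulation_fan <- function(x, ...) {
  s <- x$scenario
  cat("Shock-response fan: ", ifelse(s$shock_sign > 0, "+", "-"),
      s$shock_magnitude, " SD ", s$shock_persistence, " shock to '",
      s$regressor, "' at t = ", s$shock_time, " (", s$n_simulations,
      " simulations)\n", sep = "")
  cat("  pre-shock mean:", format(x$pre_shock_mean, digits = 4), "\n")
  cat("  equilibrium shift:", format(x$equilibrium_shift$estimate, digits = 4),
      "\n  significant:",
      paste(names(x$equilibrium_shift$significant),
            x$equilibrium_shift$significant, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.simulation_fan <- function(x, ...) x$fan

#' Equilibrium-shift verdict of a simulation fan
#'
#' Per band level: the long-run change is significant when the band over the
#' last five scenario periods excludes the pre-shock mean on every period.
#' Verdicts are monotone by band nesting (significant at 95% implies 90%
#' implies 75%).
#'
#' @param fan a `simulation_fan` whose scenario has
#'   `scenario_length - shock_time >= 10`.
#' @return data.frame with `level`, `significant`, plus the shift estimate
#'   as attribute `estimate`.
#' @export
equilibrium_shift_report <- function(fan) {
  stopifnot(inherits(fan, "simulation_fan"))
  s <- fan$scenario
  if (s$scenario_length - s$shock_time < 10L)
    stop("terminal window too short: need scenario_length - shock_time >= 10",
         call. = FALSE)
  out <- data.frame(level = names(fan$equilibrium_shift$significant),
                    significant = unname(fan$equilibrium_shift$significant),
                    stringsAsFactors = FALSE)
  attr(out, "estimate") <- fan$equilibrium_shift$estimate
  out
}

#' Write a simulation fan as CSV
#' @param fan a `simulation_fan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fan <- function(fan, path) {
  utils::write.csv(as.data.frame(fan), path, row.names = FALSE)
  invisible(path)
}

#' Plot a shock-response fan
#'
#' Dot-and-band chart: mean predicted response as points, nested percentile
#' bands as shaded polygons, with the shock time marked.
#'
#' @param x a `simulation_fan`.
#' @param ... ignored.
#' @return `x`, invisibly; draws on the active graphics device.
#' @export
plot.simulation_fan <- function(x, ...) {
  f <- x$fan
  ps <- sort(x$scenario$percentiles, decreasing = TRUE)
  ylim <- range(f[[sprintf("lo%g", ps[1L])]], f[[sprintf("hi%g", ps[1L])]])
  plot(f$time, f$mean, type = "n", ylim = ylim,
       xlab = "scenario time", ylab = "predicted response",
       main = sprintf("%+g SD shock to %s", x$scenario$shock_sign *
                        x$scenario$shock_magnitude, x$scenario$regressor))
  shades <- grDevices::colorRampPalette(c("#c6dbef", "#2171b5"))(length(ps))
  for (i in seq_along(ps)) {
    graphics::polygon(c(f$time, rev(f$time)),
                      c(f[[sprintf("lo%g", ps[i])]],
                        rev(f[[sprintf("hi%g", ps[i])]])),
                      col = shades[i], border = NA)
  }
  graphics::points(f$time, f$mean, pch = 16, cex = 0.6)
  graphics::abline(v = x$scenario$shock_time, lty = 2)
  invisible(x)
}
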