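fit_for_sim <- function(seed = 71, n = 240) {
  panel <- simulate_fire_panel(single_dgp(seed, n = n))
  list(panel = panel,
       fit = fit_ecm_ardl(panel, "area_burned", p = 0, q = 0))
}

test_that("scenario validation enforces the documented constraints", {
  expect_error(shock_scenario("wind", shock_sign = 2), "sign")
  expect_error(shock_scenario("wind", shock_magnitude = -1), "magnitude")
  expect_error(shock_scenario("wind", shock_time = 28, scenario_length = 30),
               "scenario_length")
  expect_error(shock_scenario("wind", percentiles = c(50, 100)), "percentiles")
})

test_that("a zero-magnitude shock leaves the fan flat at the equilibrium", {
  fs <- fit_for_sim()
  sc <- shock_scenario("wind", shock_magnitude = 0, n_simulations = 3000,
                       seed = 5)
  fan <- simulate_response(fs$fit, fs$panel, sc)
  # per-period Monte-Carlo standard error of the mean path, from the
  # cross-replication spread implied by the 95% band
  sim_se <- max(fan$fan$hi95 - fan$fan$lo95) / (2 * qnorm(0.975)) /
    sqrt(sc$n_simulations)
  spread <- max(fan$fan$mean) - min(fan$fan$mean)
  expect_lt(spread, 6 * sim_se)
  expect_lt(abs(fan$equilibrium_shift$estimate), 3 * sim_se)
  expect_false(any(fan$equilibrium_shift$significant))
})

test_that("the deterministic limit settles at theta times the shock", {
  fs <- fit_for_sim()
  theta <- long_run_multipliers(fs$fit)$estimate
  sc <- shock_scenario("wind", shock_time = 10, scenario_length = 60,
                       n_simulations = 100, seed = 2)
  fan <- simulate_response(fs$fit, fs$panel, sc,
                           include_parameter_uncertainty = FALSE,
                           include_residual_noise = FALSE)
  shock <- fan$theta_shock
  terminal <- fan$fan$mean[60]
  expect_lt(abs(terminal - fan$pre_shock_mean - theta * shock), 1e-6)
  # approach is geometric at rate 1 + delta_0
  dev <- terminal - fan$fan$mean[12:25]
  rate <- dev[-1] / dev[-length(dev)]
  expect_lt(max(abs(rate - (1 + fs$fit$ect_coefficient))), 1e-8)
})

test_that("the deterministic limit matches the closed form across DGPs", {
  for (s in 1:10) {
    adj <- -0.2 - 0.06 * s                 # spread adjustment speeds
    th <- 0.5 + 0.3 * s
    panel <- simulate_fire_panel(single_dgp(400 + s, theta = th,
                                            adjustment = adj))
    fit <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 0)
    theta_hat <- long_run_multipliers(fit)$estimate
    sc <- shock_scenario("wind", shock_time = 8, scenario_length = 80,
                         n_simulations = 50, seed = s)
    fan <- simulate_response(fit, panel, sc,
                             include_parameter_uncertainty = FALSE,
                             include_residual_noise = FALSE)
    expect_lt(abs(fan$fan$mean[80] - fan$pre_shock_mean -
                    theta_hat * fan$theta_shock), 1e-6)
  }
})

test_that("percentile bands nest and the fan is seed-deterministic", {
  fs <- fit_for_sim()
  sc <- shock_scenario("wind", n_simulations = 5000, seed = 9)
  fan <- simulate_response(fs$fit, fs$panel, sc)
  f <- fan$fan
  expect_true(all(f$lo95 <= f$lo90 & f$lo90 <= f$lo75))
  expect_true(all(f$hi75 <= f$hi90 & f$hi90 <= f$hi95))
  expect_true(all(f$lo75 <= f$mean & f$mean <= f$hi75))
  fan2 <- simulate_response(fs$fit, fs$panel, sc)
  expect_identical(fan$fan, fan2$fan)
})

test_that("opposite shocks are mirror images under paired seeds", {
  fs <- fit_for_sim()
  mk <- function(sign, mag = 1) shock_scenario(
    "wind", shock_sign = sign, shock_magnitude = mag,
    n_simulations = 2000, seed = 31)
  pos <- simulate_response(fs$fit, fs$panel, mk(1))$fan$mean
  neg <- simulate_response(fs$fit, fs$panel, mk(-1))$fan$mean
  nul <- simulate_response(fs$fit, fs$panel, mk(1, 0))$fan$mean
  expect_lt(max(abs(pos + neg - 2 * nul)), 1e-8)
})

test_that("a pulse shock reverts while a permanent shock shifts equilibrium", {
  fs <- fit_for_sim()
  base <- shock_scenario("wind", shock_time = 10, scenario_length = 60,
                         n_simulations = 100, seed = 4)
  pulse <- base
  pulse$shock_persistence <- "pulse"
  fan_perm <- simulate_response(fs$fit, fs$panel, base,
                                include_parameter_uncertainty = FALSE,
                                include_residual_noise = FALSE)
  fan_pulse <- simulate_response(fs$fit, fs$panel, pulse,
                                 include_parameter_uncertainty = FALSE,
                                 include_residual_noise = FALSE)
  expect_lt(abs(fan_pulse$fan$mean[60] - fan_pulse$pre_shock_mean), 1e-6)
  expect_gt(abs(fan_perm$fan$mean[60] - fan_perm$pre_shock_mean), 0.1)
})

test_that("a large shock with tiny noise is significant at every level", {
  panel <- simulate_fire_panel(single_dgp(72, noise_sd = 0.01))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 0)
  sc <- shock_scenario("wind", shock_magnitude = 3, n_simulations = 2000,
                       seed = 6)
  fan <- simulate_response(fit, panel, sc)
  expect_true(all(fan$equilibrium_shift$significant))
  rep <- equilibrium_shift_report(fan)
  expect_true(all(rep$significant))
  # monotone verdicts come free with nested bands
  sig <- fan$equilibrium_shift$significant
  expect_true(!sig[["95%"]] || sig[["90%"]])
  expect_true(!sig[["90%"]] || sig[["75%"]])
})

test_that("simulator guards: unknown regressor, unstable adjustment, short window", {
  fs <- fit_for_sim()
  sc <- shock_scenario("gusts", n_simulations = 100, seed = 1)
  expect_error(simulate_response(fs$fit, fs$panel, sc), "gusts")
  unstable <- fs$fit
  unstable$ect_coefficient <- 0.1
  expect_error(simulate_response(unstable, fs$panel,
                                 shock_scenario("wind", seed = 1)),
               "divergence")
  short <- shock_scenario("wind", shock_time = 10, scenario_length = 17,
                          n_simulations = 100, seed = 1)
  fan <- simulate_response(fs$fit, fs$panel, short)
  expect_error(equilibrium_shift_report(fan), "window")
})

test_that("fan means converge as the number of simulations grows", {
  fs <- fit_for_sim()
  mk <- function(n_sim, seed) shock_scenario("wind", n_simulations = n_sim,
                                             seed = seed)
  f1 <- simulate_response(fs$fit, fs$panel, mk(5000, 21))
  f2 <- simulate_response(fs$fit, fs$panel, mk(20000, 22))
  # pooled Monte-Carlo standard error per time point from the band widths
  sd1 <- (f1$fan$hi95 - f1$fan$lo95) / (2 * qnorm(0.975))
  pooled <- sd1 * sqrt(1 / 5000 + 1 / 20000)
  expect_true(all(abs(f1$fan$mean - f2$fan$mean) < 3.5 * pooled))
})
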