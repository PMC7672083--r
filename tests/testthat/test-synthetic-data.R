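one_var_cfg <- function(order, ar = 0, amp = 0, sd = 1, n = 2000, seed = 1) {
  dgp_config(
    n_months = n,
    variable_specs = data.frame(name = "x", order = order,
                                seasonal_amplitude = amp,
                                innovation_sd = sd, ar = ar),
    cointegration_vector = c(x = 1),
    adjustment_speed = -0.5, response_innovation_sd = 0.1, seed = seed)
}

test_that("order-0 variable with zero AR coefficient is white noise", {
  x <- panel_matrix(generate_regressors(one_var_cfg(0)))[, 1]
  # sample variance of N(0,1) white noise: se = sqrt(2/(n-1))
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / 1999))
})

test_that("order-1 variable is a random walk with unit-variance increments", {
  x <- panel_matrix(generate_regressors(one_var_cfg(1)))[, 1]
  expect_lt(abs(var(diff(x)) - 1), 3 * sqrt(2 / 1998))
  # levels wander far beyond the increment scale
  expect_gt(var(x), 10 * var(diff(x)))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- xilingol_dgp_config(seed = 7, n_months = 60)
  expect_identical(simulate_fire_panel(cfg), simulate_fire_panel(cfg))
  cfg2 <- xilingol_dgp_config(seed = 8, n_months = 60)
  expect_false(identical(simulate_fire_panel(cfg), simulate_fire_panel(cfg2)))
})

test_that("full adjustment with zero noise gives the exact lagged relation", {
  cfg <- dgp_config(
    n_months = 50,
    variable_specs = data.frame(name = "x", order = 1, seasonal_amplitude = 0,
                                innovation_sd = 1, ar = 0),
    cointegration_vector = c(x = 2),
    adjustment_speed = -1 + 1e-12,       # full adjustment boundary
    response_innovation_sd = 0, intercept = 0.3, seed = 5)
  panel <- simulate_fire_panel(cfg)
  x <- panel$x
  y <- panel$area_burned
  # y_t = intercept + 2 x_{t-1} exactly for all t >= 2
  expect_lt(max(abs(y[-1] - (0.3 + 2 * x[-length(x)]))), 1e-9)
})

test_that("least squares on the generated recursion recovers the truth", {
  cfg <- single_dgp(31, n = 240, theta = 2, adjustment = -0.5, noise_sd = 0.1)
  panel <- simulate_fire_panel(cfg)
  y <- panel$area_burned
  x <- panel$wind
  n <- length(y)
  dy <- diff(y)
  X <- cbind(1, y[-n], x[-n])
  b <- solve(t(X) %*% X, t(X) %*% dy)
  e <- dy - X %*% b
  se <- sqrt(diag(solve(t(X) %*% X)) * sum(e^2) / (n - 1 - 3))
  expect_lt(abs(b[2] - (-0.5)), 3 * se[2])   # adjustment speed
  expect_lt(abs(b[3] - 1.0), 3 * se[3])      # delta_x = -s * theta = 1.0
})

test_that("zero cointegration vector decouples the response from regressors", {
  cfg <- dgp_config(
    n_months = 2000,
    variable_specs = data.frame(name = c("a", "b"), order = c(0, 1),
                                seasonal_amplitude = 0, innovation_sd = 1,
                                ar = c(0.5, 0)),
    cointegration_vector = numeric(0),
    adjustment_speed = -0.5, response_innovation_sd = 1, seed = 17)
  panel <- simulate_fire_panel(cfg)
  y <- panel$area_burned
  expect_lt(abs(cor(y, panel$a)), 3 / sqrt(2000))
  # response is a stationary AR(1) in levels: variance far below a walk's
  expect_lt(var(y), 5)
})

test_that("noiseless deviations from equilibrium decay at rate 1 + s", {
  cfg <- single_dgp(3, n = 100, adjustment = -0.3, noise_sd = 0)
  # piecewise-constant regressor: the step at t = 50 knocks the response off
  # its new equilibrium, after which the deviation must contract by (1 + s)
  x <- rep(c(1.7, 2.7), c(49, 51))
  panel <- generate_response(monthly_panel(data.frame(wind = x)), cfg)
  y <- panel$area_burned
  target <- 2 * 2.7 - cfg$intercept / cfg$adjustment_speed
  dev <- (y - target)[55:70]
  expect_lt(max(abs(dev[-1] / dev[-length(dev)] - (1 - 0.3))), 1e-10)
})

test_that("invalid configurations are rejected", {
  specs <- data.frame(name = "x", order = 2, seasonal_amplitude = 0,
                      innovation_sd = 1, ar = 0)
  expect_error(dgp_config(100, specs, c(x = 1), -0.5, 0.1), "order")
  specs$order <- 0
  specs$innovation_sd <- 0
  expect_error(dgp_config(100, specs, c(x = 1), -0.5, 0.1), "innovation_sd")
  specs$innovation_sd <- 1
  expect_error(dgp_config(100, specs, c(x = 1), 0.2, 0.1), "adjustment_speed")
  expect_error(dgp_config(100, specs, c(x = 1), -1.2, 0.1), "adjustment_speed")
  expect_error(dgp_config(12, specs, c(x = 1), -0.5, 0.1), "24")
  expect_error(dgp_config(100, specs, c(zz = 1), -0.5, 0.1), "zz")
  expect_error(dgp_config(100, specs, c(x = 1), -0.5, 0.1,
                          response_name = "x"), "collides")
})

test_that("DGP config YAML round trip preserves every field", {
  cfg <- xilingol_dgp_config(seed = 9, n_months = 48)
  path <- withr::local_tempfile(fileext = ".yml")
  write_dgp_config(cfg, path)
  back <- read_dgp_config(path)
  expect_identical(simulate_fire_panel(back), simulate_fire_panel(cfg))
})
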