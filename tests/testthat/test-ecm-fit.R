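test_that("the noiseless full-adjustment model is fitted exactly", {
  cfg <- dgp_config(
    n_months = 80,
    variable_specs = data.frame(name = "x", order = 1, seasonal_amplitude = 0,
                                innovation_sd = 1, ar = 0),
    cointegration_vector = c(x = 2),
    adjustment_speed = -1 + 1e-12, response_innovation_sd = 0,
    intercept = 0.3, seed = 9)
  panel <- simulate_fire_panel(cfg)
  # the perfect fit makes summary()'s relative checks complain; expected here
  fit <- suppressWarnings(fit_ecm_ardl(panel, "area_burned", p = 0, q = 0))
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("least-squares invariants hold on a stochastic fit", {
  panel <- simulate_fire_panel(coint_dgp(51))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 1, q = 1)
  X <- model.matrix(fit$lm)
  # residuals orthogonal to every regressor column
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  # covariance symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_gte(min(eigen(fit$vcov, symmetric = TRUE)$values), -1e-12)
  expect_true(fit$r.squared >= 0 && fit$r.squared <= 1)
  expect_lte(fit$adj.r.squared, fit$r.squared)
  # the error-correction coefficient is the own-level coefficient
  expect_identical(fit$ect_coefficient, unname(coef(fit$lm)[["lag_y"]]))
})

test_that("QR coefficients match an independent normal-equations solve", {
  panel <- simulate_fire_panel(coint_dgp(52))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 1, q = 2)
  X <- model.matrix(fit$lm)
  yv <- model.response(model.frame(fit$lm))
  b_ne <- solve(t(X) %*% X, t(X) %*% yv)
  expect_lt(max(abs(coef(fit$lm) - b_ne)), 1e-8)
})

test_that("refitting on the constructed EC term reproduces the fitted values", {
  panel <- simulate_fire_panel(coint_dgp(53))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 1, q = 1)
  lr <- long_run_multipliers(fit)
  mm <- model.frame(fit$lm)
  X <- model.matrix(fit$lm)
  # EC_{t-1} with theta fixed at the estimate
  ec <- X[, "lag_y"] -
    X[, paste0("lag_", fit$regressors), drop = FALSE] %*% lr$estimate
  keep <- setdiff(colnames(X), c("(Intercept)", "lag_y",
                                 paste0("lag_", fit$regressors)))
  refit <- lm(model.response(mm) ~ ec + X[, keep])
  expect_lt(max(abs(fitted(refit) - fit$fitted)), 1e-8)
  # the EC coefficient is delta_0
  expect_equal(unname(coef(refit)[["ec"]]), fit$ect_coefficient,
               tolerance = 1e-8)
})

test_that("long-run multipliers follow -delta_j / delta_0 with delta SEs", {
  panel <- simulate_fire_panel(coint_dgp(54))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 1)
  lr <- long_run_multipliers(fit)
  expect_equal(lr$estimate, unname(-fit$delta / fit$ect_coefficient),
               tolerance = 1e-12)
  # degenerate adjustment refuses a long-run reading
  broken <- fit
  broken$ect_coefficient <- 1e-12
  expect_error(long_run_multipliers(broken), "degenerate")
})

test_that("elasticity statements read log-log coefficients as percent", {
  expect_equal(elasticity_statement(6.929, 1)$percent, 6.9)
  expect_equal(elasticity_statement(2.361, 1)$percent, 2.4)
  expect_equal(elasticity_statement(0, 5)$percent, 0)
  expect_error(elasticity_statement(1.2, 1, log_log = FALSE), "log")
})

test_that("collinear designs and unknown names raise targeted errors", {
  panel <- simulate_fire_panel(coint_dgp(55, n = 60))
  dup <- as.data.frame(panel)[-1]
  dup$x1_copy <- dup$x1
  panel2 <- monthly_panel(dup)
  expect_error(fit_ecm_ardl(panel2, "area_burned", p = 0, q = 0),
               "collinear.*x1")
  expect_error(fit_ecm_ardl(panel, "nope"), "not found")
  expect_error(fit_ecm_ardl(panel, "area_burned", regressors = "zz"), "zz")
})

test_that("dropping a truly irrelevant regressor barely moves the rest", {
  # x2 has true theta = 0 and no short-run role
  panel <- simulate_fire_panel(coint_dgp(56))
  full <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 0)
  slim <- fit_ecm_ardl(panel, "area_burned",
                       regressors = c("x1", "x3"), p = 0, q = 0)
  for (term in c("lag_y", "lag_x1", "lag_x3")) {
    se <- sqrt(full$vcov[term, term])
    expect_lt(abs(coef(full$lm)[[term]] - coef(slim$lm)[[term]]), 3 * se)
  }
})

test_that("the Durbin-Watson statistic centres on 2 under a correct model", {
  dws <- vapply(1:100, function(s) {
    fit_ecm_ardl(simulate_fire_panel(coint_dgp(s + 3000)), "area_burned",
                 p = 0, q = 0)$durbin_watson
  }, numeric(1))
  expect_gt(mean(dws), 1.9)
  expect_lt(mean(dws), 2.1)
})

test_that("diagnostics require enough residual degrees of freedom", {
  panel <- simulate_fire_panel(coint_dgp(57, n = 40))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 1, q = 2)
  expect_s3_class(residual_diagnostics(fit), "ecm_diagnostics")
  tiny <- fit
  tiny$lm$df.residual <- 5L
  expect_error(residual_diagnostics(tiny), "degrees of freedom")
})

test_that("contemporaneous flag shifts the short-run lag window", {
  panel <- simulate_fire_panel(coint_dgp(58))
  f0 <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 1,
                     contemporaneous = TRUE)
  f1 <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 1,
                     contemporaneous = FALSE)
  expect_true("d_x1_l0" %in% names(coef(f0$lm)))
  expect_true("d_x1_l1" %in% names(coef(f1$lm)))
  expect_false("d_x1_l1" %in% names(coef(f0$lm)))
})
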