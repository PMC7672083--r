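test_that("likelihood ratios equal twice the log-likelihood differences", {
  lc <- lag_criteria(simulate_fire_panel(coint_dgp(21)), p_max = 4)
  tab <- lc$table
  expect_equal(tab$LR[-1], 2 * diff(tab$loglik), tolerance = 1e-10)
  # log-likelihood non-decreasing in p on the common sample
  expect_true(all(diff(tab$loglik) >= -1e-8))
  # every criterion's pick is the argmin over the scanned set
  for (crit in c("FPE", "AIC", "SBC", "HQ"))
    expect_equal(lc$selected[[crit]], tab$p[which.min(tab[[crit]])])
})

test_that("a white-noise system selects lag zero", {
  picks <- vapply(1:100, function(s) {
    set.seed(s + 900)
    panel <- monthly_panel(data.frame(a = rnorm(120), b = rnorm(120)))
    lag_criteria(panel, p_max = 3)$selected[["SBC"]]
  }, numeric(1))
  expect_gt(mean(picks == 0), 0.5)
})

test_that("excessive lag depth for the sample is rejected", {
  panel <- simulate_fire_panel(coint_dgp(5, n = 30))
  expect_error(lag_criteria(panel, p_max = 8), "too large")
})

test_that("simulated bounds are ordered and reproducible", {
  cv <- bounds_critical_values(100, 2, n_sim = 2000, seed = 10)
  tab <- cv$table
  expect_true(all(tab$lower < tab$upper))
  # 1% bounds above 5% above 10%
  expect_true(all(diff(tab$lower) < 0) && all(diff(tab$upper) < 0))
  cv2 <- bounds_critical_values(100, 2, n_sim = 2000, seed = 10)
  expect_identical(cv$table, cv2$table)
  expect_error(bounds_critical_values(100, 0, n_sim = 2000), "k must")
  expect_error(bounds_critical_values(100, 2, n_sim = 500), "n_sim")
})

test_that("bounds ordering holds across the (n, k) grid", {
  for (n in c(100, 216)) for (k in c(1, 4, 8)) {
    tab <- bounds_critical_values(n, k, n_sim = 2000, seed = n + k)$table
    expect_true(all(tab$lower < tab$upper))
  }
})

test_that("simulated quantiles are stable across seeds at large n_sim", {
  cv_a <- bounds_critical_values(100, 2, n_sim = 10000, seed = 1)
  cv_b <- bounds_critical_values(100, 2, n_sim = 10000, seed = 2)
  u_a <- cv_a$table$upper[cv_a$table$alpha == 0.05]
  u_b <- cv_b$table$upper[cv_b$table$alpha == 0.05]
  # Monte-Carlo standard error of an empirical 95% quantile at n_sim = 1e4
  # is about 0.03 here; two independent draws should agree well within that
  expect_lt(abs(u_a - u_b), 0.15)
})

test_that("the Wald F equals the restricted-vs-unrestricted RSS F", {
  panel <- simulate_fire_panel(coint_dgp(42))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 1, q = 1)
  cv <- bounds_critical_values(240, 3, n_sim = 2000, seed = 6)
  f_wald <- bounds_f_test(fit, cv)$F_statistic

  # independent path: refit without the level terms and compare RSS
  mm <- model.matrix(fit$lm)
  yv <- model.response(model.frame(fit$lm))
  level_cols <- c("lag_y", paste0("lag_", fit$regressors))
  rss_u <- sum(residuals(fit$lm)^2)
  Xr <- mm[, setdiff(colnames(mm), level_cols), drop = FALSE]
  rss_r <- sum(qr.resid(qr(Xr), yv)^2)
  q <- length(level_cols)
  f_rss <- ((rss_r - rss_u) / q) / (rss_u / (nrow(mm) - ncol(mm)))
  expect_equal(f_wald, f_rss, tolerance = 1e-8)
})

test_that("bounds test decision tracks the statistic against the bounds", {
  panel <- simulate_fire_panel(coint_dgp(43))
  fit <- fit_ecm_ardl(panel, "area_burned", p = 0, q = 1)
  cv <- bounds_critical_values(240, 3, n_sim = 2000, seed = 8)
  bt <- bounds_f_test(fit, cv)
  row <- cv$table[cv$table$alpha == 0.05, ]
  expected <- if (bt$F_statistic > row$upper) "cointegrated"
              else if (bt$F_statistic < row$lower) "not cointegrated"
              else "inconclusive"
  expect_identical(bt$decision, expected)
  cv_wrong_k <- bounds_critical_values(240, 5, n_sim = 2000, seed = 8)
  expect_error(bounds_f_test(fit, cv_wrong_k), "k = 5")
})

test_that("the critical-value cache returns identical bounds without resimulating", {
  path <- withr::local_tempfile(fileext = ".csv")
  t1 <- system.time(
    cv1 <- bounds_critical_values_cached(120, 2, n_sim = 2000, seed = 3,
                                         cache_path = path))[3]
  cv2 <- bounds_critical_values_cached(120, 2, n_sim = 2000, seed = 3,
                                       cache_path = path)
  expect_equal(cv1$table$upper, cv2$table$upper, tolerance = 1e-12)
  # different key re-simulates and extends the cache
  cv3 <- bounds_critical_values_cached(120, 3, n_sim = 2000, seed = 3,
                                       cache_path = path)
  cache <- read.csv(path)
  expect_setequal(unique(cache$k), c(2, 3))
})
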