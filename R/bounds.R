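#' Monte-Carlo critical bounds for the ARDL bounds F-test
#'
#' Simulates the null distribution of the F-statistic for the joint nullity
#' of all lagged-level coefficients in the error-correction regression under
#' the two polar integration configurations of the bounds framework: all
#' regressors stationary (lower, I(0) bound) and all regressors pure random
#' walks (upper, I(1) bound). In both cases the response is an independent
#' driftless random walk, so no level relationship exists. The deterministic
#' case is the unrestricted-intercept, no-trend case ("case III"); the
#' intercept is estimated but excluded from the test, which has `k + 1`
#' restrictions (own lagged level plus the `k` regressor levels).
#'
#' @param n length of the simulated series (match the data sample).
#' @param k number of level regressors (>= 1).
#' @param case deterministic case; only `"iii"` is implemented.
#' @param n_sim number of null replications (>= 2000).
#' @param seed integer seed; bounds are bit-reproducible.
#' @param alpha significance levels for the reported bounds.
#' @return object of class `bounds_cv`: `table` with columns `alpha`,
#'   `lower`, `upper`, plus the simulation settings.
#' @export
bounds_critical_values <- function(n, k, case = "iii", n_sim = 5000L,
                                   seed = 1L, alpha = c(0.01, 0.05, 0.10)) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (n_sim < 2000L) stop("n_sim must be at least 2000", call. = FALSE)
  if (!identical(case, "iii"))
    stop("only the unrestricted-intercept, no-trend case ('iii') is implemented",
         call. = FALSE)
  set.seed(seed)
  f_lower <- numeric(n_sim)
  f_upper <- numeric(n_sim)
  for (r in seq_len(n_sim)) {
    y <- cumsum(stats::rnorm(n))
    Z <- matrix(stats::rnorm(n * k), n, k)
    f_lower[r] <- null_level_f(y, Z)
    f_upper[r] <- null_level_f(y, apply(Z, 2L, cumsum))
  }
  tab <- data.frame(alpha = alpha,
                    lower = stats::quantile(f_lower, 1 - alpha, names = FALSE),
                    upper = stats::quantile(f_upper, 1 - alpha, names = FALSE))
  structure(list(table = tab, n = n, k = k, case = case,
                 n_sim = n_sim, seed = seed),
            class = "bounds_cv")
}

# F-statistic for joint nullity of all level terms in
# dy_t ~ 1 + y_{t-1} + X_{t-1}, computed from restricted vs unrestricted RSS
null_level_f <- function(y, X) {
  n <- length(y)
  dy <- diff(y)
  Xu <- cbind(1, y[-n], X[-n, , drop = FALSE])
  q <- ncol(Xu) - 1L
  rss_u <- sum(qr.resid(qr(Xu), dy)^2)
  rss_r <- sum((dy - mean(dy))^2)
  ((rss_r - rss_u) / q) / (rss_u / (length(dy) - ncol(Xu)))
}

#' @export
print.bounds_cv <- function(x, ...) {
  cat("Simulated bounds critical values (case ", x$case, "): n = ", x$n,
      ", k = ", x$k, ", ", x$n_sim, " replications, seed ", x$seed, "\n",
      sep = "")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Cached bounds critical values
#'
#' Looks up (or computes and appends) simulated bounds in a CSV cache keyed
#' by `(n, k, case, alpha, n_sim, seed)` so repeated pipeline runs do not
#' re-simulate.
#'
#' @inheritParams bounds_critical_values
#' @param cache_path CSV cache file path.
#' @param force recompute and overwrite matching cache rows.
#' @return a `bounds_cv`.
#' @export
bounds_critical_values_cached <- function(n, k, case = "iii", n_sim = 5000L,
                                          seed = 1L, alpha = c(0.01, 0.05, 0.10),
                                          cache_path, force = FALSE) {
  cache <- if (file.exists(cache_path))
    utils::read.csv(cache_path, stringsAsFactors = FALSE) else NULL
  if (!force && !is.null(cache)) {
    hit <- cache[cache$n == n & cache$k == k & cache$case == case &
                   cache$n_sim == n_sim & cache$seed == seed, , drop = FALSE]
    if (nrow(hit) && all(alpha %in% hit$alpha)) {
      hit <- hit[match(alpha, hit$alpha), ]
      return(structure(list(table = data.frame(alpha = alpha,
                                               lower = hit$lower,
                                               upper = hit$upper),
                            n = n, k = k, case = case, n_sim = n_sim,
                            seed = seed),
                       class = "bounds_cv"))
    }
  }
  cv <- bounds_critical_values(n, k, case, n_sim, seed, alpha)
  rows <- cbind(data.frame(n = n, k = k, case = case, n_sim = n_sim,
                           seed = seed), cv$table)
  keep <- if (is.null(cache)) NULL
          else cache[!(cache$n == n & cache$k == k & cache$case == case &
                         cache$n_sim == n_sim & cache$seed == seed), ,
                     drop = FALSE]
  utils::write.csv(rbind(keep, rows), cache_path, row.names = FALSE)
  cv
}

#' ARDL bounds F-test for a level relationship
#'
#' Wald F-test that all lagged-level coefficients of a fitted
#' error-correction ARDL (the own lag \eqn{\delta_0} and every regressor lag
#' \eqn{\delta_1 \ldots \delta_k}) are jointly zero — the null of no level
#' (cointegrating) relationship. The statistic is compared against simulated
#' lower/upper critical bounds: above the upper bound at a level means
#' cointegration; below the lower bound means none; between the bounds the
#' test is inconclusive.
#'
#' @param fit an [fit_ecm_ardl()] fit.
#' @param critical_bounds a `bounds_cv` with `k` matching the fit.
#' @param level significance level used for the reported decision (must be
#'   one of the bounds' `alpha` values).
#' @return object of class `bounds_test`: F-statistic, k, bounds table and
#'   `decision` in `{"cointegrated", "inconclusive", "not cointegrated"}`.
#' @export
bounds_f_test <- function(fit, critical_bounds, level = 0.05) {
  stopifnot(inherits(fit, "ecm_fit"), inherits(critical_bounds, "bounds_cv"))
  k <- length(fit$regressors)
  if (k != critical_bounds$k)
    stop("bounds were simulated for k = ", critical_bounds$k,
         " but the fit has k = ", k, " regressors", call. = FALSE)
  terms <- c("lag_y", paste0("lag_", fit$regressors))
  b <- stats::coef(fit$lm)[terms]
  V <- fit$vcov[terms, terms]
  q <- length(terms)
  f_stat <- as.numeric(t(b) %*% solve(V, b)) / q
  tab <- critical_bounds$table
  row <- tab[tab$alpha == level, , drop = FALSE]
  if (!nrow(row))
    stop("no simulated bounds at level ", level, call. = FALSE)
  decision <- if (f_stat > row$upper) "cointegrated"
              else if (f_stat < row$lower) "not cointegrated"
              else "inconclusive"
  structure(list(F_statistic = f_stat, k = k, case = critical_bounds$case,
                 critical_bounds = tab, level = level, decision = decision,
                 n_sim = critical_bounds$n_sim, seed = critical_bounds$seed),
            class = "bounds_test")
}

#' @export
print.bounds_test <- function(x, ...) {
  cat("ARDL bounds test (case ", x$case, "), H0: no level relationship\n",
      sep = "")
  cat("  F =", format(x$F_statistic, digits = 4), "with k =", x$k,
      "regressors\n")
  print(format(x$critical_bounds, digits = 4), row.names = FALSE)
  cat("  decision at ", x$level * 100, "%: ", x$decision, "\n", sep = "")
  invisible(x)
}
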