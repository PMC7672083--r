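#' Estimate the error-correction ARDL by least squares
#'
#' Fits the single-equation error-correction form
#' \deqn{\Delta y_t = \alpha_0 + \delta_0 y_{t-1} + \sum_j \delta_j x_{j,t-1}
#'   + \sum_{i=1}^{p} \alpha_i \Delta y_{t-i}
#'   + \sum_j \sum_{l} \beta_{j,l} \Delta x_{j,t-l} + \varepsilon_t}
#' where the lagged levels carry the long-run (cointegrating) relation and
#' the differenced terms the short-run dynamics. The rearrangement
#' \eqn{\delta_0 y_{t-1} + \sum_j \delta_j x_{j,t-1} = \delta_0 EC_{t-1}}
#' identifies \eqn{\delta_0} as the error-correction coefficient: the speed
#' at which deviations from equilibrium decay (a negative estimate is
#' required for a stable long-run relation).
#'
#' Order semantics: `p` is the number of lagged \eqn{\Delta y} terms; `q[j]`
#' is the number of \eqn{\Delta x_j} terms, entering at lags
#' `0..q[j]-1` (contemporaneous difference first) or at lags `1..q[j]` when
#' `contemporaneous = FALSE`; `q[j] = 0` drops the differenced terms of that
#' regressor (its level lag always enters).
#'
#' @param panel a `monthly_panel`.
#' @param response name of the response column.
#' @param regressors names of the level regressors (default: all other
#'   columns).
#' @param p number of lagged response differences (>= 0).
#' @param q integer (recycled) or named integer vector per regressor.
#' @param contemporaneous include the contemporaneous regressor difference
#'   (lag 0) as the first short-run term.
#' @return object of class `ecm_fit`: the underlying `lm`, coefficient
#'   groups (`intercept`, `ect_coefficient` \eqn{=\delta_0}, `delta` levels,
#'   `alpha` and `beta` short-run terms), classical coefficient covariance,
#'   residuals, \eqn{R^2}, adjusted \eqn{R^2} and Durbin-Watson statistic.
#' @export
fit_ecm_ardl <- function(panel, response, regressors = NULL,
                         p = 1L, q = 1L, contemporaneous = TRUE) {
  stopifnot(inherits(panel, "monthly_panel"))
  vars <- panel_vars(panel)
  if (!response %in% vars)
    stop("response '", response, "' not found in panel", call. = FALSE)
  if (is.null(regressors)) regressors <- setdiff(vars, response)
  missing <- setdiff(regressors, vars)
  if (length(missing))
    stop("regressor(s) not in panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  k <- length(regressors)
  if (is.null(names(q))) q <- stats::setNames(rep_len(as.integer(q), k), regressors)
  else {
    if (!setequal(names(q), regressors))
      stop("named q must give an order for every regressor", call. = FALSE)
    q <- stats::setNames(as.integer(q[regressors]), regressors)
  }
  if (p < 0L || any(q < 0L)) stop("orders must be non-negative", call. = FALSE)

  y <- panel_matrix(panel, response)[, 1L]
  X <- panel_matrix(panel, regressors)
  n <- length(y)
  x_max_lag <- if (any(q > 0L))
    max(ifelse(q > 0L, q - as.integer(contemporaneous), 0L)) else 0L
  t0 <- 2L + max(p, x_max_lag)
  if (n - t0 + 1L < k + p + sum(q) + 2L + 10L)
    stop("sample too short for the requested order", call. = FALSE)
  idx <- t0:n
  dat <- data.frame(dy = y[idx] - y[idx - 1L])
  dat$lag_y <- y[idx - 1L]
  for (v in regressors) dat[[paste0("lag_", v)]] <- X[idx - 1L, v]
  if (p > 0L)
    for (i in seq_len(p))
      dat[[paste0("d_y_l", i)]] <- y[idx - i] - y[idx - i - 1L]
  for (v in regressors) {
    if (q[[v]] == 0L) next
    lags <- if (contemporaneous) 0:(q[[v]] - 1L) else seq_len(q[[v]])
    for (l in lags)
      dat[[paste0("d_", v, "_l", l)]] <- X[idx - l, v] - X[idx - l - 1L, v]
  }
  fit <- stats::lm(dy ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  sigma2 <- rss / fit$df.residual
  sm <- summary(fit)
  dw <- if (rss > 1e-16) sum(diff(res)^2) / rss else NA_real_
  structure(list(
    lm = fit,
    intercept = cf[["(Intercept)"]],
    ect_coefficient = cf[["lag_y"]],
    delta = stats::setNames(cf[paste0("lag_", regressors)], regressors),
    alpha = if (p > 0L) cf[paste0("d_y_l", seq_len(p))] else numeric(0),
    beta = cf[grep("^d_(?!y_)", names(cf), perl = TRUE)],
    orders = list(p = p, q = q, contemporaneous = contemporaneous),
    vcov = stats::vcov(fit),
    residuals = res,
    fitted = stats::fitted(fit),
    sigma2 = sigma2,
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    durbin_watson = dw,
    response = response,
    regressors = regressors,
    n_used = nrow(dat)),
    class = "ecm_fit")
}

#' @export
print.ecm_fit <- function(x, ...) {
  cat("Error-correction ARDL: d(", x$response, ") on ", length(x$regressors),
      " regressors, order (p = ", x$orders$p, "; q = ",
      paste(x$orders$q, collapse = ","), "), n = ", x$n_used, "\n", sep = "")
  sm <- summary(x$lm)$coefficients
  print(round(sm, 4))
  cat("ECT coefficient (delta_0):", format(x$ect_coefficient, digits = 4),
      "\nR-squared:", format(x$r.squared, digits = 3),
      " adjusted:", format(x$adj.r.squared, digits = 3),
      " Durbin-Watson:", format(x$durbin_watson, digits = 3), "\n")
  invisible(x)
}

#' Tidy coefficient table of an ECM fit
#' @param fit an `ecm_fit`.
#' @return data.frame with term, estimate, std_error, t_statistic, p_value.
#' @export
ecm_coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "ecm_fit"))
  sm <- summary(fit$lm)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
             t_statistic = sm[, 3L], p_value = sm[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-run multipliers from an ECM fit
#'
#' The equilibrium (long-run) multiplier of regressor \eqn{j} is
#' \eqn{\theta_j = -\delta_j / \delta_0}; in a log-log model it reads as the
#' percent change of the response per percent change of the regressor.
#' Standard errors come from the delta method applied to the joint
#' least-squares covariance of \eqn{(\delta_0, \delta_j)}.
#'
#' @param fit an `ecm_fit` with \eqn{|\delta_0|} above `tol`.
#' @param tol degeneracy tolerance on \eqn{|\delta_0|}.
#' @return data.frame with `regressor`, `estimate`, `std_error`.
#' @export
long_run_multipliers <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "ecm_fit"))
  d0 <- fit$ect_coefficient
  if (abs(d0) < tol)
    stop("degenerate adjustment: |delta_0| < ", tol,
         ", no long-run relation identified", call. = FALSE)
  out <- lapply(fit$regressors, function(v) {
    dj <- fit$delta[[v]]
    theta <- -dj / d0
    g <- c(dj / d0^2, -1 / d0)        # d theta / d (delta_0, delta_j)
    V <- fit$vcov[c("lag_y", paste0("lag_", v)),
                  c("lag_y", paste0("lag_", v))]
    data.frame(regressor = v, estimate = theta,
               std_error = sqrt(as.numeric(t(g) %*% V %*% g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Elasticity reading of a log-log coefficient
#'
#' In a model where both the response and the regressor are natural-log
#' transformed, a coefficient is an elasticity: the percent response to a 1%
#' regressor change is simply `coefficient x pct_change`, reported to one
#' decimal place.
#'
#' @param coefficient estimated log-log coefficient.
#' @param pct_change percent change of the regressor (default 1).
#' @param log_log both series are log-transformed (must be `TRUE`; the
#'   elasticity reading is invalid otherwise).
#' @return list with `percent` (rounded to one decimal) and a `statement`
#'   string.
#' @export
elasticity_statement <- function(coefficient, pct_change = 1, log_log = TRUE) {
  if (!isTRUE(log_log))
    stop("elasticity reading requires both variables log-transformed",
         call. = FALSE)
  pct <- round(coefficient * pct_change, 1L)
  list(percent = pct,
       statement = sprintf(
         "a %g%% change in the regressor moves the response by %.1f%%",
         pct_change, pct))
}
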