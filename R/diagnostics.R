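#' Residual diagnostic battery for an ECM fit
#'
#' The standard post-estimation checks for the error-correction ARDL:
#' Breusch-Godfrey LM for first-order serial correlation (auxiliary
#' regression, \eqn{nR^2} against \eqn{\chi^2_1}), ARCH LM at lag 1 on the
#' squared residuals, Ramsey RESET with squared and cubed fitted values (F
#' form), Jarque-Bera normality from residual skewness and excess kurtosis,
#' plus the Durbin-Watson statistic.
#'
#' @param fit an [fit_ecm_ardl()] fit with at least 10 residual degrees of
#'   freedom.
#' @return object of class `ecm_diagnostics`: data.frame `table` with one
#'   row per test (statistic, p_value) and `durbin_watson`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "ecm_fit"))
  if (fit$lm$df.residual < 10L)
    stop("insufficient residual degrees of freedom (",
         fit$lm$df.residual, " < 10)", call. = FALSE)
  bg <- lmtest::bgtest(fit$lm, order = 1L, type = "Chisq")
  arch <- arch_lm_test(fit$residuals, lags = 1L)
  reset <- lmtest::resettest(fit$lm, power = 2:3, type = "fitted")
  jb <- jarque_bera_test(fit$residuals)
  tab <- data.frame(
    test = c("breusch_godfrey", "arch_lm", "ramsey_reset", "jarque_bera"),
    statistic = c(unname(bg$statistic), arch$statistic,
                  unname(reset$statistic), jb$statistic),
    p_value = c(bg$p.value, arch$p_value, reset$p.value, jb$p_value),
    stringsAsFactors = FALSE)
  structure(list(table = tab, durbin_watson = fit$durbin_watson),
            class = "ecm_diagnostics")
}

#' @export
print.ecm_diagnostics <- function(x, ...) {
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("Durbin-Watson:", format(x$durbin_watson, digits = 4), "\n")
  invisible(x)
}

#' ARCH LM test
#'
#' Engle's LM test for autoregressive conditional heteroskedasticity:
#' regress squared residuals on their own lags; \eqn{nR^2} is asymptotically
#' \eqn{\chi^2} with `lags` degrees of freedom under homoskedasticity.
#'
#' @param residuals numeric residual vector.
#' @param lags number of squared-residual lags (default 1).
#' @return list with `statistic`, `p_value`, `lags`.
#' @export
arch_lm_test <- function(residuals, lags = 1L) {
  e2 <- residuals^2
  n <- length(e2)
  if (n < lags + 10L) stop("too few residuals for ARCH LM", call. = FALSE)
  idx <- (lags + 1L):n
  X <- cbind(1, vapply(seq_len(lags), function(l) e2[idx - l],
                       numeric(length(idx))))
  yv <- e2[idx]
  res <- qr.resid(qr(X), yv)
  r2 <- 1 - sum(res^2) / sum((yv - mean(yv))^2)
  stat <- length(yv) * r2
  list(statistic = stat,
       p_value = stats::pchisq(stat, lags, lower.tail = FALSE),
       lags = lags)
}

#' Jarque-Bera normality test
#'
#' \eqn{n (S^2/6 + (K-3)^2/24)} from sample skewness \eqn{S} and kurtosis
#' \eqn{K} of the residuals, against \eqn{\chi^2_2}.
#'
#' @param residuals numeric residual vector.
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis`.
#' @export
jarque_bera_test <- function(residuals) {
  x <- residuals - mean(residuals)
  n <- length(x)
  m2 <- mean(x^2)
  skew <- mean(x^3) / m2^1.5
  kurt <- mean(x^4) / m2^2
  stat <- n * (skew^2 / 6 + (kurt - 3)^2 / 24)
  list(statistic = stat,
       p_value = stats::pchisq(stat, 2L, lower.tail = FALSE),
       skewness = skew, kurtosis = kurt)
}
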