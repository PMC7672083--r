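#' Recursive CUSUM stability assessment
#'
#' Computes standardised recursive residuals by recursive least squares
#' (rank-one updating of the inverse cross-product, algebraically identical
#' to re-estimating the model on each growing sample) and their cumulative
#' sum scaled by the recursive-residual standard deviation. Under parameter
#' stability the trace is a near-martingale that stays, with the nominal
#' probability, inside the Brown-Durbin-Evans straight-line boundaries
#' \deqn{\pm\left[a\sqrt{T-K} + 2a\,(t-K)/\sqrt{T-K}\right]}
#' with \eqn{a = 0.948} at 5%. An excursion beyond either line signals
#' instability of the estimated coefficients over time.
#'
#' @param fit an [fit_ecm_ardl()] fit whose estimation sample is at least
#'   three times the parameter count.
#' @param significance one of 0.01, 0.05, 0.10 (boundary constant 1.143,
#'   0.948, 0.850).
#' @return object of class `cusum_trace`: `recursive_residuals`,
#'   `statistic` (scaled cumulative sums), `upper`/`lower` boundary vectors,
#'   `crossed` flag, and bookkeeping (`t`, `K`, `T`).
#' @export
cusum_stability <- function(fit, significance = 0.05) {
  stopifnot(inherits(fit, "ecm_fit"))
  X <- stats::model.matrix(fit$lm)
  y <- stats::model.response(stats::model.frame(fit$lm))
  n <- nrow(X)
  K <- ncol(X)
  if (n < 3L * K)
    stop("estimation sample (", n, ") must be at least 3x parameter count (",
         K, ")", call. = FALSE)
  a <- switch(as.character(significance),
              "0.01" = 1.143, "0.05" = 0.948, "0.1" = 0.850,
              stop("significance must be 0.01, 0.05 or 0.10", call. = FALSE))
  w <- recursive_residuals(X, y)
  sig <- stats::sd(w)
  W <- if (sig > 1e-12) cumsum(w) / sig else rep(0, length(w))
  tt <- (K + 1L):n
  bound <- a * sqrt(n - K) + 2 * a * (tt - K) / sqrt(n - K)
  structure(list(recursive_residuals = w, statistic = W,
                 upper = bound, lower = -bound,
                 crossed = any(abs(W) > bound),
                 t = tt, K = K, T = n, significance = significance),
            class = "cusum_trace")
}

# standardised recursive residuals w_t = (y_t - x_t'b_{t-1}) / sqrt(f_t),
# f_t = 1 + x_t' (X_{t-1}'X_{t-1})^{-1} x_t, via recursive least squares
recursive_residuals <- function(X, y) {
  n <- nrow(X)
  K <- ncol(X)
  X0 <- X[seq_len(K), , drop = FALSE]
  qx <- qr(crossprod(X0))
  if (qx$rank < K)
    stop("initial ", K, " observations give a singular design; cannot start ",
         "the recursion", call. = FALSE)
  M <- solve(crossprod(X0))
  b <- M %*% crossprod(X0, y[seq_len(K)])
  w <- numeric(n - K)
  for (t in (K + 1L):n) {
    x <- X[t, ]
    Mx <- M %*% x
    f <- 1 + sum(x * Mx)
    pred_err <- y[t] - sum(x * b)
    w[t - K] <- pred_err / sqrt(f)
    b <- b + Mx * (pred_err / f)
    M <- M - tcrossprod(Mx) / f
  }
  w
}

#' @export
print.cusum_trace <- function(x, ...) {
  cat("Recursive CUSUM (", x$significance * 100, "% bands): T = ", x$T,
      ", K = ", x$K, "\n", sep = "")
  cat("  max |W_t| / boundary:",
      format(max(abs(x$statistic) / x$upper), digits = 3), "\n")
  cat("  boundary crossed:", x$crossed, "\n")
  invisible(x)
}

#' @export
as.data.frame.cusum_trace <- function(x, ...) {
  data.frame(t = x$t, recursive_residual = x$recursive_residuals,
             cusum = x$statistic, upper = x$upper, lower = x$lower)
}
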