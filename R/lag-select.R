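#' Lag-order selection by five information criteria
#'
#' Fits vector autoregressions of order `0..p_max` to all panel variables on
#' a common estimation sample (trimmed so every candidate order uses
#' identical observations) and reports, per order: the log-likelihood, the
#' likelihood-ratio statistic against the next-smaller order, the final
#' prediction error (FPE), and the Akaike (AIC), Schwarz Bayesian (SBC) and
#' Hannan-Quinn (HQ) criteria. SBC and HQ penalise parameters more harshly
#' than AIC and tend to pick the more parsimonious model; the consensus
#' choice is the SBC minimiser (ties to the smaller lag).
#'
#' @param panel a `monthly_panel`.
#' @param p_max largest candidate order (default 4, a year-third of monthly
#'   dynamics).
#' @param vars variables included in the system (default all).
#' @return object of class `lag_selection`: `table` (one row per order),
#'   `selected` (named integer vector per criterion) and `consensus_lag`.
#' @export
lag_criteria <- function(panel, p_max = 4L, vars = panel_vars(panel)) {
  stopifnot(inherits(panel, "monthly_panel"))
  Y <- panel_matrix(panel, vars)
  n <- nrow(Y)
  K <- ncol(Y)
  T_eff <- n - p_max
  if (T_eff < K * p_max + K + 2L)
    stop("p_max = ", p_max, " too large for sample of ", n, " observations",
         call. = FALSE)
  idx <- (p_max + 1L):n
  Yt <- Y[idx, , drop = FALSE]
  rows <- vector("list", p_max + 1L)
  loglik <- numeric(p_max + 1L)
  for (p in 0:p_max) {
    X <- matrix(1, T_eff, 1L)
    if (p > 0L)
      for (i in seq_len(p)) X <- cbind(X, Y[idx - i, , drop = FALSE])
    E <- qr.resid(qr(X), Yt)
    Sigma <- crossprod(E) / T_eff
    ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
    ll <- -(T_eff / 2) * (K * log(2 * pi) + K + ld)
    m <- K * p + 1L                      # parameters per equation
    loglik[p + 1L] <- ll
    rows[[p + 1L]] <- data.frame(
      p = p,
      loglik = ll,
      LR = NA_real_,
      FPE = ((T_eff + m) / (T_eff - m))^K * exp(ld),
      AIC = ld + 2 * p * K^2 / T_eff,
      SBC = ld + log(T_eff) * p * K^2 / T_eff,
      HQ = ld + 2 * log(log(T_eff)) * p * K^2 / T_eff)
  }
  tab <- do.call(rbind, rows)
  if (p_max > 0L)
    tab$LR[-1L] <- 2 * diff(loglik)
  # sequential LR choice: from p_max down, first order whose LR test vs p-1
  # rejects at 5% (chi-square with K^2 degrees of freedom); else 0
  lr_pick <- 0L
  for (p in rev(seq_len(p_max))) {
    if (stats::pchisq(tab$LR[p + 1L], K^2, lower.tail = FALSE) < 0.05) {
      lr_pick <- p
      break
    }
  }
  selected <- c(LR = lr_pick,
                FPE = tab$p[which.min(tab$FPE)],
                AIC = tab$p[which.min(tab$AIC)],
                SBC = tab$p[which.min(tab$SBC)],
                HQ = tab$p[which.min(tab$HQ)])
  structure(list(table = tab, selected = selected,
                 consensus_lag = unname(selected[["SBC"]]),
                 k = K, n_effective = T_eff),
            class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat("Lag selection over 0..", max(x$table$p), " (", x$k, " variables, ",
      x$n_effective, " common observations)\n", sep = "")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("Selected:", paste(names(x$selected), x$selected, sep = "=",
                         collapse = "  "), "\n")
  cat("Consensus (SBC):", x$consensus_lag, "\n")
  invisible(x)
}

#' @export
as.data.frame.lag_selection <- function(x, ...) x$table
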