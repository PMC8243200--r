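#' Two-sided trimming of coefficient estimates
#'
#' Removes the ceiling(0.005 * C) largest and the same number of smallest
#' first-coefficient estimates from one condition cell's convergent
#' replications (0.5 percent per tail by default). Ties are broken by
#' original order (stable sort), so trimming is deterministic.
#'
#' @param gamma1 numeric vector of convergent first-coefficient estimates.
#' @param trim_fraction per-tail trim fraction, default 0.005.
#' @return Integer vector of the indices kept.
#' @examples
#' length(trimIndices(rnorm(1000)))  # 990
#' @export
trimIndices <- function(gamma1, trim_fraction = 0.005) {
  C <- length(gamma1)
  k <- ceiling(trim_fraction * C)
  if (2 * k >= C) return(integer(0))
  ord <- order(gamma1)  # stable: ties keep original order
  sort(ord[(k + 1):(C - k)])
}

#' Performance criteria for one condition cell
#'
#' Computes the five Monte-Carlo criteria for a single (measurement
#' condition, scoring method, link) cell: nonconvergence rate (percent of
#' all scheduled replications, before trimming), relative coefficient bias
#' RB = 100 mean(gamma1_hat - gamma1), relative standard-error bias
#' RSEB = 100 (mean(SE) / SD(gamma1_hat) - 1) with the sample (C - 1) SD,
#' root mean square error, and empirical Type I error rate, the percentage
#' of replications with p < 0.05 for the two-sided test of the true value.
#' RB/RSEB/RMSE/alpha are computed on the trimmed convergent replications.
#'
#' @param gamma1 convergent first-coefficient estimates for the cell.
#' @param se their estimated standard errors.
#' @param p their two-sided p-values for H0: gamma1 = `true_gamma`.
#' @param Ctot total scheduled replications for the cell.
#' @param true_gamma true coefficient value, default 1.
#' @param trim_fraction per-tail trim fraction, default 0.005.
#' @param min_usable minimum convergent replications required, default 10.
#' @return One-row data frame: `Ctot`, `C`, `nonconv`, `RB`, `RSEB`,
#'   `RMSE`, `alpha`, `usable`. Criteria are `NA` when the cell is
#'   unusable (too few convergent replications) or the empirical SD is
#'   zero (RSEB only).
#' @export
conditionCriteria <- function(gamma1, se, p, Ctot, true_gamma = 1,
                              trim_fraction = 0.005, min_usable = 10L) {
  stopifnot(length(gamma1) == length(se), length(gamma1) == length(p))
  n_conv <- length(gamma1)
  nonconv <- 100 * (Ctot - n_conv) / Ctot
  if (n_conv < min_usable) {
    return(data.frame(Ctot = Ctot, C = n_conv, nonconv = nonconv,
                      RB = NA_real_, RSEB = NA_real_, RMSE = NA_real_,
                      alpha = NA_real_, usable = FALSE))
  }
  keep <- trimIndices(gamma1, trim_fraction)
  g <- gamma1[keep]
  s <- se[keep]
  pv <- p[keep]
  C <- length(g)
  RB <- 100 * mean(g - true_gamma)
  sdg <- stats::sd(g)
  RSEB <- if (sdg > 0) 100 * (mean(s) / sdg - 1) else NA_real_
  RMSE <- sqrt(mean((g - true_gamma)^2))
  alpha <- 100 * mean(pv < 0.05)
  data.frame(Ctot = Ctot, C = C, nonconv = nonconv, RB = RB, RSEB = RSEB,
             RMSE = RMSE, alpha = alpha, usable = TRUE)
}
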