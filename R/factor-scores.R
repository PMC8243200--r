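#' @keywords internal
#' Symmetric matrix square root / inverse square root via eigendecomposition
#' with an eigenvalue floor; returns NULL when the matrix is effectively
#' singular for the inverse root.
.symPower <- function(M, power, floor = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- e$values
  if (power < 0 && any(vals <= floor)) return(NULL)
  vals <- pmax(vals, floor)
  e$vectors %*% diag(vals^power, nrow = length(vals)) %*% t(e$vectors)
}

.scoreMethods <- c("regression", "correlation", "total", "weighted")

#' Factor scoring weight matrix
#'
#' Computes the k x p weight matrix W of a scoring method from measurement
#' parameters, so that scores are X W'. Methods:
#' \describe{
#'   \item{regression}{W = Phi Lambda' Sigma^-1, the best linear predictor
#'     of the factors (maximal factor-score validity).}
#'   \item{correlation}{W = Phi^1/2 (Phi^1/2 Lambda' Sigma^-1 Lambda
#'     Phi^1/2)^-1/2 Phi^1/2 Lambda' Sigma^-1, the correlation-preserving
#'     estimator whose asymptotic score covariance equals Phi (the
#'     Anderson-Rubin estimator when Phi = I).}
#'   \item{total}{W = (Lambda*)', where Lambda* replaces each nonzero
#'     loading by its sign (signed unit weights).}
#'   \item{weighted}{W = Lambda', loading-weighted sums.}
#' }
#'
#' @param Lambda p x k loading matrix.
#' @param Phi k x k factor correlation matrix.
#' @param Sigma p x p indicator correlation matrix (model-implied or
#'   sample).
#' @param method one of `"regression"`, `"correlation"`, `"total"`,
#'   `"weighted"`.
#' @return k x p weight matrix, or `NULL` if a required inverse does not
#'   exist (treated as a nonconvergent replication upstream).
#' @export
scoreWeights <- function(Lambda, Phi, Sigma, method = .scoreMethods) {
  method <- match.arg(method)
  if (method == "total") return(t(sign(Lambda)))
  if (method == "weighted") return(t(Lambda))
  Sinv <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(Sinv)) return(NULL)
  A <- Phi %*% t(Lambda) %*% Sinv
  if (method == "regression") return(A)
  # correlation-preserving
  Ph <- .symPower(Phi, 0.5)
  M <- Ph %*% t(Lambda) %*% Sinv
  inner <- M %*% Lambda %*% Ph
  Iroot <- .symPower(inner, -0.5)
  if (is.null(Iroot)) return(NULL)
  Ph %*% Iroot %*% M
}

#' Factor scores from a fitted measurement model
#'
#' Standardizes the manifest data columnwise (mean 0, unit sample SD) and
#' applies a scoring method's weight matrix. By default the indicator
#' correlation matrix entering the regression and correlation-preserving
#' weights is the sample correlation matrix (the natural estimator of Sigma
#' in a correlation-metric model); `sigma = "model"` substitutes the
#' model-implied Sigma_hat = Lambda_hat Phi_hat Lambda_hat' + Theta_hat,
#' which reproduces the population score identities exactly at population
#' parameter values.
#'
#' @param fit a convergent `uls_fit`.
#' @param X n x p manifest data matrix.
#' @param method scoring method, see [scoreWeights()].
#' @param sigma `"sample"` (default) or `"model"`.
#' @return Object of class `score_set`: `method`, `W` (k x p), `F_hat`
#'   (n x k), or `NULL` when the weights do not exist.
#' @export
factorScores <- function(fit, X, method = .scoreMethods,
                         sigma = c("sample", "model")) {
  method <- match.arg(method)
  sigma <- match.arg(sigma)
  Sig <- if (sigma == "model") fit$Sigma_model else fit$S
  W <- scoreWeights(fit$Lambda_hat, fit$Phi_hat, Sig, method)
  if (is.null(W)) return(NULL)
  Z <- scale(X)
  F_hat <- Z %*% t(W)
  if (any(!is.finite(F_hat))) return(NULL)
  structure(list(method = method, W = W, F_hat = F_hat),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("Factor scores (", x$method, " method): ", nrow(x$F_hat),
      " observations x ", ncol(x$F_hat), " factors\n", sep = "")
  invisible(x)
}

#' Factor-score validity coefficients
#'
#' The correlation between each factor and its regression-method score,
#' rho = diag(Phi Lambda' Sigma^-1 Lambda Phi)^1/2 — a measure of factor
#' determinacy (rho -> 1 as loadings approach 1 and error variances vanish).
#'
#' @param model a `measurement_model` (or any list with `Lambda`, `Phi`,
#'   `Sigma`).
#' @return Numeric vector of length k with values in (0, 1].
#' @export
validityRho <- function(model) {
  Sinv <- solve(model$Sigma)
  M <- model$Phi %*% t(model$Lambda) %*% Sinv %*% model$Lambda %*% model$Phi
  sqrt(diag(M))
}
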