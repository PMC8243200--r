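#' Sample correlation matrix
#'
#' Pearson correlations of the manifest data. A zero-variance column makes
#' correlations undefined; the caller treats that as a nonconvergent
#' replication.
#'
#' @param X n x p data matrix, n >= 2.
#' @return p x p correlation matrix, or `NULL` with a warning condition if a
#'   column has zero variance.
#' @export
sampleCorrelation <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || any(!is.finite(sds))) return(NULL)
  stats::cor(X)
}

.isPD <- function(M, tol = 1e-10) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

# ULS discrepancy: sum over lower off-diagonal elements of (S - Lambda Phi
# Lambda')^2. theta: par = c(8 loadings, phi12). E below is the symmetric
# residual matrix with zero diagonal, so the objective is 0.5 * sum(E^2)
# and the gradient has the closed forms used in .ulsGrad.
.ulsResid <- function(par, S) {
  L <- .loadingPattern()
  L[L == 1] <- par[1:8]
  Phi <- matrix(c(1, par[9], par[9], 1), 2, 2)
  E <- S - L %*% Phi %*% t(L)
  diag(E) <- 0
  list(E = E, L = L)
}

.ulsObj <- function(par, S) {
  0.5 * sum(.ulsResid(par, S)$E^2)
}

.ulsGrad <- function(par, S) {
  r <- .ulsResid(par, S)
  Phi <- matrix(c(1, par[9], par[9], 1), 2, 2)
  GL <- -2 * r$E %*% r$L %*% Phi        # dF/dLambda (full matrix)
  gl <- GL[.loadingPattern() == 1]
  gphi <- -2 * drop(t(r$L[, 1]) %*% r$E %*% r$L[, 2])
  c(gl, gphi)
}

#' Fit the two-factor model by unweighted least squares
#'
#' Minimizes the sum of squared differences between the lower off-diagonal
#' elements of the sample correlation matrix and the model-implied common
#' part Lambda Phi Lambda'. Nine free parameters: eight loadings on the
#' simple-structure pattern and the interfactor correlation, all
#' unconstrained (an estimate |phi12| > 1 is caught by
#' [admissibilityCheck()]). The error variances are derived afterwards as
#' theta = 1 - diag(Lambda Phi Lambda'). Factor signs are aligned so each
#' loading column has a positive sum, with phi12 flipped accordingly.
#'
#' @param S sample correlation matrix (8 x 8).
#' @param start optional start values `c(loadings, phi12)`; defaults to
#'   loadings 0.5 and phi12 0.
#' @return Object of class `uls_fit`: `Lambda_hat`, `Phi_hat`, `theta_hat`,
#'   `Sigma_model`, `S`, `discrepancy`, `optim_ok`, `converged`, `reasons`.
#' @export
ulsFit <- function(S, start = c(rep(0.5, 8), 0)) {
  stopifnot(is.matrix(S), nrow(S) == 8L, ncol(S) == 8L)
  opt <- stats::nlminb(start, .ulsObj, .ulsGrad, S = S,
                       control = list(iter.max = 500L, eval.max = 1000L,
                                      rel.tol = 1e-12, x.tol = 1e-10))
  par <- opt$par
  optim_ok <- is.finite(opt$objective) && all(is.finite(par)) &&
    opt$iterations < 500L
  L <- .loadingPattern()
  L[L == 1] <- par[1:8]
  phi <- par[9]
  # sign alignment: each factor's loading column sums positive
  for (g in 1:2) {
    if (sum(L[, g]) < 0) {
      L[, g] <- -L[, g]
      phi <- -phi
    }
  }
  Phi <- matrix(c(1, phi, phi, 1), 2, 2)
  common <- L %*% Phi %*% t(L)
  theta <- 1 - diag(common)
  Sigma_model <- common
  diag(Sigma_model) <- 1
  fit <- structure(
    list(Lambda_hat = L, Phi_hat = Phi, theta_hat = theta,
         Sigma_model = Sigma_model, S = S, discrepancy = opt$objective,
         optim_ok = optim_ok, converged = NA, reasons = character()),
    class = "uls_fit")
  chk <- admissibilityCheck(fit)
  fit$converged <- chk$ok
  fit$reasons <- chk$reasons
  fit
}

#' Admissibility of a ULS solution
#'
#' A replication is flagged nonconvergent if the sample correlation matrix,
#' the estimated factor correlation matrix, the derived error-variance
#' matrix or the model-implied correlation matrix is not positive definite,
#' if the estimated interfactor correlation exceeds 1 in absolute value
#' (including Heywood cases through negative error variances), if any
#' loading estimate is missing or non-finite, or if the optimizer failed.
#'
#' @param fit a `uls_fit` (possibly non-converged).
#' @return List with `ok` (logical) and `reasons` (character vector of
#'   reason codes among `"optim"`, `"loading_na"`, `"phi_gt1"`, `"S_npd"`,
#'   `"Phi_npd"`, `"Theta_npd"`, `"Sigma_npd"`).
#' @export
admissibilityCheck <- function(fit) {
  reasons <- character()
  lam <- fit$Lambda_hat[.loadingPattern() == 1]
  if (!isTRUE(fit$optim_ok)) reasons <- c(reasons, "optim")
  if (anyNA(lam) || any(!is.finite(lam))) reasons <- c(reasons, "loading_na")
  phi <- fit$Phi_hat[1, 2]
  if (!is.finite(phi) || abs(phi) > 1) reasons <- c(reasons, "phi_gt1")
  if (!.isPD(fit$S)) reasons <- c(reasons, "S_npd")
  if (is.finite(phi) && abs(phi) < 1) {
    # 2x2 correlation matrix is PD iff |phi| < 1; redundant eigen check kept
    if (!.isPD(fit$Phi_hat)) reasons <- c(reasons, "Phi_npd")
  } else if (!("phi_gt1" %in% reasons)) {
    reasons <- c(reasons, "Phi_npd")
  }
  if (any(!is.finite(fit$theta_hat)) || any(fit$theta_hat <= 1e-10))
    reasons <- c(reasons, "Theta_npd")
  if (all(is.finite(fit$Sigma_model)) ) {
    if (!.isPD(fit$Sigma_model)) reasons <- c(reasons, "Sigma_npd")
  } else reasons <- c(reasons, "Sigma_npd")
  list(ok = length(reasons) == 0L, reasons = reasons)
}

#' @export
print.uls_fit <- function(x, ...) {
  cat("ULS fit:", if (isTRUE(x$converged)) "admissible" else
    paste("nonconvergent [", paste(x$reasons, collapse = ", "), "]"),
    " discrepancy =", format(x$discrepancy, digits = 6), "\n")
  cat("phi12_hat =", format(x$Phi_hat[1, 2], digits = 4), "\n")
  invisible(x)
}
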