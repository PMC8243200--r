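#' Endpoints of the loading-generating uniform distribution
#'
#' Loadings are drawn from a uniform distribution parameterized by its mean
#' and standard deviation. A Uniform(a, b) has mean (a + b)/2 and SD
#' (b - a)/(2 sqrt(3)), so the unique endpoints matching a target (mu,
#' sigma) are a = mu - sqrt(3) sigma and b = mu + sqrt(3) sigma. With
#' sigma = 0 the distribution degenerates to a point mass at mu. Over the
#' canonical design the support stays inside [0.244, 0.956].
#'
#' @param mu target mean of the loading distribution.
#' @param sigma target standard deviation (>= 0).
#' @return Numeric vector `c(a, b)`.
#' @examples
#' uniformEndpoints(0.40, 0.09)  # c(0.2441..., 0.5559...)
#' @export
uniformEndpoints <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  a <- mu - sqrt(3) * sigma
  b <- mu + sqrt(3) * sigma
  if (a <= 0 || b >= 1)
    stop("configuration error: loading support [", signif(a, 4), ", ",
         signif(b, 4), "] falls outside (0, 1)")
  c(a, b)
}

# indicator -> factor pattern: indicators 1-4 on factor 1, 5-8 on factor 2
.loadingPattern <- function() {
  P <- matrix(0, 8, 2)
  P[1:4, 1] <- 1
  P[5:8, 2] <- 1
  P
}

#' Draw a simple-structure loading matrix
#'
#' Draws eight i.i.d. loadings from the condition's uniform distribution and
#' places them in the two-factor simple-structure pattern (indicators 1-4 on
#' factor 1, 5-8 on factor 2, zero cross-loadings). Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @inheritParams uniformEndpoints
#' @return An 8 x 2 loading matrix.
#' @export
drawLoadings <- function(mu, sigma) {
  ep <- uniformEndpoints(mu, sigma)
  lam <- stats::runif(8, ep[1], ep[2])
  L <- .loadingPattern()
  L[L == 1] <- lam
  L
}

#' Build a standardized two-factor measurement model
#'
#' Given a loading matrix and an interfactor correlation, constructs the
#' population model for standardized indicators: Phi is the 2 x 2 factor
#' correlation matrix, the measurement-error covariance is the diagonal
#' Theta = I - diag(Lambda Phi Lambda'), and the implied indicator
#' correlation matrix is Sigma = Lambda Phi Lambda' + Theta, which has unit
#' diagonal by construction.
#'
#' @param Lambda 8 x 2 (or p x k) loading matrix.
#' @param phi12 interfactor correlation, |phi12| < 1.
#' @return Object of class `measurement_model` with elements `Lambda`,
#'   `Phi`, `theta` (diagonal vector), `Sigma`.
#' @examples
#' m <- buildModel(matrix(c(rep(.6, 4), rep(0, 8), rep(.6, 4)), 8, 2), 0.3)
#' diag(m$Sigma)  # all 1
#' @export
buildModel <- function(Lambda, phi12) {
  stopifnot(is.matrix(Lambda), ncol(Lambda) == 2L, abs(phi12) < 1)
  Phi <- matrix(c(1, phi12, phi12, 1), 2, 2)
  common <- Lambda %*% Phi %*% t(Lambda)
  theta <- 1 - diag(common)
  if (any(theta <= 0))
    stop("invalid design: communality >= 1 for at least one indicator ",
         "(non-positive measurement-error variance)")
  Sigma <- common
  diag(Sigma) <- 1
  structure(list(Lambda = Lambda, Phi = Phi, theta = theta, Sigma = Sigma),
            class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("Standardized measurement model:", nrow(x$Lambda), "indicators,",
      ncol(x$Lambda), "factors, phi12 =", format(x$Phi[1, 2]), "\n")
  cat("loadings:", paste(format(round(x$Lambda[x$Lambda != 0], 3)),
                         collapse = " "), "\n")
  invisible(x)
}

#' Simulate manifest data from a measurement model
#'
#' Draws true factor scores F ~ N2(0, Phi) and measurement errors
#' delta ~ Np(0, Theta), and forms X = F Lambda' + delta. Uses the current
#' RNG state.
#'
#' @param model a `measurement_model`.
#' @param n sample size (>= 1).
#' @return List of class `sample_data` with `X` (n x p), `F_true` (n x 2)
#'   and `Lambda_pop` (the loading draw realized for this sample).
#' @export
simulateSample <- function(model, n) {
  stopifnot(n >= 1)
  R <- chol(model$Phi)
  F_true <- matrix(stats::rnorm(n * 2L), n, 2L) %*% R
  p <- nrow(model$Lambda)
  delta <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(model$theta), p)
  X <- F_true %*% t(model$Lambda) + delta
  structure(list(X = X, F_true = F_true, Lambda_pop = model$Lambda),
            class = "sample_data")
}

#' Dump one replication's model and data as delimited text
#'
#' Debug helper: writes Lambda, Phi, theta, X and F_true as tab-separated
#' files under `dir` with a common `prefix`.
#'
#' @param model a `measurement_model`.
#' @param sample a `sample_data`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Character vector of file paths, invisibly.
#' @export
dumpReplication <- function(model, sample, dir, prefix = "rep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("Lambda", "Phi", "theta",
                                                "X", "F_true"), ".tsv"))
  utils::write.table(model$Lambda, paths[1], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$Phi, paths[2], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$theta, paths[3], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sample$X, paths[4], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sample$F_true, paths[5], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
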