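.links <- c("identity", "logit", "log")

# clip the linear predictor inside the inverse link during iteration to
# guard against overflow under separation
.ETA_CLIP <- 30

.linkFuns <- function(link) {
  switch(link,
    identity = list(
      linkinv = function(eta) eta,
      # dmu/deta and variance function; weights handled specially (OLS)
      mu.eta = function(eta) rep(1, length(eta)),
      varfun = function(mu) rep(1, length(mu))),
    logit = list(
      linkinv = function(eta) stats::plogis(eta),
      mu.eta = function(eta) { p <- stats::plogis(eta); p * (1 - p) },
      varfun = function(mu) mu * (1 - mu)),
    log = list(
      linkinv = function(eta) exp(eta),
      mu.eta = function(eta) exp(eta),
      varfun = function(mu) mu),
    stop("unknown link: ", link))
}

#' Generate outcomes from true factor scores
#'
#' The linear predictor is eta = f1 * gamma1 + f2 * gamma2 with gamma =
#' (1, 2) by default. Outcomes are drawn, conditional on the true scores,
#' from N(eta, 10) under the identity link, Bernoulli(plogis(eta)) under the
#' logit link, and Poisson(exp(eta)) under the log link. Uses the current
#' RNG state.
#'
#' @param F_true n x 2 matrix of true factor scores.
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param gamma true coefficient vector, default `c(1, 2)`.
#' @param sd_identity conditional outcome SD under the identity link,
#'   default `sqrt(10)`.
#' @return Numeric outcome vector of length n.
#' @export
generateOutcome <- function(F_true, link = .links, gamma = c(1, 2),
                            sd_identity = sqrt(10)) {
  link <- match.arg(link)
  eta <- drop(F_true %*% gamma)
  n <- length(eta)
  switch(link,
    identity = stats::rnorm(n, eta, sd_identity),
    logit = stats::rbinom(n, 1L, stats::plogis(eta)),
    log = stats::rpois(n, exp(eta)))
}

#' Fit an intercept-free GLM by Fisher scoring
#'
#' Maximum likelihood for g(mu) = F gamma* with canonical links (identity/
#' Gaussian, logit/Bernoulli, log/Poisson) and no intercept, via
#' iteratively reweighted least squares with the expected information
#' matrix. Standard errors come from the inverse expected information at
#' the solution; the Gaussian dispersion is estimated by the residual mean
#' square with n - k degrees of freedom. Under the identity link the
#' iteration collapses to the ordinary least-squares projection.
#'
#' Nonconvergence (iteration limit, non-finite estimates or standard
#' errors — e.g. complete separation in the logistic model) is flagged, not
#' raised.
#'
#' @param F_hat n x k matrix of regressors (factor score estimates).
#' @param y outcome vector.
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tol relative coefficient-change convergence tolerance.
#' @return Object of class `glfsr_fit`: `coef`, `se`, `vcov`, `link`,
#'   `iterations`, `converged`, `n`, `df_residual`, `dispersion`.
#' @export
fitGlfsr <- function(F_hat, y, link = .links, max_iter = 100L,
                     tol = 1e-10) {
  link <- match.arg(link)
  stopifnot(is.matrix(F_hat), nrow(F_hat) == length(y),
            nrow(F_hat) > ncol(F_hat))
  n <- nrow(F_hat)
  k <- ncol(F_hat)
  lf <- .linkFuns(link)
  if (link == "identity") {
    XtX <- crossprod(F_hat)
    fit <- tryCatch({
      beta <- drop(solve(XtX, crossprod(F_hat, y)))
      resid <- y - drop(F_hat %*% beta)
      disp <- sum(resid^2) / (n - k)
      V <- disp * solve(XtX)
      list(beta = beta, V = V, iter = 1L, disp = disp, ok = TRUE)
    }, error = function(e) list(ok = FALSE))
  } else {
    # standard GLM initialization from adjusted responses, then IRLS on
    # the working response z = eta + (y - mu) / (dmu/deta)
    eta <- if (link == "logit") stats::qlogis((y + 0.5) / 2)
           else log(y + 0.1)
    beta <- NULL
    ok <- FALSE
    iter <- 0L
    V <- NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      eta <- pmin(pmax(eta, -.ETA_CLIP), .ETA_CLIP)
      mu <- lf$linkinv(eta)
      w <- lf$mu.eta(eta)  # canonical: dmu/deta = variance function
      z <- eta + (y - mu) / w
      info <- crossprod(F_hat, F_hat * w)
      beta_new <- tryCatch(drop(solve(info, crossprod(F_hat, w * z))),
                           error = function(e) NULL)
      if (is.null(beta_new) || any(!is.finite(beta_new))) break
      conv <- !is.null(beta) &&
        max(abs(beta_new - beta)) / max(1, max(abs(beta_new))) < tol
      beta <- beta_new
      eta <- drop(F_hat %*% beta)
      if (conv) {
        # a solution at the clip boundary is a divergence (separation)
        # stabilized by the clip, not a maximum of the likelihood
        if (max(abs(eta)) >= .ETA_CLIP - 1e-6) break
        # expected information at the final coefficients
        info <- crossprod(F_hat, F_hat * lf$mu.eta(eta))
        V <- tryCatch(solve(info), error = function(e) NULL)
        ok <- !is.null(V)
        break
      }
    }
    fit <- list(beta = beta, V = V, iter = iter, disp = 1, ok = ok)
  }
  if (is.null(fit$beta)) fit$beta <- rep(NA_real_, k)
  if (!isTRUE(fit$ok) || is.null(fit$V) || any(!is.finite(fit$beta)) ||
      any(!is.finite(diag(fit$V))) || any(diag(fit$V) <= 0)) {
    return(structure(list(coef = rep(NA_real_, k), se = rep(NA_real_, k),
                          vcov = NULL, link = link,
                          iterations = if (is.null(fit$iter)) 0L else fit$iter,
                          converged = FALSE, n = n, df_residual = n - k,
                          dispersion = NA_real_),
                     class = "glfsr_fit"))
  }
  structure(list(coef = fit$beta, se = sqrt(diag(fit$V)), vcov = fit$V,
                 link = link, iterations = fit$iter, converged = TRUE,
                 n = n, df_residual = n - k, dispersion = fit$disp),
            class = "glfsr_fit")
}

#' @export
print.glfsr_fit <- function(x, ...) {
  cat("Intercept-free GLM (", x$link, " link), n = ", x$n, ", ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iteration(s)\n", sep = "")
  if (x$converged) {
    est <- rbind(estimate = x$coef, se = x$se)
    colnames(est) <- paste0("gamma", seq_along(x$coef))
    print(round(est, 4))
  }
  invisible(x)
}

#' Two-sided test of the first coefficient
#'
#' Tests H0: gamma1* = `null_value` with the Wald statistic
#' (gamma1_hat - null) / SE. The reference distribution is t with n - k
#' degrees of freedom under the identity link (where the Gaussian
#' dispersion is estimated) and standard normal under the logit and log
#' links.
#'
#' @param fit a converged `glfsr_fit`.
#' @param null_value hypothesized value, default 1.
#' @param which coefficient index, default 1.
#' @return Two-sided p-value.
#' @export
coefficientTest <- function(fit, null_value = 1, which = 1L) {
  stopifnot(isTRUE(fit$converged))
  stat <- (fit$coef[which] - null_value) / fit$se[which]
  if (fit$link == "identity") {
    2 * stats::pt(-abs(stat), df = fit$df_residual)
  } else {
    2 * stats::pnorm(-abs(stat))
  }
}

#' Score-equation residual at the solution
#'
#' Max absolute entry of F' D V^-1 (y - mu) at the fitted coefficients (for
#' canonical links D V^-1 reduces to the identity weighting of raw
#' residuals). Diagnostic; near zero at a genuine ML solution.
#'
#' @param fit a converged `glfsr_fit`.
#' @param F_hat,y the data the model was fitted to.
#' @return Scalar, max absolute score-equation component.
#' @export
scoreResidual <- function(fit, F_hat, y) {
  lf <- .linkFuns(fit$link)
  eta <- drop(F_hat %*% fit$coef)
  mu <- lf$linkinv(eta)
  r <- (y - mu) / fit$dispersion
  max(abs(crossprod(F_hat, r)))
}
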