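.metaFactors <- c("mu_lambda", "sigma_lambda", "phi12", "n", "method",
                  "link")

# Build the sum-to-zero design matrix for main effects + all first-order
# interactions of the factors present (>= 2 levels) in `table`, with a
# column -> term assignment map.
.metaDesign <- function(table, response, factors = .metaFactors) {
  stopifnot(response %in% names(table))
  present <- factors[vapply(factors, function(f) {
    f %in% names(table) && length(unique(table[[f]])) >= 2L
  }, logical(1))]
  if (length(present) < 1L) stop("no factors with >= 2 levels present")
  df <- table[, c(present, response)]
  for (f in present) df[[f]] <- factor(df[[f]])
  fml <- stats::as.formula(paste(response, "~ (",
                                 paste(present, collapse = " + "), ")^2"))
  contr <- stats::setNames(as.list(rep("contr.sum", length(present))),
                           present)
  mf <- stats::model.frame(fml, df)
  X <- stats::model.matrix(attr(mf, "terms"), mf, contrasts.arg = contr)
  list(X = X, y = df[[response]], assign = attr(X, "assign"),
       terms = attr(attr(mf, "terms"), "term.labels"))
}

.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NA_real_)
  sum(fit$residuals^2)
}

#' Type III ANOVA decomposition
#'
#' Fixed-effects ANOVA of a performance criterion on the simulation
#' factors (all categorical) with main effects and all first-order
#' interactions, under sum-to-zero contrasts. The Type III sum of squares
#' of each term is the increase in residual sum of squares when that
#' term's columns are deleted from the full model with every other term
#' retained. On the full balanced grid this reproduces the classical
#' layout: with six factors the residual has 3,616 degrees of freedom out
#' of 3,780 conditions.
#'
#' @param table condition-level data frame holding the factor columns
#'   (`mu_lambda`, `sigma_lambda`, `phi12`, `n`, `method`, `link` — those
#'   with at least two levels are used) and the response.
#' @param response name of the response column.
#' @return Data frame of class `type3_anova` with columns `term`, `df`,
#'   `SS`, the final row being `Residuals`. An `N` attribute records the
#'   number of rows analysed.
#' @export
type3Anova <- function(table, response) {
  d <- .metaDesign(table, response)
  full_rss <- .rss(d$X, d$y)
  if (is.na(full_rss)) {
    # identify empty cells for the error message
    stop("rank-deficient design (empty factor-level cells); ",
         "cannot compute Type III sums of squares")
  }
  terms <- d$terms
  out <- data.frame(term = terms, df = NA_integer_, SS = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    cols <- d$assign == i
    out$df[i] <- sum(cols)
    red_rss <- .rss(d$X[, !cols, drop = FALSE], d$y)
    out$SS[i] <- red_rss - full_rss
  }
  n_par <- ncol(d$X)
  out <- rbind(out, data.frame(term = "Residuals",
                               df = length(d$y) - n_par, SS = full_rss))
  attr(out, "N") <- length(d$y)
  class(out) <- c("type3_anova", class(out))
  out
}

#' @export
print.type3_anova <- function(x, ...) {
  cat("Type III ANOVA (sum-to-zero contrasts), N =", attr(x, "N"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Partial omega-squared effect size
#'
#' The low-bias, population-based effect-size measure for a fixed-effects
#' ANOVA term:
#' omega_p2 = df (MSS_eff - MSS_err) / (df MSS_eff + (N - df) MSS_err),
#' with MSS = SS / df. May be negative for null effects; reported as-is.
#'
#' @param ss_effect,df_effect effect sum of squares and degrees of freedom.
#' @param ss_error,df_error residual sum of squares and degrees of freedom.
#' @param N number of observations in the ANOVA.
#' @return Scalar effect size (<= 1).
#' @examples
#' omegaP2(641790, 6, 348481, 3616, 3780)  # ~0.638
#' @export
omegaP2 <- function(ss_effect, df_effect, ss_error, df_error, N) {
  stopifnot(df_effect >= 1, df_error >= 1, N > df_effect)
  mse <- ss_effect / df_effect
  msr <- ss_error / df_error
  df_effect * (mse - msr) / (df_effect * mse + (N - df_effect) * msr)
}

#' Bootstrap confidence interval for partial omega-squared
#'
#' Nonparametric percentile interval from `B` resamples of the condition
#' rows, recomputing the Type III ANOVA and the effect size each time. A
#' resample that drops a factor level entirely is redrawn (and counted in
#' the `redraws` attribute).
#'
#' @param table,response as in [type3Anova()].
#' @param effect term label (e.g. `"method:link"`).
#' @param B number of resamples, default 2000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed for the resampling.
#' @return Named vector `c(lower, upper)` with attributes `point` (the
#'   full-sample estimate), `B`, and `redraws`.
#' @export
bootstrapOmega <- function(table, response, effect, B = 2000L,
                           level = 0.95, seed = 1L) {
  stopifnot(B >= 200L)
  a0 <- type3Anova(table, response)
  if (!effect %in% a0$term) stop("unknown effect: ", effect)
  point <- .omegaFromTable(a0, effect)
  d <- .metaDesign(table, response)
  present <- intersect(.metaFactors, names(table))
  present <- present[vapply(present, function(f)
    length(unique(table[[f]])) >= 2L, logical(1))]
  set.seed(seed)
  vals <- numeric(B)
  redraws <- 0L
  N <- nrow(table)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      ok <- all(vapply(present, function(f)
        length(unique(table[[f]][idx])) ==
          length(unique(table[[f]])), logical(1)))
      if (ok) break
      redraws <- redraws + 1L
    }
    ab <- type3Anova(table[idx, , drop = FALSE], response)
    vals[b] <- .omegaFromTable(ab, effect)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  structure(stats::setNames(ci, c("lower", "upper")), point = point,
            B = B, redraws = redraws)
}

.omegaFromTable <- function(anova_tab, effect) {
  res <- anova_tab[anova_tab$term == "Residuals", ]
  eff <- anova_tab[anova_tab$term == effect, ]
  omegaP2(eff$SS, eff$df, res$SS, res$df, attr(anova_tab, "N"))
}

#' Flag practically important effects
#'
#' An effect is flagged when its confidence interval covers any value in
#' [0.14, 1], i.e. the upper bound is at least 0.14 (the conventional
#' threshold for a large effect).
#'
#' @param ci_upper numeric vector of CI upper bounds.
#' @return Logical vector.
#' @export
flagLargeEffects <- function(ci_upper) {
  ci_upper >= 0.14
}

#' Full meta-analysis of a condition summary table
#'
#' Runs the Type III ANOVA and partial omega-squared (with bootstrap CIs)
#' for one criterion over a condition-level summary table, mirroring a
#' sum-of-squares decomposition table.
#'
#' @param summary_table output of [summarizeRun()] (unusable cells are
#'   dropped with a message).
#' @param response criterion column (`"nonconv"`, `"RB"`, `"RSEB"`,
#'   `"RMSE"` or `"alpha"`).
#' @param B bootstrap resamples (set `B = 0` to skip CIs).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame: `term`, `df`, `SS`, `omega_p2`, `ci_lower`,
#'   `ci_upper`, `large` (plus the residual row).
#' @export
metaAnalyze <- function(summary_table, response, B = 2000L, seed = 1L) {
  tab <- summary_table[!is.na(summary_table[[response]]), , drop = FALSE]
  dropped <- nrow(summary_table) - nrow(tab)
  if (dropped > 0)
    message(dropped, " condition cell(s) without a usable '", response,
            "' value dropped from the meta-analysis")
  if (nrow(tab) < 2L)
    stop("no usable condition cells for response '", response,
         "' (need convergent replications in at least two cells)")
  a <- type3Anova(tab, response)
  eff <- a$term != "Residuals"
  a$omega_p2 <- NA_real_
  a$omega_p2[eff] <- vapply(a$term[eff], function(tm)
    .omegaFromTable(a, tm), numeric(1))
  a$ci_lower <- a$ci_upper <- NA_real_
  if (B >= 200L) {
    for (i in which(eff)) {
      ci <- bootstrapOmega(tab, response, a$term[i], B = B,
                           seed = seed + i)
      a$ci_lower[i] <- ci[["lower"]]
      a$ci_upper[i] <- ci[["upper"]]
    }
  }
  a$large <- ifelse(eff, flagLargeEffects(a$ci_upper), NA)
  a
}
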