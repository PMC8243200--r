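# small synthetic condition table: a balanced grid over a subset of the
# design factors with a constructed response
syntheticTable <- function(seed = 20, effect = 2) {
  set.seed(seed)
  tab <- expand.grid(mu_lambda = c(0.4, 0.8), phi12 = c(0, 0.5),
                     method = c("regression", "total"),
                     link = c("identity", "log"),
                     replica = 1:3, stringsAsFactors = FALSE)
  tab$y <- effect * (tab$method == "total") +
    0.5 * (tab$mu_lambda == 0.8) * (tab$link == "log") + rnorm(nrow(tab))
  tab
}

test_that("Type III SS matches a hand-worked balanced 2x2 ANOVA", {
  # cell means design: factors A (method), B (link), r replicates per cell
  tab <- expand.grid(method = c("regression", "total"),
                     link = c("identity", "log"), replica = 1:2,
                     stringsAsFactors = FALSE)
  # constructed responses with known effects and no noise beyond cells
  mean_map <- c(10, 14, 12, 20)  # cells (r,i), (t,i), (r,l), (t,l)
  tab$y <- mean_map[match(paste(tab$method, tab$link),
                          c("regression identity", "total identity",
                            "regression log", "total log"))]
  a <- type3Anova(tab, "y")
  r <- 2  # replicates per cell
  # textbook two-way decomposition from the cell means
  A <- mean(c(14, 20)) - mean(c(10, 12))   # method main effect
  B <- mean(c(12, 20)) - mean(c(10, 14))   # link main effect
  AB <- (20 - 14) - (12 - 10)              # interaction contrast
  expect_equal(a$SS[a$term == "method"], r * 2 * 2 * (A / 2)^2)
  expect_equal(a$SS[a$term == "link"], r * 2 * 2 * (B / 2)^2)
  expect_equal(a$SS[a$term == "method:link"], r * 4 * (AB / 4)^2)
  expect_equal(a$SS[a$term == "Residuals"], 0)
})

test_that("a constant response yields zero SS everywhere", {
  tab <- syntheticTable()
  tab$y <- 7
  a <- type3Anova(tab, "y")
  expect_true(all(abs(a$SS) < 1e-18))
})

test_that("the full grid reproduces the classical df layout", {
  g <- enumerateGrid()
  g$y <- seq_len(nrow(g)) %% 7  # arbitrary non-constant response
  a <- type3Anova(g, "y")
  expect_equal(a$df[a$term == "method"], 3L)
  expect_equal(a$df[a$term == "link"], 2L)
  expect_equal(a$df[a$term == "method:link"], 6L)
  expect_equal(a$df[a$term == "mu_lambda"], 2L)
  expect_equal(a$df[a$term == "phi12"], 6L)
  expect_equal(a$df[a$term == "n"], 4L)
  expect_equal(a$df[a$term == "Residuals"], 3616L)
  expect_equal(attr(a, "N"), 3780L)
})

test_that("Type III SS agrees with car::Anova under sum contrasts", {
  skip_if_not_installed("car")
  tab <- syntheticTable(seed = 21)
  a <- type3Anova(tab, "y")
  for (f in c("mu_lambda", "phi12", "method", "link"))
    tab[[f]] <- factor(tab[[f]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ (mu_lambda + phi12 + method + link)^2, data = tab)
  ca <- car::Anova(fit, type = "III")
  for (tm in setdiff(a$term, "Residuals")) {
    expect_equal(a$SS[a$term == tm], ca[tm, "Sum Sq"], tolerance = 1e-8,
                 label = tm)
  }
  expect_equal(a$SS[a$term == "Residuals"], ca["Residuals", "Sum Sq"],
               tolerance = 1e-8)
})

test_that("on balanced data Type III matches sequential SS and sums to total", {
  tab <- syntheticTable(seed = 22)
  a <- type3Anova(tab, "y")
  for (f in c("mu_lambda", "phi12", "method", "link"))
    tab[[f]] <- factor(tab[[f]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ (mu_lambda + phi12 + method + link)^2, data = tab)
  seq_ss <- anova(fit)  # Type I
  for (tm in c("mu_lambda", "phi12", "method", "link")) {
    expect_equal(a$SS[a$term == tm], seq_ss[tm, "Sum Sq"],
                 tolerance = 1e-8, label = tm)
  }
  total <- sum((tab$y - mean(tab$y))^2)
  expect_equal(sum(a$SS), total, tolerance = 1e-6 * total)
})

test_that("rank-deficient designs raise an informative error", {
  tab <- syntheticTable()
  tab <- tab[!(tab$method == "total" & tab$link == "log"), ]
  expect_error(type3Anova(tab, "y"), "rank-deficient")
})

test_that("partial omega-squared reproduces direct arithmetic", {
  # null effect: identical mean squares give exactly zero
  expect_equal(omegaP2(50, 5, 100, 10, 200), 0)
  # worked examples from a published sum-of-squares decomposition
  o1 <- omegaP2(641790, 6, 348481, 3616, 3780)
  expect_gte(o1, 0.622)
  expect_lte(o1, 0.653)
  o2 <- omegaP2(273851, 2, 78825, 3616, 3780)
  expect_gte(o2, 0.758)
  expect_lte(o2, 0.779)
  # negative values are reported as-is
  expect_lt(omegaP2(1, 2, 1000, 10, 50), 0)
})

test_that("bootstrap CIs are seeded, detect real effects, and cover null ones", {
  tab <- syntheticTable(seed = 23, effect = 3)
  ci1 <- bootstrapOmega(tab, "y", "method", B = 200, seed = 5)
  ci2 <- bootstrapOmega(tab, "y", "method", B = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_gt(ci1[["lower"]], 0)  # strong constructed effect
  expect_true(attr(ci1, "point") >= ci1[["lower"]] - 1e-12)
  expect_true(attr(ci1, "point") <= ci1[["upper"]] + 1e-12)
  # null response: CI covers 0 in most repeated runs
  covered <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    tab$y <- rnorm(nrow(tab))
    ci <- bootstrapOmega(tab, "y", "phi12", B = 200, seed = s)
    if (ci[["lower"]] <= 0 && ci[["upper"]] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 9L)
})

test_that("large-effect flagging follows the CI-overlap rule", {
  expect_true(flagLargeEffects(0.20))
  expect_false(flagLargeEffects(0.10))
  expect_true(flagLargeEffects(0.14))  # boundary inclusive
  expect_equal(flagLargeEffects(c(0.2, 0.1)), c(TRUE, FALSE))
})

test_that("metaAnalyze assembles the decomposition with effect sizes", {
  tab <- syntheticTable(seed = 24, effect = 3)
  res <- metaAnalyze(tab, "y", B = 0)
  expect_true("Residuals" %in% res$term)
  i <- res$term == "method"
  expect_gt(res$omega_p2[i], 0.5)
  expect_true(all(is.na(res$ci_lower)))  # B = 0 skips the bootstrap
})
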