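miniGrid <- function(reps = 2) {
  enumerateGrid(mu_lambda = 0.8, sigma_lambda = 0, phi12 = 0.3, n = 100,
                method = c("regression", "correlation", "total",
                           "weighted"),
                link = c("identity", "logit", "log"), reps = reps)
}

test_that("a single condition and replication yields 12 rows", {
  run <- runStudy(miniGrid(1), reps = 1, master_seed = 3)
  expect_equal(nrow(run), 12L)
  expect_setequal(unique(run$method),
                  c("regression", "correlation", "total", "weighted"))
  expect_setequal(unique(run$link), c("identity", "logit", "log"))
  expect_true(all(is.finite(run$gamma1) | run$nonconv))
})

test_that("runs are deterministic under a fixed master seed", {
  r1 <- runStudy(miniGrid(3), reps = 3, master_seed = 4)
  r2 <- runStudy(miniGrid(3), reps = 3, master_seed = 4)
  expect_identical(r1, r2)
  r3 <- runStudy(miniGrid(3), reps = 3, master_seed = 5)
  expect_false(identical(r1$gamma1, r3$gamma1))
})

test_that("a link-restricted run sees the same data as a full run", {
  full <- runStudy(miniGrid(2), reps = 2, master_seed = 6)
  g_id <- enumerateGrid(mu_lambda = 0.8, sigma_lambda = 0, phi12 = 0.3,
                        n = 100, method = "regression", link = "log",
                        reps = 2)
  sub <- runStudy(g_id, reps = 2, master_seed = 6)
  fsub <- full[full$method == "regression" & full$link == "log", ]
  expect_equal(sub$gamma1, fsub$gamma1)
  expect_equal(sub$se, fsub$se)
})

test_that("nonconvergence is identical across methods and links", {
  # a hard corner with appreciable nonconvergence
  g <- enumerateGrid(mu_lambda = 0.4, sigma_lambda = 0.09, phi12 = 0.8,
                     n = 50, method = c("regression", "total"),
                     link = c("identity", "log"), reps = 25)
  run <- runStudy(g, reps = 25, master_seed = 7)
  meas_nc <- run$reason != "glm" & run$reason != "scoring" & run$nonconv
  tab <- tapply(meas_nc, list(run$method, run$link), sum)
  expect_true(all(tab == tab[1, 1]))
  expect_gt(tab[1, 1], 0)  # the corner actually produces failures
})

test_that("the easiest design corner has near-zero nonconvergence", {
  g <- enumerateGrid(mu_lambda = 0.8, sigma_lambda = 0, phi12 = 0,
                     n = 1000, method = "regression", link = "identity",
                     reps = 100)
  run <- runStudy(g, reps = 100, master_seed = 8)
  expect_lt(100 * mean(run$nonconv), 2)
})

test_that("config lists drive runStudy and round-trip through CSV", {
  cfg <- list(mu_lambda = 0.8, sigma_lambda = 0, phi12 = 0.3, n = 100,
              methods = "regression", links = "identity", reps = 2,
              master_seed = 9)
  run <- runStudy(cfg)
  expect_equal(nrow(run), 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRunCSV(run, path)
  back <- readRunCSV(path)
  expect_equal(back$gamma1, run$gamma1, tolerance = 1e-12)
  s1 <- summarizeRun(run)
  s2 <- summarizeRun(back)
  expect_equal(s1$RB, s2$RB, tolerance = 1e-10)
})

test_that("summaries match a hand-built spreadsheet oracle", {
  # 20 crafted replication rows in one cell
  g1 <- c(0.8, 0.9, 0.95, 1, 1, 1.02, 1.05, 1.1, 1.15, 1.2,
          0.85, 0.92, 0.98, 1.01, 1.04, 1.08, 1.12, 1.18, 0.88, 1.3)
  rec <- data.frame(mu_lambda = 0.6, sigma_lambda = 0, phi12 = 0, n = 100,
                    rep = 1:20, method = "regression", link = "identity",
                    gamma1 = g1, se = rep(0.12, 20),
                    p = rep(c(0.01, 0.5), 10))
  s <- summarizeRun(rec)
  # hand computation: ceil(0.005*20) = 1 per tail; drop 0.8 and 1.3
  kept <- sort(g1)[2:19]
  expect_equal(s$C, 18)
  expect_equal(s$RB, 100 * mean(kept - 1), tolerance = 1e-10)
  expect_equal(s$RMSE, sqrt(mean((kept - 1)^2)), tolerance = 1e-10)
  expect_equal(s$RSEB, 100 * (0.12 / sd(kept) - 1), tolerance = 1e-10)
  # p-values of the trimmed set: 0.8 and 1.3 carried p = 0.01, 0.5
  expect_equal(s$alpha, 100 * (sum(rep(c(0.01, 0.5), 10) < 0.05) - 1) / 18,
               tolerance = 1e-10)
  expect_equal(s$nonconv, 0)
})

test_that("summarize is idempotent and schema-checked", {
  run <- runStudy(miniGrid(2), reps = 2, master_seed = 10)
  s1 <- summarizeRun(run)
  s2 <- summarizeRun(run)
  expect_identical(s1, s2)
  expect_error(summarizeRun(run[, setdiff(names(run), "se")]),
               "missing column")
  # empty input produces an empty, well-formed summary
  s0 <- summarizeRun(run[0, ])
  expect_equal(nrow(s0), 0L)
  expect_true(all(c("RB", "RSEB", "RMSE", "alpha") %in% names(s0)))
})

test_that("manifests fingerprint the configuration", {
  g <- miniGrid(2)
  m1 <- runManifest(g, 1)
  m2 <- runManifest(g, 1)
  expect_equal(m1$grid_hash, m2$grid_hash)
  g2 <- enumerateGrid(mu_lambda = 0.6, sigma_lambda = 0, phi12 = 0.3,
                      n = 100, method = "regression", link = "identity",
                      reps = 2)
  expect_false(runManifest(g2, 1)$grid_hash == m1$grid_hash)
})
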