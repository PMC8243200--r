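#' Run the GLFSR simulation study
#'
#' Executes, for every measurement condition in the grid and every
#' replication: draw loadings, simulate the sample and the true factor
#' scores, draw all three outcome types from the true scores, estimate the
#' measurement model by ULS, check admissibility, compute factor scores for
#' each requested method, and fit the intercept-free GLM for each requested
#' link, recording the first coefficient, its standard error and the
#' two-sided p-value against the true value 1.
#'
#' Each replication's RNG stream depends only on the measurement condition,
#' the replication index and the master seed — never on the scoring method
#' or link — so nonconvergence of the measurement step is identical across
#' methods and links, and results are reproducible regardless of execution
#' order. All three outcome vectors are drawn in a fixed order even when
#' only a subset of links is requested, so a restricted run sees exactly
#' the data of a full run.
#'
#' @param grid a `glfsr_grid` from [enumerateGrid()], or a config list from
#'   [readConfig()] with entries `mu_lambda`, `sigma_lambda`, `phi12`, `n`,
#'   `methods`, `links`, `reps`, `master_seed` (missing entries default to
#'   the full design).
#' @param reps replications per condition; defaults to the grid's `reps`
#'   attribute.
#' @param master_seed master seed for [replicationSeed()].
#' @param score_sigma `"sample"` (default) or `"model"`: correlation matrix used in
#'   the regression / correlation-preserving scoring weights.
#' @param gamma true structural coefficients, default `c(1, 2)`.
#' @param verbose print per-condition progress.
#' @return Long-format data frame of class `glfsr_run`, one row per
#'   (measurement condition, replication, method, link): columns
#'   `mu_lambda`, `sigma_lambda`, `phi12`, `n`, `rep`, `seed`, `nonconv`,
#'   `reason`, `method`, `link`, `gamma1`, `se`, `p`.
#' @export
runStudy <- function(grid = enumerateGrid(), reps = NULL, master_seed = 1L,
                     score_sigma = c("sample", "model"), gamma = c(1, 2),
                     verbose = FALSE) {
  score_sigma <- match.arg(score_sigma)
  if (is.list(grid) && !is.data.frame(grid)) {
    cfg <- grid
    dl <- designLevels()
    grid <- enumerateGrid(
      mu_lambda = if (!is.null(cfg$mu_lambda)) cfg$mu_lambda else dl$mu_lambda,
      sigma_lambda = if (!is.null(cfg$sigma_lambda)) cfg$sigma_lambda else dl$sigma_lambda,
      phi12 = if (!is.null(cfg$phi12)) cfg$phi12 else dl$phi12,
      n = if (!is.null(cfg$n)) cfg$n else dl$n,
      method = if (!is.null(cfg$methods)) cfg$methods else dl$method,
      link = if (!is.null(cfg$links)) cfg$links else dl$link,
      reps = if (!is.null(cfg$reps)) cfg$reps else 1000L)
    if (!is.null(cfg$master_seed)) master_seed <- cfg$master_seed
  }
  if (is.null(reps)) reps <- attr(grid, "reps")
  reps <- as.integer(reps)
  methods <- unique(grid$method)
  links <- unique(grid$link)
  mcond <- unique(grid[, c("mu_lambda", "sigma_lambda", "phi12", "n")])
  rownames(mcond) <- NULL
  n_cells <- length(methods) * length(links)
  total <- nrow(mcond) * reps * n_cells
  # plain preallocated vectors: assigning into data.frame columns inside
  # the loop copies the whole column each time
  v_mu <- numeric(total); v_sg <- numeric(total); v_ph <- numeric(total)
  v_n <- integer(total); v_rep <- integer(total); v_seed <- integer(total)
  v_nc <- logical(total); v_reason <- character(total)
  v_method <- character(total); v_link <- character(total)
  v_g <- rep(NA_real_, total); v_se <- rep(NA_real_, total)
  v_p <- rep(NA_real_, total)
  row <- 0L
  for (ci in seq_len(nrow(mcond))) {
    mu <- mcond$mu_lambda[ci]; sg <- mcond$sigma_lambda[ci]
    ph <- mcond$phi12[ci]; nn <- mcond$n[ci]
    for (r in seq_len(reps)) {
      seed <- replicationSeed(mu, sg, ph, nn, r, master_seed)
      set.seed(seed)
      L <- drawLoadings(mu, sg)
      model <- buildModel(L, ph)
      samp <- simulateSample(model, nn)
      y <- list(identity = generateOutcome(samp$F_true, "identity", gamma),
                logit = generateOutcome(samp$F_true, "logit", gamma),
                log = generateOutcome(samp$F_true, "log", gamma))
      S <- sampleCorrelation(samp$X)
      if (is.null(S)) {
        fit <- NULL; meas_ok <- FALSE; meas_reason <- "zero_var"
      } else {
        fit <- ulsFit(S)
        meas_ok <- isTRUE(fit$converged)
        meas_reason <- if (meas_ok) "" else
          paste(fit$reasons, collapse = "+")
      }
      for (m in methods) {
        sc <- if (meas_ok) factorScores(fit, samp$X, m, score_sigma)
              else NULL
        for (lk in links) {
          row <- row + 1L
          v_mu[row] <- mu; v_sg[row] <- sg; v_ph[row] <- ph
          v_n[row] <- nn; v_rep[row] <- r; v_seed[row] <- seed
          v_method[row] <- m; v_link[row] <- lk
          if (!meas_ok) {
            v_nc[row] <- TRUE; v_reason[row] <- meas_reason
          } else if (is.null(sc)) {
            v_nc[row] <- TRUE; v_reason[row] <- "scoring"
          } else {
            gf <- fitGlfsr(sc$F_hat, y[[lk]], lk)
            if (!gf$converged) {
              v_nc[row] <- TRUE; v_reason[row] <- "glm"
            } else {
              v_g[row] <- gf$coef[1]
              v_se[row] <- gf$se[1]
              v_p[row] <- coefficientTest(gf, null_value = gamma[1])
            }
          }
        }
      }
    }
    if (verbose)
      message(sprintf("condition %d/%d (mu=%.2f sd=%.2f phi=%.2f n=%d) done",
                      ci, nrow(mcond), mu, sg, ph, nn))
  }
  out <- data.frame(
    mu_lambda = v_mu, sigma_lambda = v_sg, phi12 = v_ph, n = v_n,
    rep = v_rep, seed = v_seed, nonconv = v_nc, reason = v_reason,
    method = v_method, link = v_link, gamma1 = v_g, se = v_se, p = v_p,
    stringsAsFactors = FALSE)
  class(out) <- c("glfsr_run", class(out))
  out
}

#' Summarize a replication-level run into condition criteria
#'
#' Aggregates replication records into the five performance criteria per
#' (measurement condition, method, link) cell via [conditionCriteria()].
#' Trimming is applied independently per cell.
#'
#' @param run a `glfsr_run` data frame (or one read back from CSV).
#' @param true_gamma true first coefficient, default 1.
#' @param trim_fraction per-tail trim fraction, default 0.005.
#' @return Data frame, one row per cell: the condition columns, `method`,
#'   `link`, then `Ctot`, `C`, `nonconv`, `RB`, `RSEB`, `RMSE`, `alpha`,
#'   `usable`.
#' @export
summarizeRun <- function(run, true_gamma = 1, trim_fraction = 0.005) {
  need <- c("mu_lambda", "sigma_lambda", "phi12", "n", "rep", "method",
            "link", "gamma1", "se", "p")
  missing_cols <- setdiff(need, names(run))
  if (length(missing_cols))
    stop("replication table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  keys <- c("mu_lambda", "sigma_lambda", "phi12", "n", "method", "link")
  if (nrow(run) == 0L) {
    out <- run[, keys, drop = FALSE]
    out$Ctot <- integer(0); out$C <- integer(0)
    out$nonconv <- out$RB <- out$RSEB <- out$RMSE <- out$alpha <- numeric(0)
    out$usable <- logical(0)
    return(out)
  }
  idx <- split(seq_len(nrow(run)), run[keys], drop = TRUE, sep = "\r")
  res <- lapply(idx, function(ii) {
    sub <- run[ii, ]
    ok <- is.finite(sub$gamma1) & is.finite(sub$se) & is.finite(sub$p)
    crit <- conditionCriteria(sub$gamma1[ok], sub$se[ok], sub$p[ok],
                              Ctot = nrow(sub), true_gamma = true_gamma,
                              trim_fraction = trim_fraction)
    cbind(sub[1, keys, drop = FALSE], crit)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mu_lambda, out$sigma_lambda, out$phi12, out$n,
                   out$method, out$link), ]
  rownames(out) <- NULL
  out
}

#' Write / read run artifacts as CSV
#'
#' Long-format comma-separated text with a header row, UTF-8, "." decimal.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
writeRunCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRunCSV
#' @export
readRunCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' A small record of the configuration that produced a run, sufficient to
#' reproduce it bit-for-bit: the parameter lists, master seed, replication
#' count, a grid fingerprint and the package version.
#'
#' @param grid the `glfsr_grid` used.
#' @param master_seed the master seed used.
#' @return Named list of class `run_manifest`.
#' @export
runManifest <- function(grid, master_seed) {
  key <- paste(c(t(as.matrix(grid[, c("mu_lambda", "sigma_lambda", "phi12",
                                      "n", "method", "link")]))),
               collapse = "|")
  structure(list(
    n_conditions = nrow(grid),
    reps = attr(grid, "reps"),
    master_seed = master_seed,
    grid_hash = sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)),
    package_version = as.character(utils::packageVersion("glfsr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("GLFSR run manifest\n")
  for (nm in setdiff(names(x), "timestamp"))
    cat(" ", nm, ": ", as.character(x[[nm]]), "\n", sep = "")
  cat("  timestamp: ", x$timestamp, "\n", sep = "")
  invisible(x)
}
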