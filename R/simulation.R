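#' Simulation scenario configuration
#'
#' Describes one cell of the coverage study: panel size, true-effect
#' variance, average sampling variance (realized per factor as
#' `U[0.5*m, 1.5*m]`), correlation regime among the estimates, the shape of
#' the true-effect distribution, the number of Monte-Carlo replicates, the
#' interval level, and the seed.
#'
#' @param K Panel size (>= 2).
#' @param tau2 True-effect variance (>= 0); the study grid uses 1, 0.5, 0.25.
#' @param sigma2_mean Average sampling variance; the study grid uses 0.5,
#'   0.25, 0.125.
#' @param correlation One of `"independent"`, `"moderate"`, `"strong"`.
#' @param effect_dist One of `"normal"`, `"mixture"`.
#' @param reps Monte-Carlo replicates (>= 1).
#' @param level Interval level in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(K, tau2, sigma2_mean,
                            correlation = c("independent", "moderate", "strong"),
                            effect_dist = c("normal", "mixture"),
                            reps = 10000, level = 0.95, seed = 1L) {
  correlation <- match.arg(correlation)
  effect_dist <- match.arg(effect_dist)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  if (sigma2_mean <= 0) stop("sigma2_mean must be > 0", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  structure(list(K = as.integer(K), tau2 = tau2, sigma2_mean = sigma2_mean,
                 correlation = correlation, effect_dist = effect_dist,
                 reps = as.integer(reps), level = level,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# mixture component constants: beta(2, 5) and uniform(0, 1), each
# standardized to mean 0 / variance 1 before mixing 40/20/40 with N(0, 1)
.mix_beta_shape <- c(2, 5)
.mix_beta_mean <- 2 / 7
.mix_beta_sd <- sqrt(10 / (49 * 8))

#' Draw true log odds ratios
#'
#' Draws K true effects with mean 0 and variance `tau2`. The `"normal"`
#' distribution is N(0, tau2). The `"mixture"` distribution is deliberately
#' non-normal: 40% from a (right-skewed) beta(2, 5), 20% from a uniform and
#' 40% from a normal, each component standardized to mean 0 and variance 1,
#' then scaled by `sqrt(tau2)`.
#'
#' @param config A [scenario_config()] (only `K`, `tau2`, `effect_dist` are
#'   used). Uses the current RNG state; seed at the caller.
#' @return Numeric vector of length K.
#' @export
draw_true_effects <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  k <- config$K
  if (config$tau2 == 0) return(numeric(k))
  s <- sqrt(config$tau2)
  if (config$effect_dist == "normal") return(stats::rnorm(k, 0, s))
  comp <- sample.int(3L, k, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  x <- numeric(k)
  nb <- sum(comp == 1L)
  nu <- sum(comp == 2L)
  nn <- sum(comp == 3L)
  if (nb) x[comp == 1L] <-
      (stats::rbeta(nb, .mix_beta_shape[1], .mix_beta_shape[2]) - .mix_beta_mean) / .mix_beta_sd
  if (nu) x[comp == 2L] <- (stats::runif(nu) - 0.5) * sqrt(12)
  if (nn) x[comp == 3L] <- stats::rnorm(nn)
  s * x
}

#' Nearest correlation matrix
#'
#' Returns `m` unchanged (up to forcing exact symmetry and unit diagonal)
#' when it is already positive semidefinite, otherwise projects to the
#' nearest correlation matrix by Higham's alternating-projections method.
#'
#' @param m Square symmetric matrix with unit diagonal.
#' @param tol Convergence tolerance of the projection.
#' @return A positive semidefinite correlation matrix.
#' @export
nearest_correlation <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) return(m)
  out <- as.matrix(Matrix::nearPD(m, corr = TRUE, do2eigen = FALSE,
                                  conv.tol = tol, maxit = 200)$mat)
  out <- (out + t(out)) / 2
  # the alternating projections can stop a hair outside the PSD cone;
  # clamp the residual negative eigenvalues and restore the unit diagonal
  ev <- eigen(out, symmetric = TRUE)
  if (min(ev$values) < 0) {
    out <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    out <- stats::cov2cor(out)
    out <- (out + t(out)) / 2
  }
  out
}

#' Draw a correlation matrix for the estimate noise
#'
#' `"independent"` gives the identity. Under `"moderate"` a randomly chosen
#' third of the pairwise correlations are drawn from U[-0.4, 0] and the rest
#' from U[0, 0.4]; `"strong"` uses U[-0.8, 0] and U[0, 0.8]. The raw draw is
#' then repaired to the nearest positive semidefinite correlation matrix
#' (a no-op when the draw is already valid).
#'
#' @param K Dimension.
#' @param regime `"independent"`, `"moderate"` or `"strong"`.
#' @return K x K correlation matrix with eigenvalues >= -1e-10.
#' @export
draw_correlation_matrix <- function(K, regime = c("independent", "moderate", "strong")) {
  regime <- match.arg(regime)
  if (regime == "independent") return(diag(K))
  b <- if (regime == "moderate") 0.4 else 0.8
  npair <- K * (K - 1) / 2
  neg <- sample.int(npair, floor(npair / 3))
  r <- stats::runif(npair, 0, b)
  r[neg] <- -stats::runif(length(neg), 0, b)
  m <- diag(K)
  m[upper.tri(m)] <- r
  m <- m + t(m) - diag(K)
  nearest_correlation(m)
}

#' Simulate one panel of estimated log odds ratios
#'
#' Draws true effects, per-factor sampling variances
#' `sigma2_i ~ U[0.5*m, 1.5*m]`, a noise correlation matrix R for the chosen
#' regime, and then estimates `beta_hat = beta + e` with
#' `e ~ N(0, D R D)`, `D = diag(sigma_i)`. The returned panel carries the
#' true covariance `D R D` in its `cov` field.
#'
#' @param config A [scenario_config()]. Uses the current RNG state.
#' @param corr Optional fixed correlation matrix overriding the drawn one.
#' @param sigma2 Optional fixed vector of sampling variances.
#' @return List with `beta_true` and `panel` (an [effect_panel()]).
#' @export
simulate_panel <- function(config, corr = NULL, sigma2 = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  k <- config$K
  beta_true <- draw_true_effects(config)
  if (is.null(sigma2)) {
    m <- config$sigma2_mean
    sigma2 <- stats::runif(k, 0.5 * m, 1.5 * m)
  }
  se <- sqrt(sigma2)
  if (is.null(corr) && config$correlation == "independent") {
    noise <- stats::rnorm(k, 0, se)
    cov <- diag(sigma2, nrow = k)
  } else {
    if (is.null(corr)) corr <- draw_correlation_matrix(k, config$correlation)
    cov <- corr * outer(se, se)
    noise <- drop(rmvnorm_psd(1, cov))
  }
  list(beta_true = beta_true,
       panel = effect_panel(beta_true + noise, se, cov = cov))
}

#' Run one coverage scenario
#'
#' For each replicate: simulate a panel, estimate the prior (or use the true
#' hyperparameters when `oracle = TRUE`), build prediction and confidence
#' intervals, and record whether each true effect lies inside its interval,
#' both overall and within the significant (zero-excluding) subsets.
#' Replicates whose moment estimate of `tau2` truncates to zero are retained:
#' their zero-width PIs at the prior mean count as non-covering unless the
#' true value equals the prior mean exactly; the count is reported.
#'
#' @param config A [scenario_config()]; `config$seed` seeds the whole run.
#' @param oracle Use the true `mu = 0` and `tau2` instead of estimating them?
#' @return An object of class `coverage_result`: coverage of PIs and CIs
#'   (overall and significant-subset), average interval lengths, average
#'   efficiency gain, Monte-Carlo standard errors, significant counts and
#'   the number of `tau2 = 0` replicates.
#' @export
run_scenario <- function(config, oracle = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  reps <- config$reps
  k <- config$K
  cov_pi <- cov_ci <- len_pi <- len_ci <- gain <- numeric(reps)
  sig_pi_n <- sig_pi_cov <- sig_ci_n <- sig_ci_cov <- numeric(reps)
  zero_tau2 <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_panel(config)
    prior <- if (oracle) {
      prior_estimate(0, config$tau2, k)
    } else {
      estimate_prior(sim$panel, warn_small = FALSE)
    }
    post <- compute_posterior(sim$panel, prior)
    pi <- prediction_intervals(post, config$level)
    ci <- confidence_intervals(sim$panel, config$level)
    in_pi <- sim$beta_true >= pi$lower & sim$beta_true <= pi$upper
    in_ci <- sim$beta_true >= ci$lower & sim$beta_true <= ci$upper
    cov_pi[r] <- mean(in_pi)
    cov_ci[r] <- mean(in_ci)
    len_pi[r] <- mean(pi$upper - pi$lower)
    len_ci[r] <- mean(ci$upper - ci$lower)
    gain[r] <- if (prior$tau2_hat > 0) mean(sim$panel$se^2 / prior$tau2_hat) else NA_real_
    if (prior$tau2_hat == 0) zero_tau2 <- zero_tau2 + 1L
    sig_pi_n[r] <- sum(pi$significant)
    sig_pi_cov[r] <- sum(in_pi[pi$significant])
    sig_ci_n[r] <- sum(ci$significant)
    sig_ci_cov[r] <- sum(in_ci[ci$significant])
  }
  pooled <- function(covered, n) {
    N <- sum(n)
    if (N == 0) return(c(p = NA_real_, se = NA_real_))
    p <- sum(covered) / N
    # cluster (per-replicate) ratio-estimator standard error
    se <- sqrt(sum((covered - p * n)^2)) / N
    c(p = p, se = se)
  }
  ps <- pooled(sig_pi_cov, sig_pi_n)
  cs <- pooled(sig_ci_cov, sig_ci_n)
  structure(list(
    config = config, oracle = oracle,
    coverage_pi = mean(cov_pi),
    coverage_ci = mean(cov_ci),
    coverage_pi_sig = unname(ps["p"]),
    coverage_ci_sig = unname(cs["p"]),
    avg_len_pi = mean(len_pi),
    avg_len_ci = mean(len_ci),
    avg_gain = if (all(is.na(gain))) NA_real_ else mean(gain, na.rm = TRUE),
    mc_se_pi = stats::sd(cov_pi) / sqrt(reps),
    mc_se_ci = stats::sd(cov_ci) / sqrt(reps),
    mc_se_pi_sig = unname(ps["se"]),
    mc_se_ci_sig = unname(cs["se"]),
    n_sig_pi = sum(sig_pi_n), n_sig_ci = sum(sig_ci_n),
    n_zero_tau2 = zero_tau2),
    class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<coverage_result> K=%d tau2=%g sigma2_mean=%g %s/%s reps=%d%s\n",
    cfg$K, cfg$tau2, cfg$sigma2_mean, cfg$correlation, cfg$effect_dist,
    cfg$reps, if (x$oracle) " [oracle]" else ""))
  cat(sprintf("  PI coverage %.4f (mc se %.4f); CI coverage %.4f\n",
              x$coverage_pi, x$mc_se_pi, x$coverage_ci))
  cat(sprintf("  significant-subset coverage: PI %.4f (n=%d), CI %.4f (n=%d)\n",
              x$coverage_pi_sig, x$n_sig_pi, x$coverage_ci_sig, x$n_sig_ci))
  cat(sprintf("  avg lengths: PI %.4f, CI %.4f; avg gain %.3f; tau2=0 reps: %d\n",
              x$avg_len_pi, x$avg_len_ci, x$avg_gain, x$n_zero_tau2))
  invisible(x)
}

coverage_result_row <- function(res) {
  cfg <- res$config
  data.frame(tau2 = cfg$tau2, sigma2_mean = cfg$sigma2_mean,
             correlation = cfg$correlation, effect_dist = cfg$effect_dist,
             K = cfg$K,
             coverage_pi = res$coverage_pi,
             coverage_pi_sig = res$coverage_pi_sig,
             coverage_ci_sig = res$coverage_ci_sig,
             avg_len_pi = res$avg_len_pi, avg_len_ci = res$avg_len_ci,
             gain = res$avg_gain, mc_se = res$mc_se_pi,
             stringsAsFactors = FALSE)
}

#' Run the full coverage grid
#'
#' Sweeps the 3 x 3 grid of true-effect variance `tau2` in {1, 0.5, 0.25}
#' and average sampling variance `sigma2_mean` in {0.5, 0.25, 0.125},
#' crossed with correlation regimes and panel sizes, holding the remaining
#' settings of `base_config` fixed. Scenario seeds are derived
#' deterministically from `base_config$seed`, so the grid is reproducible.
#'
#' @param base_config A [scenario_config()] supplying `effect_dist`, `reps`,
#'   `level` and the base `seed`.
#' @param K_values Panel sizes to sweep.
#' @param correlations Correlation regimes to sweep.
#' @param tau2_values,sigma2_means Grid axes.
#' @return Long-format data frame, one row per scenario, with columns
#'   `tau2, sigma2_mean, correlation, effect_dist, K, coverage_pi,
#'   coverage_pi_sig, coverage_ci_sig, avg_len_pi, avg_len_ci, gain, mc_se`.
#' @export
scenario_grid <- function(base_config,
                          K_values = c(10, 20, 50, 100),
                          correlations = c("independent", "moderate", "strong"),
                          tau2_values = c(1, 0.5, 0.25),
                          sigma2_means = c(0.5, 0.25, 0.125)) {
  stopifnot(inherits(base_config, "scenario_config"))
  cells <- expand.grid(K = K_values, correlation = correlations,
                       sigma2_mean = sigma2_means, tau2 = tau2_values,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- scenario_config(K = cells$K[i], tau2 = cells$tau2[i],
                           sigma2_mean = cells$sigma2_mean[i],
                           correlation = cells$correlation[i],
                           effect_dist = base_config$effect_dist,
                           reps = base_config$reps, level = base_config$level,
                           seed = (base_config$seed + 97L * i) %% .Machine$integer.max)
    rows[[i]] <- coverage_result_row(run_scenario(cfg))
  }
  do.call(rbind, rows)
}

#' Panel plot of a coverage grid
#'
#' Base-graphics rendering of a [scenario_grid()] result: a matrix of panels
#' (rows: `tau2` descending; columns: `sigma2_mean` descending) showing
#' average PI coverage against panel size K, one line per correlation
#' regime, with the nominal level as a horizontal reference.
#'
#' @param grid Data frame from [scenario_grid()].
#' @param level Nominal level to mark.
#' @return Invisibly, `grid`.
#' @export
plot_coverage_grid <- function(grid, level = 0.95) {
  tau2s <- sort(unique(grid$tau2), decreasing = TRUE)
  s2s <- sort(unique(grid$sigma2_mean), decreasing = TRUE)
  regimes <- unique(grid$correlation)
  op <- graphics::par(mfrow = c(length(tau2s), length(s2s)),
                      mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  for (t2 in tau2s) for (s2 in s2s) {
    sub <- grid[grid$tau2 == t2 & grid$sigma2_mean == s2, ]
    graphics::plot(range(sub$K), range(c(sub$coverage_pi, level)),
                   type = "n", xlab = "K", ylab = "PI coverage",
                   main = sprintf("tau2=%g, sigma2=%g", t2, s2))
    graphics::abline(h = level, col = "grey60", lty = 2)
    for (j in seq_along(regimes)) {
      s <- sub[sub$correlation == regimes[j], ]
      s <- s[order(s$K), ]
      graphics::lines(s$K, s$coverage_pi, lty = j, col = j)
      graphics::points(s$K, s$coverage_pi, col = j, pch = 16, cex = 0.6)
    }
  }
  invisible(grid)
}
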