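#' Construct a prior estimate by hand
#'
#' Mostly used internally by [estimate_prior()]; exported so that oracle
#' analyses (true hyperparameters supplied, estimation bypassed) can be run,
#' e.g. in coverage simulations.
#'
#' @param mu_hat Prior mean on the log odds ratio scale.
#' @param tau2_hat Prior variance (>= 0; `Inf` allowed as the no-shrinkage
#'   limit).
#' @param k Panel size the prior refers to.
#' @param truncated Was a negative raw moment estimate truncated to zero?
#' @return An object of class `prior_estimate`.
#' @export
prior_estimate <- function(mu_hat, tau2_hat, k, truncated = FALSE) {
  if (!is.finite(mu_hat)) stop("mu_hat must be finite", call. = FALSE)
  if (is.na(tau2_hat) || tau2_hat < 0) stop("tau2_hat must be >= 0", call. = FALSE)
  structure(list(mu_hat = mu_hat, tau2_hat = tau2_hat, k = as.integer(k),
                 truncated = isTRUE(truncated)),
            class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("<prior_estimate> mu_hat = %.6g, tau2_hat = %.6g, K = %d%s\n",
              x$mu_hat, x$tau2_hat, x$k,
              if (x$truncated) " (truncated at 0)" else ""))
  invisible(x)
}

#' Estimate the prior mean and variance from a panel
#'
#' Under exchangeability the true log odds ratios are modelled as draws from
#' a common prior with mean `mu` and variance `tau2`. The prior mean is
#' estimated as the unweighted average of the individual MLEs. The prior
#' variance is estimated by the method of moments:
#' \deqn{\hat\tau^2 = \max\left(0,\; S^2 - \frac{1}{K}\sum_i \hat\sigma_i^2
#'   + \frac{2}{K(K-1)}\sum_{i<j} \hat\sigma_{ij}\right)}
#' where \eqn{S^2} is the sample variance of the estimates. The covariance
#' term corrects for correlated estimates (linkage disequilibrium); with an
#' absent covariance matrix independence is assumed and the term vanishes.
#'
#' @param panel An [effect_panel()] with K >= 2.
#' @param warn_small Warn when K is below [minimum_panel_size()] for the
#'   estimated variance ratio?
#' @return A [prior_estimate()].
#' @examples
#' p <- effect_panel(beta = c(0, 1, 2), se = sqrt(rep(0.5, 3)))
#' estimate_prior(p) # mu_hat = 1, tau2_hat = 0.5
#' @export
estimate_prior <- function(panel, warn_small = TRUE) {
  stopifnot(inherits(panel, "effect_panel"))
  k <- length(panel$beta)
  if (k < 2L) stop("prior estimation needs a panel of at least 2 factors",
                   call. = FALSE)
  mu_hat <- mean(panel$beta)
  s2 <- stats::var(panel$beta)
  mean_sig2 <- mean(panel$se^2)
  off_mean <- if (is.null(panel$cov)) 0 else {
    (sum(panel$cov) - sum(diag(panel$cov))) / (k * (k - 1))
  }
  raw <- s2 - mean_sig2 + off_mean
  tau2_hat <- max(0, raw)
  if (warn_small) {
    if (tau2_hat == 0) {
      warning("tau2_hat = 0: panel shows no excess variance; posterior ",
              "intervals degenerate to the prior mean", call. = FALSE)
    } else {
      k_req <- minimum_panel_size(mean_sig2 / tau2_hat)
      if (k < k_req) {
        warning("panel size K = ", k, " is below the recommended minimum of ",
                k_req, " for sigma2/tau2 ratio ",
                signif(mean_sig2 / tau2_hat, 3),
                "; prediction intervals may undercover", call. = FALSE)
      }
    }
  }
  prior_estimate(mu_hat, tau2_hat, k, truncated = raw < 0)
}

#' Posterior means and variances for a panel
#'
#' Combines each estimate with the estimated prior: the posterior variance is
#' the harmonic-mean combination of prior and sampling variance,
#' \eqn{V^*_i = (1/\hat\tau^2 + 1/\hat\sigma_i^2)^{-1}}, and the posterior
#' mean is the precision-weighted average
#' \eqn{E^*_i = V^*_i(\hat\mu/\hat\tau^2 + \hat\beta_i/\hat\sigma_i^2)},
#' which shrinks each MLE toward the overall mean. Limits: `tau2_hat = 0`
#' gives complete shrinkage (`E* = mu_hat`, `V* = 0`); `tau2_hat = Inf`
#' reproduces the MLEs and their variances.
#'
#' @param panel An [effect_panel()].
#' @param prior A [prior_estimate()], normally from [estimate_prior()] on the
#'   same panel.
#' @return An object of class `posterior_panel` with `post_mean`, `post_var`,
#'   the `prior`, and the parent `panel`.
#' @export
compute_posterior <- function(panel, prior) {
  stopifnot(inherits(panel, "effect_panel"), inherits(prior, "prior_estimate"))
  sig2 <- panel$se^2
  tau2 <- prior$tau2_hat
  if (tau2 == 0) {
    post_var <- rep(0, length(sig2))
    post_mean <- rep(prior$mu_hat, length(sig2))
  } else if (is.infinite(tau2)) {
    post_var <- sig2
    post_mean <- unname(panel$beta)
  } else {
    post_var <- 1 / (1 / tau2 + 1 / sig2)
    post_mean <- post_var * (prior$mu_hat / tau2 + panel$beta / sig2)
  }
  structure(list(post_mean = stats::setNames(unname(post_mean), panel$labels),
                 post_var = stats::setNames(unname(post_var), panel$labels),
                 prior = prior, panel = panel),
            class = "posterior_panel")
}

#' @export
print.posterior_panel <- function(x, ...) {
  cat("<posterior_panel> K =", length(x$post_mean), "\n")
  print(x$prior)
  invisible(x)
}

new_interval_set <- function(labels, lower, upper, level, kind) {
  out <- data.frame(label = labels, lower = unname(lower), upper = unname(upper),
                    stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  structure(out, level = level, kind = kind,
            class = c("interval_set", "data.frame"))
}

#' Empirical-Bayes prediction intervals
#'
#' The level-`level` prediction interval for factor i is
#' \eqn{E^*_i \pm z_{(1+level)/2}\sqrt{V^*_i}}. For a sufficiently large
#' exchangeable panel it carries a direct probabilistic interpretation: the
#' true log odds ratio lies inside with probability `level`.
#'
#' @param posterior A [compute_posterior()] result.
#' @param level Interval level in (0, 1); default 0.95.
#' @return An `interval_set` data frame (`label`, `lower`, `upper`,
#'   `significant`) with attributes `level` and `kind = "PI"`. A factor is
#'   flagged significant when its interval excludes zero.
#' @export
prediction_intervals <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "posterior_panel"))
  z <- z_quantile(level)
  half <- z * sqrt(posterior$post_var)
  new_interval_set(posterior$panel$labels,
                   posterior$post_mean - half, posterior$post_mean + half,
                   level, "PI")
}

#' Wald confidence intervals
#'
#' The usual asymptotic interval \eqn{\hat\beta_i \pm z_{(1+level)/2}
#' \hat\sigma_i} for each factor.
#'
#' @param panel An [effect_panel()].
#' @param level Interval level in (0, 1); default 0.95.
#' @return An `interval_set` with `kind = "CI"`.
#' @export
confidence_intervals <- function(panel, level = 0.95) {
  stopifnot(inherits(panel, "effect_panel"))
  z <- z_quantile(level)
  half <- z * panel$se
  new_interval_set(panel$labels, panel$beta - half, panel$beta + half,
                   level, "CI")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d %s%% %ss (%d significant)\n",
              nrow(x), format(100 * attr(x, "level")), attr(x, "kind"),
              sum(x$significant)))
  NextMethod()
}

#' Efficiency gain of prediction over confidence intervals
#'
#' The relative variance reduction for factor i is
#' \eqn{gain_i = \hat\sigma_i^2 / \hat\tau^2}; equivalently
#' \eqn{\hat\sigma_i^2 / V^*_i = 1 + gain_i}, so the squared CI/PI length
#' ratio is `1 + gain`. Large gains arise when sampling noise dominates the
#' between-factor spread.
#'
#' @param panel An [effect_panel()].
#' @param prior A [prior_estimate()]; `tau2_hat = 0` yields infinite gains
#'   with a warning.
#' @return List with `per_factor` (ratio scale), `percent` (per factor),
#'   `average` and `average_percent`.
#' @export
efficiency_gain <- function(panel, prior) {
  stopifnot(inherits(panel, "effect_panel"), inherits(prior, "prior_estimate"))
  if (prior$tau2_hat == 0) {
    warning("tau2_hat = 0: efficiency gain is undefined (infinite)",
            call. = FALSE)
    g <- rep(Inf, length(panel$se))
  } else {
    g <- panel$se^2 / prior$tau2_hat
  }
  g <- stats::setNames(unname(g), panel$labels)
  list(per_factor = g, percent = 100 * g,
       average = mean(g), average_percent = 100 * mean(g))
}

#' Expected number of true values covered by a set of prediction intervals
#'
#' For n prediction intervals at a given level, the expected number of true
#' log odds ratios falling inside their intervals is `level * n`. Restricted
#' to significant intervals (which exclude zero, hence exclude any true
#' negative), this is the expected number of true positives.
#'
#' @param intervals An `interval_set` of kind `"PI"`.
#' @param subset Optional logical or integer subset of rows (e.g.
#'   `intervals$significant`); default all.
#' @return Expected count (numeric scalar).
#' @examples
#' # 10 significant 95% PIs -> 9.5 expected true positives
#' @export
expected_coverage_count <- function(intervals, subset = NULL) {
  stopifnot(inherits(intervals, "interval_set"))
  if (!identical(attr(intervals, "kind"), "PI")) {
    stop("expected coverage counts apply to prediction intervals only",
         call. = FALSE)
  }
  n <- if (is.null(subset)) nrow(intervals) else nrow(intervals[subset, , drop = FALSE])
  attr(intervals, "level") * n
}

#' Minimum panel size for nominal prediction-interval coverage
#'
#' The number of exchangeable factors required before the prediction
#' intervals attain their nominal coverage grows with the noise-to-signal
#' ratio `mean(sigma^2) / tau2`: about 20 factors suffice when the ratio is
#' at most 0.125, 30 up to 0.25, 50 up to 0.5, and 100 or more beyond that.
#'
#' @param ratio Positive ratio of average sampling variance to prior
#'   variance; vectorized.
#' @return Required panel size(s): 20, 30, 50 or 100.
#' @export
minimum_panel_size <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  out <- rep(100L, length(ratio))
  out[ratio <= 0.5] <- 50L
  out[ratio <= 0.25] <- 30L
  out[ratio <= 0.125] <- 20L
  out
}

#' Full empirical-Bayes analysis of a panel
#'
#' Convenience wrapper chaining [estimate_prior()], [compute_posterior()],
#' [prediction_intervals()], [confidence_intervals()] and
#' [efficiency_gain()], and assembling the per-factor results table.
#'
#' @param panel An [effect_panel()].
#' @param level Interval level; default 0.95.
#' @param warn_small Passed to [estimate_prior()].
#' @return List of class `eb_analysis`: `panel`, `prior`, `posterior`, `ci`,
#'   `pi`, `gain`, and `table` (one row per factor: `id, beta, se, ci_low,
#'   ci_high, post_mean, post_var, pi_low, pi_high, gain, significant`).
#' @export
eb_analysis <- function(panel, level = 0.95, warn_small = TRUE) {
  prior <- estimate_prior(panel, warn_small = warn_small)
  posterior <- compute_posterior(panel, prior)
  ci <- confidence_intervals(panel, level)
  pi <- prediction_intervals(posterior, level)
  gain <- if (prior$tau2_hat > 0) efficiency_gain(panel, prior) else {
    list(per_factor = rep(Inf, length(panel$beta)),
         percent = rep(Inf, length(panel$beta)),
         average = Inf, average_percent = Inf)
  }
  tab <- data.frame(id = panel$labels,
                    beta = unname(panel$beta), se = unname(panel$se),
                    ci_low = ci$lower, ci_high = ci$upper,
                    post_mean = unname(posterior$post_mean),
                    post_var = unname(posterior$post_var),
                    pi_low = pi$lower, pi_high = pi$upper,
                    gain = unname(gain$per_factor),
                    significant = pi$significant,
                    stringsAsFactors = FALSE)
  structure(list(panel = panel, prior = prior, posterior = posterior,
                 ci = ci, pi = pi, gain = gain, table = tab, level = level),
            class = "eb_analysis")
}

#' @export
print.eb_analysis <- function(x, ...) {
  cat("Empirical-Bayes panel analysis\n")
  print(x$prior)
  cat(sprintf("  level %.2f: %d of %d PIs significant; avg CI length %.4g, ",
              x$level, sum(x$pi$significant), nrow(x$table),
              mean(x$ci$upper - x$ci$lower)))
  cat(sprintf("avg PI length %.4g\n", mean(x$pi$upper - x$pi$lower)))
  if (is.finite(x$gain$average_percent)) {
    cat(sprintf("  average efficiency gain %.1f%%\n", x$gain$average_percent))
  }
  invisible(x)
}
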