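#' A panel of estimated log odds ratios
#'
#' Holds per-factor maximum-likelihood estimates on the log odds ratio scale,
#' their standard errors, and optionally the full covariance matrix of the
#' estimates (diagonal `se^2`, off-diagonal the estimate covariances, e.g.
#' from [approx_covariance()]).
#'
#' @param beta Numeric vector of log odds ratio estimates.
#' @param se Numeric vector of standard errors, strictly positive.
#' @param cov Optional K x K covariance matrix; must be symmetric with
#'   diagonal equal to `se^2` (tolerance 1e-10, relative).
#' @param labels Optional factor labels (default `F1`, `F2`, ...).
#' @return An object of class `effect_panel`.
#' @export
effect_panel <- function(beta, se, cov = NULL, labels = NULL) {
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  if (length(beta) != length(se)) stop("beta and se lengths differ", call. = FALSE)
  if (any(!is.finite(beta)) || any(!is.finite(se))) {
    stop("beta and se must be finite", call. = FALSE)
  }
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  k <- length(beta)
  if (is.null(labels)) labels <- paste0("F", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k) stop("labels length must equal panel size", call. = FALSE)
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (nrow(cov) != k || ncol(cov) != k) {
      stop("cov must be a ", k, " x ", k, " matrix", call. = FALSE)
    }
    scale <- max(se^2)
    if (max(abs(cov - t(cov))) > 1e-10 * scale) {
      stop("cov must be symmetric", call. = FALSE)
    }
    if (max(abs(diag(cov) - se^2)) > 1e-10 * max(1, scale)) {
      stop("diag(cov) must equal se^2", call. = FALSE)
    }
    dimnames(cov) <- list(labels, labels)
  }
  structure(list(beta = stats::setNames(beta, labels),
                 se = stats::setNames(se, labels),
                 cov = cov, labels = labels),
            class = "effect_panel")
}

#' @export
print.effect_panel <- function(x, ...) {
  cat("<effect_panel> K =", length(x$beta),
      if (is.null(x$cov)) "(independent)" else "(with covariance)", "\n")
  df <- data.frame(label = x$labels, beta = unname(x$beta), se = unname(x$se))
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x$beta) > 10) cat("  ... and", length(x$beta) - 10, "more\n")
  invisible(x)
}

#' @export
length.effect_panel <- function(x) length(x$beta)
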