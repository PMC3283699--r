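#' A 2x2 exposure-disease table
#'
#' Container for the classic case-control fourfold table: `a` exposed cases,
#' `b` exposed controls, `c` unexposed cases, `d` unexposed controls.
#'
#' @param a,b,c,d Non-negative counts.
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(20, 10, 10, 20)
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all four counts must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(counts), class = "two_by_two")
}

#' Crude log odds ratio and its standard error
#'
#' Computes the Woolf estimate `log(a*d / (b*c))` with asymptotic standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)` from a 2x2 table.
#'
#' Zero cells make the estimate undefined; by default this is an error naming
#' the offending cell(s). With `haldane = TRUE` the Haldane-Anscombe
#' continuity correction (add 0.5 to every cell) is applied whenever any cell
#' is zero.
#'
#' @param table A [two_by_two()] object, or a numeric vector of length 4
#'   giving `a, b, c, d`.
#' @param haldane Apply the +0.5 continuity correction when a cell is zero?
#' @return A list with elements `beta` (log odds ratio) and `se`.
#' @examples
#' crude_logor(two_by_two(20, 10, 10, 20)) # beta = log(4)
#' @export
crude_logor <- function(table, haldane = FALSE) {
  if (inherits(table, "two_by_two")) {
    x <- unlist(table)
  } else if (is.numeric(table) && length(table) == 4L) {
    x <- unlist(two_by_two(table[1], table[2], table[3], table[4]))
  } else {
    stop("`table` must be a two_by_two object or a numeric vector of length 4",
         call. = FALSE)
  }
  if (any(x == 0)) {
    if (!haldane) {
      stop("zero cell(s) in 2x2 table: ",
           paste(names(x)[x == 0], collapse = ", "),
           " (use haldane = TRUE for the +0.5 correction)", call. = FALSE)
    }
    x <- x + 0.5
  }
  list(beta = log(x[["a"]] * x[["d"]] / (x[["b"]] * x[["c"]])),
       se = sqrt(sum(1 / x)))
}

#' A genotype/phenotype panel
#'
#' Allele-count genotypes (0, 1 or 2 copies of the coded allele; `NA`
#' allowed) for a set of individuals at a set of variants, together with a
#' binary case/control phenotype. Allele orientation is taken as given: counts
#' refer to whichever allele the input coded, with no minor-allele flipping.
#'
#' @param genotypes Numeric matrix, individuals x variants, entries in
#'   `{0, 1, 2, NA}`.
#' @param phenotype Vector of 0 (control) / 1 (case), one per individual.
#' @param labels Optional variant labels (default: column names, else V1...).
#' @return An object of class `genotype_panel` with elements `geno`, `pheno`,
#'   `labels`.
#' @export
genotype_panel <- function(genotypes, phenotype, labels = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotypes must be allele counts in {0, 1, 2} or NA; found ",
         paste(unique(genotypes[bad]), collapse = ", "), call. = FALSE)
  }
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length must equal the number of individuals", call. = FALSE)
  }
  if (any(is.na(phenotype)) || !all(phenotype %in% c(0, 1))) {
    stop("phenotype must be 0 (control) or 1 (case), no missing values",
         call. = FALSE)
  }
  if (sum(phenotype == 1) < 1 || sum(phenotype == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- colnames(genotypes) %||% paste0("V", seq_len(ncol(genotypes)))
  }
  if (length(labels) != ncol(genotypes)) {
    stop("labels length must equal the number of variants", call. = FALSE)
  }
  colnames(genotypes) <- labels
  structure(list(geno = genotypes, pheno = phenotype,
                 labels = as.character(labels)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$geno), " individuals (",
      sum(x$pheno == 1), " cases / ", sum(x$pheno == 0), " controls), ",
      ncol(x$geno), " variants\n", sep = "")
  invisible(x)
}

#' Single-variant logistic regression
#'
#' Fits `phenotype ~ allele count` by logistic regression (IRLS, relative
#' deviance tolerance 1e-10, at most 100 iterations) for one variant,
#' dropping individuals with a missing genotype at that variant. Quasi- or
#' complete separation is flagged via `|beta| > 15`.
#'
#' @param panel A [genotype_panel()].
#' @param variant Column index or label of the variant to fit.
#' @return List with `beta`, `se`, `converged`, `separated`, `n` (individuals
#'   used).
#' @export
fit_variant_logor <- function(panel, variant) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno[, variant]
  keep <- !is.na(g)
  g <- g[keep]
  y <- panel$pheno[keep]
  if (length(unique(g)) < 2L) {
    stop("variant ", if (is.character(variant)) variant else panel$labels[variant],
         " is constant among observed genotypes: no information", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ g, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- unname(stats::coef(fit)["g"])
  se <- sqrt(stats::vcov(fit)["g", "g"])
  list(beta = beta, se = se,
       converged = fit$converged,
       separated = is.na(beta) || abs(beta) > 15,
       n = length(y))
}

#' Fit every variant in a panel
#'
#' Runs [fit_variant_logor()] across all variants and assembles an
#' [effect_panel()]. Variants whose fit did not converge or showed separation
#' are excluded with a warning.
#'
#' @param panel A [genotype_panel()].
#' @return An [effect_panel()]; excluded variants are recorded in the
#'   `"excluded"` attribute (character vector of labels).
#' @export
fit_panel_logor <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  fits <- lapply(seq_along(panel$labels), function(j) fit_variant_logor(panel, j))
  ok <- vapply(fits, function(f) f$converged && !f$separated, logical(1))
  if (!any(ok)) stop("no variant produced a usable logistic fit", call. = FALSE)
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " variant(s) with non-converged or ",
            "separated fits: ", paste(panel$labels[!ok], collapse = ", "),
            call. = FALSE)
  }
  out <- effect_panel(beta = vapply(fits[ok], `[[`, numeric(1), "beta"),
                      se = vapply(fits[ok], `[[`, numeric(1), "se"),
                      labels = panel$labels[ok])
  attr(out, "excluded") <- panel$labels[!ok]
  out
}

#' Pairwise Pearson correlation of allele counts
#'
#' Linkage disequilibrium between variant pairs measured as the Pearson
#' correlation of allele counts, computed pairwise over individuals with both
#' genotypes observed. Pairs with fewer than 3 complete observations or with
#' zero variance get correlation 0 (with a warning).
#'
#' @param panel A [genotype_panel()] with at least two variants.
#' @return Symmetric correlation matrix with unit diagonal, labelled by
#'   variant.
#' @export
pairwise_pearson <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  if (ncol(g) < 2L) stop("need at least two variants", call. = FALSE)
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  obs <- !is.na(g)
  npair <- crossprod(obs)
  bad <- is.na(r) | npair < 3
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad[upper.tri(bad)]),
            " variant pair(s) with <3 complete observations or zero variance; ",
            "correlation set to 0", call. = FALSE)
    r[bad] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(panel$labels, panel$labels)
  r
}

#' Approximate covariance of crude log odds ratio estimates
#'
#' For crude (univariate) estimates the covariance between two log odds ratio
#' estimators is approximated as `cov_ij = r_ij * se_i * se_j`, with `r_ij`
#' the Pearson correlation (linkage disequilibrium) between the two factors.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param se Vector of positive standard errors, same dimension as `corr`.
#' @return Covariance matrix with diagonal `se^2`.
#' @export
approx_covariance <- function(corr, se) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || length(se) != nrow(corr)) {
    stop("dimension mismatch between correlation matrix and se vector",
         call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8) {
    stop("`corr` must be symmetric with unit diagonal", call. = FALSE)
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be strictly positive", call. = FALSE)
  }
  corr * outer(se, se)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions from genotype counts,
#' by enumeration of all heterozygote counts compatible with the observed
#' allele counts: the p-value is the sum of the conditional probabilities of
#' all configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25) # ~1: perfect HW proportions
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8) || sum(counts) == 0) {
    stop("genotype counts must be non-negative integers with a positive total",
         call. = FALSE)
  }
  counts <- round(counts)
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]
  # heterozygote counts share the parity of the minor-allele count
  h <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma(n - (nA + h) / 2 + 1) + h * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(counts[2], h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Filter variants on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains variants whose minor allele frequency among controls is at least
#' `maf_min` and whose Hardy-Weinberg exact p-value among controls is at
#' least `hwe_p_min`. Both criteria use controls only, complete cases per
#' variant. Per-variant exclusion reasons are recorded in the `"exclusions"`
#' attribute.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum control minor allele frequency, in `[0, 0.5)`.
#' @param hwe_p_min Minimum Hardy-Weinberg exact p-value, in `[0, 1]`.
#' @return A filtered [genotype_panel()]; errors if nothing survives.
#' @export
filter_variants <- function(panel, maf_min = 0.01, hwe_p_min = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)", call. = FALSE)
  if (hwe_p_min < 0 || hwe_p_min > 1) stop("hwe_p_min must be in [0, 1]", call. = FALSE)
  ctrl <- panel$geno[panel$pheno == 0, , drop = FALSE]
  stats_v <- vapply(seq_len(ncol(ctrl)), function(j) {
    g <- ctrl[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(c(maf = 0, hwe_p = 1))
    p <- mean(g) / 2
    hwe <- hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
    c(maf = min(p, 1 - p), hwe_p = hwe)
  }, c(maf = 0, hwe_p = 0))
  maf <- stats_v["maf", ]
  hwe_p <- stats_v["hwe_p", ]
  keep <- maf >= maf_min & hwe_p >= hwe_p_min
  reason <- rep("", length(keep))
  reason[maf < maf_min] <- "maf"
  reason[maf >= maf_min & hwe_p < hwe_p_min] <- "hwe"
  exclusions <- data.frame(label = panel$labels, maf = maf, hwe_p = hwe_p,
                           retained = keep, reason = reason,
                           stringsAsFactors = FALSE)
  if (!any(keep)) stop("no variants survive the MAF/HWE filters", call. = FALSE)
  out <- genotype_panel(panel$geno[, keep, drop = FALSE], panel$pheno,
                        labels = panel$labels[keep])
  attr(out, "exclusions") <- exclusions
  out
}
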