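test_that("crude_logor reproduces the closed form and its symmetries", {
  est <- crude_logor(two_by_two(10, 10, 10, 10))
  expect_equal(est$beta, 0)
  expect_equal(est$se, sqrt(0.4))

  est <- crude_logor(two_by_two(20, 10, 10, 20))
  expect_equal(est$beta, log(4))
  expect_equal(est$se, sqrt(0.3))

  # exposure-relabel antisymmetry and se permutation invariance
  set.seed(41)
  for (i in 1:25) {
    x <- sample(1:40, 4, replace = TRUE)
    e1 <- crude_logor(two_by_two(x[1], x[2], x[3], x[4]))
    e2 <- crude_logor(two_by_two(x[2], x[1], x[4], x[3]))
    expect_equal(e1$beta, -e2$beta)
    xp <- sample(x)
    expect_equal(crude_logor(two_by_two(xp[1], xp[2], xp[3], xp[4]))$se, e1$se)
  }
})

test_that("zero cells error by default and obey the Haldane correction", {
  expect_error(crude_logor(two_by_two(0, 10, 10, 10)), "zero cell.*a")
  expect_error(crude_logor(two_by_two(5, 0, 10, 0)), "b, d")
  est <- crude_logor(two_by_two(0, 10, 10, 10), haldane = TRUE)
  expect_equal(est$beta, log(0.5 * 10.5 / (10.5 * 10.5)))
  expect_equal(est$se, sqrt(1 / 0.5 + 2 / 10.5 + 1 / 10.5))
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
})

test_that("single-variant logistic fit matches the 2x2 closed form", {
  gp <- gp_from_table(20, 10, 10, 20)
  fit <- fit_variant_logor(gp, 1)
  ref <- crude_logor(two_by_two(20, 10, 10, 20))
  expect_equal(fit$beta, ref$beta, tolerance = 1e-6)
  expect_equal(fit$se, ref$se, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separated)
})

test_that("logistic fit handles nulls, constants and separation", {
  # constant genotype column carries no information
  gp <- genotype_panel(matrix(c(rep(1, 6)), ncol = 1), c(1, 1, 1, 0, 0, 0))
  expect_error(fit_variant_logor(gp, 1), "constant")

  # null simulation: slope consistent with zero
  set.seed(7)
  n <- 10000
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  y <- rbinom(n, 1, 0.4)
  fit <- fit_variant_logor(genotype_panel(g, y), 1)
  expect_lt(abs(fit$beta), 3 * fit$se)

  # perfectly separated variant is flagged and excluded by the panel fitter
  g2 <- cbind(ok = rbinom(40, 2, 0.4), sep = c(rep(2, 20), rep(0, 20)))
  y2 <- c(rep(1, 20), rep(0, 20))
  gp2 <- genotype_panel(g2, y2)
  expect_true(fit_variant_logor(gp2, "sep")$separated)
  expect_warning(panel <- fit_panel_logor(gp2), "separated")
  expect_identical(panel$labels, "ok")
  expect_identical(attr(panel, "excluded"), "sep")
})

test_that("missing genotypes are dropped per variant", {
  g <- matrix(c(1, 1, 0, 0, NA, 1, 0, 1, 0, 0), ncol = 1)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  fit <- fit_variant_logor(genotype_panel(g, y), 1)
  expect_equal(fit$n, 9)
  ref <- fit_variant_logor(genotype_panel(g[-5, , drop = FALSE], y[-5]), 1)
  expect_equal(fit$beta, ref$beta)
})

test_that("pairwise_pearson measures LD and handles degenerate pairs", {
  set.seed(11)
  g1 <- rbinom(200, 2, 0.4)
  gp <- genotype_panel(cbind(a = g1, b = g1, c = 2 - g1), rbinom(200, 1, 0.5))
  r <- pairwise_pearson(gp)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_identical(r, t(r))

  set.seed(12)
  big <- genotype_panel(cbind(x = rbinom(10000, 2, 0.3),
                              y = rbinom(10000, 2, 0.3)),
                        rbinom(10000, 1, 0.5))
  expect_lt(abs(pairwise_pearson(big)["x", "y"]), 0.05)

  # zero-variance column and a pair with <3 shared observations both zeroed
  g <- cbind(u = c(0, 1, 2, 1, 0), v = c(1, 1, 1, 1, 1),
             w = c(NA, NA, NA, 0, 2))
  gpd <- genotype_panel(g, c(1, 1, 0, 0, 1))
  expect_warning(rd <- pairwise_pearson(gpd), "set to 0")
  expect_equal(rd["u", "v"], 0)
  expect_equal(rd["u", "w"], 0)
  expect_equal(unname(diag(rd)), rep(1, 3))
})

test_that("approx_covariance applies r_ij * se_i * se_j", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  cov <- approx_covariance(r, c(0.6, 0.5))
  expect_equal(cov[1, 2], 0.15)
  expect_equal(diag(cov), c(0.36, 0.25))

  se <- c(0.3, 0.7, 1.1)
  expect_equal(approx_covariance(diag(3), se), diag(se^2))

  set.seed(21)
  k <- 6
  m <- matrix(runif(k * k, -0.5, 0.5), k)
  r2 <- (m + t(m)) / 2; diag(r2) <- 1
  se2 <- runif(k, 0.2, 1)
  cov2 <- approx_covariance(r2, se2)
  expect_equal(cov2, t(cov2))
  # converting back to correlation recovers the input
  expect_equal(stats::cov2cor(cov2), r2, tolerance = 1e-12)

  expect_error(approx_covariance(r, c(1, 2, 3)), "dimension")
  expect_error(approx_covariance(r, c(0.5, -1)), "positive")
})

test_that("HWE exact test matches brute-force enumeration", {
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  expect_gt(hwe_exact_test(25, 50, 25), 0.99)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)

  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12,
                 info = paste(counts, collapse = ","))
  }
  expect_error(hwe_exact_test(0, 0, 0), "positive total")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("filter_variants applies control-only MAF and HWE rules, idempotently", {
  set.seed(51)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  ctrl <- y == 0
  good <- rbinom(n, 2, 0.3)
  mono <- rep(0, n)
  # perfect HW proportions among the 60 controls: 15/30/15
  hw_ok <- rbinom(n, 2, 0.5)
  hw_ok[ctrl] <- rep(c(2, 1, 0), times = c(15, 30, 15))
  # gross heterozygote deficit among controls
  hw_bad <- rbinom(n, 2, 0.5)
  hw_bad[ctrl] <- rep(c(2, 0), times = c(30, 30))
  gp <- genotype_panel(cbind(good = good, mono = mono,
                             hw_ok = hw_ok, hw_bad = hw_bad), y)
  kept <- filter_variants(gp, maf_min = 0.01, hwe_p_min = 0.05)
  expect_setequal(kept$labels, c("good", "hw_ok"))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$reason[excl$label == "mono"], "maf")
  expect_equal(excl$reason[excl$label == "hw_bad"], "hwe")
  expect_gt(excl$hwe_p[excl$label == "hw_ok"], 0.99)

  again <- filter_variants(kept, maf_min = 0.01, hwe_p_min = 0.05)
  expect_identical(again$geno, kept$geno)

  mono_gp <- genotype_panel(matrix(0, 10, 2), rep(c(1, 0), 5))
  expect_error(filter_variants(mono_gp), "no variants survive")
  expect_error(filter_variants(gp, maf_min = 0.6), "maf_min")
})

test_that("genotype_panel validates its inputs", {
  expect_error(genotype_panel(matrix(3, 2, 1), c(0, 1)), "allele counts")
  expect_error(genotype_panel(matrix(1, 2, 1), c(1, 1)), "case and.*control")
  expect_error(genotype_panel(matrix(1, 2, 1), c(0, NA)), "phenotype")
})
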