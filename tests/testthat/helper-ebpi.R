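# shared fixture builders; everything is generated in code, no data files

make_panel <- function(beta = c(0, 1, 2), sigma2 = rep(0.5, 3), cov = NULL) {
  effect_panel(beta, sqrt(sigma2), cov = cov)
}

random_panel <- function(k, seed) {
  set.seed(seed)
  effect_panel(rnorm(k, 0.2, 1), sqrt(runif(k, 0.1, 0.6)))
}

# binary-coded genotype panel matching a 2x2 table (a,b,c,d) exactly
gp_from_table <- function(a, b, c, d) {
  g <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  genotype_panel(matrix(g, ncol = 1, dimnames = list(NULL, "S1")), y)
}

# independent HWE oracle: conditional genotype-count probabilities obtained by
# normalizing multinomial HW likelihoods over all heterozygote configurations
# (the allele-frequency factor cancels), then the two-sided exact sum
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  h <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(h, function(het) {
    stats::dmultinom(c((nA - het) / 2, het, n - (nA + het) / 2),
                     prob = c(0.25, 0.5, 0.25))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_Aa, h)] * (1 + 1e-7)])
}

# memoized heavy scenario runs shared between acceptance tests
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(key, config, oracle = FALSE) {
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- run_scenario(config, oracle = oracle)
  }
  .scenario_cache[[key]]
}
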