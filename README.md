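# ebpi — empirical-Bayes prediction intervals for panels of log odds ratios

Epidemiological screens report one odds-ratio estimate and one Wald
confidence interval (CI) per factor. For a *panel of exchangeable factors*
— say, the SNPs in a candidate region, none distinguishable a priori — this
package implements the empirical-Bayes alternative: treat the true log odds
ratios as draws from a common prior `N(mu, tau2)`, estimate `mu` and `tau2`
from the panel itself, and report **prediction intervals** (PIs) built from
the per-factor posterior. PIs are shorter than CIs, carry a direct
probabilistic interpretation (a 95% PI contains its true value with
probability 0.95, so `0.95 * n` true values are expected inside `n` such
intervals), and retain nominal coverage even among the intervals selected
for excluding zero — where naive CIs undercover badly.

## The method

For MLEs `beta_i` with standard errors `sigma_i` (and optional estimate
covariances `sigma_ij`, approximated for crude estimates by
`r_ij * sigma_i * sigma_j` with `r_ij` the linkage-disequilibrium Pearson
correlation):

```
mu_hat   = mean(beta_i)
tau2_hat = max(0, S^2 - mean(sigma_i^2) + mean_offdiag(sigma_ij))   # moments
V*_i     = 1 / (1/tau2_hat + 1/sigma_i^2)                           # posterior var
E*_i     = V*_i * (mu_hat/tau2_hat + beta_i/sigma_i^2)              # shrinkage
PI_i     = E*_i  ± z * sqrt(V*_i)        CI_i = beta_i ± z * sigma_i
```

The per-factor efficiency gain is `sigma_i^2 / tau2_hat` (PI variance is
`1 + gain` times smaller than the CI's). Validity of the probabilistic
interpretation needs a minimum panel size: K = 20/30/50/100 for
noise-to-signal ratios `mean(sigma^2)/tau2` up to 0.125/0.25/0.5/beyond.

The package also ships the estimation front end (2×2 tables, per-variant
logistic regression, minor-allele-frequency and Hardy-Weinberg-exact
filters in controls, pairwise-LD covariance approximation), a full coverage
simulation framework, a synthetic case-control genotype generator, and a
CLI (`fit` / `estimate` / `simulate` / `fixture`).

## Worked example

```r
library(ebpi)
panel <- effect_panel(beta = c(0, 1, 2), se = sqrt(rep(0.5, 3)))
a <- eb_analysis(panel, warn_small = FALSE)
a
#> Empirical-Bayes panel analysis
#> <prior_estimate> mu_hat = 1, tau2_hat = 0.5, K = 3
#>   level 0.95: 2 of 3 PIs significant; avg CI length 2.772, avg PI length 1.96
#>   average efficiency gain 100.0%
a$table
#>  id beta ci_low ci_high post_mean pi_low pi_high gain significant
#>  F1    0 -1.386   1.386       0.5  -0.48    1.48    1       FALSE
#>  F2    1 -0.386   2.386       1.0   0.02    1.98    1        TRUE
#>  F3    2  0.614   3.386       1.5   0.52    2.48    1        TRUE
```

Reading: the prior mean is the average MLE (1); the prior variance is the
excess of the sample variance (1) over the average sampling variance (0.5).
Because here `sigma_i^2 = tau2_hat`, each posterior mean is the midpoint of
the MLE and the prior mean, and each PI is `sqrt(2)` times shorter than its
CI (gain 100%). The middle factor is significant under the PI but not the
CI — shrinkage plus the shorter interval moved its lower bound past zero.

A coverage scenario (10,000 replicates, K = 100 effects with `tau2 = 1`,
sampling variances averaging 0.25, independent noise):

```r
run_scenario(scenario_config(K = 100, tau2 = 1, sigma2_mean = 0.25,
                             reps = 10000, seed = 11))
#>   PI coverage 0.9484 (mc se 0.0002); CI coverage 0.9498
#>   significant-subset coverage: PI 0.9483 (n=338184), CI 0.9235 (n=390682)
#>   avg lengths: PI 1.7240, CI 1.9383; avg gain 0.258
```

Both interval types sit at 95% overall, but restricted to the
zero-excluding ("significant") intervals only the PIs stay nominal — the
CIs drop to 92% here and as low as ~70% in noisier settings.

## Command line

```sh
Rscript inst/cli/ebpi fixture  --out geno.tsv --cases 96 --controls 50 --variants 66 --seed 1
Rscript inst/cli/ebpi fit      --genotypes geno.tsv --out fit_out
Rscript inst/cli/ebpi estimate --panel fit_out/panel.tsv --corr fit_out/corr.tsv --out est_out
Rscript inst/cli/ebpi simulate --config scenario.cfg --out sim_out
```

Exit codes: 0 success, 1 data error, 2 usage error. Every output directory
contains a `manifest.json` (command, config, seed, version, input
checksums); seeded commands are byte-reproducible.

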