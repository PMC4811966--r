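# zinbal — adaptive LASSO variable selection for zero-inflated count phenotypes

Count phenotypes in genetic association studies (numbers of affected
joints, pain sites, radiographic lesions, ...) frequently carry far more
zeros than Poisson or negative binomial (NB) regression can explain. The
zero-inflated negative binomial (ZINB) model handles this with a two-part
mixture,

    P(y = 0) = pi + (1 - pi) * (theta / (theta + mu))^theta
    P(y = j) = (1 - pi) * NB(j; mu, theta),            j = 1, 2, ...
    log(mu_i) = X_i beta,    logit(pi_i) = X_i gamma,

but joint modeling of many (possibly highly linked) SNPs makes maximum
likelihood fragile and calls for sparse estimation. `zinbal` is a toolkit
for exactly that setting, aimed at statistical geneticists and
biostatisticians who analyze or simulate zero-inflated count traits:

* **Unpenalized fitters** for Poisson, NB (fixed dispersion), ZIP and ZINB
  regression — EM for the mixtures, analytic observed-information Wald
  standard errors, principled non-identifiability flagging.
* **The EM adaptive LASSO** for the ZINB model: minimize

      -2 log L(beta, gamma) + lambda1 * sum_j w1j |beta_j|
                            + lambda2 * sum_j w2j |gamma_j|

  with weights `w = 1 / |pilot coefficient|` (MLE pilot, ridge fallback),
  solved by an EM algorithm whose M-step runs coordinate descent with
  soft-thresholding on a weighted penalized NB likelihood and a penalized
  logistic likelihood (compiled kernel). Tuning parameters are chosen by
  `BIC = -2 log L + d log(n)` along a warm-started regularization path;
  unit weights give the plain LASSO.
* **A genotype/phenotype simulator**: correlated SNPs from a dichotomized
  latent Gaussian AR(1) process (LD controlled by `rho`), effect sizes
  calibrated by marginal variance `h_j^2 = 2 maf (1 - maf) beta_j^2`, and
  ZINB phenotype generation with controlled zero inflation.
* **An evaluation battery**: power and type I error with
  Benjamini–Yekutieli FDR adjustment, selection sensitivity/specificity,
  per-coefficient mean squared error, and non-convergence accounting, all
  wired together by a config-driven experiment driver.

## A worked example

```r
library(zinbal)

des <- simulation_design(n = 500, rho = 0.5, h_total = 0.30)  # 50 SNPs, 5 causal
dat <- replicate_data(des, base_seed = 1, s = 1)
dat
#> zic_data: n = 500, count covariates = 50, zero covariates = 0, zero fraction = 0.722

w    <- adaptive_weights(dat)          # reciprocal ZINB-MLE magnitudes
path <- build_path_select_bic(dat, w)  # 30-point path, BIC selection
path$fit
#> penalized ZINB fit: lambda1 = 17.39, lambda2 = 0, df = 4, BIC = 1117.69
#> count support: 11, 21

subset(post_selection_tests(path$fit, dat), selected)
#>    variable selected estimate    se    z        p significant
#> 11       11     TRUE    0.903 0.244 3.70 0.000217        TRUE
#> 21       21     TRUE    0.569 0.224 2.54 0.011023        TRUE
```

The selected support (SNPs 11 and 21) is a subset of the five causal SNPs
(1, 11, 21, 31, 41) of this n = 500 draw; the post-selection Wald tests
refit the unpenalized ZINB on the support, and both supported effects are
significant at the 5% level. A small comparison study:

```r
cfg <- experiment_config(des, methods = c("NB", "ZINB", "AL"), R = 50, base_seed = 2)
run_experiment(cfg)
#> study summary: n = 500, R = 50, h = 0.3, rho = 0.5
#>  method   n  R n_converged nonconv_pct power     type1 sensitivity specificity
#>      NB 500 50          42          16 0.481 0.0153439          NA          NA
#>    ZINB 500 50          50           0 0.128 0.0008889          NA          NA
#>      AL 500 50          50           0 0.248 0.0008889       0.548      0.9836
#>      mse mse_mc_se
#>  0.14926  0.005725
#>  0.16382  0.006163
#>  0.03928  0.002391
```

Here `power`/`type1` are per-SNP rejection frequencies (BY-adjusted, 5%
level) averaged over causal and null SNPs, `mse` is the per-coefficient
mean squared error of the count-model coefficients over converged
replicates, and `nonconv_pct` shows the fragility of the unpenalized NB
fit under LD that the penalized estimator does not share.

`reproduce_table("T3", n = 1000, mv = 0.01, R = 200)` replays whole cells
of the reference simulation grid (three LD scenarios, six marginal
variances, three sample sizes) and reports recomputed MSEs with
Monte-Carlo standard errors next to the published reference values.

A thin command-line front end over the same functions lives at
`inst/cli/zinbal.R` (subcommands `simulate`, `fit`, `select`, `run`,
`reproduce-table`), with designs supplied as YAML/JSON configs.

## Documentation

The methods vignette (`vignettes/zinb-adaptive-lasso.Rmd`) documents the
model, the EM/coordinate-descent algorithm and its numerical choices, the
simulator's assumptions, and known limitations. Every exported function
carries roxygen documentation.
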