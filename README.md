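# misurv — cause-specific survival from multiply imputed causes of death

Cancer registries often know *that* a patient died long before they know
*why*: causes of death arrive years late from national coding offices, and
a sizeable fraction is never recovered. For cancers of the elderly such as
prostate cancer, where most deaths are from other causes, this blocks the
quantity clinicians actually want — **cause-specific survival**. The
conventional fallback, **net survival** (the Pohar-Perme life-table
estimator), needs no causes of death but routinely exceeds 100% for
prostate-cancer cohorts, because screened men are healthier than the male
population their life table describes.

`misurv` treats the missing causes (and incomplete clinical covariates)
as a missing-data problem:

1. **Impute** — m completed cohorts by chained equations (fully
   conditional specification) with predictive mean matching, logistic and
   multinomial imputation models, *conditional domains* (cause of death
   only for the deceased, pathological staging only after surgery) and
   *passive* derived variables (T_new, N_new, d'Amico group), with
   Gelman-Rubin convergence diagnostics;
2. **Estimate** — on each completed cohort, cause-specific Kaplan-Meier
   (other-cause deaths censored) and the competing-risks cumulative
   incidence complement 1 − CIF;
3. **Pool** — the m curves by Rubin's rules after a complementary log-log
   transformation. With S_i(t) the per-dataset survival and
   Q_i(t) = log(−log(1 − S_i(t))), the delta method carries the
   per-dataset variance to the transformed scale,
   U_i = Var[S_i] / (log(1−S_i)·(1−S_i))², Rubin's rules give
   Q̄, Ū, B and the total variance T = Ū + (1 + 1/m)·B, and the pooled
   curve and its 95% bounds 1 − exp(−exp(Q̄ ± 1.96√T)) come back by the
   inverse transform.

A Pohar-Perme net-survival estimator, Dixon-style MCAR screening
(Mann-Whitney / Fisher tests on missingness indicators), three
sensitivity-analysis protocols, and a synthetic ERSPC-like cohort
generator with exact ground truth round out the package. See the
vignette (`vignettes/pooled-cause-specific-survival.Rmd`) for the model,
its assumptions and the design choices.

## Worked example

```r
library(misurv)

coh <- generate_cohort(n = 2844, seed = 20260927)$cohort  # masked cohort
lt  <- generate_life_table(40:105, 1995:2025, "gompertz") # population table
fit <- misurv(coh, m = 20, maxit = 10, life_table = lt, seed = 1)
print(fit)
#> Pooled cause-specific survival after multiple imputation
#>   n = 2844 patients, 329 deaths (164 with missing cause), m = 20
#>   pooled cause-specific KM at 10 y: 0.949 [0.935-0.961]
#>   pooled competing risks at 10 y: 0.952 [0.938-0.963]
#>   net survival (Pohar-Perme) included

round(summary(fit)[, c("years","overall","net","km","km_low","km_high","cr")], 3)
#>   years overall   net    km km_low km_high    cr
#> 1     1   0.979 1.001 0.993  0.989   0.996 0.993
#> 2     3   0.934 1.005 0.978  0.970   0.984 0.978
#> 3     5   0.899 1.026 0.969  0.959   0.976 0.970
#> 4    10   0.833 1.131 0.949  0.935   0.961 0.952
```

Reading the table: overall survival (all causes) falls to 0.83 by 10
years, but the pooled cause-specific curve — with half of the causes of
death imputed — stabilises near 0.95, with the Kaplan-Meier and
competing-risks versions nearly equal (their closeness is itself the
empirical check of the independence assumption). Net survival drifts
*above* 1 because this cohort dies more slowly than its life table
expects: the pattern that motivates imputing causes instead.

Convergence of the chained equations (below 1.1 ⇒ converged):

```r
round(rhat(fit$imputation), 2)
#>        psa_diag              cT              cN              cM   gleason_group
#>            0.99            1.01            1.01            0.99            0.99
#> first_treatment              pT              pN        psa_post           cause
#>            1.13            1.05            1.05            1.00            0.98
```

Sensitivity of the imputation model (protocol 1: mask a fraction of known
causes MCAR, re-impute, compare with the known truth):

```r
comp <- generate_cohort(n = 1400, seed = 1, missing_covariates = FALSE)$complete
runs <- protocol_random_removal(build_subcohort(comp, seed = 1),
                                m = 20, maxit = 2, seed = 2)
sapply(runs, function(r) r$coverage)   # fraction of grid inside the 95% band
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/misurv-cli.R` (subcommands `simulate`, `survival`,
`sensitivity`).

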