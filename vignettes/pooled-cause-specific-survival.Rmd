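---
title: "Pooled cause-specific survival from multiply imputed causes of death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled cause-specific survival from multiply imputed causes of death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misurv)
```

## The problem

Cause-specific survival — the survival a patient cohort would experience if
only the cancer under study could kill — is the natural summary for a
slow-moving disease like screening-detected prostate cancer, where most
deaths are from other causes. Estimating it needs a cause of death per
deceased patient, and registries rarely have all of them: causes arrive
years late from national coding offices, some patients are never matched.
The two usual escapes are

* **net survival** (Pohar-Perme), which avoids causes of death entirely by
  referencing a population life table, but inherits that table's
  unrepresentativeness — for prostate-cancer cohorts (healthier than the
  male population of the same age) the estimate routinely exceeds 100%;
* **complete-case analysis**, which throws away every death with an
  unknown cause and is biased unless the causes are missing completely at
  random.

`misurv` implements a third route: treat the missing causes (and the
incomplete clinical covariates) as a missing-data problem, create m
completed datasets by chained-equations multiple imputation, estimate the
cause-specific curve on each, and pool the curves with Rubin's rules on a
scale where normal-theory intervals behave.

## The pooling model

For each completed dataset $i = 1,\dots,m$ and each grid time $t_j$ we
have a survival estimate $\hat S_i(t_j)$ with pointwise variance
$V[\hat S_i(t_j)]$ (Greenwood's for Kaplan-Meier, the competing-risks
delta-method variance for $1-\mathrm{CIF}$). Survival probabilities live
in $[0,1]$ and their sampling distribution near the boundary is skewed,
so the curves are first transformed,

$$\hat Q_i(t_j) = \log\left(-\log\left[1 - \hat S_i(t_j)\right]\right),$$

with the matching delta-method variance

$$U_i(t_j) \approx
  \frac{V[\hat S_i(t_j)]}{\left[\log(1-\hat S_i(t_j))\,(1-\hat S_i(t_j))\right]^2}.$$

Rubin's rules then combine the transformed curves: the pooled estimate is
the mean $\bar Q(t_j)$, the within-imputation variance the mean $\bar
U(t_j)$, the between-imputation variance $B(t_j)$ the sample variance of
the $\hat Q_i(t_j)$, and the total variance

$$T(t_j) = \bar U(t_j) + \left(1 + \tfrac{1}{m}\right) B(t_j).$$

Point estimate and the 95% bounds
$\bar Q(t_j) \pm 1.96\sqrt{T(t_j)}$ are back-transformed by
$S = 1 - \exp(-\exp(Q))$. `pool_curves()` does all of this on the union
grid of the m curves' event times, evaluating each step function
right-continuously with last-value-carried-forward.

Numerical choices, all visible as arguments:

* the transform is undefined at $S \in \{0, 1\}$; estimates are clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-10}$ and the
  transformed-scale variance floored at $10^{-12}$;
* union-grid points before *every* curve's first event are passed through
  untransformed as $S = 1$ with the degenerate interval $[1,1]$;
* the normal quantile 1.96 is used as conventionally printed; a
  Barnard-Rubin small-m degrees-of-freedom correction is available via
  `df_correction = TRUE` but off by default;
* the union grid (rather than a fixed calendar grid) was chosen so that no
  imputation's event is ever interpolated away; with last-value carry
  forward the two conventions agree except between adjacent event times.

## The imputation model

`mice_impute()` is a fully-conditional-specification engine specialised to
the prostate-cohort data model. Per-variable methods follow standard
practice: predictive mean matching for the continuous PSA measurements
(donor pool of 5), logistic regression for binary variables (cN, cM, pN,
cause of death), a multinomial logit for unordered categories (cT,
Gleason group, first treatment, pT). Three features matter beyond the
defaults of a generic engine:

* **Conditional domains.** Cause of death exists only for the deceased;
  pathological staging only after surgery. These variables are imputed on
  their domain and remain structurally missing elsewhere. When first
  treatment is itself imputed, the pT/pN domain follows the *current*
  treatment, so every completed dataset satisfies "pT/pN present exactly
  for surgical patients".
* **Passive derived variables.** T_new/N_new (pathological stage when
  surgery, clinical stage otherwise) and the d'Amico risk group are
  recomputed after every update rather than imputed. They carry staging
  information into models for which raw pT/pN would be undefined. A
  passive variable is never allowed to predict a variable it derives from:
  for surgical rows T_new *is* pT, and feeding it back makes the chain
  reinforce its own imputations instead of mixing (we observed exactly
  this as a sustained between-chain drift before the rule was added).
* **Weakly-informative priors on the regression draws.** Coefficients are
  drawn from their asymptotic normal posterior. With few observed events
  relative to the design (imputing causes after 70–90% masking leaves a
  few dozen observed causes against ~20 design columns) the unpenalised
  posterior is so diffuse that drawn probabilities collapse toward 0.5
  and bias the pooled curve. A ridge penalty of 0.16 per
  scale-standardized coefficient — a N(0, 2.5²) prior, negligible at
  registry sample sizes — stabilises both the fit and the draw
  (`ridge`/`decay` arguments).

The predictor matrix defaults to a `quickpred()` screen (retain a
predictor when the maximum of its value-correlation and
missingness-correlation with the target is ≥ 0.1 and its usable-case
proportion is ≥ 0.4), after which it can be edited by hand — the intended
workflow mirrors clinician review. Follow-up time, the event indicator
and a Nelson-Aalen cumulative-hazard transform are available as optional
predictors (`use_outcome = TRUE`) but excluded by default; in cohorts of
this shape their correlations with the imputation targets are small and
including them does not move the curves. The visiting order is the
clinical chronology (PSA at diagnosis, cT, cN, cM, Gleason, first
treatment, pT, pN, post-treatment PSA, cause of death); defaults are
m = 20 imputations and 20 iterations.

Convergence is judged by the Gelman-Rubin potential scale reduction on
the per-iteration chain means of the imputed values (`rhat()`; below 1.1
is read as converged) and by observed-vs-imputed comparisons
(`compare_observed_imputed()`).

## Missingness diagnostics

`dixon_battery()` screens MCAR against MAR/MNAR: the cohort is split by a
target's missingness indicator and every companion variable is compared
across the split — Mann-Whitney-Wilcoxon for continuous companions,
Fisher's exact test for categorical ones — with Bonferroni correction by
default (configurable to Holm or none; the threshold choice is a
documented convention, not an inference). MAR versus MNAR is untestable
from the data; the package's MNAR generator exists precisely to show what
the method does when the assumption fails.

## The synthetic study scenario

`generate_cohort()` draws ERSPC-like cohorts with known ground truth; its
defaults are the package's reference scenario and are not tuned per
analysis: 2844 men aged 56–78 (truncated normal, mean 66), diagnosed
2003–2011, administrative censoring mid-2013 capped at 3624 days;
screening-era stage/PSA/Gleason marginals; ~11% deceased with roughly a
third of observed causes being prostate deaths; 50% of causes masked,
exactly counted, MCAR by default (MAR tied to diagnosis year and MNAR
tied to the true cause are available); covariate missingness rates
follow the registry pattern (cN worst at ~64%, Gleason best at ~5%).
Cause-specific event times use constant per-subject hazards with
log-linear age/Gleason/metastasis effects (baselines 9e-6 and 3e-5 per
day for prostate and other causes), so the generating cause-specific
survival — the large-sample limit of the cause-specific Kaplan-Meier
estimator under independent censoring — is computable exactly by
numerical integration over the drawn covariates (`truth$true_cs_survival`).

What the generator does **not** emulate: the joint covariate dependence of
a real registry beyond the configured pairwise links, non-proportional or
time-varying hazards, loss to follow-up other than administrative
censoring, and miscoded (as opposed to missing) causes of death. Passing
tests on this scenario therefore demonstrate the estimator's and
engine's correctness and calibration under a faithful but idealised
missingness process, not robustness to cause-of-death measurement error.

## Sensitivity protocols

Three protocols probe the imputation model, each comparing a "true"
cause-specific curve with the pooled curve after deliberate masking:

1. `protocol_random_removal()`: from a complete sub-cohort (all deaths
   with known cause plus half of the alive, preserving the dead/alive
   ratio), mask 10–90% of causes MCAR, re-impute, pool.
2. `protocol_reimpute_original()`: within each first-level completed
   dataset, delete the *originally observed* causes, keep the first-level
   imputations as pseudo-truth, re-impute.
3. `protocol_cross_validation()`: as 2 but masking a random draw of the
   same size among all deaths.

The package summarises each run by a scalar the original presentation
leaves visual: the fraction of pooled-grid points at which the truth lies
inside the pooled 95% band (`coverage`). Because the intervals are
pointwise, not simultaneous, occasional single-replicate excursions are
expected at high masking even for a perfectly calibrated method; the
reference checks therefore aggregate over seeded replicates (mean
pointwise coverage ≥ 0.95 and median replicate coverage 1 up to 70%
masking; mean coverage ≥ 0.9 at 90%), and coverage is monotone
nonincreasing in the masking fraction on average.

## Problem sizes used by the checks

The packaged tests and the acceptance script run the reference scenario at
full cohort size (n = 2844, m = 20, 20 iterations) for the convergence and
pooling summaries; calibration and coverage properties use n = 900–1500
cohorts, and the 50-replicate sensitivity sweeps use n = 1400 cohorts with
cause-only re-imputation (m = 20, 2 iterations — with a single incomplete
variable the chained equations have no cross-variable feedback and extra
sweeps only redraw from the same conditional). These sizes are the
package's chosen reference configuration; all of them are arguments.

## Known limitations

* The cause-specific estimates read as net survival only under
  conditional independence of the competing hazards; the package shows
  the KM and competing-risks pooled curves side by side (they nearly
  coincide when independence holds) but cannot test independence.
* The Pohar-Perme variance is the Poisson-type estimator; late-time
  instability with few weighted subjects at risk is inherited from the
  estimator itself.
* Multinomial imputation draws use the asymptotic normal posterior of a
  weight-decayed fit; with very sparse categories the draw degrades to
  maximum-likelihood probabilities (with a warning) rather than failing.
* No MNAR-adjusted (delta) imputation is provided; the MNAR generator is
  a negative control, not a correction.
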