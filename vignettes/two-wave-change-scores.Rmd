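---
title: "Modelling cross-sectional and longitudinal genetic effects in two-wave cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cross-sectional and longitudinal genetic effects in two-wave cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twowave)
```

## The problem

Large genomic studies of human aging have mostly relied on cross-sectional
outcomes: a variant associated with lower grip strength or slower reaction
time in a single assessment may reflect life-long differences in peak
function rather than effects on the *rate* of age-related decline. With two
assessment waves per individual — a baseline and a follow-up some years
later — the two kinds of effect can in principle be separated, but the
choice of the per-individual "change" summary turns out to matter a great
deal. `twowave` implements the full desk-scale machinery for studying this
question: a generative simulator, the three standard change definitions,
association scans with selective-attrition corrections, a two-sample
Mendelian randomization stage on standardized summary statistics, and an
evaluation harness with a closed-form oracle for the best-known failure
mode (baseline-adjusted change).

## The generative model

`scenario()` parameterizes a structural causal model for an observed
phenotype $P^*_t$ at waves $t \in \{0, 1\}$:

$$P^*_t = P_t + \varepsilon_t
       = \lambda + \alpha G + \beta E_t + \gamma\, G\, E_t + \varepsilon_t$$

where $G$ is a biallelic dosage (0/1/2, Hardy–Weinberg proportions at the
scenario's allele frequency), $\alpha$ the time-invariant (cross-sectional)
genetic effect, $E_t$ a time-varying environment, $\beta$ its main effect,
$\gamma$ a gene-by-environment interaction, and $\varepsilon_t$ independent
Gaussian measurement error per wave. Both $\alpha_j$ and $\gamma_j$ are
per-SNP vectors on the same panel, so a variant can be
cross-sectional-only, longitudinal-only, or both.

Design choices worth spelling out:

* **Age-linked environment.** $E_t = \text{env\_slope}\cdot(age_t -
  \text{env\_center}) + u_i$ with individual-level Gaussian noise $u_i$
  shared across waves, so $E_1 - E_0 = \text{env\_slope} \cdot FU$ is
  deterministic given the follow-up duration and $\gamma$ acts as a
  gene-by-age effect. Centering the environment at the mean baseline age
  (the default) keeps a pure $\gamma$ variant out of the baseline model;
  `env_center = 0` reproduces the uncentered parameterization in which
  $\gamma$ also contributes $\gamma E[E_0]$ to the baseline association.
* **Ages and durations.** Baseline age uniform on 40–69 years (a typical
  adult-biobank recruitment window) and follow-up duration uniform on 2–12
  years, bracketing a mean of 7; both are free scenario parameters.
* **Measurement error.** Equal-SD i.i.d. Gaussian at both waves by
  default, with a per-wave override (`error_sd = c(sd0, sd1)`).
* **Intercept.** The linear form defaults to $\lambda = 30$ (think of a
  raw test score) so phenotypes stay strictly positive and log-difference
  scores are well defined in the small-relative-change regime. This is not
  cosmetic: log scores applied to a phenotype whose mean is only a few
  error-SDs above zero pick up curvature that visibly mis-calibrates them
  (see "Limitations").
* **Proportional decline.** `decline_form = "exponential"` exponentiates
  the same linear predictor, so decline is proportional to the current
  level: absolute change scales with the baseline while relative (log)
  change does not — the cleanest mechanism generating scale-dependent
  conclusions.
* **Participation.** Follow-up participation is Bernoulli with a logistic
  model in the *observed* baseline phenotype, age and sex
  (`participation_model()`). Selection on the observed value makes
  attrition missing-not-at-random with respect to the latent trait yet
  correctable by inverse probability weighting on observed covariates,
  which is exactly the identifying assumption IPW needs. True inverse
  probability weights are stored alongside the data so estimated weights
  can be benchmarked against them.

## Three definitions of change

For baseline $P^*_0$ and follow-up $P^*_1$, oriented so larger values mean
more decline:

* **Absolute change** `diff_score()`: $\Delta_{DIFF} = P^*_0 - P^*_1$.
* **Conditional change** `residual_change()`: residuals of
  $\Delta_{DIFF}$ on the observed baseline.
* **Relative change** `log_score()`: $\Delta_{LOG} = \log P^*_0 - \log
  P^*_1$, insensitive to the baseline level under proportional change.
  Non-positive phenotypes are a hard error naming the offending rows; a
  constant-shift argument exists for simulation designs only and is never
  applied implicitly.

Each change score is then residualized on baseline age, follow-up
duration, their interaction, and squared age
(`residualize_change()`; the quadratic absorbs non-linear rates of
change), and baseline scores are residualized on age and squared age and
z-scored (`standardize_baseline()`). Composites across phenotypes average
standardized components with row-wise mean imputation
(`composite_score()`); the `min_observed` floor defaults to 1, i.e. any
partially observed row is imputed. For the conditional score the pipeline
residualizes on the baseline *first* and on age/follow-up second (the
order in which the definitions are stated); `baseline_first = FALSE`
provides the alternative ordering as a sensitivity flag.

## Why baseline adjustment misleads, exactly

Under the linear model the difference score
$\Delta = -(\beta + \gamma G)(E_1 - E_0) + \varepsilon_0 - \varepsilon_1$
contains no $\alpha$: purely cross-sectional effects cancel. But
conditioning on the *observed* baseline re-introduces them. Writing
$b = \mathrm{Cov}(\Delta, P^*_0)/\mathrm{Var}(P^*_0)$, the expected
coefficient of a regression of the baseline-residualized change on dosage
is

$$E[\hat\beta_{RES,j}] \;=\; -\,\gamma_j\,E[\Delta E]\;-\;
  b\,\bigl(\alpha_j + \gamma_j E[E_0]\bigr),$$

with every covariance available in closed form from the scenario
parameters (`oracle_res_expectation()` implements the general multi-SNP
expression). When $\gamma = 0$ this collapses to

$$E[\hat\beta_{RES,j}] = -\,\alpha_j\,
  \frac{\sigma_0^2}{\mathrm{Var}(P^*_0)},$$

a spurious "change" association proportional to the baseline genetic
effect *and* to the measurement-error variance — regression to the mean
dressed up as decline. The oracle was cross-checked against brute-force
Monte Carlo (single replicate, $n = 10^6$) during development and that
check is retained, at $n = 2\times 10^5$, in the test suite; the harness
additionally verifies the Monte-Carlo mean against the oracle over a
$3\times3$ grid of $(\alpha, \sigma)$ values chosen on the analytically
monotone branch of the bias curve
($|\text{bias}|$ grows in $\alpha$ until
$\alpha^* = \sqrt{(c + \sigma^2)/\mathrm{Var}(G)}$, far above the grid).

## Association scans, attrition, and weighting

`snp_regression()` fits outcome ~ intercept + dosage + covariates per SNP
via the Frisch–Waugh–Lovell decomposition, vectorized across SNPs: the
outcome and all dosages are projected off the covariates once, after
which each SNP is a simple regression. The result is numerically
identical to per-SNP `lm()` (asserted to machine precision in the tests)
but scans thousands of SNPs in milliseconds. Weighted fits (inverse
probability of participation weights) use WLS with HC1 sandwich standard
errors — homoscedastic errors are invalid under IPW — and the hand-built
sandwich is verified against the `sandwich` package in the test suite.
Plain OLS standard errors are used unweighted. A whole-genome ridge
two-step (as mixed-model GWAS tools use) is deliberately absent: the
simulator has no relatedness or LD, so per-SNP OLS estimates the same
quantity. `gxsex_regression()` adds sex main and gene-by-sex interaction
terms. `estimate_ipw_weights()` fits the logistic participation model,
inverts fitted probabilities for participants, truncates at the 0.99
quantile by default, and reports the Kish effective sample size;
complete separation is an explicit error.

`standardize_stats()` maps per-SNP estimates to the standardized scale
used by the MR stage, $\gamma_{STD} = (\beta/SE)/\sqrt{N}$ and
$SE_{STD} = 1/\sqrt{N}$, preserving z-scores exactly.

## The Mendelian randomization stage

`select_instruments()` keeps SNPs passing the exposure threshold
($5\times10^{-8}$) and requires at least five instruments — fewer is an
explicit *skipped* status, not an error. `mr_ivw()` computes the
inverse-variance weighted estimate (Wald ratios $r_j = \beta_{out}/
\beta_{exp}$, weights $(\beta_{exp}/SE_{out})^2$); the default standard
error uses multiplicative random effects with the scale floored at 1 (the
common default of two-sample MR software), so it never undercuts the
fixed-effect SE; `method = "fixed"` switches it off. Whether the original
analyses used fixed or random effects is not documented in the main text
we model after; both are provided and the default is stated here.
Diagnostics follow the standard suite: Cochran's $Q$ on $k-1$ df
(`cochran_q()`), the MR-Egger intercept after orienting instruments to
non-negative exposure effects (`mr_egger()`, $t$ on $k-2$ df, scale
floored at 1), mean instrument strength $F$ (`instrument_strength()`),
and three-level Bonferroni flags at $0.05$, $0.05/11$ and $0.05/106$
(`multiple_testing()`, the dimension counts being configurable).
Instrument harmonization and LD clumping are out of scope: simulated
instruments are independent by construction, and real-data input is
assumed pre-clumped.

The coverage simulation in the tests evaluates the *fixed-effect* IVW
because its data-generating process has no excess heterogeneity; the
random-effects default is mildly conservative there by construction
(its SE is floored at the fixed-effect SE).

## The evaluation harness

`run_scenario()` repeats simulate → participate → score → scan, seeding
replicate $r$ at `seed + r` so runs are reproducible and replicates
independent, and aggregates per-estimator mean estimate, bias against the
model target, empirical SD, mean model SE, and rejection rates at both
0.05 (calibration) and $5\times10^{-8}$ (discovery realism). Targets are
$\alpha_j + \gamma_j E[E_0]$ for the baseline model and $-\gamma_j
E[\Delta E]$ for the difference and (under exponential decline) log
models; the conditional score has no clean estimand, so its bias is
reported against the difference-score target with the analytic oracle
tracked separately. Replicates in which an estimator fails (e.g. log
scores meeting a non-positive phenotype) are dropped and counted; more
than 5% failures aborts the scenario.

`age_effect()` estimates the slope of a plain z-scored baseline phenotype
on age (SD per year — the attenuation analyses deliberately do *not* use
the age-residualized z-score, whose age slope is zero by construction),
and `attenuation_curve()` sweeps attrition rates: at each level the
participation intercept is recalibrated to the target rate with the
selection slopes held fixed, and the age effect is re-estimated
unweighted, with true weights, and with estimated weights, against the
full-sample reference. Two behaviours of the logistic selection mechanism
are worth knowing. First, monotone attenuation across attrition levels
emerges when selection is steep (near-threshold truncation); under weak
logistic selection of a Gaussian phenotype the deep-attrition limit is an
exponential tilt, which shifts the mean without flattening the slope, so
the attenuation-vs-attrition curve can be humped. The default
demonstration scenario uses a selection coefficient of about 2.5 per
phenotype SD, firmly in the truncation regime. Second, untruncated true
weights become extremely variable under strong selection; the 0.99
truncation default trades a little bias for a lot of variance, and
like-for-like benchmarking of estimated against true weights should use
equal truncation settings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the following scales,
chosen so the full suite runs comfortably on a single core: calibration
on 2,000 null SNPs at $n = 20{,}000$; the baseline-adjustment-bias
scenario at 500 replicates ($n = 20{,}000$) plus a $3\times3$ oracle grid
at 200 replicates per cell; recovery runs at 50–200 replicates; the
attrition sweep at $n = 50{,}000$ with 20–30 replicates per attrition
level; 1,000 simulated instrument sets for IVW coverage. Log-score
recovery under exponential decline is checked at $n = 200{,}000$ with 50
replicates: the estimator carries a small $O(1/n)$ finite-sample bias
(projection coefficients estimated in-sample), and at error-free
settings the Monte-Carlo standard error is so small that this bias is
resolvable unless $n$ is large relative to the replicate count.

Other numerical conventions: rank-deficient residualization designs drop
aliased columns with a warning; zero-variance dosages yield flagged `NA`
results rather than being dropped; zero-variance baselines are hard
errors; weight truncation uses the empirical quantile of participant
weights; all random draws derive from explicit scenario or function
seeds.

## What the simulator does and does not emulate

It emulates: HWE dosages, realistic age and follow-up windows, additive
measurement error, gene-by-age interactions, proportional decline, and
phenotype-dependent attrition with recoverable weights. It does not
emulate: LD structure, chromosomes or positions, imputation dosage
uncertainty, relatedness or population stratification, cohort effects
masquerading as age effects, non-Gaussian measurement error, or
practice/learning effects at re-assessment. Passing tests therefore show
that the estimators behave as the theory predicts under clean
assumptions; they do not certify behaviour on real biobank data, where
the excluded features (and phenotype-specific measurement properties) can
matter.

## Known limitations

* Log-difference scores require a positively scaled phenotype and lose
  calibration when mean decline is non-negligible relative to the
  baseline level (curvature pulls in baseline genetic effects); with a
  steep environmental decline ($\beta$ a few times the default) and a
  strong baseline variant, the log model's type-I error visibly exceeds
  the nominal level even though the difference model stays exact.
* The residual-change oracle covers the linear form without sex effects;
  exponential scenarios are evaluated by simulation only.
* Two waves only: latent-growth or three-wave slope models are out of
  scope.
* The MR stage assumes independent, pre-harmonized instruments and does
  not implement outlier-robust estimators; per-instrument Wald ratios and
  the heterogeneity/pleiotropy diagnostics are the intended substitute at
  this scale.
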