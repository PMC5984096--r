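---
title: "Two-sample Mendelian randomization with summary statistics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

## The problem and the model

Observational associations between an exposure (here: ever having used
cannabis) and a disease outcome (schizophrenia) may reflect
confounding or reverse causation rather than a causal effect.
Mendelian randomization (MR) sidesteps both by using genetic variants
as instrumental variables: alleles are assorted at conception, so a
SNP that raises the odds of the exposure acts like a randomized
nudge. In the *two-sample, summary-data* design, all we need per SNP
$j$ are published association estimates:

* $\hat\gamma_j \pm \sigma_{\gamma j}$ — SNP–exposure log-odds effect
  (an ever-use-of-cannabis GWAS of 32,330 individuals in the worked
  case study),
* $\hat\Gamma_j \pm \sigma_{\Gamma j}$ — SNP–outcome log-odds effect
  (a schizophrenia GWAS of 34,241 cases and 45,604 controls),
* optionally $\hat\delta_j \pm \sigma_{\delta j}$ — SNP–covariate
  effect (ever-smoking, 111,898 individuals), for multivariable
  adjustment.

If SNP $j$ is a valid instrument, $\Gamma_j = \theta\,\gamma_j$ where
$\theta$ is the causal log-OR of the outcome per log-odds unit of
exposure. Each SNP therefore yields a Wald ratio
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$, with first-order
delta-method standard error
$se_j = \sqrt{\sigma_{\Gamma j}^2/\hat\gamma_j^2 +
\hat\Gamma_j^2\sigma_{\gamma j}^2/\hat\gamma_j^4}$, and the ratios are
pooled by inverse-variance weighting (fixed effect), with a
DerSimonian–Laird random-effects pooling as a sensitivity analysis.

Two caveats on the delta method are worth recording. First, it is a
first-order expansion: at instrument strength around $z = 5$ the true
sampling SD of a ratio of normals exceeds the first-order value by
roughly 10–15% (we verified this against a Monte-Carlo oracle of
$10^6$ draws), and the gap closes as instruments strengthen. Second,
the package also exposes a leading-term variant
(`se_method = "delta1"`, $se_j = \sigma_{\Gamma j}/|\hat\gamma_j|$)
because with those weights fixed-effect IVW is *algebraically
identical* to the weighted through-origin regression of
$\hat\Gamma$ on $\hat\gamma$ with weights $1/\sigma_{\Gamma j}^2$ —
an identity the tests assert to $10^{-10}$. The two-term default is
used for reported results; the identity holds exactly only for the
leading-term weights.

## Harmonization and orientation

Summary files from different consortia report effects on whichever
allele each chose. `harmonize()` matches SNPs by rsid and re-expresses
every trait per copy of the exposure's effect allele, flipping the
sign of the beta and complementing the allele frequency where the
allele pair is swapped, and refusing allele pairs that are neither
identical nor swapped. Palindromic SNPs (A/T, C/G) cannot be
strand-checked from labels alone; when their allele frequency is in
[0.42, 0.58] we warn and keep them — with a fixed, published list of
instruments, exclusion is the analyst's decision, not the
harmonizer's. Matching is by rsid only: the instruments are a named
list, not a genome scan, so positional matching and liftover are out
of scope.

`orient_exposure_increasing()` then flips rows so every
$\hat\gamma_j \ge 0$ (negating outcome and covariate betas in step).
Wald ratios are invariant to this, but MR-Egger is not (its intercept
depends on the orientation convention), which is why the Egger fit
applies it internally.

## Pleiotropy-robust estimators

**MR-Egger.** Weighted regression
$\hat\Gamma_j = \beta_{0E} + \beta_{1E}\hat\gamma_j$ with weights
$1/\sigma_{\Gamma j}^2$. A nonzero intercept is evidence of
directional pleiotropy; the slope is a pleiotropy-adjusted causal
estimate. Standard errors come from a parametric bootstrap (default
10,000 replicates): each replicate redraws
$\hat\Gamma_j \sim N(\hat\Gamma_j, \sigma_{\Gamma j}^2)$ and, by
default, $\hat\gamma_j$ likewise, re-orients and refits. We chose the
parametric flavour over resampling SNPs because with ten instruments
the nonparametric bootstrap has only coarse support; whether the
exposure estimates should also be redrawn is not decidable from the
published record, so both modes exist and redrawing both is the
default. P-values use the normal approximation on the bootstrap SE,
with a $t_{k-2}$ reference available behind a flag.

**I²GX and SIMEX.** All of this assumes the SNP–exposure estimates
carry no measurement error (NOME). The $I^2_{GX}$ statistic — an
$I^2$ computed on the $\hat\gamma_j$ with weights
$1/\sigma_{\gamma j}^2$ — estimates the reliability of the Egger
slope; we report the expected proportional attenuation as
$1 - I^2_{GX}$. (Published analyses sometimes quote a bias percentage
that does not equal $1-I^2$; the definitional complement is what this
package reports.) Simulation extrapolation then corrects the
attenuation: for each $\lambda$ on a grid (default 0 to 2 by 0.25) we
add noise $N(0, \lambda\sigma_{\gamma j}^2)$, refit (default 1,000
replicates per grid point), model the mean coefficients as a quadratic
in $\lambda$, and extrapolate to $\lambda = -1$. The grid, replicate
count and quadratic extrapolant are conventional SIMEX defaults; the
SIMEX standard error reruns the whole procedure inside a parametric
bootstrap at 100 replicates per grid point, a deliberate
cost/precision compromise.

**Penalized weighted median.** The weighted median of the per-SNP
ratios is consistent while under half the weight comes from invalid
instruments. We use the interpolated convention: sort the ratios, form
standardized cumulative weights $S_j = (\sum_{i\le j} w_i - w_j/2) /
\sum w_i$, and interpolate linearly to the 50% point (with equal
weights and odd $k$ this is the sample median). Penalization
down-weights heterogeneous instruments:
$w^*_j = w_j\min(1, 20\,q_j)$ with $q_j$ the upper-tail $\chi^2_1$
probability of $Q_j = w_j(\hat\theta_j - \hat\theta_{WM})^2$; the
constant 20 follows the estimator's source methodology.

**Multivariable MR.** Where the exposure shares instruments with a
second trait (cannabis and tobacco use are strongly genetically
correlated), the direct effect is estimated by the weighted
no-intercept regression
$\hat\Gamma_j = \theta_c\hat\gamma_j + \theta_t\hat\delta_j +
\epsilon_j$. We regress the outcome effects on both exposures' effects
— the only direction in which "adjusting for tobacco" is a coherent
regression — and return $\theta_c$ with bootstrap SEs. A
rank-deficiency check refuses collinear designs.

## Scale of the reported odds ratios

The exposure GWAS models *log-odds of ever use*, so pooled estimates
are "per 1-log-unit increase in odds of ever use" — not a clinically
interpretable contrast. `to_users_vs_nonusers()` converts to an
ever-vs-never contrast. The default divides the log-OR by $p(1-p)$,
the Bernoulli variance of exposure status at prevalence $p$ (default
0.43, a config parameter): this is the linear-probability link between
a per-log-odds slope and a one-unit change in exposure status, and at
$p = 0.43$ it maps a per-log-unit OR of 1.08 to a users-vs-nonusers
OR of 1.37. An alternative (`method = "risk_solve"`) routes the
rescaled relative effect through the population lifetime risk
($K = 0.007$) and returns the odds ratio implied by the solved risks
in users and non-users. The exact algebra used in the original
analyses of this design is not fully specified in main texts; the
$p(1-p)$ rescaling is therefore a documented default, not a claim of
exactness, and the prevalence is deliberately a visible parameter.

## Diagnostics

*Instrument strength*: per-SNP $F_j = (\hat\gamma_j/\sigma_{\gamma
j})^2$ and $R^2_j = F_j/(F_j + n - 2)$, summed across independent
instruments; an allele-frequency-based $R^2$ variant
($2f(1-f)\hat\gamma^2 p(1-p)$) is available when frequencies are
present. *Power*: $\Phi\!\big(|\ln OR|\sqrt{N R^2\phi(1-\phi)} -
z_{1-\alpha/2}\big)$, the standard binary-outcome approximation; at
the null it returns $\alpha/2$ (one-tail convention). *Influence*:
leave-one-out IVW estimates, externally studentized residuals and
Cook's distances from the IVW-equivalent weighted regression; the
residual threshold 2 and the Cook's cutoff $4/k$ are reported flags,
never exclusions. For a one-parameter weighted regression Cook's
distance is proportional to the squared leave-one-out slope shift, so
the two diagnostics rank instruments identically — a property the
tests assert across simulated tables. *Subset analysis* reruns the
core pipeline on a named instrument subset (e.g. the two SNPs with
putative functional roles).

## Observational comparison

`meta_random_effects()` pools observational study odds ratios with
DerSimonian–Laird, reconstructing SEs from printed CIs under log-scale
symmetry (asymmetry beyond 5% warns and averages the half-widths).
`compare_estimates()` then tests genetic vs observational agreement
with $\chi^2_1 = (\beta_a-\beta_b)^2/(se_a^2+se_b^2)$. The packaged
`observational_studies.csv` carries the one cohort whose estimate is
printed in text form (OR 1.50, 1.10–2.00) plus labelled placeholder
rows: the other four studies' estimates appear only graphically in
their source figure, and digitizing a figure is not a data source this
package will pretend to have.

## The synthetic-data generator

`sim_model()`/`simulate_summary_stats()` generate summary statistics
directly — true $\gamma_j$, $\alpha_j$ (pleiotropy: none, balanced or
directional; an InSIDE-violation switch makes $\alpha$ track
$\gamma$), $\delta_j$, $\Gamma_j = \theta\gamma_j + \alpha_j +
\theta_t\delta_j$ — with SEs from the case-control approximation
$1/\sqrt{2f(1-f)\,n\,\phi(1-\phi)}$ and observed values drawn
normally around the truths. No individual-level genotypes are
simulated: every estimator in the package consumes only summary
statistics, so simulating at the summary level tests everything the
package does, at negligible cost. Defaults are the worked case study's
conditions (10 SNPs, the three GWAS sample sizes above, ever-use
prevalence 0.43, instrument z-statistics near 4.8, causal effect
$\ln 1.08$).

`simulate_reference_fixture()` is a deterministic calibration of the
same generator: observed exposure z-statistics are pinned to a
4.6–5.0 band (so every exposure p-value lies in $(10^{-7}, 10^{-5})$
by construction and the cumulative $R^2$ lands near 0.7%), and only
the outcome and covariate estimates carry sampling noise. Its
covariate effects are positive on average but vary independently of
the instrument effects, keeping the multivariable design
well-conditioned. The committed files under `inst/extdata/` are this
fixture at the default seed, clearly labelled synthetic.

What passing tests on these fixtures shows — and what it does not:
the generator satisfies the two-sample MR assumptions by
construction (independent instruments, normal sampling error, correct
SE model, no LD, no sample overlap, no winner's-curse selection of
instruments). Results on it validate the estimators' algebra,
calibration and robustness properties, not the biological validity of
any real instrument set.

## Numerical choices and degenerate inputs

* CI multiplier fixed at 1.959964; p-values are two-sided normal
  unless a t reference is requested.
* A single estimate pools to itself with $Q = 0$ on 0 df; $\tau^2$
  and $I^2$ are floored at 0.
* Exposure betas of exactly 0 are kept (with a warning) by the
  orientation step but refuse a Wald ratio; all-equal exposure betas
  are a collinearity error in Egger.
* Numerically exact regression fits report zero influence statistics
  rather than amplified rounding noise.
* Stage seeds are derived from the single pipeline seed by hashing
  the stage name, so adding or toggling a stage never perturbs
  another stage's draws; reruns are byte-identical.
* Simulation sizes in the test suite (400–1,000 replicates for
  coverage and type-I checks, 10,000 bootstrap replicates where SEs
  are asserted) were chosen so Monte-Carlo error is well inside the
  asserted tolerances.

## Known limitations

* The users-vs-nonusers transformation is an approximation whose
  exact published counterpart is under-specified; both variants are
  provided and the prevalence is an explicit parameter.
* The first-order delta SE understates ratio uncertainty for weak
  instruments (see above).
* No LD handling, no strand inference from a reference genome, no
  mode-based or outlier-removal estimators (MR-PRESSO and relatives
  postdate the method set implemented here).
* The SIMEX standard error is itself a simulation at reduced
  replicate counts; treat it as indicative next to the analytic
  estimators.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_reference_fixture()
cfg <- mr_config(
  exposure = sim$exposure, outcome = sim$outcome,
  covariate = sim$covariate,
  studies = system.file("extdata", "observational_studies.csv",
                        package = "mrsummary"),
  bootstrap_reps = 10000, seed = 20170124)
report <- run_mr_pipeline(cfg)
report$estimates
autoplot(report)
write_mr_report(report, "mr_report")
```
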