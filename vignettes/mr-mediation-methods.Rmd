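---
title: "Two-sample MR with two-step mediation: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific problem

Observational associations between glycemic traits (type 2 diabetes
liability, fasting insulin) and fatty liver disease, and between iron
homeostasis biomarkers (ferritin, serum iron) and the same outcomes, are
confounded by adiposity, inflammation, and lifestyle. Mendelian
randomization (MR) side-steps much of this confounding by using genetic
variants — randomly allocated at conception — as instrumental variables.
`mrmediate` implements the full two-sample, summary-statistics MR workflow
needed to ask a *mediation* question on this system: how much of the
effect of an exposure (e.g. fasting insulin) on an outcome (e.g. liver
steatosis) flows through a mediator (e.g. ferritin)?

Everything operates on per-variant GWAS summary statistics (effect allele,
other allele, effect-allele frequency, beta, SE, p, n); no individual-level
data are touched.

## Model and estimators

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) with the outcome,
aligned to the same effect allele. Under the instrumental-variable
assumptions each Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
causal effect $\theta$.

* **IVW with multiplicative random effects** (the main analysis): the
  weighted through-origin regression
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, $w_j = 1/\sigma_{Yj}^2$. The fixed-effect SE is
  inflated by $\max(1, \sqrt{Q/(L-1)})$ where $Q$ is Cochran's statistic:
  overdispersion from balanced pleiotropy widens the interval, while
  underdispersion is never allowed to shrink it (the floor at 1 is a
  deliberate convention; it makes the null test slightly conservative,
  measured rejection ~0.035–0.05 at nominal 0.05 in the acceptance suite).
  Heterogeneity is summarized as $I^2 = \max(0, (Q - df)/Q)$.
* **MR-Egger**: the same regression with an intercept, after orienting all
  instruments to non-negative exposure effects. The intercept estimates
  average directional pleiotropy (its p-value is the overall
  horizontal-pleiotropy test); the slope is consistent under InSIDE. The
  $I^2_{GX}$ statistic reports how much regression-dilution bias the slope
  may carry.
* **Weighted median**: consistent when instruments carrying $\ge$ half the
  weight ($w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$) are valid; the estimate
  interpolates the ratio at cumulative standardized weight 0.5, and its SE
  comes from a seeded parametric bootstrap (default 1000 replicates;
  `n_boot = 0` skips the bootstrap when only the point estimate is needed).
* **MR-PRESSO**: leave-one-out IVW expected values define a residual sum of
  squares whose null distribution is simulated parametrically; per-variant
  simulated residuals give Bonferroni-adjusted outlier p-values, flagged
  variants are removed for a corrected IVW fit, and a distortion test
  compares the raw-vs-corrected shift with random-removal expectations.
  Empirical p-values use the add-one rule, so the smallest attainable p is
  $1/(n_{sim}+1)$.
* **MVMR**: weighted through-origin multiple regression of outcome betas on
  $K$ exposure-beta columns gives *conditional* effects — the mechanism by
  which the mediator is "adjusted for".

## The mediation decomposition

Two-step MR: step 1 estimates exposure $\to$ mediator ($a$, univariable
IVW on the exposure's instruments); step 2 estimates mediator $\to$ outcome
adjusted for the exposure ($b$, from MVMR on the union of both traits'
instruments). The indirect effect is $ab$ with first-order delta SE
$\sqrt{a^2 s_b^2 + b^2 s_a^2}$ (two-sample independence assumed; a
covariance term and the second-order $s_a^2 s_b^2$ term are available as
arguments). The proportion mediated is $ab/\theta_{total}$ with the
delta-method variance combining both uncertainties; the CI is reported on
the plain ratio scale by default, with a log-scale option
(`log_scale = TRUE`) since the published analyses do not state which was
used. Effects of liability-scale (log-odds) exposures are rescaled by
$\ln 2 = 0.693$ to read per doubling of exposure prevalence; the proportion
mediated is invariant to this rescaling.

A numerical note verified in the acceptance suite: the proportion is a
ratio of approximately normal quantities, and a ratio of normals has *no
finite variance* — a plain Monte-Carlo SD of simulated ratios diverges
(dominated by rare near-zero denominators) even when the delta SE is a
perfectly good local scale. The Monte-Carlo oracle for the proportion SE
therefore uses half the central 68.27% quantile spread; agreement with the
delta SE is within 5% on all tested parameter sets.

## The synthetic-data generator: what it emulates, and what not

`sim_config()` / `simulate_gwas()` state a generative world:
$\gamma_j \sim N(0, \texttt{gamma\_sd})$ are true per-variant exposure
effects; the mediator receives $\kappa_j = a\gamma_j + \delta_j$ with
mediator-specific $\delta_j$ on a configurable fraction of variants (so the
MVMR design has full rank, exactly as real mediator GWAS contribute their
own instruments); the outcome, on the log-odds scale, receives
$\Gamma_j = \theta_{direct}\gamma_j + b\kappa_j + \alpha_j$ with
$\alpha_j$ optional horizontal pleiotropy. Observed betas add
$N(0, \sigma_j)$ noise with $\sigma_j = 1/\sqrt{2p_j(1-p_j)n}$ — the
standard large-sample SE of a per-allele regression coefficient on a
standardized trait.

Defaults are the conditions of the fasting-insulin chain at published-GWAS
scale: $L = 150$, $n$ of 158,550 / 246,139 / 885,701 for
exposure / mediator / outcome, $\theta_{direct} = 1.113$, $a = 0.375$,
$b = 0.223$, so $\theta_{total} = 1.197$ (an OR of 3.31 per unit) and the
true proportion mediated is $ab/\theta_{total} \approx 7\%$.
`gamma_sd = 0.03` reproduces a realistic instrument strength (per-variant
$R^2$ matching ~1.3% variance explained over a few dozen instruments);
20% of variants are palindromic A/T or G/C so harmonization is exercised;
half the variants carry mediator-specific effects with
$\delta$-SD 0.03 (ferritin-scale).

Deliberate simplifications: instruments are unlinked (LD enters only
through the user-supplied correlation matrix of the clumping path); the
binary outcome lives on a linear log-odds structural scale rather than a
threshold model; there is no between-cohort sample overlap. A green
recovery test therefore establishes correctness of the estimators under
the stated model — not robustness to LD misspecification or overlap bias.

Two generator conventions deserve explanation:

* **"Directional" pleiotropy is defined in the exposure-increasing-allele
  frame** ($\alpha_j$ multiplied by $\mathrm{sign}(\gamma_j)$). With
  sign-symmetric instruments, an offset attached to an arbitrary allele
  orientation averages to zero after the Egger orientation step, making
  directional pleiotropy undetectable by construction; the sign coupling is
  the only definition under which an Egger intercept can recover the mean
  pleiotropic effect.
* **Exact noiseless identities split by design.** With
  `observation_noise = FALSE` and no mediator-specific effects, univariable
  IVW returns exactly $\theta_{total}$ and step 1 exactly $a$; with
  mediator-specific effects present, MVMR returns exactly
  ($\theta_{direct}$, $b$) with $Q = 0$. No single configuration yields all
  identities at once: without $\delta_j$ the MVMR design is rank-1, and with
  $\delta_j$ the univariable slope carries genuine $b\delta_j$ heterogeneity.

## Recovery bands and known finite-sample biases

Recovery criteria compare a summary of estimates over seeded replicates
with the generator truth using the estimator's *own* Monte-Carlo 95%
interval (mean or median within $\pm 1.96\,\mathrm{SD}$ of the replicate
distribution); "detectably biased" means landing outside that interval.
This is the reading under which the robustness contrast is well posed: at
realistic GWAS noise the weighted median carries a finite-sample
quantile-shift bias (measured $\approx +0.04$ on $\theta = 0.25$ with 40%
invalid instruments) that is small against its sampling spread but many
standard errors of the mean, while IVW's contamination bias
($\approx +0.08$) exceeds even its sampling spread.

The mediation chain shows the same phenomenon: over 500 seeds the mean
estimated proportion mediated is 0.074 against a truth of 0.070. The
+0.004 is errors-in-variables bias — the estimators treat exposure and
mediator betas as fixed regressors although they are measured with noise,
so step 2 absorbs a sliver of the large direct effect through the noisy
mediator column. Scaling all sample sizes by 100 removes it (mean 0.0701).
This is a property of the standard summary-statistics estimators
themselves, shared by the published analyses that use them, and is
documented rather than corrected.

## Numerical and procedural conventions

* CIs are Wald at $z = 1.959964$; all p-values two-sided normal. P-values
  that underflow to a printed 0 in input tables are floored at the smallest
  positive double rather than dropped.
* SEs missing from an input table are reconstructed as $|\beta|/z(p)$ with
  the quantile evaluated on the log scale, so arbitrarily small p-values
  cannot overflow.
* Harmonization: strict palindromic ambiguity window (a variant with EAF
  exactly 0.42 is retained); palindromic variants with a missing EAF on
  either side are discarded (orientation unverifiable); retained variants
  are emitted in ascending variant-ID order, making every downstream result
  order-independent.
* Greedy LD clumping visits candidates in ascending p (variant ID as
  tiebreak) and compares squared correlations against the threshold;
  without an LD matrix the input is treated as pre-pruned, with a logged
  note.
* Meta-analysis uses the DerSimonian–Laird moment estimator for
  $\tau^2$ (the common default when only "random-effects" is specified) and
  pools cohort-level estimates; variant-level pooling across cohorts is
  deliberately not offered.
* Power calculations use the normal approximation
  $\Phi(|b|\sqrt{n R^2 \,[cf(1-cf)]} - z_{1-\alpha/2})$, documented in the
  output; a zero effect returns $\alpha/2$ (one tail) by construction.
* MVMR instruments are the union of each trait's genome-wide-significant
  instruments intersected with availability in all tables; everything is
  aligned to the first exposure's orientation.
* All stochastic procedures (weighted-median bootstrap, MR-PRESSO,
  simulation) take explicit seeds and restore the caller's RNG state;
  reports regenerate byte-identically from the same inputs and seeds.

## Known limitations

* No LD-reference-panel clumping, liftover, multi-allelic variants, or
  GWAS-VCF ingestion; instruments are assumed bi-allelic and (after
  clumping) independent.
* The step-1/step-2 covariance is assumed zero by default (two-sample
  design); partial sample overlap must be handled through the optional
  `cov_ab` argument.
* Headline published estimates (meta-analyzed ORs per exposure–outcome
  pair) are reproducible only with the original harmonized instrument
  tables, which are not distributed with the package; the pipeline accepts
  such tables as ordinary TSV inputs.
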