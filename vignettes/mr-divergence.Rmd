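---
title: "Methods: two-sample MR across diverging outcome datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR across diverging outcome datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdiv)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on a disease from published GWAS summary statistics alone: genetic
variants robustly associated with the exposure serve as instrumental
variables, and per-variant exposure and outcome associations from two
different study populations are combined. For diseases of old age such as
Alzheimer's, "the outcome GWAS" is not one thing. There are case-control
studies of clinically diagnosed disease (GWAS), studies where case status is
a self-reported parental history of the disease (GWAS-by-proxy, GWAX), and
meta-analyses of the two. These measure different phenotypes with different
error structures, and causal estimates computed against them can disagree —
up to and including sign reversal.

`mrdiv` implements the whole comparison workflow: per-dataset MR with a
pleiotropy screen, a secondary analysis restricted to the variants shared by
all datasets, and an explicit per-variant heterogeneity analysis *between*
outcome datasets, treating each variant's two Wald ratios as two "studies"
in a miniature meta-analysis.

## Model and estimators

For variant $j$ let $\hat\beta_{Xj}, se(\hat\beta_{Xj})$ be its association
with the exposure (here: years of schooling, in SD units per effect allele)
and $\hat\beta_{Yj}, se(\hat\beta_{Yj})$ its association with the outcome
(log odds of disease), both expressed for the same effect allele after
harmonization. The variant-level causal estimate is the Wald ratio

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}}, \qquad
  v_j = \frac{se(\hat\beta_{Yj})^2}{\hat\beta_{Xj}^2},$$

the usual first-order variance, which conditions on the exposure effect
(reasonable when instruments are genome-wide significant). The combiners:

* **IVW**: $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ with
  $w_j = 1/v_j$. The fixed-effect SE is $(\sum_j w_j)^{-1/2}$; the
  multiplicative random-effects model inflates it by
  $\max\{1, \sqrt{Q/(J-1)}\}$ with $Q = \sum_j w_j(\hat\theta_j -
  \hat\theta)^2$. The default `auto` uses the fixed model below four
  variants and the multiplicative model otherwise; the point estimate is
  identical under all models, so odds ratios are model-invariant.
* **Weighted median**: the inverse-variance weighted median of the
  $\hat\theta_j$, interpolated at standardized cumulative weight 1/2;
  consistent when at least half the weight comes from valid instruments.
  Its SE is a parametric bootstrap (each $\hat\theta_j$ redrawn as
  $N(\hat\theta_j, v_j)$), 10,000 replicates by default, seeded.
* **MR-Egger**: weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with weights $1/se(\hat\beta_{Yj})^2$ and a free
  intercept estimating average directional pleiotropy. Every variant is
  first oriented so $\hat\beta_{Xj} \ge 0$, which the intercept needs to be
  identifiable. SEs use the multiplicative overdispersion convention
  (fixed-effect SE times $\max(1, \hat\sigma)$); tests and intervals use
  the $t$ distribution with $J - 2$ df.
* **Outlier-corrected IVW (MR-PRESSO style)**: see the screen below; the
  corrected estimate is IVW on the panel minus flagged variants.

IVW and weighted-median p-values use the normal reference; 95% intervals
use 1.959964 rather than 2. Odds ratios are $\exp(\cdot)$ of estimate and
interval bounds, interpretable per 1 SD of the exposure.

## Harmonization

Outcome records are aligned to the exposure's effect allele. Identical and
swapped allele pairs, and their strand complements, are reconciled
mechanically (a swap negates the outcome effect). Palindromic variants
(A/T, C/G) are ambiguous between "swapped" and "other strand"; the policy
is configurable:

* `eaf_infer` (default): orient by comparing effect-allele frequencies,
  dropping the variant when either frequency is missing or within 0.08 of
  0.5 (the conventional conservative window);
* `drop`: always drop;
* `keep`: trust the stated alleles (appropriate when both studies are
  known to report on the same reference strand; reproducing published
  analyses whose variant counts show no palindromic exclusions requires
  this).

Variants with $|\hat\beta_{Xj}| < 10^{-12}$ are dropped ("weak-zero")
because the Wald variance divides by $\hat\beta_{Xj}^2$. Every input
variant ends up either in the panel or in a `dropped` table with a reason;
nothing is discarded silently.

## The simulation-based outlier screen

The global test measures departure from a single shared slope with the
weighted residual sum of squares
$\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} - \hat\theta_{(-j)}
\hat\beta_{Xj})^2$, $w_j = 1/se(\hat\beta_{Yj})^2$, where
$\hat\theta_{(-j)}$ is the leave-one-out IVW slope. Its null distribution
is simulated: each replicate redraws
$\hat\beta^*_{Xj} \sim N(\hat\beta_{Xj}, se(\hat\beta_{Xj})^2)$ and
$\hat\beta^*_{Yj} \sim N(\hat\theta_{(-j)}\hat\beta_{Xj},
se(\hat\beta_{Yj})^2)$ and recomputes the RSS with leave-one-out slopes
re-estimated on the replicate. The per-variant outlier test compares each
observed weighted squared residual with its own simulated distribution,
Bonferroni-adjusted across the panel; flagged variants are removed in a
single pass and IVW is refit.

Numerical choices worth stating:

* Empirical p-values use the add-one estimator $(1 + \#\{\cdot\})/(n_{sim}
  + 1)$, so they are never zero and are bounded below by
  $1/(n_{sim}+1)$; `n_sim` below 100 is refused.
* All draws come from per-variant substreams keyed by (master seed, rsid),
  so the p-values are invariant to row order — the price is that results
  are not bit-identical to an order-dependent single-stream implementation,
  only distributionally equivalent.
* The screen's operating characteristics are measured in the test suite:
  type-I error of the global test at $\alpha = 0.05$ over 1,000 simulated
  null panels ($J = 20$, 1,000 replicates each), recovery of a 10-SE
  injected outlier over 150 panels, and IVW interval coverage over 700
  panels of 60 variants. These sizes were chosen so the whole battery runs
  in well under a minute while keeping binomial noise around a percentage
  point.
* A distortion test (comparing corrected and uncorrected estimates) is not
  implemented; exclusion is a single pass, which matches the workflow this
  package targets.

## Cross-dataset heterogeneity

For each variant shared by two outcome datasets, the two Wald ratios are
treated as two independent estimates of the same quantity and combined in a
fixed-effect meta-analysis: with $w = 1/v$,

$$Q = w_a(\hat\theta_a - \bar\theta)^2 + w_b(\hat\theta_b - \bar\theta)^2
    = \frac{(\hat\theta_a - \hat\theta_b)^2}{v_a + v_b},$$

chi-square with 1 df under homogeneity, and
$I^2 = \max\{0, (Q-1)/Q\} \times 100\%$, banded as 0–25 (low), 25–50
(moderate), 50–75 (large), 75–100 (extreme). Summary counts use strict
inequalities ($I^2 > 25\%$, $I^2 > 50\%$), so boundary values land in the
lower count. No multiplicity correction is applied to per-variant Q
p-values: the bands, not the tests, are the reporting unit. A paired
t test (`stats::t.test(..., paired = TRUE)`) compares the average Wald
estimators between the two datasets; when the differences are exactly
degenerate (identical panels) the table reports the means with `NA` in
place of a statistic rather than failing.

The two-dataset Q cancels the shared exposure denominator, so it is exact
chi-square(1) under the null even for weaker instruments — the test suite
exploits this identity.

## The synthetic-data generator

`simulate_study()` generates a full study — one exposure dataset, several
outcome datasets, ground truth — under the structural model

$$\hat\beta_{Xj} = \gamma_j + e_{Xj}, \qquad
  \hat\beta_{Ydj} = \lambda_d\,\theta_d\,\gamma_j +
  \mathrm{sign}(\gamma_j)\,\alpha_j\,1[j \in \text{pleiotropic}] + b_{dj} +
  e_{Ydj},$$

with per-dataset causal slope $\theta_d$, multiplicative proxy-dilution
$\lambda_d$, directional pleiotropy $\alpha_j$ in a configurable fraction
of variants (oriented to the exposure-increasing allele — a fixed-allele
offset would cancel under the orientation MR-Egger requires), per-variant
between-dataset heterogeneity $b_{dj} \sim N(0, \tau^2)$, and sampling
noise at the drawn standard errors. P-values are normal Wald tests; allele
pairs are non-palindromic by construction, with configurable fractions of
records reported swapped or on the opposite strand to exercise
harmonization.

Defaults describe a well-powered schooling-to-Alzheimer's study and are
deliberately fixed: 162 instruments; true exposure effects drawn from the
tails of $N(0, 0.02^2)$ beyond 0.016 SD per allele (a published instrument
list contains only genome-wide significant variants, so the untruncated
normal — which produces arbitrarily weak instruments with unbounded Wald
ratios — is not what such a list looks like; set `gamma_min = 0` to remove
the truncation); exposure SEs uniform on [0.0025, 0.004] as in a
continuous-trait GWAS of roughly 400,000 people; outcome log-odds SEs
uniform on [0.015, 0.04] as in case-control samples of tens of thousands;
per-dataset slopes $-0.34$ (clinically diagnosed GWAS), $+0.09$ and
$+0.61$ (two proxy GWAX datasets) on the log-odds scale; no pleiotropy,
dilution or extra heterogeneity, so the default study satisfies the MR
validity assumptions.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium between instruments
(instruments are independent by construction), sample overlap between
exposure and outcome studies, liability-threshold misclassification (proxy
dilution is a multiplicative slope factor plus independent noise, not a
model of how family history misreports disease), allele-frequency- and
sample-size-derived standard errors, and winner's curse in the instrument
effects. Agreement with the generator validates the estimators'
arithmetic and operating characteristics under the stated model, nothing
more.

## Design choices that were genuinely open

* **IVW variance model.** Published tables rarely state whether fixed or
  random-effects IVW produced the intervals. Both are implemented; `auto`
  (fixed below $J=4$, multiplicative random effects otherwise) follows the
  convention of the standard MR tooling. Odds ratios are unaffected.
* **Exclusion authority.** Both the Egger intercept test and the outlier
  screen are computed per dataset, but only outlier-test flags remove
  variants; the intercept test is reported as a screen. Pooled (union)
  exclusion applies in the shared-variant secondary analysis, so every
  dataset's secondary panel contains the same variants.
* **Palindrome default.** `eaf_infer` with a 0.08 window is the
  conservative field convention and the default; `keep` exists because
  analyses that match on rsid alone (no palindromic exclusions) are common
  and must be reproducible.
* **Duplicate rsids** are a hard error on read: an ambiguous instrument
  silently resolved first-wins is irreproducible.
* **Missing variants** (present in the exposure list, absent from an
  outcome dataset) are dropped with a logged count; no proxy lookup is
  attempted.

## Worked example

```{r example}
study <- simulate_study(sim_config(n_variants = 143, seed = 2026))
report <- run_full_analysis(study$exposure, study$outcomes,
                            compare = c("GWAS:GWAX2018", "GWAS:GWAX2021"),
                            seed = 11, n_sim = 2000, n_boot = 2000)
report
```

The protective estimate in the clinical dataset, the null-to-adverse
estimates in the proxy datasets, the excess of variants with $I^2$ above
25%, and the significant paired difference of average Wald estimators are
all consequences of the generator's configured slopes, recovered by the
pipeline.

## Known limitations

* The weighted-median bootstrap is parametric only (normal per-variant
  draws); no jackknife or nonparametric alternative.
* No mode-based, robust-regression (RAPS), contamination-mixture or
  multivariable estimators; no SIMEX correction of MR-Egger under
  violation of its no-measurement-error assumption.
* The outlier screen's simulated null treats leave-one-out slopes as the
  truth; with very small panels ($J$ near its minimum of 4) the empirical
  p-values are conservative.
* Heterogeneity comparisons assume the two outcome datasets are
  independent; comparing overlapping meta-analyses (e.g. a GWAS against a
  meta-analysis containing it) violates that assumption and is not
  prevented, only documented.
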