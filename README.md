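# mrdiv

Two-sample Mendelian randomization (MR) across outcome datasets that
measure the same disease differently.

## The problem

MR uses genetic variants as instrumental variables: a variant robustly
associated with an exposure (here, educational attainment in SD units of
years of schooling) but affecting a disease (here, Alzheimer's) only
through that exposure identifies the causal effect from summary statistics
alone. For late-life diseases the outcome association can come from very
different kinds of studies: case-control GWAS of clinically diagnosed
patients, GWAS-by-proxy (GWAX) where "cases" are people reporting a parent
with the disease, or meta-analyses of both. These phenotypes are not the
same thing, and MR estimates computed against them can disagree — up to
sign reversal. `mrdiv` is for analysts who need to run the same MR
pipeline against several such datasets and quantify, per variant, how much
the datasets disagree.

## What it computes

For each harmonized exposure/outcome panel of J variants, with per-variant
effects β̂_Xj (exposure, SD units) and β̂_Yj (outcome, log odds):

- **Wald ratio** θ̂_j = β̂_Yj/β̂_Xj with variance v_j = se(β̂_Yj)²/β̂_Xj².
- **IVW**: Σ w_j θ̂_j / Σ w_j, w_j = 1/v_j; fixed or multiplicative
  random-effects SE.
- **Weighted median**: inverse-variance weighted median of the θ̂_j,
  parametric-bootstrap SE.
- **MR-Egger**: weighted regression of β̂_Yj on β̂_Xj with a free
  intercept estimating average directional pleiotropy (intercept test:
  t, J−2 df).
- **Outlier screen (MR-PRESSO style)**: leave-one-out weighted residual
  sum of squares with a simulated null for a global pleiotropy p-value and
  per-variant outlier p-values (Bonferroni-adjusted); flagged variants are
  removed and IVW refit.
- **Cross-dataset heterogeneity**: per shared variant, Cochran's
  Q = (θ̂_a − θ̂_b)²/(v_a + v_b) between two outcome datasets (χ², 1 df),
  I² = max(0, (Q−1)/Q)·100% banded low/moderate/large/extreme, counts of
  I² > 25% and > 50%, plus a paired t test of the Wald estimators.

Estimates are reported on both the log-odds and odds-ratio scales (per 1
SD of exposure). `run_full_analysis()` chains everything: harmonize each
dataset, screen, exclude flagged outliers, estimate with all four methods,
re-run on the variants shared by every dataset (minus pooled exclusions),
and compare requested dataset pairs. A seeded synthetic-study generator
(`simulate_study()`) with recorded ground truth backs the test suite.

## Worked example

```r
library(mrdiv)

study <- simulate_study(sim_config(n_variants = 143, seed = 2026))
report <- run_full_analysis(study$exposure, study$outcomes,
                            compare = c("GWAS:GWAX2018", "GWAS:GWAX2021"),
                            seed = 11, n_sim = 2000, n_boot = 2000)
report
```

```
Cross-dataset MR report: 3 outcome dataset(s), seed 11
Shared variants after pooled exclusions: 143 (excluded: none)

Pleiotropy screen:
   dataset n_variants egger_intercept egger_ci_low egger_ci_high egger_p presso_global_p outliers
1     GWAS        143       0.0042895    -0.007179       0.01576  0.4609          0.6402
2 GWAX2018        143      -0.0007176    -0.012175       0.01074  0.9016          0.9370
3 GWAX2021        143       0.0088952    -0.002327       0.02012  0.1194          0.8256

Primary estimates (per-dataset instruments, outliers removed):
    dataset          method     or or_low or_high    pvalue n_variants
1      GWAS             IVW 0.7299 0.6385  0.8343 3.956e-06        143
5  GWAX2018             IVW 1.0462 0.9148  1.1965 5.097e-01        143
9  GWAX2021             IVW 1.8179 1.5937  2.0736 5.579e-19        143
...

Heterogeneity comparisons:
     comparison n_variants n_i2_gt25 n_i2_gt50  mean_a  mean_b t_stat    pvalue
1 GWAS:GWAX2018        143        32        20 -0.2573 0.07922 -2.717 7.415e-03
2 GWAS:GWAX2021        143        49        35 -0.2573 0.64306 -7.441 8.753e-12
```

Reading it: the generator planted causal slopes −0.34 (clinical GWAS),
+0.09 and +0.61 (proxy GWAX) on the log-odds scale. The pipeline recovers
a protective odds ratio 0.73 in the clinical dataset, a null 1.05 and a
strongly adverse 1.82 in the proxy datasets; no pleiotropy is flagged
(none was planted); a third of the shared variants show I² > 25% between
GWAS and GWAX 2021, and the paired t test puts the average Wald estimator
in the clinical dataset (−0.26) significantly below the proxy dataset's
(+0.64, p ≈ 9e−12). With real summary tables, replace the simulated study
with file paths: `run_full_analysis("eduyears.tsv", list(GWAS =
"gwas.tsv", ...), ...)`.

`write_report(report, "out/")` serializes the screen, estimate and
heterogeneity tables as TSV plus a `report.json` with provenance (seed,
simulation sizes, exclusions).

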