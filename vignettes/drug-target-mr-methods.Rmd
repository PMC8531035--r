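---
title: "Drug-target MR with correlated instruments: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugTargetMR)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables: if a variant affects the outcome only through the exposure, the
ratio of its outcome effect to its exposure effect estimates the causal
slope. For a set of instruments with exposure effects $\hat\beta_x$
(per SD of a lipid fraction, per effect allele) and outcome effects
$\hat\beta_y$ (log-odds of disease), the package fits

$$\hat\beta_y = \theta\,\hat\beta_x + \varepsilon,\qquad
\varepsilon \sim N(0,\ \Sigma),\qquad \Sigma = D\,R\,D,$$

by generalized least squares, where $D$ is the diagonal of outcome standard
errors and $R$ the signed LD correlation matrix from a reference panel. This
allows instruments correlated up to the clumping threshold (r² < 0.4) to be
used jointly — important in a *cis* design where a single gene region rarely
offers many independent variants. MR-Egger adds a free intercept capturing
average directional pleiotropy; before an Egger fit, instruments are
oriented so every $\hat\beta_x \ge 0$ (outcome effects and LD signs flipped
along), which makes the intercept identifiable. Multivariable MR replaces
the single column $\hat\beta_x$ with one column per lipid fraction and
estimates direct effects jointly.

Assumptions worth stating plainly: the covariance is first order in the
outcome SEs only — uncertainty in $\hat\beta_x$ is ignored, the standard
two-sample practice. With strong instruments (per-variant exposure z of 10
or more, typical at consortium sample sizes) the resulting weak-instrument
attenuation is a fraction of a percent; it grows as instruments weaken and
is documented, not corrected. The reference LD is assumed exchangeable with
the GWAS cohorts' LD.

## Model selection and pruning

Four candidate models are compared: IVW or Egger family, fixed or random
effects. Following the Rücker logic, the family is decided by the drop in
Cochran's Q when the intercept is freed: $Q_{IVW}-Q_{Egger}$ is
$\chi^2_1$ under no directional pleiotropy. Within the family, random
effects (variance inflation by $\max(1, Q/df)$) is used when the family's
own Q is significant at 5%.

The family decision defaults to the **1% level** rather than 5%. The switch
is a pretest: draws falsely routed into the Egger family are exactly the
draws whose accidental intercept is large, and their post-selection
confidence intervals cover the truth less than half the time. At a 5% false
switch rate this drags the selected-model coverage of a true effect to
roughly 91% in well-powered settings; at 1% the selected-model coverage
stays between 92% and 98% across the simulation grid below while genuine
directional pleiotropy (a common intercept of 0.05 across instruments) is
still detected with high and $n$-increasing power. Both levels are exposed
(`selectModel(alphaQ =, alphaFamily =)`).

Outlier handling mirrors the two-step practice of removing gross
heterogeneity before final model selection: variants are removed one at a
time (largest whitened squared residual) while the global Q p-value is
below 0.001, re-fitting the selected model after each removal; then a
*single* sweep removes variants whose hat-matrix leverage exceeds three
times the mean. The leverage sweep is deliberately not iterated: under IVW
through the origin, leverage is proportional to $\hat\beta_x^2$, whose
chi-square-like spread across variants means a freshly recomputed 3×-mean
threshold is almost always exceeded by someone, and iteration cascades
through perfectly consistent strong instruments (in development it cut a
homogeneous 36-instrument set to 8). Pruning never goes below one variant
(IVW) or three (Egger).

Near-singular LD (duplicated variants, extreme synthetic configurations) is
handled by a lazy ridge: the Cholesky is attempted exactly first, then with
1e-8 on the LD diagonal, escalating tenfold to 1e-4 before a conditioning
error. Well-conditioned problems are therefore computed exactly, which
matters for oracle tests that compare against closed forms at 1e-10.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| genome-wide p threshold | 1e-6 | — | exposure instrument selection |
| *cis* p threshold | 1e-4 | — | relaxed for gene-region instruments |
| MAF filter | > 0.01 | frequency | exclude poorly estimated rare effects |
| clumping r² | < 0.4 | — | thin LD; residual correlation modeled by GLS |
| gene flank | 50,000 | bp | *cis* window and phenome-scan window |
| heterogeneity pruning | Q p < 0.001 | — | remove gross outliers only |
| leverage cut | 3 × mean | — | single sweep, see above |
| fixed-vs-random | 5% | — | Q within chosen family |
| IVW-vs-Egger | 1% | — | pretest calibration, see above |
| coloc priors | 1e-4, 1e-4, 1e-5 | per variant | exposure-only, outcome-only, shared |
| coloc ABF prior SD | 0.15 / 0.2 | per SD / log-odds | quantitative vs binary effect scale |
| colocalization call | PP4 > 0.8 | strict | decision threshold |
| palindrome MAF | 0.3 | frequency | drop at or above; align by frequency below |
| phenome-scan significance | 5e-8 | — | genome-wide convention |

The 50 kb / r² < 0.4 pair is the combination a grid search over positive
controls favors; `gridSearchCalibration()` reports per-cell direction
correctness, |z| and instrument counts over any (window, r²) grid, and
deliberately reports rather than auto-optimizes.

## Colocalization

Per variant, the log approximate Bayes factor is
$\tfrac12[\log(1-r) + r z^2]$ with $r = W^2/(W^2+V)$, $V$ the squared SE and
$W$ the prior effect SD (0.15 for per-SD traits, 0.2 on the log-odds scale —
the conventional defaults, since only "default priors" are ever stated for
this analysis style). The five hypothesis sums are evaluated in log space
with log-sum-exp; per-variant log ABFs beyond 700 would overflow a naive
implementation and do occur at consortium sample sizes. A single-variant
region has an empty two-distinct-variants sum, so PP3 is exactly zero.

Because the posterior assumes a single causal variant per trait, regions
are first decomposed by a stepwise conditional analysis on summary
statistics: forward selection of the smallest conditional p below 5e-8,
skipping candidates with r² > 0.9 against selected leads; conditional
effects come from the joint GLS projection with the reference LD, a
simplification of the COJO approach without per-variant sample-size
adjustment. Each exposure signal is then colocalized against the outcome
statistics conditioned on the other leads. The single-causal-variant
assumption within a signal remains, and regions with tightly linked
multiple causal variants can still yield false negatives.

## The synthetic generator

`simConfig()`/`simulatePanel()`/`simulateGwas()` emulate the statistical
structure of the real data: haplotypes are dichotomized AR(1) latent
Gaussians (corr $\rho^{|i-j|}$, optionally restarted in independent blocks),
summed to dosages; a 5000-individual reference panel supplies the empirical
LD. Exposure phenotypes are linear in standardized dosages with correlated
residuals across the three lipids (r of −0.1, 0.3, −0.4 for LDL/HDL,
LDL/TG, HDL/TG); the binary outcome follows a logistic model on the
exposures plus optional direct (pleiotropic) variant effects, on an
independent cohort — the two-sample design is enforced by construction, and
sample overlap is out of scope. Default sizes mirror the study conditions:
discovery exposure n = 188,577 and outcome n = 184,305 at case fraction
0.33; replication n = 33,029 and n = 296,525 at 0.1165. Default
architecture: 20 causal variants explaining h² = 0.1 per lipid.

Two modes draw from the same process. `"individual"` simulates cohorts and
runs per-variant regressions — linear for the exposures, logistic for the
outcome with either a one-step score estimator or full `glm` fits (the two
agree within 2% for |log-odds| < 0.3 and are cross-checked in tests).
`"summary"` draws the marginal estimate vector directly from its asymptotic
multivariate normal given the same truth (mean $R B$, covariance $R/n$ on
the standardized scale), which makes thousand-repetition grids cheap; the
two modes are verified to share their mean structure. Repetition studies
(coverage, calibration, colocalization rates) use summary mode; individual
mode backs the asymptotic identities (e.g. SE $\approx 1/\sqrt{2n f(1-f)}$).

What the generator does **not** emulate: real-genome LD maps and long-range
structure, population stratification, sample overlap, imputation error, and
allele-frequency drift between cohorts. Passing tests therefore demonstrate
the estimators' statistical properties under a faithful two-sample
structure, not robustness to those real-data pathologies.

The test fixture (`makeFixtures()`) plants a known truth in four
independent 20-variant blocks separated by 200 kb: an LDL-driven positive
control gene (replicates, colocalizes, liver-specific one-hot expression),
an HDL gene, a TG gene whose outcome signal is sign-reversed in the
replication draw (designed discordant), and a causal-free druggable gene
exercising the no-instruments path. Problem sizes throughout the suite —
80-variant fixtures, reference panels of 1,500–5,000, 100–1,000 repetitions
per property — were chosen so each check is informative at desk scale while
the whole suite stays in the low minutes.

## Numerical and degenerate-input choices

- Variants are matched by (chromosome, position, allele set), never rsid;
  coordinates are 1-based inclusive GRCh37.
- Clumping ties are broken by (p, chromosome, position), making the output
  invariant to input order. Threshold comparisons are strict exactly where
  printed that way (r² < 0.4, PP4 > 0.8, z > 1, MAF > 0.01).
- Sub-threshold palindromic variants are aligned by allele frequency by
  default; a flag (`dropAllPalindromes`) removes all palindromes instead,
  since only the phenome-scan stage of the source design states the 0.3
  rule explicitly.
- Two-sided p-values use the normal approximation and are clamped at
  1e-300 so downstream distributional checks stay in (0, 1].
- Zero-variance dosage columns raise a typed error naming the variant; an
  all-zero expression profile has no defined tau; empty instrument sets
  raise a typed error carrying the analysis unit.
- Dropped records are never silent: harmonization and readers log counts
  and attach them as attributes; stage outputs carry a JSON manifest with
  parameters and seed.

## Known limitations

- No weighted-median or mode estimators, no Steiger filtering: the
  framework deliberately implements only the IVW/Egger family with model
  selection.
- Weak-instrument bias is documented, not corrected; with *cis* thresholds
  at p ≤ 1e-4 and small replication samples, attenuation toward the null is
  expected.
- The conditional decomposition is a simplified COJO: reference LD stands
  in for in-sample LD and no per-variant sample-size adjustment is made.
- Tau's scale invariance is exact on raw expression but only approximate
  after the log2(x+1) transform (within ~0.05 for scale factors in
  [0.5, 2] on typically expressed profiles); both variants are exposed.
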