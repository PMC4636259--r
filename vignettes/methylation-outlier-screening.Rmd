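---
title: "Outlier-based methylation biomarker screening: models, parameters and design"
author: "methoutlier developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier-based methylation biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methoutlier)
```

## Why an outlier statistic

Promoter hypermethylation in solid tumors is frequently confined to a
subset of cases. A two-sample t-test on β-values compares group means and
loses power exactly when the biology is most interesting — when 30% of
tumors are strongly methylated and the rest look normal. Outlier
statistics in the COPA family address this by asking, per gene, how many
tumor samples exceed what normal tissue ever does, and how extreme those
samples are.

`methoutlier` implements the workflow end to end: screening, integration
with expression, and diagnostic evaluation of the resulting marker panel,
plus a synthetic-cohort generator that encodes the statistical structure
the analysis assumes.

## The screening model

For each gene, with β-values of the normal samples $x_1,\dots,x_m$ and of
the tumor samples $y_1,\dots,y_n$:

1. **Baseline cutoff** (right tail):
   $c = \max\{q_{75}(x) + k \cdot \mathrm{IQR}(x),\; \mathrm{median}(x) + \delta\}$
   with Tukey multiplier $k = 1.5$ and minimum-change floor
   $\delta = 0.10$. The left tail is the mirror image. The floor
   guarantees that any called outlier differs from a typical normal
   sample by at least 10% methylation — smaller changes are treated as
   biologically meaningless. Quantiles use the type-7 (linear
   interpolation) convention throughout, fixed for reproducibility.
2. **Outlier calls**: tumor samples with $y_j > c$ (strict inequality; a
   sample exactly at the cutoff is not an outlier).
3. **Score**: ranks are computed jointly over all non-missing samples
   (both groups, midranks for ties) and
   $S = \sum_{j \in \text{flagged}} r_j / N$ where $N$ is the number of
   ranked samples. $S = 0$ exactly when nothing is flagged, and $S$ grows
   both with the number of flagged tumors and with how extreme they are.
4. Optionally, an empirical null: class labels are permuted, the cutoff
   is recomputed from each permuted "normal" group, and
   $p = (1 + \#\{S_{perm} \ge S_{obs}\})/(1 + B)$ (add-one estimator, so
   $p$ is never 0).

### Interpretation of the score scale

The score scale is implementation-defined: different members of the
outlier-statistic family normalize ranks differently, and published
per-gene scores from other implementations (or cutoffs such as a
published 13.2) do not transfer. What is stable, and what this package's
tests assert, is *ranking behavior*: genes with planted heterogeneous
signal outrank null genes, adding flagged samples at the top ranks never
decreases $S$, raising $\delta$ never increases it, and the score is
invariant to sample order within groups. Selection therefore supports
both an explicit score cutoff and a `top_k` rule (ties at the k-th score
included).

### Choices where the design was open

- **Floor semantics.** "Minimum change" could be read pairwise between
  samples or as a floor on the cutoff. We implement it as a floor on the
  distance of the cutoff from the normal median, which makes every called
  outlier differ from a typical normal by at least $\delta$; the pairwise
  reading has no single-gene formulation that composes with a rank
  statistic.
- **Ranking population.** Ranks are computed over all samples (tumor and
  normal jointly), not tumors alone, so that the same statistic covers
  left- and right-tail screens symmetrically.
- **Zero-score genes are never selected.** A gene with no outlier
  samples carries no evidence. Under a tie-inclusive `top_k` rule this
  also prevents a degenerate outcome on realistic data, where the large
  block of genes tied at score 0 would otherwise be swallowed into the
  selection.
- **Missing β-values** are excluded from that gene's ranks and from $N$;
  no imputation. A sample missing in either matrix is likewise dropped
  from that gene's methylation-expression correlation.

## Integration with expression

Promoter methylation that silences a gene should anti-correlate with its
expression. The filter retains candidates with Spearman $\rho < 0$
(strictly; $\rho = 0$ is dropped). No p-value ceiling is applied by
default — the sign rule matches how such candidate tables are typically
constructed, where raw p-values are reported but not thresholded — and an
optional `max_p` argument tightens it. $\rho$ is computed as the Pearson
correlation of midranks; p-values use the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, with an exact permutation option for
$n \le 9$. Group tests are two-sided Welch t-tests (unequal group sizes
and variances are the norm in tumor/normal designs); the degenerate
both-groups-constant case reports statistic 0, p = 1 rather than
erroring. Comparisons can be stratified by HPV status (positive at
$\ge 1$ viral copy per genome per cell, inclusive), and a Fisher exact
test on outlier *presence* (outlier/non-outlier × tumor/normal) covers
genes whose heterogeneous signal a t-test misses. No multiple-testing
correction is applied by default; a Benjamini–Hochberg column is
available as clearly-auxiliary output.

## Diagnostic evaluation

QMSP measures a methylation-specific target against a
methylation-independent β-actin loading control. The standard-curve
method interpolates quantity from Ct through a fitted line
$Ct = m\,\log_{10}(q) + b$; Ct values past 38 cycles (or undetermined)
are censored to quantity zero — late amplification is treated as
false-positive signal. The relative level is $100\,q_{target}/q_{actin}$;
a sample whose β-actin failed is *invalid* and excluded from all
denominators (it is not a negative). Detection is dichotomized at zero,
and a marker panel is positive if any member is (OR rule) — which can
only gain sensitivity and lose specificity, a property the tests verify.

Statistical conventions, each chosen where the field has several:

- **Exact binomial CIs** are Clopper–Pearson via the inverse incomplete
  beta. At 35/35 the lower bound is 90.0%; published tables sometimes
  print 89.9% for the same quantity (a rounding/method artifact of other
  software), so comparisons in the tests are at one decimal place.
- **Fisher's exact test** (two-sided) uses the minimum-likelihood rule —
  the sum of hypergeometric probabilities of all tables with the observed
  margins no more probable than the observed one (relative tolerance
  `1e-7`) — which is also what `stats::fisher.test` computes; our
  enumeration is tested against it as an independent oracle.
- **Cohen's κ** uses $\kappa = (p_o - p_e)/(1 - p_e)$ with the full
  Fleiss–Cohen–Everitt large-sample standard error for its CI. On 2×2
  concordance tables reconstructed from published marginals this SE
  reproduces all four published intervals to two decimals, where the
  cruder $\sqrt{p_o(1-p_o)}/((1-p_e)\sqrt{N})$ form does not. κ is
  undefined when $p_e = 1$; the evaluation reports `NA` there instead of
  a silent 0.
- **Paired concordance** (tissue vs saliva) is computed per patient —
  pairing is by `patient_id`, never by sample id — with κ, percent
  agreement and Spearman on the continuous relative levels (binary calls
  would discard the quantitative signal; a tie-rich binary-like input
  still works through midranks).
- **2^-ΔΔCt** expression uses the arithmetic mean of the reference Cts
  when two reference genes are supplied, the standard practice when no
  combination rule is stated.
- `reconstruct_paired_table()` inverts published concordance summaries
  (n, both positives counts, agreement %) into the unique nonnegative
  integer 2×2 table, enabling exact reproduction of published κ values
  from printed marginals.

## The synthetic-data generator

`generate_discovery_cohort()` encodes the world the screen assumes:

- Normals (and unaffected tumors) draw β from a clipped Gaussian with
  mean 0.03 and SD 0.02, so per-gene normal means stay at or below ~0.06
  — the "quiet normal" regime in which absolute specificity is possible.
  A moment-matched Beta option exists (`beta_noise = "beta"`); only the
  outlier geometry matters to the rank statistic, so the clipped Gaussian
  default keeps moments directly controllable.
- Each signal gene shifts a Bernoulli($f = 0.3$) subset of the 44 tumors
  by $\Delta\beta = 0.3$, attenuated ×0.5 in the ~30% of tumors marked
  HPV-positive (hypermethylation concentrates in HPV-negative disease).
- Expression is $8 - 5\beta + \mathcal N(0, 1)$: anti-coupled with slope
  −5 per unit β, unit noise, on a log-like scale.

`generate_validation_assay()` encodes the validation world: 59 cases with
paired tissue and saliva, 35 saliva / 31 tissue controls, per-gene tissue
positivity 44.1/39/32.2%, conditional saliva sensitivity 0.19/0.43/0.42,
and controls with *zero* signal (specificity is exactly 100% on every
seed by construction — a spec invariant, not a statistical outcome).
Positivity is **correlated across genes within a patient** through two
latent Gaussian factors: `patient_correlation = 0.7` for tissue
(calibrated a priori so the implied any-marker tissue rate matches the
observed ~58% rather than the ~77% independence would give) and
`saliva_correlation = 0.9` for the conditional saliva events (saliva
shedding is largely a patient property; the observed any-marker saliva
rate is far below the independence prediction). Positive relative levels
are log-normal (median 5, sdlog 0.8, truncated below 0.5 so every
planted positive stays inside the 38-cycle detection window), and Ct
values are back-computed through a fixed standard curve (slope −3.3,
intercept 36.5) so quantification round-trips exactly.

### What a green test does and does not establish

The generator produces clean, well-separated signal: no batch effects,
no probe-level chemistry, no cellular heterogeneity, no borderline
β-values near the cutoff, and controls that are *exactly* negative.
Green tests therefore establish that the statistics are computed
correctly and that the pipeline recovers the structure it assumes; they
do not establish field performance on real arrays or real salivary
rinses, where contamination, partial methylation and assay noise erode
both the 100%-specificity regime and the planted-outlier geometry.

## Numerical and operational choices

- Quantiles: type 7 everywhere; midranks for all ties; strict
  inequalities at every dichotomization boundary (outlier cutoff, level
  > 0, ρ < 0).
- Matrices are tab-delimited, '.' decimal separator, UTF-8, LF newlines,
  `NA` for missing (never 0 — a β of 0 and a relative level of 0 are
  meaningful measurements), so round trips are byte-stable and reruns of
  the pipeline with the same seed are byte-identical.
- All randomness flows from a single integer seed; outputs embed the
  seed and an md5 hash of the scientific (path-independent) part of the
  run config.
- The pipeline writes stage outputs eagerly: a failure in the
  integration stage (e.g. missing expression matrix) still leaves the
  screening TSV on disk, and the error condition names the failing
  stage.

## Known limitations

- The outlier score's absolute scale is not comparable to other
  implementations of the family; only rankings are.
- The exact-permutation Spearman p is limited to $n \le 9$ (factorial
  enumeration).
- Expression matrices must already be normalized, one row per gene;
  probe-to-gene mapping beyond a two-column map, and array
  normalization, are out of scope.
- The κ CI is asymptotic; for very sparse 2×2 tables it can exceed
  [−1, 1] and should be read with care.
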