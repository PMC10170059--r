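---
title: "Models and methods behind refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

`refstab` covers the full path from a transcriptome-wide expression matrix
to a validated RT-qPCR reference-gene panel: a coefficient-of-variation
screen on log2(TPM), four Ct-based stability statistics, their
geometric-mean aggregation, and a linear calibration between expression and
quantification cycle. This vignette documents the models, the numerical
decisions, and what the synthetic-data tests do and do not demonstrate.

## The CV screen

TPM is a within-sample-normalized unit, so between-condition comparisons of
the same gene are meaningful. Replicates are averaged **on the TPM scale**
within each condition (`collapse_replicates()`), making the condition —
stage, tissue, or timepoint — the unit of variation; replicate-level
technical noise is deliberately not counted as instability. Per gene the
screen computes, across conditions,

- μ = mean log2(TPM),
- SD = sample standard deviation of log2(TPM) (n − 1 denominator, the
  spreadsheet convention),
- CV = SD / μ,

and passes genes with μ > 5, SD < 1, CV < 0.2 (all strict). The μ filter
removes genes too weakly expressed for reliable qPCR detection; the SD
filter caps absolute variation; the CV cut-off of 0.2 is the conventional
threshold for calling expression stable across heterogeneous genes. A gene
sitting exactly on a cut-off is excluded: the exclusion rule for expression
is stated as "≤ 5", and we treat the SD/CV boundaries symmetrically since
boundary genes are ambiguous anyway. `excluded_reason` records the first
failing filter in the order low-expression → high-SD → high-CV.

**Zero TPM.** CV on the log scale is undefined when any TPM ≤ 0. Such genes
are flagged `nonpositive_tpm` and excluded rather than rescued with a
pseudocount: a usable reference gene must be detectably expressed in every
condition, and a pseudocount distorts SD and CV precisely in the low
expression range where the cut-offs operate. A consequence worth noting: if
the original data were processed with a pseudocount, candidate counts will
differ near the thresholds, so exact reproduction of any particular
dataset's candidate totals is not promised.

Candidates are ranked by ascending CV with lexicographic gene-id
tie-breaking (determinism; CV ties are rare and scientifically
interchangeable). `intersect_candidates()` reports both exclusive Venn
regions and total intersection sizes for 2–3 labelled candidate sets.

## Relative quantities

The Ct-based methods that work on expression ratios need relative
quantities Q = E^(minCt − Ct), with E the amplification efficiency per
cycle. E defaults to 2 (perfect doubling) because per-primer efficiencies
are rarely reported alongside panel data; it is configurable wherever used.
Each gene is calibrated to its own minimum Ct, so max(Q) = 1 per gene —
geNorm's statistics are invariant to this per-gene scaling, which is
asserted as a test property.

## The four stability statistics

**geNorm.** M_j = mean over partners k ≠ j of SD_samples(log2(Q_j/Q_k)).
Stable pairs keep constant ratios, so low M is stable. The least stable
gene (highest M, ties broken by removing the lexicographically last id) is
excluded and M recomputed until two genes remain; these two are reported as
tied ranks 1.5/1.5, since the method cannot order its final pair — the tie
propagates honestly into rank aggregation. V(n→n+1) =
SD_samples(log2(NF_n/NF_{n+1})), NF_n being the per-sample geometric mean
of the n most stable genes' quantities, is reported for judging panel size
but not thresholded (the common V < 0.15 rule is a reporting convention,
not a decision this package takes).

**NormFinder.** Log-scale data y (one Ct unit = one log2(E) unit) are
modelled as gene + sample (+ gene-by-group) effects with gene-specific
residual variance σ²_g. With G genes and n samples, the residual mean
square of the two-way fit satisfies E[s²_g] = σ²_g(G − 2)/G + mean(σ²)/G,
so the package uses the unbiased estimator

σ̂²_g = G/(G − 2) · (s²_g − mean(s²)/(G − 1)), floored at 0.

In grouped mode the per-group estimates are pooled (weights n_k − 1), the
intergroup deviation d_gk is taken on sample-centred data (each gene's
group mean minus its grand mean), and the variance of true deviations γ²
is estimated by moments: mean(d²) minus its sampling contribution
mean(σ̂²/n), floored at 0. Deviations are shrunk by γ²/(γ² + σ̂²_g/n_k) —
a noisy deviation estimate from a high-variance gene is discounted — and
the stability value is

ρ_g = mean over groups of ( |d̃_gk| + σ̂_g/√n_k ),

combining systematic between-group deviation with within-group noise.
Adding the intragroup term directly (rather than a posterior SD of d̃)
keeps the ranking informative in the boundary case γ̂² = 0, where pure
shrinkage algebra would send every gene's score to zero and destroy the
ordering; the 0/0 shrinkage arising when a floored σ̂² meets γ̂² = 0 is
defined as no shrinkage needed (d̃ = 0). Ungrouped mode reports ρ_g = σ̂_g
from the same bias-corrected estimator. Grouped mode requires ≥ 2 groups
with ≥ 2 samples each and ≥ 3 genes (the bias correction needs G ≥ 3).

**BestKeeper.** Descriptive statistics on raw Ct: arithmetic and geometric
mean, min, max, SD(Ct), CV% = 100·SD/mean; the BestKeeper index is the
per-sample geometric mean of Ct over the panel, and each gene's Pearson r
against the index is reported with a two-sided t-test p (n − 2 df). The
primary ranking key is SD(Ct) — the tool's headline statistic — with r
reported but not ranked on, and SD(Ct) > 1 flagged `inconsistent`. A
zero-variance gene has undefined r (reported `NA`) and ranks by SD alone.

**ΔCt.** score_j = mean over k ≠ j of SD_samples(Ct_j − Ct_k); ascending.
The full pairwise SD table (symmetric, zero diagonal) is returned.

Missing Ct is handled complete-case per analysis with an explicit warning
naming the dropped genes; qPCR panels are far too small for imputation to
be verifiable.

## Comprehensive ranking

The four methods measure different things and disagree in detail; the
consensus is the geometric mean of rank positions, GM = (r₁r₂r₃r₄)^¼,
ascending — the convention popularized by RefFinder-style tools. Ranks, not
raw stability values, are aggregated: the four scores live on incompatible
scales (M values, model SDs, Ct SDs), and a geometric mean over them would
be dominated by whichever scale is largest. Within-method ties carry
average ranks so the GM stays well defined; exact GM ties are broken by the
ΔCt rank and then gene id for a deterministic output.

## The Ct calibration

`fit_tpm_ct()` is ordinary least squares of Ct on log2(TPM) via
`stats::lm`, reporting slope, intercept, R², and the regression F-test
p-value on (1, n − 2) df — in simple regression identical to the two-sided
slope t-test, and the "ANOVA of the regression" in the classical sense. R²
equals the squared Pearson correlation (asserted as a test identity).
`predict_ct()` applies β₀ + β₁·log2(TPM) for TPM > 0. One global line is
fitted across genes, not per-gene calibration curves: the cross-gene
relation is what lets Ct be anticipated before designing a qPCR assay,
and it is intentionally weak — expression level explains only part of Ct
variation across genes (primer efficiency, amplicon properties and probe
chemistry contribute the rest), which is why the fitted line's residual
noise is large.

## The synthetic generator

`synthetic_spec()` describes the statistical structure the analysis
assumes, with all randomness flowing from one integer seed:

| parameter | default | meaning |
|---|---|---|
| n_genes / n_conditions / n_replicates | 2000 / 12 / 3 | developmental-series-scale design |
| fraction_stable | 0.1 | minority of genes with low log-scale variance |
| stable_sd_range | 0.01–0.15 | per-condition log2 SD of stable genes |
| unstable_sd_range | 1.2–3.0 | condition-dependent expression shifts |
| mean_log2tpm_range | 6–18 | per-gene mean expression (all detectable) |
| replicate_noise_sd | 0.1 | log2 technical noise within a condition |
| ct_slope / ct_intercept | −0.5405 / 34.51 | generating calibration line |
| ct_noise_sd | 2.5 | Ct noise around the line |

Expression noise is log-normal (Normal on log2) because the entire analysis
operates on log2(TPM). The stable SD ceiling of 0.15 sits comfortably under
both cut-offs for any mean above 5, so stable genes pass screening by
construction; 12 conditions give the SD < 1 filter enough degrees of
freedom that genes with true SD ≥ 1.2 are excluded with high probability
(the residual false-pass rate, ~3%, is the sampling tail of the SD
estimate, and the screening specificity of ~0.97 follows from it — both
are verified against the analytic chi-square expectation in the tests).
Ct is generated from the global linear model plus independent Gaussian
noise — the only expression–Ct link the workflow quantifies — with optional
per-gene noise overrides (to inject poorly behaving panel genes) and
per-group shifts (to exercise grouped NormFinder). The Ct noise SD of 2.5
is a tuning choice reflecting how weak the global cross-gene line is in
practice, not a measured value.

What the generator does **not** emulate: sequencing-depth and library-size
effects (TPM is taken as given), count-level sampling noise at low
expression, correlated co-regulation between genes, primer-specific
amplification efficiencies, and batch structure. Passing the end-to-end
tests therefore demonstrates that the statistics and their implementations
recover truth under the assumed log-normal model — not that the screen's
thresholds are optimal for any particular real dataset.

## Problem sizes in the test-suite and acceptance script

The suite verifies oracle equivalence on hundreds of randomized panels of
up to 10 genes × 10 samples (tolerance 1e-10, sufficient for double
precision through these O(G²) computations), truth-label recovery on 20
seeds of the default 2000-gene design, panel-noise recovery on 100 seeds of
a 10-gene panel, and calibration recovery on 5000 simulated pairs — sizes
chosen so each property is measured with comfortable Monte-Carlo margin on
a desk machine. The acceptance script refits the calibration on 5000 pairs
(500 genes × 10 conditions) and reports the recovered intercept.

## Known limitations

- The screen's candidate counts depend on the zero-TPM policy and the
  strictness convention at the cut-offs; datasets processed with
  pseudocounts will not match exactly.
- geNorm's final pair is inherently unordered; downstream consumers must
  accept tied ranks 1.5.
- NormFinder's grouped estimates are noisy below ~4 genes or 2 samples per
  group; the preconditions guard the worst cases but small panels remain
  small.
- BestKeeper's ranking-by-SD convention ignores r; a gene tracking the
  index badly but with small SD still ranks well, as in the original tool.
- The calibration is a single global line; per-gene prediction error is
  large by design and the model should not be used to compare two specific
  genes' Ct.
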