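---
title: "Methods: integrated promoter methylation and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated promoter methylation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methex)
library(dplyr)
```

## The analysis

methex implements an integrated analysis of promoter DNA methylation and
mRNA/lncRNA expression for small two-group cohorts, of the kind used to
screen epigenetically silenced or activated markers in ulcerative colitis
(UC) versus healthy colon. The chain is:

1. **Promoters.** Each gene's promoter is the strand-relative interval from
   1500 bp upstream to 500 bp downstream of its TSS (0-based half-open).
2. **CpG-density classes.** Every 500-bp window of the promoter sequence is
   scored by its observed/expected CpG ratio, `(#CpG × L) / (#C × #G)`, and
   GC fraction. A promoter is an **HCP** if some window has ratio > 0.75 and
   GC > 0.55, an **LCP** if no window has ratio > 0.48, else an **ICP**. All
   comparisons are strict, so the classes partition the input and an
   HCP-qualifying window (ratio > 0.75 > 0.48) always defeats the LCP rule.
3. **Differential expression.** Intensities are quantile normalized, then
   each feature gets an equal-variance two-sample t-test on log2 values with
   Benjamini–Hochberg adjustment, run separately for mRNAs and lncRNAs. A
   feature is differentially expressed iff `|log2FC| > 1` **and**
   `FDR < 0.05`, both strict.
4. **Differential promoter methylation.** Promoter methylation in a sample
   is the arithmetic mean beta over the promoter's CpG sites (skipping
   missing values). Promoters are ranked by the signed two-sample
   t-statistic (case − control) and the extreme 5% tails are called:
   high tail *hyper*-methylated, low tail *hypo*-methylated. This is a
   rank-based definition — it always calls `2k` promoters per stratum,
   whatever the effect sizes.
5. **Integration.** Candidate markers are features that are differentially
   expressed, carry a DMP call, and are direction-concordant with
   promoter-mediated repression: up-regulated/hypo-methylated or
   down-regulated/hyper-methylated. No other combination can appear.
6. **Network.** All candidate lncRNA × candidate mRNA pairs are tested for
   Pearson correlation across the shared expression samples; pairs with
   r > 0.98 (signed; strict) and p < 0.01 become edges of a bipartite
   co-expression graph, and nodes are ranked by degree to find hubs.
7. **Diagnostics.** Hub mRNA expression is fed to a maximum-likelihood
   logistic model (hand-rolled IRLS); performance is measured by ROC/AUC on
   an independent test cohort. A `2^-ddCt` helper covers qRT-PCR style
   relative quantification against a housekeeping reference.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `upstream`/`downstream` | 1500 / 500 bp | promoter extent around the TSS |
| `window` | 500 bp | CpG-class scan window |
| `hcp_ratio`, `hcp_gc`, `lcp_ratio` | 0.75, 0.55, 0.48 | class thresholds (strict) |
| `step` | 1 bp | scan step; exhaustive by default |
| `lfc_cut`, `fdr_cut` | 1, 0.05 | DE thresholds (strict) |
| `tail_fraction` | 0.05 | DMP tail at each extreme |
| `r_cut`, `p_cut` | 0.98, 0.01 | co-expression edge thresholds (strict) |

Interpretive notes on choices the published rule set leaves open:

* **CpG ratio formula.** Only the thresholds are given in the rule set; the
  observed/expected form above is the standard one on which 0.75/0.48 are
  meaningful, so it is adopted and documented.
* **Window step.** "Contains at least one 500-bp region" is an existential
  claim, so the scan is exhaustive (step 1); a coarser step is available for
  speed and agrees with step 1 on ≥ 99% of synthetic promoters.
* **Strand.** The forward-strand reference sequence of the interval is
  scanned; CpG is strand-symmetric so no reverse-complement pass is needed.
  `N` bases count toward window length only.
* **Quantile vs quartile.** "Quartile normalized" is read as quantile
  normalization (standard array practice); an upper-quartile (75th
  percentile) scaling is available via `method = "upper_quartile"`.
* **Moderated statistics.** The t-test is deliberately plain rather than an
  empirical-Bayes moderated test. At n = 3 vs 3 a moderated test is more
  powerful; the plain test keeps the pipeline self-contained and its
  behaviour analytically transparent, and the caveat is surfaced here rather
  than hidden.
* **DMP tail size.** `k = round_half_up(tail_fraction × n)`, symmetric for
  both tails, ranked separately within mRNA- and lncRNA-gene promoters by
  the signed t-statistic (`stat = "delta_beta"` is available). Published
  per-class tallies of this design are internally inconsistent with any
  single symmetric rounding rule, so the rule here is explicit and
  configurable rather than reverse-engineered.
* **Signed correlation.** "Correlation above 0.98" is read literally as
  signed r > 0.98 (positive co-expression); `absolute = TRUE` switches to
  |r|. With 6 samples, r > 0.98 implies p ≈ 6e-4 < 0.01, so the r threshold
  dominates the joint filter.
* **Diagnostic score scale.** ROC curves are computed on the linear
  predictor rather than the response probability: the two orderings are
  identical mathematically, but with separation-scale coefficients
  `plogis()` saturates to exactly 0/1 in double precision and destroys the
  ranking on shifted test data.

## The synthetic cohort generator

Every stage is exercised on synthetic cohorts with known planted structure
(`simulate_cohort()`), emulating the data shape of a small UC methylation +
expression study: a 3 vs 3 two-colour-array-style expression cohort, a
3 control vs 8 disease 450k-style methylation cohort, beta values in [0, 1]
per CpG site mapped to promoters, and log-scale intensities whose planted
fold changes are anti-correlated with planted promoter methylation shifts.

Design, chosen once and kept fixed:

* **Layout.** One synthetic chromosome; 2-kb promoters tiled with ≥ 1-kb
  gaps (no overlap ambiguity); strands alternate.
* **Class-targeted sequences.** Compositional generators per class (CpG-rich
  island throughout for HCP; CpG-depleted AT-rich for LCP, with ~10% of
  random-composition CpGs retained so LCP promoters still have measurable
  sites; one moderate 500-bp island on CpG-poor background for ICP), each
  followed by a classify-and-resample check so the truth class is exact by
  construction. Default class mix 10/25/65% HCP/ICP/LCP, close to the
  LCP-heavy proportions of genome-wide annotation.
* **Methylation.** Site betas are Beta-distributed around class-typical
  baselines (HCP 0.15, ICP 0.50, LCP 0.80 — high-CpG promoters are the
  least methylated) with concentration 50; bounded support is the reason for
  the Beta noise model. Planted genes are drawn from the ICP pool so the
  ±0.3 shift in the disease group stays well inside (0, 1).
* **Expression.** Gene baselines uniform on log2 [6, 12], within-group sd
  0.15 (typical array replicate noise); planted genes shift ±2 log2 units,
  up for hypo-methylated and down for hyper-methylated promoters (4 and 3
  genes per biotype by default).
* **Co-expression edges.** Each planted edge pairs a planted lncRNA with a
  same-direction planted mRNA; the lncRNA profile is the partner's profile
  re-centred at its own baseline plus N(0, 0.05) noise. At n = 6 this pins
  the sample correlation above 0.98 with high probability. An optional
  per-pair shared latent factor (`coexpr_latent_sd`) carries the pair
  correlation when no group effect is planted.
* **Seeding.** One root seed; every stage derives its own RNG stream by a
  fixed offset, so fixtures are byte-identical across runs and stages can be
  re-drawn independently (e.g. fresh methylation noise over a fixed gene
  set).

What the generator does **not** emulate: Infinium type I/II probe chemistry,
batch effects, realistic chromosome structure, cross-platform differences,
and the correlation structure of real co-regulated transcriptomes. Passing
tests therefore demonstrate that the *procedures* are implemented correctly
and recover planted structure under clean conditions — not that the pipeline
is robust to the messiness of real array data.

One consequence of a realistic two-group design is worth stating explicitly:
in a cohort with planted group effects, *every* pair of same-direction
differential genes is genuinely correlated through the shared group
indicator (at effect 2 and sd 0.15 the shared variance dominates), so edges
between non-partnered candidates in a full pipeline run are real
co-expression, not false positives of the edge filter. The false-positive
behaviour of the filter is therefore measured on a dedicated planted-edge
fixture with no group effects (`expr_log2fc_effect = 0`,
`coexpr_latent_sd = 1`), where null pairs are exactly independent; there the
spurious-edge rate is ~0.02% against planted retention above 99%.

## Verification strategy and problem sizes

The test suite checks each fast path against an independent brute-force
oracle: the vectorised window scan against a substring-by-substring rescan,
quantile normalization against sort-and-average, DMP tails against a full
independent sort of per-promoter `t.test()` statistics, AUC against the
O(n²) pairwise count (and pROC), network degrees against an edge-list
recount, and the IRLS fit against `glm()` plus a likelihood grid.

Monte-Carlo recovery checks run at deliberately modest sizes so the whole
suite stays fast: 240-gene cohorts for promoter-class fidelity and DMP
recovery (20 methylation redraws over a fixed gene set), 100-gene cohorts
over 50 seeds for edge retention, default 240-gene cohorts over 50 seeds for
DE top-ranking, and 30 train/test pairs of 10 + 10 samples with three
informative genes (effect 1.0, sd 0.5) for the diagnostic AUC — sized so the
logistic fit usually converges rather than separating, which a 3 vs 3 cohort
with strong effects almost surely does. Separation is still exercised and
flagged (`converged = FALSE` with a warning), with predictions retained for
ranking.

## Degenerate inputs and tie-breaks

* Zero-variance features: equal group means give t = 0, p = 1; unequal
  means with zero pooled variance give ±Inf and p = 0.
* DMP ties on the ranking statistic break by larger |Δβ|, then gene id;
  tail calling needs ≥ 20 promoters per stratum.
* Sites overlapping two promoters count for both; promoters with no sites
  are excluded from methylation analysis with a message; a promoter is
  dropped only when a whole group's mean is missing.
* Perfectly correlated pairs (|r| = 1) get p = 0 by convention;
  zero-variance candidates are skipped with a message.
* ROC ties contribute one half; the AUC equals the trapezoidal area of the
  step curve to machine precision.

## Known limitations

The plain t-test is anti-conservative relative to moderated alternatives at
n = 3; the rank-based DMP definition guarantees calls even in pure noise (by
design — it mirrors the screening rule it implements); hub identity and
published headline counts depend on the original study's annotation and
cohorts and are out of scope; and the diagnostic model is evaluated on
synthetic cohorts drawn from a shared truth, not on cross-platform external
validation sets.
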