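---
title: "Methods: translational efficiency and regulation from polysome pools"
author: "polysomeTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational efficiency and regulation from polysome pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysomeTE)
```

## The experimental design this package models

A translational profiling experiment separates cytoplasmic mRNA on a
sucrose gradient and combines the 20-odd fractions into three pools by
ribosomal content: pool 1 (no 28S rRNA, non-translated), pool 2
(intermediate) and pool 3 (ribosome-bound). Each biological replicate is
profiled in all three pools under both a glucocorticoid (GC) treatment and
its ethanol (EtOH) carrier control, giving a paired design; a typical study
has 2 cell lines × 2 treatments × 3 pools × 3 replicates = 36 arrays, with
log2 expression values on a [0, 16] scale. The `PoolProfileSet` class (a
`SummarizedExperiment` with a `cell_line`/`treatment`/`pool`/`replicate`
column design) enforces this structure: validity requires, per
(cell line, replicate), all three pools under both treatments. Analyses are
run separately per cell line, because representative-transcript choices and
expression filters are cell-line specific.

Because pooling discards the fraction-level resolution, the design
interrogates translation initiation (the rate-limiting, most commonly
regulated step); elongation or termination effects are invisible to it.

## Relative expression and translational efficiency

All downstream quantities derive from the linear-scale proportion of a
gene's mRNA per pool. For log2 intensities $E_1, E_2, E_3$:

$$RE_i = \frac{2^{E_i}}{2^{E_1} + 2^{E_2} + 2^{E_3}}.$$

We define RE this way because it is the only form that yields a composition
(values in $[0,1]$ summing to 1, interpretable as the percentage of mRNA
per pool) and is invariant to array-wide additive shifts on the log2 scale,
so any common normalization offset cancels. RE in pool 3 is the
translational efficiency (TE). RE is computed **per replicate and then
averaged** (arithmetically) rather than averaging expression first: the
per-replicate compositions are the experimental unit, and their mean is
what a per-gene summary table should report. `summarizeTE()` pools
per-replicate TE values (optionally across treatments and cell lines) into
a mean with a two-sided 95 % t-interval on $n-1$ df.

The implementation subtracts the per-gene maximum before exponentiating,
so the proportions are stable for any representable log2 values.

## Pre-processing

Two steps reduce transcript-level arrays to analysable genes:

* **Representative transcript per gene** (`selectRepresentative`): strict
  lexicographic priority — protein-coding biotype first, then more than 3
  probes, then highest mean expression over all arrays, final ties broken
  by smallest transcript id. We read the stated preference order as
  lexicographic rather than a combined score because the criteria are
  qualitatively heterogeneous (a biotype, a probe-count cutoff, a
  continuous mean); a weighted score would need arbitrary weights. The
  id tie-break makes the choice deterministic and order-invariant.
* **Expressed-gene filter** (`filterExpressed`): a gene is kept if its
  replicate-averaged log2 expression exceeds 3 (default, the conventional
  detection floor on this scale) in at least one (pool, treatment). The
  filter is applied to replicate means rather than to single replicates:
  one noisy replicate should neither rescue nor kill a gene. The filter is
  idempotent and order-preserving.

## Translational regulation and the moderated test

Per condition, total mRNA is the log2 linear-scale mean across pools,
$T = \log_2((2^{E_1}+2^{E_2}+2^{E_3})/3)$ — linear because pools partition
physical mRNA, so their amounts add on the linear scale, consistent with
the RE definition. (The arithmetic mean of log2 values is available as
`scale = "log"` for comparison, since either convention appears in
practice; with it, `trans_reg` becomes the pool-3 change minus the average
pool change.) Per paired replicate,

$$\text{txn\_reg} = T_{GC} - T_{EtOH}, \qquad
  \text{trans\_reg} = (E_{3,GC} - E_{3,EtOH}) - \text{txn\_reg}.$$

`trans_reg` is invariant to replicate-wide additive shifts and is zero
when a treatment scales all pools equally — it isolates redistribution
between bound and unbound pools.

The per-gene `trans_reg` values (one per replicate, $n = 3$ typically) are
tested against zero with a one-sample empirical-Bayes moderated t-test.
With $d = n-1$ and per-gene variance $s^2$, the ensemble of variances is
modelled as $s^2 \sim s_0^2 F(d, d_0)$; matching the mean and variance of
$\log s^2$ (digamma/trigamma closed forms) gives $(\hat d_0, \hat
s_0^2)$, the posterior variance $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 +
d)$, $t = \bar x / (\tilde s/\sqrt n)$, and two-sided p-values on $d_0 + d$
df. We test each cell line's three per-replicate values separately
(one-sample, $n=3$) rather than fitting a joint two-group model: the
per-replicate pairing is already encoded in `trans_reg`, and per-cell-line
testing matches the cell-line-specific pre-processing.

Numerical choices:

* The trigamma inversion uses Newton iteration (relative tolerance
  $10^{-12}$); the unit tests verify agreement with an independently coded
  `uniroot`-based solver and with `limma::squeezeVar`.
* If the moment estimator diverges (log-variance spread at or below what
  sampling alone explains), $d_0$ is capped at $10^6$ — numerically
  indistinguishable from infinity while keeping the t-distribution df
  finite — and the result is flagged (`d0Capped`). An all-zero-variance
  matrix takes this path rather than erroring; genes with zero mean and
  zero posterior variance report $t = 0$.
* Forcing `d0 = 0` reproduces the ordinary one-sample t-test exactly;
  forcing `d0 = Inf` takes the exact fully pooled limit
  $t = \bar x \sqrt n / s_0$.
* BH adjustment implements the step-up rule directly in the textbook
  expression order, so adjusted values match a brute-force enumeration of
  the definition bit-for-bit; `stats::p.adjust` agrees to 1 ulp.

Two-sided p-values are used because the scientific question is whether
translational regulation differs from zero in either direction.

## Enrichment analyses

`lowTESelection` takes the bottom `ceiling(fraction * N)` genes by TE
(default 5 %), ties broken by gene id. `hypergeomEnrichment` scores each
gene set by the hypergeometric upper tail $P(X \ge k)$ after intersecting
the set with the background universe, and BH-adjusts across sets. Both raw
and adjusted p-values are reported, since adjustment across families is a
reporting choice we make explicit rather than silently impose.
`topMotifTest` compares TOP-motif genes against **all** expressed
protein-coding genes with a one-tailed Welch test (alternative: lower mean
TE). Comparing against all genes — overlap included — is the literal
protocol this analysis follows in the field, although it is statistically
unusual; `exclude_top = TRUE` gives the disjoint variant, and
`var_equal = TRUE` the pooled-variance Student test. Welch is the default
because nothing guarantees equal variances between a small motif group and
the genome-wide background.

## The synthetic data generator

`generateDataset(syntheticConfig(...))` emulates the study design with
known ground truth. Per gene: log2 total abundance $\sim N(7, 2^2)$; pool
composition $\pi$ from a Dirichlet prior, concentration $(2,2,2)$ for
protein-coding genes — making TE marginally Beta(2, 4): unimodal on (0,1),
mean 1/3, slight positive skew (sample skewness ≈ 0.46 at 5000 genes, as
the acceptance script measures), with realistic extremes (TE below 0.01
and above 0.9) — and $(6, 1.5, 0.75)$ for non-coding biotypes, which
concentrates them in the non-translated pool. The biotype mix defaults to
74 % protein-coding. Treatment effects are injected under GC only:
transcriptional effects multiply abundance by $2^{\text{txn\_effect}}$;
translational effects shift the log-odds of pool 3 versus pools 1+2 and
renormalize, which keeps $\pi$ a valid composition and maps directly onto
the pool-3-versus-total contrast the analysis tests. Observed values are
$\mathrm{clip}(\log_2(A\,\pi_p) + \varepsilon,\, 0,\, 16)$ with
$\varepsilon \sim N(0, 0.25^2)$ per array; GC/EtOH samples of the same
replicate index are paired. The replicate noise magnitude 0.25 log2 units
is a fixture choice (no published value constrains it), sized so that the
expression filter and the moderated test are both meaningfully exercised.
Abundance centred at 7 with sd 2 leaves a realistic minority of genes
below the detection floor, exercising the filter.

Randomness: gene-level draws (biotype, abundance, composition, regulation
flags) use a substream of the root seed that is independent of the
replicate and cell-line counts, so enlarging the design does not reshuffle
the truth; per-(cell line, replicate) noise uses separate derived seeds.
Identical configs are bit-reproducible.

What the generator does **not** emulate: fraction-level gradients, rRNA
contamination, probe-level intensities, array batch effects,
between-cell-line differences in truth (both simulated cell lines share
per-gene ground truth), or correlated noise across pools. Passing tests on
this generator therefore demonstrate the correctness and calibration of
the statistical machinery under idealized independent Gaussian log-scale
noise — not robustness to the full messiness of real microarray data.

`generateGeneSets` builds set fixtures whose "enriched" sets draw a
configurable fraction of members from the bottom-5 % true-TE tail,
providing a known ordering for the over-representation analysis.

## Problem sizes and measured operating characteristics

The test-suite and acceptance-script simulations use 800–5000 genes
(2000 for calibration runs, matching a desk-scale fraction of a
genome-wide study while leaving the variance-shrinkage ensemble large).
Under the default conditions the suite measures, among others: exact
agreement of the moderated test and BH adjustment with independent
oracles; zero false discoveries on null simulations (mean significant
fraction 0 over 20 seeds at FDR 5 %); sensitivity ≈ 0.84–0.98 for a 1.5
log-odds effect in 5 % of genes across the two-cell-line design; and a
correlation of ≈ 0.89 between the estimated mean translational regulation
and the realized noise-free effect. That correlation is noise-limited: with
per-array noise 0.25 and six paired experiments, the estimator variance
(~0.014) is an appreciable fraction of the injected signal variance
(~0.05), which bounds attainable recovery near 0.89 regardless of gene
count.

## Known limitations

* The pooled 3-fraction design cannot see elongation/termination control,
  and mRNA-destabilizing repression (the dominant miRNA mode) lowers all
  pools equally, so it leaves TE unchanged.
* TE is a composition, not a rate: it estimates ribosome association, not
  protein output.
* The moderated test assumes exchangeable per-gene variances on a common
  F-ensemble; strong variance-expression trends would call for a
  trend-aware variant, which this package deliberately does not implement.
* GEO series-matrix input is supported as a raw matrix plus user-supplied
  design; no sample-metadata inference is attempted, and accession-based
  comparisons should allow for the (unstated) numeric precision of
  deposited matrices.
* The top-fraction biotype summary defaults to the first treatment present;
  which treatment a study displays is a presentation choice, so it is
  exposed as an argument rather than fixed.
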