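# polysomeTE

Translational efficiency and translational regulation from polysome-pool
expression profiles.

## The problem

In translational profiling, cytoplasmic mRNA is separated on a sucrose
gradient by the number of bound ribosomes and the fractions are combined
into three pools — non-translated (pool 1), intermediate (pool 2) and
ribosome-bound (pool 3) — which are then expression-profiled. For lymphoid
cells treated with glucocorticoids (GC) versus an ethanol carrier control
(EtOH) in a paired design (several biological replicates, each profiled in
all three pools under both treatments), two questions arise:

1. How efficiently is each gene translated — what fraction of its mRNA is
   ribosome-bound?
2. Does the treatment shift mRNAs between the bound and unbound pools,
   i.e. regulate translation, beyond its effect on total mRNA levels?

`polysomeTE` implements this analysis for anyone working with pooled
polysome-fraction expression matrices, together with a ground-truth
synthetic data generator so the whole pipeline is testable without any
external data.

## The statistics

With `E_i` the log2 expression of a gene in pool `i`, the **relative
expression** in pool `i` is the linear-scale proportion

    RE_i = 2^E_i / (2^E_1 + 2^E_2 + 2^E_3),

the fraction of the gene's mRNA in that pool. RE in pool 3 is the
**translational efficiency** (TE). RE is computed per replicate and then
averaged across replicates.

The **total mRNA** level of a condition is the log2 linear-scale mean
across pools, `T = log2((2^E1 + 2^E2 + 2^E3)/3)`. Per paired replicate,
**transcriptional regulation** is `ΔT = T_GC − T_EtOH` and **translational
regulation** is

    trans_reg = (E3_GC − E3_EtOH) − ΔT,

the change in ribosome-bound mRNA beyond the change in total mRNA. Each
gene's per-replicate `trans_reg` values are tested against zero with an
empirical-Bayes **moderated one-sample t-test**: per-gene variances `s²`
(d = n−1 df) are shrunk toward a prior `(d0, s0²)` estimated from the
log-variance ensemble by digamma/trigamma moment matching,

    s̃² = (d0·s0² + d·s²) / (d0 + d),   t = mean / (s̃ / √n),

with p-values on `d0 + d` degrees of freedom, adjusted by
Benjamini–Hochberg step-up FDR control. Gene-set over-representation among
the lowest-TE genes uses the hypergeometric upper tail; TOP-motif genes are
compared against all expressed protein-coding genes with a one-tailed Welch
t-test.

## Worked example

Simulate one cell line of a paired 3-pool × 2-treatment × 3-replicate
design with a translational effect (+1.5 on the pool-3 log-odds) injected
into 5 % of 1000 genes, then run the analysis:

```r
library(polysomeTE)
cfg <- syntheticConfig(n_genes = 1000, seed = 7, cell_lines = "CL1",
                       frac_trans_regulated = 0.05, trans_effect_logodds = 1.5)
sim  <- generateDataset(cfg)
expr <- filterExpressed(sim$expression)   # drop genes below log2 expr 3
expr
#> PoolProfileSet with 942 genes, 18 samples
#>   cell lines: CL1
#>   treatments: GC, EtOH | pools:  1,2,3 | replicates: 1,2,3
#>   log2 expression range: [0, 16]

re <- relativeExpression(expr)
te <- translationalEfficiency(re, treatment = "EtOH")
round(summary(te), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.001   0.101   0.247   0.263   0.384   0.945
```

Most genes spread their mRNA over all pools (median TE 0.25); the most
efficiently translated gene keeps 94.5 % of its mRNA ribosome-bound, with a
tight t-based 95 % confidence interval across replicates:

```r
top <- names(which.max(te))
round(summarizeTE(perReplicateRE(re, genes = top)$RE3), 3)
#>  mean lower upper
#> 0.945 0.936 0.953
```

The moderated test recovers the injected translational regulation:

```r
fit <- moderatedOneSampleTest(transReg(regulationTable(expr)))
fit
#> ModeratedTestResult: 942 genes
#>   d0 = 8.743, s0^2 = 0.089, residual df = 2, total df = 10.74
#>   min adjusted p = 4.597e-05
res <- testResults(fit)
sum(res$adj.p < 0.05)
#> [1] 45
```

45 genes are called at FDR 5 %; 43 of them are truly regulated in the
generator's ground truth (`sim$truth`). On a null simulation (no injected
effects) the same pipeline calls nothing — the adjusted p-values stay far
from significance, reproducing in kind the negative result such designs
give when a treatment leaves translation untouched.

`runPipeline(runConfig(...))` orchestrates the full run (simulate or load,
filter, summary table, regulation test, enrichment) and writes TSV/JSON
artifacts per cell line.

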