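test_that("config validation catches inconsistent parameters", {
    expect_error(syntheticConfig(biotype_proportions = c(protein_coding = 0.5)),
                 "sum to 1")
    expect_error(syntheticConfig(frac_trans_regulated = 1.5), "\\[0, 1\\]")
    expect_error(syntheticConfig(expression_floor = 16,
                                 expression_ceiling = 3), "floor")
    expect_error(syntheticConfig(te_concentration = c(1, 2)), "numeric\\(3\\)")
})

test_that("generation is deterministic and gene-level draws are stable", {
    cfg <- syntheticConfig(n_genes = 40, seed = 11)
    a <- generateDataset(cfg)
    b <- generateDataset(cfg)
    expect_identical(SummarizedExperiment::assay(a$expression),
                     SummarizedExperiment::assay(b$expression))
    expect_identical(a$truth, b$truth)

    ## gene-level truth does not depend on the replicate or cell-line count
    cfg2 <- syntheticConfig(n_genes = 40, seed = 11, n_replicates = 5,
                            cell_lines = "X")
    c <- generateDataset(cfg2)
    expect_identical(a$truth, c$truth)
})

test_that("zero-noise data reproduce the true pool proportions exactly", {
    cfg <- syntheticConfig(n_genes = 300, seed = 21, noise_sd = 0,
                           cell_lines = "CL1")
    sim <- generateDataset(cfg)
    re <- relativeExpression(sim$expression)
    avg <- averagedRE(re, treatment = "EtOH")
    ## away from the clipping bounds in every pool
    mu <- outer(sim$truth$log2_abundance, rep(1, 3)) +
        log2(as.matrix(sim$truth[, c("pi1", "pi2", "pi3")]))
    unclipped <- rowSums(mu > 0 & mu < 16) == 3
    i <- match(sim$truth$gene_id[unclipped], avg$gene_id)
    expect_lt(max(abs(avg$RE3[i] - sim$truth$pi3[unclipped])), 1e-12)
    expect_lt(max(abs(avg$RE1[i] - sim$truth$pi1[unclipped])), 1e-12)
})

test_that("pool proportions stay a composition after effect injection", {
    cfg <- syntheticConfig(n_genes = 500, seed = 31,
                           frac_trans_regulated = 0.3,
                           trans_effect_logodds = 2,
                           frac_txn_regulated = 0.2)
    sim <- generateDataset(cfg)
    s <- with(sim$truth, pi1_gc + pi2_gc + pi3_gc)
    expect_lt(max(abs(s - 1)), 1e-9)
    expect_true(all(sim$truth[, c("pi1_gc", "pi2_gc", "pi3_gc")] > 0))
    ## unregulated genes keep their composition
    unreg <- !sim$truth$trans_regulated
    expect_identical(sim$truth$pi3[unreg], sim$truth$pi3_gc[unreg])
    expect_true(all(sim$truth$trans_effect[unreg] == 0))
})

test_that("with no injected effects the measured translational regulation is centred at zero", {
    cfg <- syntheticConfig(n_genes = 2000, seed = 7, cell_lines = "CL1")
    sim <- generateDataset(cfg)
    reg <- regulationTable(sim$expression)
    v <- as.numeric(transReg(reg))
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v)), 3 * se)
})

test_that("the default TE distribution is unimodal on (0,1) with positive skew", {
    cfg <- syntheticConfig(n_genes = 5000, seed = 13, cell_lines = "CL1")
    sim <- generateDataset(cfg)
    te <- sim$truth$pi3[sim$truth$biotype == "protein_coding"]
    expect_gt(sampleSkewness(te), 0)
    expect_true(all(te > 0 & te < 1))
    ## unimodality: histogram counts rise then fall (single peak) on a
    ## coarse grid
    h <- hist(te, breaks = seq(0, 1, by = 0.1), plot = FALSE)$counts
    peaks <- sum(diff(sign(diff(h))) == -2)
    expect_lte(peaks, 1)
    ## non-coding biotypes sit in pool 1
    nc <- sim$truth$biotype != "protein_coding"
    expect_gt(mean(sim$truth$pi1[nc]), mean(sim$truth$pi1[!nc]))
})

test_that("stronger injected log-odds shifts give larger measured TE differences", {
    measured_shift <- function(effect) {
        cfg <- syntheticConfig(n_genes = 800, seed = 17, cell_lines = "CL1",
                               frac_trans_regulated = 0.2,
                               trans_effect_logodds = effect)
        sim <- generateDataset(cfg)
        re <- relativeExpression(sim$expression)
        te_gc <- averagedRE(re, treatment = "GC")
        te_et <- averagedRE(re, treatment = "EtOH")
        reg <- sim$truth$trans_regulated
        i <- match(sim$truth$gene_id[reg], te_gc$gene_id)
        mean(te_gc$RE3[i] - te_et$RE3[i])
    }
    shifts <- vapply(c(0.5, 1, 1.5, 2), measured_shift, 0)
    expect_true(all(diff(shifts) > 0))
})

test_that("generated gene sets honour the enrichment contract", {
    cfg <- syntheticConfig(n_genes = 1000, seed = 19, cell_lines = "CL1")
    sim <- generateDataset(cfg)

    ## strength 1: every member of an enriched set is in the bottom-5% list
    sets1 <- generateGeneSets(sim$truth, n_sets = 4, enriched_set_size = 50,
                              enrichment_strength = 1, seed = 1,
                              n_enriched = 2)
    ord <- order(sim$truth$pi3, sim$truth$gene_id)
    low <- sim$truth$gene_id[ord[seq_len(ceiling(0.05 * 1000))]]
    expect_true(all(geneSets(sets1)$ENR001 %in% low))
    expect_true(all(geneSets(sets1)$ENR002 %in% low))

    ## determinism and size errors
    sets1b <- generateGeneSets(sim$truth, n_sets = 4, enriched_set_size = 50,
                               enrichment_strength = 1, seed = 1,
                               n_enriched = 2)
    expect_identical(geneSets(sets1), geneSets(sets1b))
    expect_error(generateGeneSets(sim$truth, enriched_set_size = 2000),
                 "exceeds")
})

test_that("unenriched random sets give approximately uniform hypergeometric p-values", {
    ## a configuration dense enough that the discrete null p-values are
    ## close to uniform: 4000 genes, 400-member sets, 200-gene selection
    cfg <- syntheticConfig(n_genes = 4000, seed = 23, cell_lines = "CL1")
    sim <- generateDataset(cfg)
    sets <- generateGeneSets(sim$truth, n_sets = 200,
                             enriched_set_size = 400,
                             enrichment_strength = 0, seed = 2,
                             n_enriched = 0)
    bg <- sim$truth$gene_id
    te <- setNames(sim$truth$pi3, sim$truth$gene_id)
    low <- lowTESelection(te, 0.05)
    enr <- hypergeomEnrichment(low, sets, bg)
    ks <- suppressWarnings(ks.test(enr$p.value, "punif"))
    expect_gt(ks$p.value, 0.01)
})
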