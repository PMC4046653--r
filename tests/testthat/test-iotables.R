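test_that("expression write/read round-trips exactly and respects the design", {
    sim <- generateDataset(syntheticConfig(n_genes = 2, seed = 1))
    ep <- withr::local_tempfile(fileext = ".tsv")
    dp <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(sim$expression, ep, dp)
    back <- readExpressionTable(ep, dp)
    expect_identical(SummarizedExperiment::assay(back, "exprs"),
                     SummarizedExperiment::assay(sim$expression, "exprs"))
    expect_identical(sampleDesign(back), sampleDesign(sim$expression))

    ## default synthetic design is 2 cell lines x 2 treatments x 3 pools x
    ## 3 replicates = 36 arrays
    sim50 <- generateDataset(syntheticConfig(n_genes = 50, seed = 1))
    expect_identical(dim(SummarizedExperiment::assay(sim50$expression)),
                     c(50L, 36L))
})

test_that("readers reject malformed inputs with informative errors", {
    sim <- generateDataset(syntheticConfig(n_genes = 5, seed = 2,
                                           cell_lines = "CL1"))
    ep <- withr::local_tempfile(fileext = ".tsv")
    dp <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(sim$expression, ep, dp)

    ## design missing pool 2 of one replicate: error names the experiment
    d <- readDesignTable(dp)
    d2 <- d[!(d$pool == 2 & d$treatment == "GC" & d$replicate == 1), ]
    dp2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(d2, dp2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readExpressionTable(ep, dp2),
                 "cell_line=CL1, treatment=GC, replicate=1")

    ## missing sample column is named
    tab <- read.delim(ep, check.names = FALSE)
    tab$CL1_GC_p1_r1 <- NULL
    ep2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(tab, ep2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readExpressionTable(ep2, dp), "CL1_GC_p1_r1")

    ## non-numeric cell is located
    tab <- read.delim(ep, check.names = FALSE)
    tab$CL1_EtOH_p2_r2[3] <- "oops"
    ep3 <- withr::local_tempfile(fileext = ".tsv")
    write.table(tab, ep3, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readExpressionTable(ep3, dp), "CL1_EtOH_p2_r2.*row 3")

    ## duplicated gene id
    tab <- read.delim(ep, check.names = FALSE)
    tab$gene_id[2] <- tab$gene_id[1]
    ep4 <- withr::local_tempfile(fileext = ".tsv")
    write.table(tab, ep4, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readExpressionTable(ep4, dp), "duplicated gene_id")
})

test_that("design acceptance is order-independent", {
    sim <- generateDataset(syntheticConfig(n_genes = 3, seed = 3))
    ep <- withr::local_tempfile(fileext = ".tsv")
    dp <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(sim$expression, ep, dp)
    d <- readDesignTable(dp)
    set.seed(1)
    d <- d[sample(nrow(d)), ]
    dp2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(d, dp2, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- readExpressionTable(ep, dp2)
    expect_identical(colnames(back), d$sample_id)
    m0 <- SummarizedExperiment::assay(sim$expression)
    expect_identical(SummarizedExperiment::assay(back),
                     m0[, d$sample_id])
})

test_that("gene annotation reader maps rows and enforces the schema", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        paste("transcript_id", "gene_id", "probe_count", "gene_name",
              "gene_biotype", "chromosome_name", "extra", sep = "\t"),
        paste("ENST01", "ENSG01", 12, "TLN1", "protein_coding", 9, "x",
              sep = "\t"),
        paste("ENST02", "ENSG02", 4, "CCDC7", "protein_coding", 2, "y",
              sep = "\t"),
        paste("ENST03", "ENSG03", 7, "SNORD1", "snoRNA", 11, "z",
              sep = "\t")), path)
    ann <- readGeneAnnotation(path)
    expect_equal(nrow(ann), 3)
    expect_identical(ann$transcript_id, c("ENST01", "ENST02", "ENST03"))
    expect_equal(ann$probe_count[1], 12)
    expect_false("extra" %in% colnames(ann))

    ## missing required column
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste("transcript_id", "gene_id", "probe_count",
                       "gene_name", "gene_biotype", sep = "\t"),
                 paste("ENST01", "ENSG01", 12, "TLN1", "protein_coding",
                       sep = "\t")), path2)
    expect_error(readGeneAnnotation(path2), "chromosome_name")

    ## duplicated transcript id
    path3 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        paste("transcript_id", "gene_id", "probe_count", "gene_name",
              "gene_biotype", "chromosome_name", sep = "\t"),
        paste("ENST01", "ENSG01", 1, "A", "protein_coding", 1, sep = "\t"),
        paste("ENST01", "ENSG02", 2, "B", "protein_coding", 2, sep = "\t")),
        path3)
    expect_error(readGeneAnnotation(path3), "duplicated transcript_id")
})

test_that("summary table has the supplemental layout and round-trips RE", {
    ## one gene whose EtOH/GC relative expression is exactly (0.2, 0.3, 0.5)
    means <- log2(32 * c(0.2, 0.3, 0.5))
    pps <- makeConstantPPS(matrix(rep(means, 2), nrow = 1))
    re <- relativeExpression(pps)
    path <- withr::local_tempfile(fileext = ".tsv")
    ann <- data.frame(transcript_id = "T001", gene_id = "G001",
                      probe_count = 5, gene_name = "SYN1",
                      gene_biotype = "protein_coding", chromosome_name = "1")
    writeSummaryTable(re, poolExpressionMeans(pps), ann, path)
    tab <- read.delim(path, check.names = FALSE)
    expect_identical(
        colnames(tab)[1:6],
        c("transcript_id", "gene_id", "probe_count", "gene_name",
          "gene_biotype", "chromosome_name"))
    gc_cells <- sprintf("%.6f", unlist(tab[1, c("RE.p1.GC", "RE.p2.GC",
                                                "RE.p3.GC")]))
    expect_identical(sprintf("%.6f", sum(as.numeric(gc_cells))), "1.000000")
    expect_equal(tab$RE.p3.EtOH, 0.5, tolerance = 1e-6)

    ## a 100-gene synthetic run writes 1 header + 100 data rows and
    ## re-parses to the computed RE values within the 6-decimal precision
    sim <- generateDataset(syntheticConfig(n_genes = 100, seed = 4,
                                           cell_lines = "CL1"))
    re <- relativeExpression(sim$expression)
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeSummaryTable(re, poolExpressionMeans(sim$expression),
                      sim$annotation, path2)
    expect_equal(length(readLines(path2)), 101)
    tab2 <- read.delim(path2, check.names = FALSE)
    avg <- averagedRE(re, treatment = "GC")
    expect_equal(tab2$RE.p2.GC[match(avg$gene_id, tab2$gene_id)],
                 avg$RE2, tolerance = 1e-6)
})

test_that("gene-set files round-trip and unknown-annotation genes warn", {
    sets <- GeneSetCollection(list(S1 = c("a", "b"), S2 = c("b", "c", "d")))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeGeneSets(sets, path)
    back <- readGeneSets(path)
    expect_identical(geneSets(back), geneSets(sets))

    sim <- generateDataset(syntheticConfig(n_genes = 5, seed = 5,
                                           cell_lines = "CL1"))
    re <- relativeExpression(sim$expression)
    ann <- sim$annotation[-2, ]
    path2 <- withr::local_tempfile(fileext = ".tsv")
    expect_warning(
        writeSummaryTable(re, poolExpressionMeans(sim$expression), ann,
                          path2),
        "missing from annotation")
})

test_that("series-matrix files parse into metadata plus a numeric matrix", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(
        '!Series_title\t"synthetic polysome profiling"',
        '!Series_geo_accession\t"GSE00000"',
        '!Sample_title\t"p1"\t"p2"',
        "!series_matrix_table_begin",
        paste("\"ID_REF\"", "\"S1\"", "\"S2\"", sep = "\t"),
        paste("\"G1\"", "1.5", "2.5", sep = "\t"),
        paste("\"G2\"", "3", "4", sep = "\t"),
        "!series_matrix_table_end"), path)
    sm <- readSeriesMatrix(path)
    expect_identical(sm$metadata$Series_geo_accession, "GSE00000")
    expect_identical(sm$metadata$Sample_title, c("p1", "p2"))
    expect_identical(dimnames(sm$exprs), list(c("G1", "G2"), c("S1", "S2")))
    expect_equal(sm$exprs["G1", "S2"], 2.5)
    ## a truncated table is rejected
    path2 <- withr::local_tempfile(fileext = ".txt")
    writeLines(readLines(path)[1:6], path2)
    expect_error(readSeriesMatrix(path2), "delimiters")
})
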