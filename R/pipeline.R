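## End-to-end orchestration: (optional) simulation, expressed-gene
## filtering, relative expression / TE summaries, translational-regulation
## testing and gene-set enrichment, with TSV/JSON artifacts per cell line.

#' Pipeline run configuration
#'
#' Collects paths and parameters for \code{\link{runPipeline}}. Provide
#' either input paths (\code{expression_path} + \code{design_path} +
#' \code{annotation_path}) or a \code{simulate} config.
#'
#' @param output_dir directory for run artifacts (created if needed).
#' @param expression_path,design_path,annotation_path,sets_path input TSVs
#'   (see the \code{read*} functions); all optional when simulating.
#' @param simulate optional \code{\link{syntheticConfig}}; when given, the
#'   dataset is generated and written to \code{output_dir}.
#' @param expr_threshold expressed-gene log2 threshold (default 3).
#' @param top_fraction top fraction for biotype composition (default 0.01).
#' @param low_fraction low-TE fraction for enrichment (default 0.05).
#' @param n_groups TE groups (default 5).
#' @param fdr FDR threshold for the reported significant-gene counts
#'   (default 0.05).
#' @param total_mrna_scale \code{"linear"} or \code{"log"}, see
#'   \code{\link{totalMrna}}.
#' @param seed integer seed for any randomness (simulation, generated gene
#'   sets).
#' @return a list of class \code{RunConfig}.
#' @export
runConfig <- function(output_dir,
                      expression_path = NULL, design_path = NULL,
                      annotation_path = NULL, sets_path = NULL,
                      simulate = NULL,
                      expr_threshold = 3, top_fraction = 0.01,
                      low_fraction = 0.05, n_groups = 5L, fdr = 0.05,
                      total_mrna_scale = c("linear", "log"), seed = 1L) {
    total_mrna_scale <- match.arg(total_mrna_scale)
    stopifnot(top_fraction > 0, top_fraction <= 1,
              low_fraction > 0, low_fraction < 1,
              n_groups >= 2L, fdr > 0, fdr < 1)
    if (is.null(simulate) &&
        (is.null(expression_path) || is.null(design_path) ||
         is.null(annotation_path)))
        stop("provide input paths or a 'simulate' config")
    structure(class = "RunConfig", list(
        output_dir = output_dir, expression_path = expression_path,
        design_path = design_path, annotation_path = annotation_path,
        sets_path = sets_path, simulate = simulate,
        expr_threshold = expr_threshold, top_fraction = top_fraction,
        low_fraction = low_fraction, n_groups = as.integer(n_groups),
        fdr = fdr, total_mrna_scale = total_mrna_scale,
        seed = as.integer(seed)))
}

pipelineStage <- function(name, log, expr) {
    writeLines(paste0("[stage] ", name), log)
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full translational-profiling pipeline
#'
#' Stages: load (or simulate) the pool expression data; filter to expressed
#' genes per cell line; compute relative expression and write the per-gene
#' summary table; compute per-replicate translational regulation and the
#' moderated one-sample test with BH adjustment; run low-TE gene-set
#' enrichment (when gene sets are available). All artifacts are written
#' under \code{config$output_dir}; the run is deterministic given the
#' config.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, the run metadata list (also written as
#'   \code{run_metadata.json}): seed, gene counts per stage, shrinkage
#'   hyperparameters and significant-gene count per cell line.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(config$output_dir, "run.log")
    log <- file(log_path, open = "wt")
    on.exit(close(log))

    if (!is.null(config$simulate)) {
        sim <- pipelineStage("simulate", log, {
            cfg <- config$simulate
            cfg$seed <- config$seed
            generateDataset(cfg)
        })
        expr <- sim$expression
        annotation <- sim$annotation
        pipelineStage("write-simulated-inputs", log, {
            writeExpressionTable(expr,
                file.path(config$output_dir, "expression.tsv"),
                file.path(config$output_dir, "design.tsv"))
            utils::write.table(sim$truth,
                file.path(config$output_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(annotation,
                file.path(config$output_dir, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
        })
    } else {
        expr <- pipelineStage("load-expression", log,
            readExpressionTable(config$expression_path, config$design_path))
        annotation <- pipelineStage("load-annotation", log,
            readGeneAnnotation(config$annotation_path))
    }

    sets <- NULL
    if (!is.null(config$sets_path))
        sets <- pipelineStage("load-gene-sets", log,
                              readGeneSets(config$sets_path))
    else if (!is.null(config$simulate))
        sets <- pipelineStage("generate-gene-sets", log, {
            ## set size capped by the low-TE tail so small simulations work
            size <- min(50L, ceiling(0.05 * nrow(sim$truth)))
            generateGeneSets(sim$truth, enriched_set_size = size,
                             seed = config$seed)
        })

    meta <- list(package = "polysomeTE",
                 version = as.character(utils::packageVersion("polysomeTE")),
                 seed = config$seed,
                 total_mrna_scale = config$total_mrna_scale,
                 fdr = config$fdr,
                 n_genes_input = nrow(expr),
                 cell_lines = list())

    for (cl in cellLines(expr)) {
        x <- selectCellLine(expr, cl)
        x <- pipelineStage(paste0("filter-expressed:", cl), log,
                           filterExpressed(x, config$expr_threshold))
        re <- pipelineStage(paste0("relative-expression:", cl), log,
                            relativeExpression(x))
        pipelineStage(paste0("write-summary:", cl), log,
            writeSummaryTable(re, poolExpressionMeans(x), annotation,
                file.path(config$output_dir,
                          paste0("summary_", cl, ".tsv"))))
        regtab <- pipelineStage(paste0("regulation:", cl), log,
                                regulationTable(x, scale = config$total_mrna_scale))
        fit <- pipelineStage(paste0("moderated-test:", cl), log,
                             moderatedOneSampleTest(transReg(regtab)))
        res <- testResults(fit)
        out <- data.frame(gene_id = res$gene_id,
                          txn_reg_mean = rowMeans(txnReg(regtab)),
                          stringsAsFactors = FALSE)
        tr <- transReg(regtab)
        for (j in seq_len(ncol(tr)))
            out[[paste0("trans_reg_", colnames(tr)[j])]] <- tr[, j]
        out$trans_reg_mean <- res$mean
        out$t <- res$t
        out$p.value <- res$p.value
        out$adj.p <- res$adj.p
        pipelineStage(paste0("write-regulation:", cl), log,
            utils::write.table(out,
                file.path(config$output_dir,
                          paste0("regulation_", cl, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE))

        enr_sig <- NA
        if (!is.null(sets)) {
            enr <- pipelineStage(paste0("enrichment:", cl), log, {
                te <- translationalEfficiency(re, treatment = "EtOH")
                coding <- annotation$gene_id[
                    annotation$gene_biotype == "protein_coding"]
                te <- te[names(te) %in% coding]
                bg <- names(te)
                low <- lowTESelection(te, config$low_fraction)
                hypergeomEnrichment(low, sets, bg)
            })
            utils::write.table(enr,
                file.path(config$output_dir,
                          paste0("enrichment_", cl, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            enr_sig <- sum(enr$adj.p < config$fdr)
        }

        sp <- shrinkageParameters(fit)
        meta$cell_lines[[cl]] <- list(
            n_genes_expressed = nrow(x),
            d0 = sp$d0, s0sq = sp$s0sq, df_total = sp$dfTotal,
            d0_capped = sp$d0Capped,
            min_adj_p = min(res$adj.p),
            n_significant = sum(res$adj.p < config$fdr),
            n_enriched_sets = enr_sig)
        writeLines(sprintf("[result] %s: %d expressed genes, %d significant at FDR %g",
                           cl, nrow(x), sum(res$adj.p < config$fdr),
                           config$fdr), log)
    }

    jsonlite::write_json(meta,
                         file.path(config$output_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(meta)
}
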