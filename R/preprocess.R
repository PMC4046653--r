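## Pre-processing: one representative transcript per gene, and the
## expressed-gene filter on the log2 scale.

#' Select the representative transcript for one gene
#'
#' When a gene is measured by several transcript probe sets, one
#' representative is chosen by lexicographic priority: (1) protein_coding
#' biotype first; (2) more than 3 probes first; (3) highest mean expression
#' across all arrays; remaining ties broken by the lexicographically
#' smallest \code{transcript_id}. The choice is deterministic and invariant
#' to input order.
#'
#' @param candidates data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{biotype}, \code{probe_count},
#'   \code{mean_expression}; all rows must share one \code{gene_id}.
#' @return the selected \code{transcript_id} (character scalar).
#' @export
selectRepresentative <- function(candidates) {
    if (is.null(candidates) || !NROW(candidates))
        stop("empty candidate list")
    req <- c("transcript_id", "gene_id", "biotype", "probe_count",
             "mean_expression")
    miss <- setdiff(req, colnames(candidates))
    if (length(miss))
        stop("candidates missing column(s): ", paste(miss, collapse = ", "))
    if (length(unique(candidates$gene_id)) != 1L)
        stop("all candidates must belong to one gene")
    if (any(!is.finite(candidates$mean_expression)))
        stop("mean_expression must be finite")
    ord <- order(candidates$biotype != "protein_coding",   # coding first
                 candidates$probe_count <= 3,              # >3 probes first
                 -candidates$mean_expression,
                 candidates$transcript_id)
    candidates$transcript_id[ord[1]]
}

#' Choose representative transcripts for all genes
#'
#' Applies \code{\link{selectRepresentative}} per gene over a transcript
#' annotation table joined with mean expression.
#'
#' @param annotation data.frame in \code{\link{readGeneAnnotation}} layout.
#' @param mean_expression named numeric, average log2 expression per
#'   \code{transcript_id} across all arrays.
#' @return data.frame with columns \code{gene_id}, \code{transcript_id}
#'   (one row per gene, gene order of first appearance).
#' @export
representativeTranscripts <- function(annotation, mean_expression) {
    me <- mean_expression[annotation$transcript_id]
    if (anyNA(me))
        stop("mean_expression missing for transcript(s): ",
             annotation$transcript_id[which(is.na(me))[1]])
    cand <- data.frame(transcript_id = annotation$transcript_id,
                       gene_id = annotation$gene_id,
                       biotype = annotation$gene_biotype,
                       probe_count = annotation$probe_count,
                       mean_expression = as.numeric(me),
                       stringsAsFactors = FALSE)
    genes <- unique(cand$gene_id)
    chosen <- vapply(genes, function(g)
        selectRepresentative(cand[cand$gene_id == g, , drop = FALSE]), "")
    data.frame(gene_id = genes, transcript_id = unname(chosen),
               stringsAsFactors = FALSE)
}

#' Filter to expressed genes
#'
#' A gene is kept if its replicate-averaged log2 expression exceeds
#' \code{threshold} in at least one (cell line, treatment, pool)
#' combination; this drops genes with very low expression in all pools under
#' both treatments. Gene order is preserved, and the filter is idempotent.
#'
#' @param x a \code{\link{PoolProfileSet}}.
#' @param threshold log2 expression threshold (default 3).
#' @return the filtered \code{PoolProfileSet}.
#' @export
filterExpressed <- function(x, threshold = 3) {
    stopifnot(is(x, "PoolProfileSet"))
    m <- SummarizedExperiment::assay(x, "exprs")
    cd <- colData(x)
    grp <- paste(cd$cell_line, cd$treatment, cd$pool, sep = "\r")
    keep <- rep(FALSE, nrow(m))
    for (g in unique(grp)) {
        mu <- rowMeans(m[, grp == g, drop = FALSE])
        keep <- keep | mu > threshold
    }
    x[keep, ]
}
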