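## Relative expression across pools, translational efficiency and its
## summaries: the percentage of a gene's mRNA in each pool, computed on the
## linear scale from log2 intensities.

#' RelativeExpressionTable: per-gene relative expression across pools
#'
#' Holds, per gene and (cell line, treatment, replicate), the relative
#' expression \code{RE1}, \code{RE2}, \code{RE3} (fractions summing to 1),
#' and the replicate-averaged values per (cell line, treatment). The
#' translational efficiency (TE) of a gene is its RE in pool 3, the
#' ribosome-bound pool.
#'
#' @slot geneIds character, gene ids in input order.
#' @slot perReplicate data.frame: gene_id, cell_line, treatment, replicate,
#'   RE1, RE2, RE3.
#' @slot average data.frame: gene_id, cell_line, treatment, RE1, RE2, RE3
#'   (arithmetic means over replicates).
#' @exportClass RelativeExpressionTable
setClass("RelativeExpressionTable",
         representation(geneIds = "character", perReplicate = "data.frame",
                        average = "data.frame"))

setValidity("RelativeExpressionTable", function(object) {
    pr <- object@perReplicate
    s <- pr$RE1 + pr$RE2 + pr$RE3
    if (any(abs(s - 1) > 1e-9))
        return("per-replicate RE must sum to 1 (1e-9)")
    TRUE
})

#' @export
setMethod("show", "RelativeExpressionTable", function(object) {
    cat("RelativeExpressionTable:", length(object@geneIds), "genes,",
        nrow(object@average), "gene x (cell line, treatment) averages\n")
})

#' @describeIn RelativeExpressionTable-class per-replicate RE values,
#'   optionally restricted to genes/treatment/cell line.
#' @param x a \code{RelativeExpressionTable}
#' @param genes,treatment,cell_line optional filters.
#' @export
setMethod("perReplicateRE", "RelativeExpressionTable",
    function(x, genes = NULL, treatment = NULL, cell_line = NULL) {
        d <- x@perReplicate
        if (!is.null(genes)) d <- d[d$gene_id %in% genes, ]
        if (!is.null(treatment)) d <- d[d$treatment %in% treatment, ]
        if (!is.null(cell_line)) d <- d[d$cell_line %in% cell_line, ]
        d
    })

#' @describeIn RelativeExpressionTable-class replicate-averaged RE values.
#' @export
setMethod("averagedRE", "RelativeExpressionTable",
    function(x, genes = NULL, treatment = NULL, cell_line = NULL) {
        d <- x@average
        if (!is.null(genes)) d <- d[d$gene_id %in% genes, ]
        if (!is.null(treatment)) d <- d[d$treatment %in% treatment, ]
        if (!is.null(cell_line)) d <- d[d$cell_line %in% cell_line, ]
        d
    })

#' Relative expression across the three pools
#'
#' For log2 expression values \eqn{E_1, E_2, E_3} of a gene in pools 1-3,
#' the relative expression in pool \eqn{i} is the linear-scale proportion
#' \deqn{RE_i = 2^{E_i} / (2^{E_1} + 2^{E_2} + 2^{E_3}),}
#' the fraction of the gene's mRNA located in that pool. The three values
#' sum to 1 and are invariant under adding a constant to all three inputs.
#'
#' @param x numeric vector of pool-1 log2 expression (or a
#'   \code{\link{PoolProfileSet}}, see the method below).
#' @param E2,E3 numeric vectors for pools 2 and 3 (same length as \code{x}).
#' @param ... unused.
#' @return For numeric input, a matrix with columns \code{RE1}, \code{RE2},
#'   \code{RE3}.
#' @examples
#' relativeExpression(1, 2, 3)   # 2/14, 4/14, 8/14
#' @export
setMethod("relativeExpression", "numeric", function(x, E2, E3, ...) {
    if (!all(is.finite(x), is.finite(E2), is.finite(E3)))
        stop("log2 expression values must be finite")
    ## subtract the max for numerical stability; RE is shift-invariant
    mx <- pmax(x, E2, E3)
    w1 <- 2^(x - mx); w2 <- 2^(E2 - mx); w3 <- 2^(E3 - mx)
    s <- w1 + w2 + w3
    cbind(RE1 = w1 / s, RE2 = w2 / s, RE3 = w3 / s)
})

#' @describeIn relativeExpression compute per-replicate and
#'   replicate-averaged relative expression for every gene and
#'   (cell line, treatment) of a \code{PoolProfileSet}. RE is computed per
#'   replicate first and then averaged.
#' @export
setMethod("relativeExpression", "PoolProfileSet", function(x, ...) {
    m <- SummarizedExperiment::assay(x, "exprs")
    cd <- as.data.frame(colData(x))
    cd$sample_id <- rownames(cd)
    conds <- unique(cd[, c("cell_line", "treatment", "replicate")])
    per <- vector("list", nrow(conds))
    for (i in seq_len(nrow(conds))) {
        cc <- conds[i, ]
        sid <- function(p) cd$sample_id[cd$cell_line == cc$cell_line &
                                        cd$treatment == cc$treatment &
                                        cd$replicate == cc$replicate &
                                        cd$pool == p]
        re <- relativeExpression(m[, sid(1)], m[, sid(2)], m[, sid(3)])
        per[[i]] <- data.frame(gene_id = rownames(m),
                               cell_line = cc$cell_line,
                               treatment = cc$treatment,
                               replicate = cc$replicate,
                               RE1 = re[, 1], RE2 = re[, 2], RE3 = re[, 3],
                               row.names = NULL, stringsAsFactors = FALSE)
    }
    per <- do.call(rbind, per)
    agg <- stats::aggregate(per[, c("RE1", "RE2", "RE3")],
                            by = per[, c("gene_id", "cell_line", "treatment")],
                            FUN = mean)
    ## restore gene input order within each condition
    agg <- agg[order(agg$cell_line, agg$treatment,
                     match(agg$gene_id, rownames(m))), ]
    rownames(agg) <- NULL
    methods::new("RelativeExpressionTable", geneIds = rownames(m),
                 perReplicate = per, average = agg)
})

#' @describeIn RelativeExpressionTable-class per-gene translational
#'   efficiency: the replicate-averaged RE in pool 3, averaged over the
#'   selected treatments and cell lines (all by default).
#' @export
setMethod("translationalEfficiency", "RelativeExpressionTable",
    function(x, treatment = NULL, cell_line = NULL, ...) {
        d <- averagedRE(x, treatment = treatment, cell_line = cell_line)
        te <- tapply(d$RE3, d$gene_id, mean)
        te <- te[x@geneIds[x@geneIds %in% names(te)]]
        setNames(as.numeric(te), names(te))
    })

#' Mean and 95\% confidence interval for translational efficiency
#'
#' Pools per-replicate TE values (e.g. over experiments, cell lines and
#' treatments) and returns the mean with a two-sided 95\% t-interval on
#' \eqn{n - 1} degrees of freedom.
#'
#' @param values numeric vector of per-replicate TE values (length >= 2).
#' @return named numeric: \code{mean}, \code{lower}, \code{upper}.
#' @export
summarizeTE <- function(values) {
    n <- length(values)
    if (n < 2L) stop("need at least 2 TE values")
    m <- mean(values)
    se <- stats::sd(values) / sqrt(n)
    half <- stats::qt(0.975, n - 1) * se
    c(mean = m, lower = m - half, upper = m + half)
}

#' Biotype composition of the top fraction of genes by relative expression
#'
#' Selects the \code{ceiling(fraction * N)} genes with the highest
#' replicate-averaged RE in the given pool (ties broken by gene id) and
#' tabulates their biotypes. Non-coding biotypes concentrate among the top
#' genes of pool 1; pool-3 top genes are almost exclusively protein coding.
#'
#' @param re a \code{\link{RelativeExpressionTable}}.
#' @param pool 1, 2 or 3.
#' @param annotation gene annotation data.frame covering all genes.
#' @param fraction top fraction in (0, 1] (default 0.01).
#' @param treatment,cell_line condition whose averaged RE is ranked
#'   (defaults: first treatment/cell line present).
#' @return data.frame with columns \code{biotype}, \code{count},
#'   \code{proportion} (proportions sum to 1), sorted by decreasing count.
#' @export
topFractionBiotypes <- function(re, pool, annotation, fraction = 0.01,
                                treatment = NULL, cell_line = NULL) {
    stopifnot(is(re, "RelativeExpressionTable"), pool %in% 1:3)
    if (fraction <= 0 || fraction > 1)
        stop("fraction must be in (0, 1]")
    d <- averagedRE(re, treatment = treatment, cell_line = cell_line)
    if (is.null(treatment)) d <- d[d$treatment == d$treatment[1], ]
    if (is.null(cell_line)) d <- d[d$cell_line == d$cell_line[1], ]
    v <- d[[paste0("RE", pool)]]
    n_top <- ceiling(fraction * nrow(d))
    ord <- order(-v, d$gene_id)
    top <- d$gene_id[ord[seq_len(n_top)]]
    bt <- annotation$gene_biotype[match(top, annotation$gene_id)]
    if (anyNA(bt))
        stop("annotation does not cover gene(s): ", top[which(is.na(bt))[1]])
    tab <- sort(table(bt), decreasing = TRUE)
    data.frame(biotype = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
}

#' Partition genes into equal-count translational-efficiency groups
#'
#' Rank-based partition of per-gene TE values into \code{k} groups of as
#' equal size as possible (sizes differ by at most 1; the lower-TE groups
#' take the extra genes). Group 1 holds the lowest TE values. Ties are
#' broken by gene id before splitting, so the partition is deterministic and
#' invariant under strictly monotone transforms of TE.
#'
#' @param te named numeric vector of TE values (names = gene ids).
#' @param k number of groups (default 5).
#' @return integer vector of group labels 1..k, named by gene, in the input
#'   order.
#' @export
partitionTEGroups <- function(te, k = 5L) {
    n <- length(te)
    if (k < 2L) stop("k must be >= 2")
    if (n < k) stop("fewer genes than groups")
    if (is.null(names(te))) stop("te must be named by gene id")
    ord <- order(te, names(te))
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    labels <- rep(seq_len(k), times = sizes)
    out <- integer(n)
    out[ord] <- labels
    setNames(out, names(te))
}

#' Replicate-averaged log2 expression per pool and treatment
#'
#' Helper for \code{\link{writeSummaryTable}}: per-gene mean log2 expression
#' across replicates for each pool and treatment of one cell line.
#'
#' @param x a \code{\link{PoolProfileSet}}.
#' @param cell_line cell line to summarize (default: the only one present).
#' @return data.frame with \code{gene_id} and columns
#'   \code{exprs.p<pool>.<treatment>}.
#' @export
poolExpressionMeans <- function(x, cell_line = NULL) {
    stopifnot(is(x, "PoolProfileSet"))
    if (is.null(cell_line)) {
        cls <- cellLines(x)
        if (length(cls) > 1L)
            stop("multiple cell lines present; specify 'cell_line'")
        cell_line <- cls
    }
    x <- selectCellLine(x, cell_line)
    m <- SummarizedExperiment::assay(x, "exprs")
    cd <- colData(x)
    out <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
    for (tr in TREATMENT_LEVELS)
        for (p in 1:3) {
            sel <- cd$treatment == tr & cd$pool == p
            out[[sprintf("exprs.p%d.%s", p, tr)]] <-
                rowMeans(m[, sel, drop = FALSE])
        }
    out
}
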