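#' PoolProfileSet: log2 expression across polysome pools
#'
#' A \code{PoolProfileSet} is a
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} holding one assay
#' (\code{"exprs"}) of log2 expression values for genes (rows) across samples
#' (columns), where each sample is one polysome pool of one
#' (cell line, treatment, replicate) experiment. The column data must carry
#' the sample descriptors \code{cell_line}, \code{treatment} (\code{"GC"} or
#' \code{"EtOH"}), \code{pool} (1, 2 or 3: non-translated, intermediate,
#' ribosome-bound) and \code{replicate}.
#'
#' Validity requires a complete paired design: for every
#' (cell line, replicate) present, all three pools must be present for both
#' treatments. Expression values must be finite and lie within the declared
#' range (default \code{c(0, 16)}, the log2 scale of the arrays), stored in
#' \code{metadata(x)$expression_range}.
#'
#' @slot .. see \code{SummarizedExperiment}; no additional slots.
#'
#' @seealso \code{\link{readExpressionTable}}, \code{\link{generateDataset}},
#'   \code{\link{filterExpressed}}, \code{\link{relativeExpression}}
#' @importFrom methods new validObject is
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @exportClass PoolProfileSet
setClass("PoolProfileSet", contains = "SummarizedExperiment")

DESIGN_COLUMNS <- c("cell_line", "treatment", "pool", "replicate")
TREATMENT_LEVELS <- c("GC", "EtOH")

## Check a design data.frame for the paired 3-pool structure.
## Returns NULL if valid, otherwise a character description of the problem.
checkDesign <- function(design) {
    miss <- setdiff(DESIGN_COLUMNS, colnames(design))
    if (length(miss))
        return(paste0("design is missing column(s): ",
                      paste(miss, collapse = ", ")))
    if (!all(design$treatment %in% TREATMENT_LEVELS))
        return("treatment must be one of 'GC', 'EtOH'")
    if (!all(design$pool %in% 1:3))
        return("pool must be 1, 2 or 3")
    if (any(design$replicate < 1) || any(design$replicate != round(design$replicate)))
        return("replicate must be a positive integer")
    key <- paste(design$cell_line, design$treatment, design$pool,
                 design$replicate, sep = "\r")
    if (anyDuplicated(key))
        return("duplicated (cell_line, treatment, pool, replicate) combination")
    ## paired completeness: all 3 pools under both treatments for each
    ## (cell_line, replicate) experiment
    for (cl in unique(design$cell_line)) {
        d <- design[design$cell_line == cl, ]
        for (r in unique(d$replicate)) {
            dr <- d[d$replicate == r, ]
            for (tr in TREATMENT_LEVELS) {
                pools <- sort(dr$pool[dr$treatment == tr])
                if (!identical(as.integer(pools), 1:3))
                    return(sprintf(
                        "incomplete paired design for (cell_line=%s, treatment=%s, replicate=%s): pools present = {%s}",
                        cl, tr, r, paste(pools, collapse = ",")))
            }
        }
    }
    NULL
}

setValidity("PoolProfileSet", function(object) {
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    m <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(object)))
        return("gene ids (rownames) are required")
    if (anyDuplicated(rownames(object)))
        return("duplicated gene ids")
    if (!all(is.finite(m)))
        return("expression values must be finite")
    rng <- S4Vectors::metadata(object)$expression_range
    if (is.null(rng) || length(rng) != 2L)
        return("metadata(x)$expression_range must be numeric(2)")
    if (nrow(m) && ncol(m) && (min(m) < rng[1] || max(m) > rng[2]))
        return(sprintf("expression values outside declared range [%g, %g]",
                       rng[1], rng[2]))
    msg <- checkDesign(as.data.frame(colData(object)))
    if (!is.null(msg)) return(msg)
    TRUE
})

#' Construct a PoolProfileSet
#'
#' @param values numeric matrix of log2 expression, genes x samples, with
#'   unique rownames (gene ids). Column names must match
#'   \code{design$sample_id}.
#' @param design data.frame with columns \code{sample_id}, \code{cell_line},
#'   \code{treatment}, \code{pool}, \code{replicate}; one row per sample.
#'   Columns of \code{values} are reordered to the design order.
#' @param range numeric(2), the declared expression range (default
#'   \code{c(0, 16)}).
#'
#' @return A validated \code{PoolProfileSet}.
#' @examples
#' sim <- generateDataset(syntheticConfig(n_genes = 20, seed = 1))
#' sim$expression
#' @export
PoolProfileSet <- function(values, design, range = c(0, 16)) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (!"sample_id" %in% colnames(design))
        stop("design must contain a 'sample_id' column")
    missing_cols <- setdiff(design$sample_id, colnames(values))
    if (length(missing_cols))
        stop("expression matrix is missing sample column(s): ",
             paste(missing_cols, collapse = ", "))
    values <- values[, design$sample_id, drop = FALSE]
    cd <- S4Vectors::DataFrame(design[, DESIGN_COLUMNS, drop = FALSE],
                               row.names = design$sample_id)
    cd$pool <- as.integer(cd$pool)
    cd$replicate <- as.integer(cd$replicate)
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
    S4Vectors::metadata(se)$expression_range <- as.numeric(range)
    out <- methods::new("PoolProfileSet", se)
    validObject(out)
    out
}

#' @describeIn PoolProfileSet the sample design as a data.frame with a
#'   \code{sample_id} column.
#' @param x a \code{PoolProfileSet}
#' @export
setMethod("sampleDesign", "PoolProfileSet", function(x) {
    d <- as.data.frame(colData(x))
    data.frame(sample_id = rownames(d), d, row.names = NULL,
               stringsAsFactors = FALSE)
})

#' @describeIn PoolProfileSet the declared log2 expression range.
#' @export
setMethod("expressionRange", "PoolProfileSet", function(x)
    S4Vectors::metadata(x)$expression_range)

#' @describeIn PoolProfileSet cell lines present in the design.
#' @export
setMethod("cellLines", "PoolProfileSet", function(x)
    unique(colData(x)$cell_line))

#' @describeIn PoolProfileSet treatments present in the design.
#' @export
setMethod("treatments", "PoolProfileSet", function(x)
    unique(colData(x)$treatment))

#' @export
setMethod("show", "PoolProfileSet", function(object) {
    cd <- colData(object)
    cat("PoolProfileSet with", nrow(object), "genes,", ncol(object),
        "samples\n")
    cat("  cell lines:", paste(unique(cd$cell_line), collapse = ", "), "\n")
    cat("  treatments:", paste(unique(cd$treatment), collapse = ", "),
        "| pools: ", paste(sort(unique(cd$pool)), collapse = ","),
        "| replicates:", paste(sort(unique(cd$replicate)), collapse = ","),
        "\n")
    rng <- expressionRange(object)
    cat(sprintf("  log2 expression range: [%g, %g]\n", rng[1], rng[2]))
})

## Subset the samples of a PoolProfileSet to one cell line.
## Exported convenience: downstream analyses run per cell line.
#' Subset a PoolProfileSet to a single cell line
#'
#' Translational profiling analyses are run separately per cell line; this
#' returns the sub-experiment for one cell line (still a complete paired
#' design).
#'
#' @param x a \code{PoolProfileSet}
#' @param cell_line character scalar, one of \code{cellLines(x)}
#' @return a \code{PoolProfileSet}
#' @export
selectCellLine <- function(x, cell_line) {
    stopifnot(is(x, "PoolProfileSet"))
    if (!cell_line %in% cellLines(x))
        stop("unknown cell line: ", cell_line)
    x[, colData(x)$cell_line == cell_line]
}
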