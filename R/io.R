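## Readers and writers for the flat TSV exchange formats: expression +
## design tables, gene annotation, gene sets, the supplemental-style summary
## table, and the GEO series-matrix dialect. TSV is tab-separated, UTF-8,
## "." decimal throughout.

#' GeneSetCollection: named gene sets
#'
#' A minimal container for gene sets (e.g. predicted miRNA-family targets or
#' a TOP-motif gene list): a named list of unique gene-id vectors plus an
#' optional description per set.
#'
#' @slot sets named list of character vectors (unique, non-empty).
#' @slot descriptions named character, same names as \code{sets}.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (is.null(names(s)) || any(!nzchar(names(s))))
        return("sets must be named")
    if (anyDuplicated(names(s)))
        return("duplicated set ids")
    for (i in seq_along(s)) {
        if (!length(s[[i]]))
            return(paste0("empty set: ", names(s)[i]))
        if (!is.character(s[[i]]) || anyDuplicated(s[[i]]))
            return(paste0("set members must be unique character ids: ",
                          names(s)[i]))
    }
    if (!identical(names(object@descriptions), names(s)))
        return("descriptions must be named like sets")
    TRUE
})

#' @param sets named list of character vectors.
#' @param descriptions optional named character of set descriptions.
#' @return a \code{GeneSetCollection}.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(m) unique(as.character(m)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    obj <- methods::new("GeneSetCollection", sets = sets,
                        descriptions = descriptions[names(sets)])
    validObject(obj)
    obj
}

#' @describeIn GeneSetCollection-class the member lists.
#' @param x a \code{GeneSetCollection}
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class per-set descriptions.
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "sets; sizes",
        paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a sample design table
#'
#' Expects a TSV with columns \code{sample_id}, \code{cell_line},
#' \code{treatment} (GC/EtOH), \code{pool} (1-3) and \code{replicate}, and
#' validates the complete paired 3-pool structure.
#'
#' @param path path to the design TSV.
#' @return a data.frame.
#' @export
readDesignTable <- function(path) {
    d <- readTsv(path)
    miss <- setdiff(c("sample_id", DESIGN_COLUMNS), colnames(d))
    if (length(miss))
        stop("design file is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicated sample_id in design file")
    msg <- checkDesign(d)
    if (!is.null(msg)) stop(msg)
    d
}

#' Read an expression matrix with its design into a PoolProfileSet
#'
#' The expression TSV must have a \code{gene_id} header column followed by
#' one numeric column per sample id of the design. Columns are ordered per
#' the design file.
#'
#' @param path expression TSV.
#' @param design_path design TSV (see \code{\link{readDesignTable}}).
#' @param range declared log2 expression range (default \code{c(0, 16)}).
#' @return a \code{\link{PoolProfileSet}}.
#' @export
readExpressionTable <- function(path, design_path, range = c(0, 16)) {
    design <- readDesignTable(design_path)
    tab <- readTsv(path)
    if (!"gene_id" %in% colnames(tab))
        stop("expression file must have a 'gene_id' column")
    if (anyDuplicated(tab$gene_id))
        stop("duplicated gene_id in expression file: ",
             tab$gene_id[duplicated(tab$gene_id)][1])
    miss <- setdiff(design$sample_id, colnames(tab))
    if (length(miss))
        stop("expression matrix is missing sample column(s): ",
             paste(miss, collapse = ", "))
    for (sid in design$sample_id) {
        col <- tab[[sid]]
        if (!is.numeric(col)) {
            bad <- which(is.na(suppressWarnings(as.numeric(col))) &
                         !is.na(col))[1]
            stop(sprintf("non-numeric value in column '%s', data row %d: '%s'",
                         sid, bad, col[bad]))
        }
    }
    m <- as.matrix(tab[, design$sample_id, drop = FALSE])
    rownames(m) <- tab$gene_id
    PoolProfileSet(m, design, range = range)
}

#' Write a PoolProfileSet to expression + design TSVs
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x a \code{\link{PoolProfileSet}}.
#' @param path output expression TSV.
#' @param design_path output design TSV.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(x, path, design_path) {
    stopifnot(is(x, "PoolProfileSet"))
    m <- SummarizedExperiment::assay(x, "exprs")
    out <- cbind(gene_id = rownames(m),
                 as.data.frame(apply(m, 2, function(v) sprintf("%.17g", v)),
                               check.names = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sampleDesign(x), design_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

ANNOTATION_COLUMNS <- c("transcript_id", "gene_id", "probe_count",
                        "gene_name", "gene_biotype", "chromosome_name")

#' Read a gene/transcript annotation table
#'
#' Expects at least the columns \code{transcript_id}, \code{gene_id},
#' \code{probe_count}, \code{gene_name}, \code{gene_biotype} and
#' \code{chromosome_name}; extra columns are ignored.
#'
#' @param path annotation TSV.
#' @return a data.frame with the six annotation columns, row order preserved.
#' @export
readGeneAnnotation <- function(path) {
    d <- readTsv(path)
    miss <- setdiff(ANNOTATION_COLUMNS, colnames(d))
    if (length(miss))
        stop("annotation file is missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(d$transcript_id))
        stop("duplicated transcript_id in annotation: ",
             d$transcript_id[duplicated(d$transcript_id)][1])
    if (any(!nzchar(d$gene_biotype)) || any(is.na(d$gene_biotype)))
        stop("gene_biotype must be non-empty")
    d[, ANNOTATION_COLUMNS]
}

#' Read a gene-set file
#'
#' Two-column TSV (\code{set_id}, \code{gene_id}), one membership per line;
#' duplicate memberships are removed.
#'
#' @param path gene-set TSV.
#' @return a \code{\link{GeneSetCollection}}.
#' @export
readGeneSets <- function(path) {
    d <- readTsv(path)
    miss <- setdiff(c("set_id", "gene_id"), colnames(d))
    if (length(miss))
        stop("gene-set file is missing column(s): ",
             paste(miss, collapse = ", "))
    GeneSetCollection(split(as.character(d$gene_id), d$set_id))
}

#' Write a GeneSetCollection to a two-column TSV
#'
#' @param sets a \code{\link{GeneSetCollection}}.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeGeneSets <- function(sets, path) {
    stopifnot(is(sets, "GeneSetCollection"))
    d <- data.frame(set_id = rep(names(sets), lengths(geneSets(sets))),
                    gene_id = unlist(geneSets(sets), use.names = FALSE))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the per-gene summary table (supplemental-table layout)
#'
#' One row per gene: the six annotation columns, treatment-averaged relative
#' expression per pool (\code{RE.p1.GC} ... \code{RE.p3.EtOH}, 6 decimal
#' places, each treatment's three pools summing to 1) and replicate-averaged
#' log2 expression per pool (\code{exprs.p1.GC} ... \code{exprs.p3.EtOH}).
#'
#' @param re a \code{\link{RelativeExpressionTable}} for a single cell line.
#' @param expr_means data.frame from \code{\link{poolExpressionMeans}} with
#'   columns \code{gene_id} and \code{exprs.p<pool>.<treatment>}.
#' @param annotation gene annotation data.frame
#'   (\code{\link{readGeneAnnotation}} layout); genes without annotation are
#'   written with empty annotation fields, with a warning.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeSummaryTable <- function(re, expr_means, annotation, path) {
    stopifnot(is(re, "RelativeExpressionTable"))
    avg <- averagedRE(re)
    genes <- unique(avg$gene_id)
    if (!setequal(genes, expr_means$gene_id))
        stop("re and expr_means must cover the same genes")
    wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (tr in TREATMENT_LEVELS) {
        a <- avg[avg$treatment == tr, ]
        i <- match(genes, a$gene_id)
        for (p in 1:3)
            wide[[sprintf("RE.p%d.%s", p, tr)]] <- a[[paste0("RE", p)]][i]
    }
    em <- expr_means[match(genes, expr_means$gene_id), , drop = FALSE]
    for (tr in TREATMENT_LEVELS)
        for (p in 1:3) {
            cn <- sprintf("exprs.p%d.%s", p, tr)
            if (!cn %in% colnames(em))
                stop("expr_means is missing column ", cn)
            wide[[cn]] <- em[[cn]]
        }
    ai <- match(genes, annotation$gene_id)
    if (anyNA(ai))
        warning(sum(is.na(ai)), " gene(s) missing from annotation; ",
                "written with empty annotation fields")
    ann <- annotation[ai, ANNOTATION_COLUMNS, drop = FALSE]
    ann[is.na(ai), ] <- ""
    out <- cbind(ann[, c("transcript_id"), drop = FALSE],
                 gene_id = genes,
                 ann[, c("probe_count", "gene_name", "gene_biotype",
                         "chromosome_name"), drop = FALSE])
    for (cn in grep("^RE\\.", colnames(wide), value = TRUE))
        out[[cn]] <- sprintf("%.6f", wide[[cn]])
    for (cn in grep("^exprs\\.", colnames(wide), value = TRUE))
        out[[cn]] <- sprintf("%.6f", wide[[cn]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Parse a GEO series-matrix text file
#'
#' Parses the plain series-matrix dialect: \code{!}-prefixed metadata lines
#' (key, then tab-separated quoted fields) and a sample-by-gene table
#' delimited by \code{!series_matrix_table_begin} /
#' \code{!series_matrix_table_end}. Sample-to-descriptor mapping is not
#' inferred; pair the returned matrix with a user-supplied design table to
#' build a \code{\link{PoolProfileSet}}.
#'
#' @param path series-matrix text file.
#' @return list with \code{metadata} (named list of character vectors) and
#'   \code{exprs} (numeric matrix, genes x samples).
#' @export
readSeriesMatrix <- function(path) {
    lines <- readLines(path)
    unquote <- function(x) gsub('^"|"$', "", x)
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin)
        stop("missing or malformed series_matrix table delimiters")
    meta_lines <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
    metadata <- list()
    for (ln in meta_lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        key <- sub("^!", "", parts[1])
        metadata[[key]] <- c(metadata[[key]], unquote(parts[-1]))
    }
    tab <- lines[(begin + 1L):(end - 1L)]
    header <- unquote(strsplit(tab[1], "\t", fixed = TRUE)[[1]])
    rows <- strsplit(tab[-1], "\t", fixed = TRUE)
    ids <- unquote(vapply(rows, `[`, "", 1L))
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    dimnames(m) <- list(ids, header[-1])
    list(metadata = metadata, exprs = m)
}
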