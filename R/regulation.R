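## Translational-regulation analysis: total mRNA per condition,
## transcriptional vs translational regulation per paired replicate, the
## empirical-Bayes moderated one-sample t-test, and BH FDR adjustment.

#' Total mRNA level across pools
#'
#' The total mRNA level of a gene under one condition is the log2 of the
#' linear-scale mean across the three pools,
#' \deqn{T = \log_2((2^{E_1} + 2^{E_2} + 2^{E_3}) / 3).}
#' With \code{scale = "log"} the arithmetic mean of the log2 values is used
#' instead.
#'
#' @param E1,E2,E3 numeric vectors of log2 expression in pools 1-3.
#' @param scale \code{"linear"} (default) or \code{"log"}.
#' @return numeric vector of total mRNA levels (log2).
#' @examples
#' totalMrna(1, 2, 3)   # log2(14/3)
#' @export
totalMrna <- function(E1, E2, E3, scale = c("linear", "log")) {
    scale <- match.arg(scale)
    if (!all(is.finite(E1), is.finite(E2), is.finite(E3)))
        stop("log2 expression values must be finite")
    if (scale == "log")
        return((E1 + E2 + E3) / 3)
    mx <- pmax(E1, E2, E3)
    mx + log2((2^(E1 - mx) + 2^(E2 - mx) + 2^(E3 - mx)) / 3)
}

#' Transcriptional and translational regulation for one paired replicate
#'
#' For paired GC and EtOH pool triples of the same replicate:
#' transcriptional regulation is the change in total mRNA,
#' \code{txn_reg = T(GC) - T(EtOH)}; translational regulation is the change
#' in ribosome-bound (pool 3) mRNA beyond it,
#' \code{trans_reg = (E3_GC - E3_EtOH) - txn_reg}. A nonzero
#' \code{trans_reg} indicates a treatment-induced shift between bound and
#' unbound pools.
#'
#' @param e_gc,e_etoh numeric matrices (genes x 3 pools) or length-3 vectors
#'   of log2 expression under GC and EtOH for one replicate.
#' @param scale passed to \code{\link{totalMrna}}.
#' @return list with numeric vectors \code{txn_reg} and \code{trans_reg}.
#' @export
translationalRegulation <- function(e_gc, e_etoh,
                                    scale = c("linear", "log")) {
    scale <- match.arg(scale)
    if (is.null(dim(e_gc))) e_gc <- matrix(e_gc, nrow = 1)
    if (is.null(dim(e_etoh))) e_etoh <- matrix(e_etoh, nrow = 1)
    if (!identical(dim(e_gc), dim(e_etoh)) || ncol(e_gc) != 3L)
        stop("e_gc and e_etoh must be genes x 3 matrices of equal size")
    txn <- totalMrna(e_gc[, 1], e_gc[, 2], e_gc[, 3], scale) -
        totalMrna(e_etoh[, 1], e_etoh[, 2], e_etoh[, 3], scale)
    trans <- (e_gc[, 3] - e_etoh[, 3]) - txn
    list(txn_reg = txn, trans_reg = trans)
}

#' RegulationTable: per-gene regulation across paired replicates
#'
#' Per gene and replicate of one cell line: total mRNA under GC and EtOH,
#' transcriptional regulation (their difference), and translational
#' regulation. Each replicate's values are computed from that replicate's
#' paired GC and EtOH samples only.
#'
#' @slot geneIds character.
#' @slot cellLine character scalar.
#' @slot tGC,tEtOH,txnReg,transReg numeric matrices, genes x replicates.
#' @slot scale "linear" or "log" (total-mRNA pooling scale).
#' @exportClass RegulationTable
setClass("RegulationTable",
         representation(geneIds = "character", cellLine = "character",
                        tGC = "matrix", tEtOH = "matrix",
                        txnReg = "matrix", transReg = "matrix",
                        scale = "character"))

#' @export
setMethod("show", "RegulationTable", function(object) {
    cat("RegulationTable:", length(object@geneIds), "genes x",
        ncol(object@transReg), "replicates (cell line",
        object@cellLine, ", total-mRNA scale:", object@scale, ")\n")
})

#' @describeIn RegulationTable-class per-replicate translational regulation
#'   (genes x replicates matrix).
#' @param x a \code{RegulationTable}
#' @export
setMethod("transReg", "RegulationTable", function(x, ...) x@transReg)

#' @describeIn RegulationTable-class per-replicate transcriptional
#'   regulation (genes x replicates matrix).
#' @export
setMethod("txnReg", "RegulationTable", function(x, ...) x@txnReg)

#' Per-replicate regulation table for one cell line
#'
#' Computes \code{\link{translationalRegulation}} for every gene and paired
#' replicate of one cell line of a \code{\link{PoolProfileSet}}.
#'
#' @param x a \code{\link{PoolProfileSet}}.
#' @param cell_line cell line to analyse (default: the only one present).
#' @param scale total-mRNA pooling scale, see \code{\link{totalMrna}}.
#' @return a \code{\link{RegulationTable-class}} object.
#' @export
regulationTable <- function(x, cell_line = NULL,
                            scale = c("linear", "log")) {
    scale <- match.arg(scale)
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
    reps <- sort(unique(cd$replicate))
    ng <- nrow(m)
    tGC <- tE <- txn <- trans <- matrix(
        0, ng, length(reps),
        dimnames = list(rownames(m), paste0("r", reps)))
    for (j in seq_along(reps)) {
        r <- reps[j]
        pick <- function(tr, p)
            m[, cd$treatment == tr & cd$pool == p & cd$replicate == r]
        egc <- cbind(pick("GC", 1), pick("GC", 2), pick("GC", 3))
        eet <- cbind(pick("EtOH", 1), pick("EtOH", 2), pick("EtOH", 3))
        tGC[, j] <- totalMrna(egc[, 1], egc[, 2], egc[, 3], scale)
        tE[, j] <- totalMrna(eet[, 1], eet[, 2], eet[, 3], scale)
        reg <- translationalRegulation(egc, eet, scale)
        txn[, j] <- reg$txn_reg
        trans[, j] <- reg$trans_reg
    }
    methods::new("RegulationTable", geneIds = rownames(m),
                 cellLine = cell_line, tGC = tGC, tEtOH = tE,
                 txnReg = txn, transReg = trans, scale = scale)
}

#' ModeratedTestResult: empirical-Bayes moderated one-sample t-test
#'
#' Result container for \code{\link{moderatedOneSampleTest}}: the per-gene
#' table plus the global shrinkage hyperparameters.
#'
#' @slot table data.frame: gene_id, mean, t, p.value, adj.p.
#' @slot d0 prior degrees of freedom.
#' @slot s0sq prior variance.
#' @slot dfResidual residual df per gene (n - 1).
#' @slot dfTotal total df used for p-values (d0 + dfResidual).
#' @slot d0Capped TRUE if the moment estimator diverged and d0 was set to
#'   the documented cap (1e6).
#' @exportClass ModeratedTestResult
setClass("ModeratedTestResult",
         representation(table = "data.frame", d0 = "numeric",
                        s0sq = "numeric", dfResidual = "numeric",
                        dfTotal = "numeric", d0Capped = "logical"))

#' @export
setMethod("show", "ModeratedTestResult", function(object) {
    cat("ModeratedTestResult:", nrow(object@table), "genes\n")
    cat(sprintf("  d0 = %.4g%s, s0^2 = %.4g, residual df = %g, total df = %.4g\n",
                object@d0, if (object@d0Capped) " (capped)" else "",
                object@s0sq, object@dfResidual, object@dfTotal))
    cat("  min adjusted p =", format(min(object@table$adj.p), digits = 4),
        "\n")
})

#' @describeIn ModeratedTestResult-class the per-gene result table.
#' @param object a \code{ModeratedTestResult}
#' @export
testResults <- function(object) {
    stopifnot(is(object, "ModeratedTestResult"))
    object@table
}

#' @describeIn ModeratedTestResult-class the shrinkage hyperparameters as a
#'   named list.
#' @export
shrinkageParameters <- function(object) {
    stopifnot(is(object, "ModeratedTestResult"))
    list(d0 = object@d0, s0sq = object@s0sq,
         dfResidual = object@dfResidual, dfTotal = object@dfTotal,
         d0Capped = object@d0Capped)
}

D0_CAP <- 1e6

## Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
## which is nearly linear in y.
trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:75) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (abs(dif) / y < 1e-12) break
    }
    y
}

#' Empirical-Bayes moderated one-sample t-test
#'
#' Tests, per gene, whether the mean of the per-replicate translational
#' regulation values differs from zero, borrowing variance information
#' across genes. Per gene with \eqn{n} replicates: sample mean \eqn{m} and
#' variance \eqn{s^2} on \eqn{d = n - 1} df. The ensemble of variances is
#' modelled as scaled F: hyperparameters \eqn{(d_0, s_0^2)} are estimated by
#' matching the moments of \eqn{\log s^2} (digamma/trigamma closed forms,
#' trigamma inverted by Newton iteration). The posterior variance is
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' the moderated statistic \eqn{t = m / (\tilde s / \sqrt n)} with
#' \eqn{d_0 + d} degrees of freedom, and p-values are two-sided. If the
#' moment estimator diverges (near-constant variances), \eqn{d_0} is set to
#' the cap 1e6 and flagged.
#'
#' @param X numeric matrix, genes x replicates (>= 2 columns; >= 10 rows
#'   unless \code{d0} is forced), e.g. \code{transReg()} of a
#'   \code{\link{regulationTable}}.
#' @param d0 optional: force the prior df instead of estimating it
#'   (\code{0} gives the ordinary one-sample t-test; \code{Inf} or values
#'   above the cap give the fully pooled test \eqn{t = m\sqrt n / s_0}).
#' @param s0sq optional: force the prior variance (only used together with
#'   \code{d0}).
#' @return a \code{\link{ModeratedTestResult-class}} object (adjusted
#'   p-values by \code{\link{bhAdjust}} included).
#' @export
moderatedOneSampleTest <- function(X, d0 = NULL, s0sq = NULL) {
    X <- as.matrix(X)
    n <- ncol(X)
    if (n < 2L) stop("need at least 2 replicate columns")
    gene_id <- rownames(X)
    if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(X)))
    d <- n - 1
    m <- rowMeans(X)
    s2 <- apply(X, 1, stats::var)

    capped <- FALSE
    exact_pool <- FALSE
    if (is.null(d0)) {
        if (nrow(X) < 10L)
            stop("need >= 10 genes to estimate shrinkage hyperparameters")
        pos <- s2 > 0
        if (!any(pos)) {
            ## degenerate: no variance information at all
            capped <- TRUE
            d0 <- D0_CAP
            if (is.null(s0sq)) s0sq <- 0
        } else {
            e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
            emean <- mean(e)
            evar <- stats::var(e)
            target <- evar - trigamma(d / 2)
            if (is.na(target) || target <= 0) {
                capped <- TRUE
                d0 <- D0_CAP
            } else {
                d0 <- 2 * trigammaInverse(target)
                if (d0 > D0_CAP) { d0 <- D0_CAP; capped <- TRUE }
            }
            if (is.null(s0sq))
                s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        }
    } else {
        if (is.infinite(d0)) { exact_pool <- TRUE; d0 <- D0_CAP; capped <- TRUE }
        else if (d0 > D0_CAP) { d0 <- D0_CAP; capped <- TRUE }
        if (d0 > 0 && is.null(s0sq))
            stop("s0sq must be given when forcing d0 > 0")
        if (d0 == 0 && is.null(s0sq)) s0sq <- 0
    }

    ## forcing d0 = Inf takes the exact fully pooled limit s2post = s0sq
    s2post <- if (exact_pool) rep(s0sq, length(s2)) else
        (d0 * s0sq + d * s2) / (d0 + d)
    tstat <- m / sqrt(s2post / n)
    tstat[m == 0 & s2post == 0] <- 0
    df_total <- d0 + d
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    tab <- data.frame(gene_id = gene_id, mean = m, t = tstat, p.value = p,
                      adj.p = bhAdjust(p), row.names = NULL,
                      stringsAsFactors = FALSE)
    methods::new("ModeratedTestResult", table = tab, d0 = d0, s0sq = s0sq,
                 dfResidual = d, dfTotal = df_total, d0Capped = capped)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} n / j)}, returned in the
#' original order. Adjusted values are monotone in the raw p-value ranks and
#' never smaller than the raw values.
#'
#' @param p numeric vector of raw p-values in \code{[0, 1]}.
#' @return numeric vector of adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    n <- length(p)
    ord <- order(p)
    q <- rev(cummin(rev(pmin(1, p[ord] * n / seq_len(n)))))
    out <- numeric(n)
    out[ord] <- q
    out
}
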