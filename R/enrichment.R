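## Gene-set over-representation among poorly translated genes, and the
## TOP-motif mean-TE comparison.

#' Hypergeometric over-representation of gene sets
#'
#' For each set, tests whether its members are over-represented in a
#' selected gene list (e.g. the lowest-TE genes) relative to a background
#' universe. Each set is intersected with the background first; the overlap
#' \eqn{k} of the selected list (size \eqn{n}) with the set (size \eqn{K})
#' in a background of size \eqn{N} is scored with the hypergeometric upper
#' tail \eqn{P(X \ge k)}. P-values are BH-adjusted across all tested sets.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of \code{background}).
#' @param sets a \code{\link{GeneSetCollection}}.
#' @param background character vector, the background gene universe.
#' @return data.frame with one row per set: \code{set_id},
#'   \code{description}, \code{K}, \code{n}, \code{k}, \code{N},
#'   \code{p.value}, \code{adj.p}; sorted by p-value, ties by set id.
#' @export
hypergeomEnrichment <- function(selected, sets, background) {
    stopifnot(is(sets, "GeneSetCollection"))
    background <- unique(as.character(background))
    if (!length(background)) stop("empty background")
    selected <- unique(as.character(selected))
    if (!all(selected %in% background))
        stop("selected genes must be a subset of the background")
    N <- length(background)
    n <- length(selected)
    sl <- geneSets(sets)
    K <- k <- integer(length(sl))
    p <- numeric(length(sl))
    for (i in seq_along(sl)) {
        members <- intersect(sl[[i]], background)
        K[i] <- length(members)
        k[i] <- length(intersect(selected, members))
        p[i] <- stats::phyper(k[i] - 1, K[i], N - K[i], n,
                              lower.tail = FALSE)
    }
    out <- data.frame(set_id = names(sl),
                      description = unname(setDescriptions(sets)),
                      K = K, n = n, k = k, N = N, p.value = p,
                      adj.p = bhAdjust(p), stringsAsFactors = FALSE)
    out <- out[order(out$p.value, out$set_id), ]
    rownames(out) <- NULL
    out
}

#' Select the genes with the lowest translational efficiency
#'
#' The bottom \code{ceiling(fraction * N)} genes by TE, ties broken by gene
#' id. The caller restricts \code{te} to the intended universe (typically
#' expressed protein-coding genes).
#'
#' @param te named numeric vector of per-gene TE values.
#' @param fraction fraction in (0, 1) (default 0.05).
#' @return character vector of selected gene ids.
#' @export
lowTESelection <- function(te, fraction = 0.05) {
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must be in (0, 1)")
    if (is.null(names(te))) stop("te must be named by gene id")
    n_sel <- ceiling(fraction * length(te))
    ord <- order(te, names(te))
    names(te)[ord[seq_len(n_sel)]]
}

#' One-tailed comparison of TOP-motif gene TE against all genes
#'
#' Tests whether genes carrying a 5' terminal oligopyrimidine (TOP) motif
#' have on average a lower translational efficiency than the full set of
#' expressed protein-coding genes. By default a Welch (unequal-variance)
#' one-tailed two-sample t-test is used, with the TOP genes compared against
#' all genes (overlap included); \code{exclude_top} removes the TOP genes
#' from the comparison group (requires named vectors).
#'
#' @param te_top numeric vector of TE values of TOP-motif genes (length
#'   >= 2).
#' @param te_all numeric vector of TE values of all genes (length >= 2).
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @param exclude_top exclude TOP genes from \code{te_all} by name.
#' @return named list: \code{mean_top}, \code{mean_all}, \code{p.value},
#'   \code{statistic}, \code{df}.
#' @export
topMotifTest <- function(te_top, te_all, var_equal = FALSE,
                         exclude_top = FALSE) {
    if (exclude_top) {
        if (is.null(names(te_top)) || is.null(names(te_all)))
            stop("exclude_top requires named TE vectors")
        te_all <- te_all[setdiff(names(te_all), names(te_top))]
    }
    if (length(te_top) < 2L || length(te_all) < 2L)
        stop("both groups must have at least 2 values")
    ht <- stats::t.test(te_top, te_all, alternative = "less",
                        var.equal = var_equal)
    list(mean_top = mean(te_top), mean_all = mean(te_all),
         p.value = ht$p.value, statistic = unname(ht$statistic),
         df = unname(ht$parameter))
}
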