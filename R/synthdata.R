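#' Configuration for the synthetic translatome generator
#'
#' Bundles all parameters of \code{\link{generateDataset}}. Defaults emulate
#' the study design the package targets: two cell lines, paired GC/EtOH
#' treatments, three polysome pools and three biological replicates
#' (36 arrays), log2 expression on \code{[0, 16]}, a wide unimodal
#' translational-efficiency distribution with slight positive skew, and
#' non-coding biotypes concentrated in the non-translated pool.
#'
#' @param n_genes number of genes to simulate.
#' @param cell_lines character vector of cell line names (default two lines,
#'   mirroring a two-cell-line design).
#' @param n_replicates biological replicates per cell line (default 3).
#' @param biotype_proportions named numeric, fractions per biotype summing
#'   to 1; default is roughly 74\% protein_coding with the remainder spread
#'   over common non-coding classes.
#' @param abundance_log2_mean,abundance_log2_sd mean and sd of per-gene total
#'   mRNA abundance on the log2 scale (defaults 7 and 2; with the expression
#'   floor at 0 and the conventional expressed-gene threshold of 3 this
#'   leaves a realistic minority of genes below the filter).
#' @param te_concentration positive numeric(3); Dirichlet concentration of
#'   the pool-proportion prior for coding genes. The default \code{c(2,2,2)}
#'   gives translational efficiency (pool-3 proportion) distributed
#'   Beta(2, 4): unimodal, mean 1/3, slight positive skew.
#' @param noncoding_concentration positive numeric(3); prior for non-coding
#'   biotypes, shifted toward pool 1 (default \code{c(6, 1.5, 0.75)}).
#' @param noise_sd sd of per-array log2 replicate noise (default 0.25).
#' @param frac_txn_regulated,txn_effect_log2 fraction of genes with a
#'   transcriptional GC effect and its log2 fold-change size.
#' @param frac_trans_regulated,trans_effect_logodds fraction of genes with a
#'   translational GC effect and its size as an additive shift on the
#'   log-odds of pool 3 versus pools 1+2.
#' @param expression_floor,expression_ceiling clipping bounds of the log2
#'   scale (defaults 0 and 16).
#' @param seed integer root seed; all randomness in the generator derives
#'   from it.
#'
#' @return a validated \code{SyntheticConfig} object.
#' @seealso \code{\link{generateDataset}}, \code{\link{generateGeneSets}}
#' @export
syntheticConfig <- function(n_genes = 2000L,
                            cell_lines = c("CL1", "CL2"),
                            n_replicates = 3L,
                            biotype_proportions = c(
                                protein_coding = 0.74,
                                processed_transcript = 0.05,
                                lincRNA = 0.04,
                                pseudogene = 0.05,
                                snoRNA = 0.04,
                                snRNA = 0.03,
                                miRNA = 0.02,
                                misc_RNA = 0.03),
                            abundance_log2_mean = 7,
                            abundance_log2_sd = 2,
                            te_concentration = c(2, 2, 2),
                            noncoding_concentration = c(6, 1.5, 0.75),
                            noise_sd = 0.25,
                            frac_txn_regulated = 0,
                            txn_effect_log2 = 1,
                            frac_trans_regulated = 0,
                            trans_effect_logodds = 0,
                            expression_floor = 0,
                            expression_ceiling = 16,
                            seed = 1L) {
    cfg <- structure(class = "SyntheticConfig", list(
        n_genes = as.integer(n_genes),
        cell_lines = as.character(cell_lines),
        n_replicates = as.integer(n_replicates),
        biotype_proportions = biotype_proportions,
        abundance_log2_mean = abundance_log2_mean,
        abundance_log2_sd = abundance_log2_sd,
        te_concentration = te_concentration,
        noncoding_concentration = noncoding_concentration,
        noise_sd = noise_sd,
        frac_txn_regulated = frac_txn_regulated,
        txn_effect_log2 = txn_effect_log2,
        frac_trans_regulated = frac_trans_regulated,
        trans_effect_logodds = trans_effect_logodds,
        expression_floor = expression_floor,
        expression_ceiling = expression_ceiling,
        seed = as.integer(seed)))
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    stopifnot(cfg$n_genes >= 1L, cfg$n_replicates >= 1L,
              length(cfg$cell_lines) >= 1L)
    bp <- cfg$biotype_proportions
    if (is.null(names(bp)) || any(!nzchar(names(bp))))
        stop("biotype_proportions must be a named vector")
    if (any(bp < 0) || abs(sum(bp) - 1) > 1e-9)
        stop("biotype_proportions must be non-negative and sum to 1 (1e-9)")
    for (f in c("frac_txn_regulated", "frac_trans_regulated"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop(f, " must be in [0, 1]")
    if (length(cfg$te_concentration) != 3L || any(cfg$te_concentration <= 0))
        stop("te_concentration must be positive numeric(3)")
    if (length(cfg$noncoding_concentration) != 3L ||
        any(cfg$noncoding_concentration <= 0))
        stop("noncoding_concentration must be positive numeric(3)")
    if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
    if (cfg$expression_floor >= cfg$expression_ceiling)
        stop("expression_floor must be below expression_ceiling")
    invisible(TRUE)
}

#' @export
print.SyntheticConfig <- function(x, ...) {
    cat("SyntheticConfig:", x$n_genes, "genes,",
        length(x$cell_lines), "cell line(s),", x$n_replicates,
        "replicates, seed", x$seed, "\n")
    cat(sprintf("  noise_sd %g | txn: %g%% at %g log2 | trans: %g%% at %g log-odds\n",
                x$noise_sd, 100 * x$frac_txn_regulated, x$txn_effect_log2,
                100 * x$frac_trans_regulated, x$trans_effect_logodds))
    invisible(x)
}

## Dirichlet draw: ng x 3 matrix of pool proportions.
rdirichlet3 <- function(ng, alpha) {
    g <- cbind(stats::rgamma(ng, alpha[1]),
               stats::rgamma(ng, alpha[2]),
               stats::rgamma(ng, alpha[3]))
    g / rowSums(g)
}

## Shift the log-odds of pool 3 vs pools 1+2 by delta, renormalizing the
## composition; rows with delta = 0 are returned unchanged.
shiftPool3LogOdds <- function(pi, delta) {
    out <- pi
    i <- delta != 0
    if (any(i)) {
        p3 <- stats::plogis(stats::qlogis(pi[i, 3]) + delta[i])
        scale <- (1 - p3) / (1 - pi[i, 3])
        out[i, 1] <- pi[i, 1] * scale
        out[i, 2] <- pi[i, 2] * scale
        out[i, 3] <- p3
    }
    out
}

#' Generate a synthetic polysome-pool expression dataset with known truth
#'
#' Simulates a paired translational-profiling experiment. Per gene, a total
#' mRNA abundance is drawn log-normally on the log2 scale and a pool
#' composition \eqn{\pi = (\pi_1, \pi_2, \pi_3)} from a Dirichlet prior
#' (non-coding biotypes from a prior shifted toward pool 1). Under GC
#' treatment, transcriptionally regulated genes have their abundance
#' multiplied by \code{2^txn_effect_log2} and translationally regulated genes
#' have the log-odds of pool 3 versus pools 1+2 shifted by
#' \code{trans_effect_logodds} (composition renormalized). The observed
#' signal is \code{clip(log2(A * pi_pool) + noise, floor, ceiling)} with
#' independent Gaussian noise per array; GC and EtOH samples of the same
#' replicate index are paired. Gene-level draws use a dedicated substream of
#' the root seed, so changing \code{n_replicates} or \code{cell_lines} does
#' not reshuffle the per-gene truth.
#'
#' @param config a \code{\link{syntheticConfig}} object.
#' @return A list with elements
#'   \describe{
#'     \item{expression}{a \code{\link{PoolProfileSet}}}
#'     \item{truth}{data.frame of per-gene ground truth: biotype, log2
#'       abundance, EtOH pool proportions \code{pi1..pi3} (true TE =
#'       \code{pi3}), GC proportions \code{pi1_gc..pi3_gc}, regulation flags,
#'       injected effect sizes, and \code{trans_effect_log2}, the realized
#'       noise-free translational regulation \code{log2(pi3_gc/pi3)}.}
#'     \item{annotation}{data.frame in gene-annotation format (one
#'       representative transcript per gene).}
#'   }
#' @examples
#' sim <- generateDataset(syntheticConfig(n_genes = 100, seed = 7))
#' head(sim$truth)
#' @export
generateDataset <- function(config) {
    validateSyntheticConfig(config)
    ng <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(ng))

    ## gene-level substream: independent of replicate/cell-line settings
    set.seed(config$seed %% 1000000000L)
    biotype <- sample(names(config$biotype_proportions), ng, replace = TRUE,
                      prob = config$biotype_proportions)
    log2A <- stats::rnorm(ng, config$abundance_log2_mean,
                          config$abundance_log2_sd)
    coding <- biotype == "protein_coding"
    pi <- rdirichlet3(ng, config$te_concentration)
    pi_nc <- rdirichlet3(ng, config$noncoding_concentration)
    pi[!coding, ] <- pi_nc[!coding, ]
    n_txn <- round(config$frac_txn_regulated * ng)
    n_trans <- round(config$frac_trans_regulated * ng)
    txn_idx <- sample(ng, n_txn)
    trans_idx <- sample(ng, n_trans)
    txn_effect <- numeric(ng); txn_effect[txn_idx] <- config$txn_effect_log2
    trans_effect <- numeric(ng)
    trans_effect[trans_idx] <- config$trans_effect_logodds
    probe_count <- sample(2:30, ng, replace = TRUE)

    pi_gc <- shiftPool3LogOdds(pi, trans_effect)
    log2A_gc <- log2A + txn_effect

    design <- expand.grid(pool = 1:3,
                          treatment = TREATMENT_LEVELS,
                          replicate = seq_len(config$n_replicates),
                          cell_line = config$cell_lines,
                          stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    design <- design[, c("cell_line", "treatment", "pool", "replicate")]
    design$sample_id <- sprintf("%s_%s_p%d_r%d", design$cell_line,
                                design$treatment, design$pool,
                                design$replicate)
    design <- design[, c("sample_id", DESIGN_COLUMNS)]

    mu <- matrix(0, ng, 6,
                 dimnames = list(NULL, paste0(rep(TREATMENT_LEVELS, each = 3),
                                              "_p", 1:3)))
    for (p in 1:3) {
        mu[, p] <- log2A_gc + log2(pi_gc[, p])       # GC_p1..3
        mu[, p + 3] <- log2A + log2(pi[, p])         # EtOH_p1..3
    }

    vals <- matrix(0, ng, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
    ## noise substream per (cell line, replicate): draws within are ordered
    ## by treatment then pool, so gene draws stay aligned
    for (ci in seq_along(config$cell_lines)) {
        for (r in seq_len(config$n_replicates)) {
            set.seed((config$seed %% 1000000000L +
                      104729L * ci + 7919L * r) %% 2147483647L)
            for (tr in TREATMENT_LEVELS) {
                for (p in 1:3) {
                    sid <- sprintf("%s_%s_p%d_r%d", config$cell_lines[ci],
                                   tr, p, r)
                    eps <- if (config$noise_sd > 0)
                        stats::rnorm(ng, 0, config$noise_sd) else numeric(ng)
                    e <- mu[, paste0(tr, "_p", p)] + eps
                    vals[, sid] <- pmin(config$expression_ceiling,
                                        pmax(config$expression_floor, e))
                }
            }
        }
    }

    truth <- data.frame(
        gene_id = gene_ids,
        biotype = biotype,
        log2_abundance = log2A,
        pi1 = pi[, 1], pi2 = pi[, 2], pi3 = pi[, 3],
        pi1_gc = pi_gc[, 1], pi2_gc = pi_gc[, 2], pi3_gc = pi_gc[, 3],
        txn_regulated = seq_len(ng) %in% txn_idx,
        txn_effect = txn_effect,
        trans_regulated = seq_len(ng) %in% trans_idx,
        trans_effect = trans_effect,
        trans_effect_log2 = log2(pi_gc[, 3] / pi[, 3]),
        stringsAsFactors = FALSE)

    annotation <- data.frame(
        transcript_id = sub("^G", "T", gene_ids),
        gene_id = gene_ids,
        probe_count = probe_count,
        gene_name = sub("^G", "SYN", gene_ids),
        gene_biotype = biotype,
        chromosome_name = as.character(1 + (seq_len(ng) %% 22L)),
        stringsAsFactors = FALSE)

    expr <- PoolProfileSet(vals, design,
                           range = c(config$expression_floor,
                                     config$expression_ceiling))
    list(expression = expr, truth = truth, annotation = annotation)
}

#' Generate synthetic gene sets with controlled low-TE enrichment
#'
#' Builds gene-set fixtures for the over-representation analysis. Enriched
#' sets draw a fraction \code{enrichment_strength} of their members from the
#' bottom 5\% of genes by true translational efficiency (true \eqn{\pi_3})
#' and the rest uniformly from the remaining genes; control sets draw
#' uniformly from all genes.
#'
#' @param truth the \code{truth} data.frame from \code{\link{generateDataset}}.
#' @param n_sets total number of sets.
#' @param enriched_set_size members per set.
#' @param enrichment_strength fraction in \code{[0, 1]} of enriched-set
#'   members sampled from the low-TE tail.
#' @param seed integer seed.
#' @param n_enriched how many of the sets are enriched (default
#'   \code{max(1, n_sets \%/\% 4)}); set 0 for all-control sets.
#' @return a \code{\link{GeneSetCollection}}; enriched sets are named
#'   \code{ENR...} with description \code{"enriched"}, controls \code{CTL...}
#'   with \code{"control"}.
#' @export
generateGeneSets <- function(truth, n_sets = 20L, enriched_set_size = 50L,
                             enrichment_strength = 0.8, seed = 1L,
                             n_enriched = max(1L, n_sets %/% 4L)) {
    stopifnot(enrichment_strength >= 0, enrichment_strength <= 1,
              n_enriched <= n_sets)
    ng <- nrow(truth)
    if (enriched_set_size > ng)
        stop("enriched_set_size exceeds the number of genes")
    ord <- order(truth$pi3, truth$gene_id)
    n_low <- ceiling(0.05 * ng)
    low <- truth$gene_id[ord[seq_len(n_low)]]
    rest <- setdiff(truth$gene_id, low)
    set.seed(seed %% 2147483647L)
    sets <- vector("list", n_sets)
    descr <- character(n_sets)
    nm <- character(n_sets)
    for (i in seq_len(n_sets)) {
        if (i <= n_enriched) {
            k_low <- round(enrichment_strength * enriched_set_size)
            if (k_low > length(low))
                stop("enriched_set_size * enrichment_strength exceeds the low-TE tail")
            members <- c(sample(low, k_low),
                         sample(rest, enriched_set_size - k_low))
            nm[i] <- sprintf("ENR%03d", i)
            descr[i] <- "enriched"
        } else {
            members <- sample(truth$gene_id, enriched_set_size)
            nm[i] <- sprintf("CTL%03d", i - n_enriched)
            descr[i] <- "control"
        }
        sets[[i]] <- sort(unique(members))
    }
    names(sets) <- nm
    names(descr) <- nm
    GeneSetCollection(sets, descr)
}
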