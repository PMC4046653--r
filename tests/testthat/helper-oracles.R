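## Independent oracles used by the unit and acceptance tests. These are
## deliberately coded without reference to the package internals: uniroot
## instead of Newton for the trigamma inversion, explicit enumeration for
## BH and the hypergeometric tail.

## Moderated one-sample t: direct coding of the closed-form empirical-Bayes
## equations (log-variance moments, digamma/trigamma matching, posterior
## variance, t with d0 + d df).
oracleModeratedT <- function(X) {
    n <- ncol(X)
    d <- n - 1
    m <- apply(X, 1, mean)
    s2 <- apply(X, 1, function(v) sum((v - mean(v))^2) / d)
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    target <- stats::var(e) - trigamma(d / 2)
    if (target > 0) {
        d0 <- 2 * stats::uniroot(function(y) trigamma(y) - target,
                                 c(1e-6, 1e8), tol = 1e-14)$root
    } else {
        d0 <- 1e6
    }
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s0sq + d * s2) / (d0 + d)
    tstat <- m / sqrt(s2post / n)
    p <- 2 * stats::pt(-abs(tstat), df = d0 + d)
    list(d0 = d0, s0sq = s0sq, t = tstat, p = p)
}

## BH step-up by brute-force enumeration of the definition:
## q_(i) = min_{j >= i} min(1, p_(j) * n / j), back in input order.
oracleBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(n)
    for (i in seq_len(n)) {
        vals <- vapply(i:n, function(j) min(1, ps[j] * n / j), 0)
        q[i] <- min(vals)
    }
    out <- numeric(n)
    out[ord] <- q
    out
}

## Hypergeometric upper tail P(X >= k) by explicit combinatorial summation.
oracleHyperTail <- function(N, K, n, k) {
    jmax <- min(K, n)
    if (k > jmax) return(0)
    js <- k:jmax
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Sample skewness (adjusted Fisher-Pearson not needed; sign is what the
## tests assert).
sampleSkewness <- function(x) {
    mean((x - mean(x))^3) / stats::sd(x)^3
}

## Small hand-built PoolProfileSet: one cell line, values given per
## (treatment, pool, replicate) via a function or matrix list.
makeDesign <- function(cell_lines = "CL1", n_replicates = 3) {
    d <- expand.grid(pool = 1:3, treatment = c("GC", "EtOH"),
                     replicate = seq_len(n_replicates),
                     cell_line = cell_lines, stringsAsFactors = FALSE)
    d$sample_id <- sprintf("%s_%s_p%d_r%d", d$cell_line, d$treatment,
                           d$pool, d$replicate)
    d[, c("sample_id", "cell_line", "treatment", "pool", "replicate")]
}

## Build a PoolProfileSet from a genes x 6 matrix of pool means
## (GC p1..p3, EtOH p1..p3) replicated identically across replicates.
makeConstantPPS <- function(means, gene_ids = NULL, n_replicates = 3,
                            range = c(0, 16)) {
    if (is.null(dim(means))) means <- matrix(means, nrow = 1)
    if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(means)))
    design <- makeDesign(n_replicates = n_replicates)
    vals <- matrix(0, nrow(means), nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
    for (i in seq_len(nrow(design))) {
        col <- (design$treatment[i] == "EtOH") * 3 + design$pool[i]
        vals[, i] <- means[, col]
    }
    PoolProfileSet(vals, design, range = range)
}
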