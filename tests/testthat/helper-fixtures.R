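suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# tiny hand-built Ct container: 2 housekeepers + 2 genes, 3 cells
makeToyCt <- function(lod = 40) {
    ct <- rbind(Ubc    = c(14, 15, 14),
                Polr2a = c(16, 15, 18),
                GeneA  = c(20, 22, 24),
                GeneB  = c(25, lod, 26))
    colnames(ct) <- c("c1", "c2", "c3")
    detected <- ct < lod
    CtExperiment(ct, detected,
        cell_meta = data.frame(cell_id = colnames(ct),
                               population = c("HSC1", "HSC1", "HSC2")),
        assay_meta = data.frame(gene_name = rownames(ct),
                                is_housekeeper = c(TRUE, TRUE, FALSE, FALSE)),
        lod_ct = lod)
}

# planted 2-cluster feature matrix for embedding tests; the structure
# lives in the first two coordinates so a 2D map can represent it
makeBlobs <- function(n_per = 100, p = 10, sep = 20, sd = 1, seed = 1) {
    set.seed(seed)
    centers <- rbind(rep(0, 2), rep(sep, 2))
    lab <- rep(1:2, each = n_per)
    x <- cbind(matrix(rnorm(2 * n_per * 2, centers[lab, ], sd), 2 * n_per),
               matrix(rnorm(2 * n_per * (p - 2), 0, 0.1 * sd), 2 * n_per))
    rownames(x) <- sprintf("b%03d", seq_len(2 * n_per))
    colnames(x) <- sprintf("f%02d", seq_len(p))
    list(x = x, labels = lab)
}

# F1 of a MolO assignment against the planted truth
moloF1 <- function(assign, truth) {
    lab <- moloLabels(assign)
    pred <- stats::setNames(as.character(lab) == "MolO", names(lab))
    tr <- stats::setNames(truth$molo, truth$cell_id)[names(pred)]
    tp <- sum(pred & tr)
    fp <- sum(pred & !tr)
    fn <- sum(!pred & tr)
    2 * tp / (2 * tp + fp + fn)
}

# run one generator + embedding + MolO identification round
runMoloRound <- function(seed, k = 50, alpha = 0.05, n_perm = 499) {
    spec <- SimSpec(seed = as.integer(seed))
    sim <- simulateQPCR(spec)
    dct <- applyGeneExclusions(
        deltaCtNormalize(sim$ct, housekeepers = c("Ubc", "Polr2a")),
        c("Cdkn2a", "Egfl7"))
    emb <- embedTSNE(t(dctValues(dct)), seed = seed)
    labels <- stats::setNames(sim$truth$strategy, sim$truth$cell_id)
    w <- stats::setNames(spec@repop_prob, paste0("HSC", 1:5))
    assign <- identifyMolo(emb, labels, w, k = k, alpha = alpha,
                           n_perm = n_perm, seed = seed)
    list(spec = spec, sim = sim, dct = dct, emb = emb, assign = assign)
}

# independent brute-force helpers used as oracles --------------------------

bruteSizeFactors <- function(m) {
    usable <- rowSums(m == 0) == 0
    gm <- apply(m[usable, , drop = FALSE], 1, function(x) exp(mean(log(x))))
    sf <- apply(m[usable, , drop = FALSE] / gm, 2, median)
    sf / exp(mean(log(sf)))
}

bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

bruteKnnComposition <- function(xy, labels, k) {
    n <- nrow(xy)
    S <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
    t(vapply(seq_len(n), function(i) {
        d <- sqrt(colSums((t(xy) - xy[i, ])^2))
        nb <- order(d)[seq_len(k)]
        vapply(S, function(s) sum(labels[nb] == s) / k, numeric(1))
    }, numeric(length(S))))
}

# exact two-sided rank-sum p-value by full enumeration (no ties)
bruteWilcoxP <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    r <- rank(pooled)
    obs <- sum(r[seq_along(a)])
    combs <- utils::combn(n, length(a))
    sums <- apply(combs, 2, function(i) sum(rank(pooled)[i]))
    mu <- mean(sums)
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided Spearman p-value by permutation enumeration (no ties)
bruteSpearmanP <- function(x, y) {
    n <- length(x)
    perms <- .permutations(n)
    obs <- cor(x, y, method = "spearman")
    rhos <- apply(perms, 1, function(pm) cor(x, y[pm], method = "spearman"))
    mean(abs(rhos) >= abs(obs) - 1e-9)
}

.permutations <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- .permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

bruteLdaGrid <- function(doses, n_mice, n_neg) {
    ll <- function(f) {
        p_neg <- exp(-f * doses)
        sum(n_neg * log(p_neg) +
            (n_mice - n_neg) * log(pmax(1 - p_neg, 1e-300)))
    }
    grid <- exp(seq(log(1e-6), log(1), length.out = 20001))
    best <- grid[which.max(vapply(grid, ll, numeric(1)))]
    # refine around the coarse optimum, within the frequency domain
    fine <- seq(best * 0.99, min(best * 1.01, 1), length.out = 4001)
    fine[which.max(vapply(fine, ll, numeric(1)))]
}
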