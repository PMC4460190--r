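#' Median-of-ratios size factors
#'
#' For each cell, the median over usable genes (genes with a nonzero count
#' in every cell) of the ratio between the cell's count and the gene's
#' geometric mean, rescaled so the size factors have geometric mean 1. If no
#' gene is usable the per-cell library-size ratio is used instead, with a
#' warning. Scaling one cell's counts by `c` scales its factor by `c`.
#'
#' @param x a `SingleCellExperiment`/matrix of counts (genes x cells).
#'   Spike-in rows (rowData `is_spikein`) are excluded when flagged.
#' @return named numeric vector of positive per-cell size factors.
#' @export
computeSizeFactors <- function(x) {
    m <- .countsOf(x, drop_spikes = TRUE)
    usable <- rowSums(m == 0) == 0
    if (!any(usable)) {
        warning("no gene has nonzero counts in every cell; ",
                "falling back to library-size ratios")
        sf <- colSums(m)
        sf <- sf / .geomean(sf)
        return(stats::setNames(sf, colnames(m)))
    }
    mm <- m[usable, , drop = FALSE]
    gm <- apply(mm, 1, .geomean)
    sf <- apply(sweep(mm, 1, gm, "/"), 2, stats::median)
    stats::setNames(sf / .geomean(sf), colnames(m))
}

.countsOf <- function(x, drop_spikes = FALSE, spikes_only = FALSE) {
    if (is(x, "SummarizedExperiment")) {
        m <- assay(x, "counts")
        sp <- rowData(x)$is_spikein
        if (!is.null(sp)) {
            if (drop_spikes) m <- m[!sp, , drop = FALSE]
            if (spikes_only) m <- m[sp, , drop = FALSE]
        } else if (spikes_only)
            stop("no rowData()$is_spikein flag; cannot locate spike-ins")
        m
    } else {
        m <- as.matrix(x)
        if (spikes_only) stop("spike-in selection needs a SingleCellExperiment")
        m
    }
}

#' Fit technical noise on spike-ins
#'
#' Regresses the squared coefficient of variation of size-factor-normalized
#' spike-in counts on the reciprocal mean, `CV2 = a1 / mu + a0`, with a
#' gamma-family GLM (identity link); ordinary least squares is the fallback
#' if the GLM does not converge. Spike-ins are external standards of known
#' abundance, so their variability is purely technical: `a1` captures
#' shot noise (1 in the Poisson limit) and `a0` the asymptotic
#' multiplicative noise floor.
#'
#' @param x counts (`SingleCellExperiment` with `is_spikein` rowData, or a
#'   spike-in-only matrix).
#' @param sf per-cell size factors.
#' @param min_mean minimum normalized mean for a spike-in to enter the fit.
#' @param min_spikeins minimum spike-ins required above `min_mean`.
#' @return a [NoiseFit-class].
#' @export
fitTechnicalNoise <- function(x, sf, min_mean = 10, min_spikeins = 10) {
    sp <- if (is(x, "SummarizedExperiment"))
        .countsOf(x, spikes_only = TRUE) else as.matrix(x)
    norm <- sweep(sp, 2, sf, "/")
    mu <- rowMeans(norm)
    cv2 <- apply(norm, 1, stats::var) / mu^2
    keep <- is.finite(cv2) & mu >= min_mean
    if (sum(keep) < min_spikeins)
        stop(sum(keep), " spike-ins at normalized mean >= ", min_mean,
             " (need >= ", min_spikeins, "); lower min_mean")
    df <- data.frame(cv2 = cv2[keep], inv_mu = 1 / mu[keep])
    ols <- stats::lm(cv2 ~ inv_mu, data = df)
    fit <- tryCatch(
        stats::glm(cv2 ~ inv_mu, data = df,
                   family = stats::Gamma(link = "identity"),
                   start = pmax(stats::coef(ols), 1e-8)),
        error = function(e) ols, warning = function(w) ols)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    new("NoiseFit", a0 = unname(co[1]), a1 = unname(co[2]),
        se_a0 = unname(se[1]), se_a1 = unname(se[2]),
        min_mean = min_mean, n_spikeins = as.integer(sum(keep)),
        spike_stats = data.frame(gene = names(mu)[keep], mean = mu[keep],
                                 cv2 = cv2[keep]))
}

#' Call highly variable genes against the technical noise fit
#'
#' Per gene, the exceedance statistic `(n - 1) * CV2 / (a1 / mu + a0)` is
#' referred to the upper tail of a chi-square distribution with `n - 1`
#' degrees of freedom; q-values are Benjamini-Hochberg. A gene is variable
#' when it is significant at `fdr` *and* its CV2 exceeds the fitted curve.
#' `mode = "exceedance"` skips the test and flags plain exceedance of the
#' curve. Zero-variance genes get `p = 1` and are never variable.
#'
#' @param x counts (`SingleCellExperiment` or genes x cells matrix;
#'   spike-ins excluded when flagged).
#' @param sf per-cell size factors.
#' @param fit a [NoiseFit-class].
#' @param fdr FDR level (default 0.1).
#' @param mode `"chisq"` (default) or `"exceedance"`.
#' @return data.frame (gene, mean, cv2, tech_cv2, p, q, variable).
#' @export
callVariableGenes <- function(x, sf, fit, fdr = 0.1,
                              mode = c("chisq", "exceedance")) {
    mode <- match.arg(mode)
    m <- .countsOf(x, drop_spikes = TRUE)
    n <- ncol(m)
    norm <- sweep(m, 2, sf, "/")
    mu <- rowMeans(norm)
    v <- apply(norm, 1, stats::var)
    cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
    tech <- technicalCV2(fit, mu)
    stat <- (n - 1) * cv2 / tech
    p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
    p[!is.finite(p) | v == 0] <- 1
    q <- stats::p.adjust(p, "BH")
    exceeds <- is.finite(cv2) & cv2 > tech & v > 0
    variable <- if (mode == "chisq") q <= fdr & exceeds else exceeds
    data.frame(gene = rownames(m), mean = mu, cv2 = cv2, tech_cv2 = tech,
               p = p, q = q, variable = variable, row.names = NULL)
}

#' Log-normalized expression
#'
#' `log2(count / size_factor + 1)`, genes x cells — the expression scale
#' used for PCA and score correlation.
#'
#' @param x counts (`SingleCellExperiment` or matrix).
#' @param sf per-cell size factors.
#' @return numeric matrix, genes x cells.
#' @export
normalizedLogExpression <- function(x, sf) {
    m <- .countsOf(x)
    log2(sweep(m, 2, sf, "/") + 1)
}

#' PCA of cells on the variable genes
#'
#' Centered (optionally scaled) principal component analysis of cells on
#' log-normalized expression over a gene set.
#'
#' @param expr numeric matrix, genes x cells (e.g. variable genes only).
#' @param n_components components to return.
#' @param scale. scale genes to unit variance (default FALSE).
#' @return list with `scores` (cells x PCs), `loadings` (genes x PCs,
#'   orthonormal), `var_explained` (fractions).
#' @export
pcaCells <- function(expr, n_components = 10, scale. = FALSE) {
    if (ncol(expr) < 3) stop("need at least 3 cells")
    fit <- stats::prcomp(t(expr), center = TRUE, scale. = scale.)
    n_components <- min(n_components, ncol(fit$rotation))
    list(scores = fit$x[, seq_len(n_components), drop = FALSE],
         loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
         var_explained = fit$sdev^2 / sum(fit$sdev^2))
}

#' Rank genes by correlation with a per-cell score
#'
#' Per gene, Spearman rank correlation of expression with the score (MolO
#' or SuMO) with a two-sided p-value, Benjamini-Hochberg corrected;
#' significant positive and negative sets are reported separately via the
#' `direction` column. Constant genes (undefined correlation) are excluded
#' and counted in `attr(x, "n_constant")`.
#'
#' @param expr numeric matrix, genes x cells (log-normalized expression).
#' @param score a [MolOScore-class]/[SuMOScore-class] or named numeric,
#'   matched to columns of `expr` by cell id.
#' @param fdr FDR level (default 0.1).
#' @return data.frame (gene, rho, p, q, direction, significant) ranked by
#'   rho.
#' @export
correlateGenesWithScore <- function(expr, score, fdr = 0.1) {
    s <- if (is(score, "MolOScore") || is(score, "SuMOScore"))
        cellScores(score) else score
    if (!is.null(names(s)) && !is.null(colnames(expr)))
        s <- s[.matchCells(colnames(expr), names(s), "scored cells")]
    if (ncol(expr) < 5) stop("need at least 5 cells")
    constant <- apply(expr, 1, function(x) stats::sd(x) == 0)
    keep <- which(!constant)
    res <- do.call(rbind, lapply(keep, function(g) {
        ct <- suppressWarnings(
            stats::cor.test(expr[g, ], s, method = "spearman"))
        data.frame(gene = rownames(expr)[g], rho = unname(ct$estimate),
                   p = ct$p.value)
    }))
    res$q <- stats::p.adjust(res$p, "BH")
    res$direction <- ifelse(res$rho >= 0, "positive", "negative")
    res$significant <- res$q <= fdr
    res <- res[order(res$rho, decreasing = TRUE), ]
    attr(res, "n_constant") <- sum(constant)
    res
}
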