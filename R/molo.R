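#' Normalized repopulation weights
#'
#' Converts per-strategy repopulation probabilities into the mixture weights
#' the neighborhood search targets: `w_s = p_s / sum(p)`, non-negative and
#' summing to one.
#'
#' @param p named numeric of per-strategy repopulation probabilities in
#'   `[0, 1]`.
#' @return named numeric weight vector summing to 1.
#' @export
repopWeights <- function(p) {
    stopifnot(!is.null(names(p)), all(p >= 0), all(p <= 1), sum(p) > 0)
    p / sum(p)
}

#' Per-cell neighborhood strategy composition
#'
#' For every HSC-strategy cell, the fraction of each sorting strategy among
#' its `k` nearest HSC-strategy cells (Euclidean metric on the 2D embedding,
#' the cell itself included). Distance ties are broken by cell index order.
#'
#' @param emb an [Embedding2D-class].
#' @param labels per-cell strategy labels, named by cell id or aligned with
#'   the embedding rows.
#' @param k neighborhood size (must be below the number of HSC cells).
#' @param strategies which labels count as HSC strategies; other cells are
#'   excluded from neighborhoods. Default: all observed labels.
#' @return matrix (HSC cells x strategies) of compositions, rows summing to
#'   1, with the neighbor index matrix in `attr(x, "neighbors")`.
#' @export
neighborhoodComposition <- function(emb, labels, k = 50,
                                    strategies = NULL) {
    xy <- coords(emb)
    labels <- .alignLabels(labels, rownames(xy))
    if (is.null(strategies)) strategies <- sort(unique(labels))
    hsc <- which(labels %in% strategies)
    n_hsc <- length(hsc)
    if (k >= n_hsc) {
        if (k > n_hsc) stop("k (", k, ") exceeds the ", n_hsc, " HSC cells")
    }
    xy_h <- xy[hsc, , drop = FALSE]
    lab_h <- factor(labels[hsc], levels = strategies)
    d <- as.matrix(stats::dist(xy_h))
    # stable order breaks distance ties by cell index
    ni <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
    comp <- .compositionFromNeighbors(ni, as.integer(lab_h),
                                      length(strategies)) / k
    dimnames(comp) <- list(rownames(xy_h), strategies)
    attr(comp, "neighbors") <- ni
    attr(comp, "hsc_cells") <- rownames(xy_h)
    comp
}

# counts of each label value among the neighbors of each cell
.compositionFromNeighbors <- function(ni, lab_int, n_levels) {
    m <- matrix(lab_int[ni], nrow(ni), ncol(ni))
    vapply(seq_len(n_levels), function(s) rowSums(m == s),
           numeric(nrow(ni)))
}

.alignLabels <- function(labels, ids) {
    labels <- stats::setNames(as.character(labels),
                              if (is.null(names(labels))) ids
                              else names(labels))
    out <- labels[ids]
    if (anyNA(out)) stop("labels missing for some embedded cells")
    out
}

#' Identify the molecular overlapping (MolO) subpopulation
#'
#' Searches the 2D embedding for cells whose local neighborhood is composed
#' of the HSC sorting strategies in proportions matching their repopulation
#' probabilities. Each HSC cell's neighborhood composition is compared with
#' the normalized weight vector by Jensen-Shannon divergence (nats); a
#' permutation null — strategy labels shuffled over the HSC cells, neighbor
#' geometry fixed — yields a per-cell p-value
#' `p_i = (1 + #\{d_null <= d_i\}) / (1 + n_perm)`, and a cell is labeled
#' MolO when its divergence falls at or below the `alpha`-quantile of its
#' null (`p_i <= alpha`). Cells from strategies without a weight are labeled
#' `non-HSC`; remaining HSC cells are `NoMO`. The decision is invariant to
#' uniform rescaling of the embedding coordinates.
#'
#' @param emb an [Embedding2D-class].
#' @param labels per-cell strategy labels (named by cell id or aligned).
#' @param weights named per-strategy repopulation probabilities (see
#'   [repopWeights()]); at least two strategies must have nonzero weight.
#' @param k neighborhood size.
#' @param alpha decision level: the null quantile below which a cell counts
#'   as matching the target mixture.
#' @param n_perm number of label permutations (values below 100 warn).
#' @param seed integer seed for the permutations.
#' @return a [MolOAssignment-class].
#' @export
identifyMolo <- function(emb, labels, weights, k = 50, alpha = 0.05,
                         n_perm = 999, seed = 0L) {
    stopifnot(!is.null(names(weights)))
    if (sum(weights > 0) < 2)
        stop("need at least two strategies with nonzero weight")
    if (n_perm < 100)
        warning("n_perm < 100 gives an unstable MolO threshold")
    xy <- coords(emb)
    labels <- .alignLabels(labels, rownames(xy))
    strategies <- names(weights)
    w <- repopWeights(weights)

    comp <- neighborhoodComposition(emb, labels, k = k,
                                    strategies = strategies)
    ni <- attr(comp, "neighbors")
    hsc_ids <- attr(comp, "hsc_cells")
    lab_int <- as.integer(factor(labels[hsc_ids], levels = strategies))
    d_obs <- .jsdRows(comp, w)

    set.seed(as.integer(seed))
    n_hsc <- length(hsc_ids)
    exceed <- integer(n_hsc)
    for (b in seq_len(n_perm)) {
        perm <- lab_int[sample.int(n_hsc)]
        cmp <- .compositionFromNeighbors(ni, perm, length(strategies)) / k
        exceed <- exceed + (.jsdRows(cmp, w) <= d_obs)
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
    call_molo <- p_perm <= alpha

    all_ids <- rownames(xy)
    label_out <- factor(rep("non-HSC", length(all_ids)),
                        levels = c("MolO", "NoMO", "non-HSC"))
    names(label_out) <- all_ids
    label_out[hsc_ids] <- ifelse(call_molo, "MolO", "NoMO")
    div_out <- p_out <- rep(NA_real_, length(all_ids))
    div_out[match(hsc_ids, all_ids)] <- d_obs
    p_out[match(hsc_ids, all_ids)] <- p_perm

    new("MolOAssignment", cell_id = all_ids, label = unname(label_out),
        divergence = div_out, p_perm = p_out, k = as.integer(k),
        weights = w, alpha = alpha, n_perm = as.integer(n_perm))
}

#' Genes differentially expressed between MolO and NoMO cells
#'
#' Two-sided Wilcoxon rank-sum test per gene on delta-Ct values, with
#' Benjamini-Hochberg correction. Direction is the sign of the median
#' delta-Ct difference; since lower delta-Ct means higher expression,
#' `direction = "up"` marks genes more highly expressed in MolO cells.
#'
#' @param dct a [DeltaCtExperiment-class].
#' @param assign a [MolOAssignment-class]; both groups need at least
#'   `min_cells` cells present in `dct`.
#' @param fdr significance level on the BH-adjusted q-values.
#' @param min_cells minimum group size.
#' @return data.frame (gene, median_molo, median_nomo, direction, p, q,
#'   significant), ordered by q then p.
#' @export
moloDifferentialGenes <- function(dct, assign, fdr = 0.05, min_cells = 5) {
    lab <- moloLabels(assign)
    ids <- colData(dct)$cell_id
    lab <- lab[ids[ids %in% names(lab)]]
    g_molo <- names(lab)[lab == "MolO"]
    g_nomo <- names(lab)[lab == "NoMO"]
    if (length(g_molo) < min_cells || length(g_nomo) < min_cells)
        stop("too few cells per group: MolO = ", length(g_molo),
             ", NoMO = ", length(g_nomo), " (need >= ", min_cells, ")")
    m <- dctValues(dct)
    res <- do.call(rbind, lapply(seq_len(nrow(m)), function(g) {
        a <- m[g, g_molo]
        b <- m[g, g_nomo]
        p <- if (stats::sd(c(a, b)) == 0) 1 else
            suppressWarnings(stats::wilcox.test(a, b)$p.value)
        data.frame(gene = rowData(dct)$gene_name[g],
                   median_molo = stats::median(a),
                   median_nomo = stats::median(b), p = p)
    }))
    res$direction <- ifelse(res$median_molo < res$median_nomo, "up", "down")
    res$q <- stats::p.adjust(res$p, "BH")
    res$significant <- res$q <= fdr
    res[order(res$q, res$p), ]
}

#' Index-sort markers distinguishing MolO from NoMO cells
#'
#' Per-channel two-sided Wilcoxon rank-sum test of recorded intensities
#' between MolO and NoMO cells, BH-corrected and ranked — a shortlist for
#' designing a prospective sorting gate. Direction `"up"` marks channels
#' with higher median intensity in MolO cells.
#'
#' @param idx an [IndexSortTable-class] joinable to the assignment by
#'   cell id.
#' @param assign a [MolOAssignment-class].
#' @param fdr significance level on q-values.
#' @return data.frame (channel, median_molo, median_nomo, direction, p, q,
#'   significant) ranked by q then p; unjoinable cells are counted in
#'   `attr(x, "n_unjoined")`.
#' @export
indexMarkerEnrichment <- function(idx, assign, fdr = 0.05) {
    lab <- moloLabels(assign)
    common <- intersect(cellIds(idx), names(lab)[lab %in% c("MolO", "NoMO")])
    n_unjoined <- sum(!cellIds(idx) %in% names(lab))
    ch <- channelData(idx)[match(common, cellIds(idx)), , drop = FALSE]
    grp <- lab[common]
    if (!any(grp == "MolO") || !any(grp == "NoMO"))
        stop("both MolO and NoMO cells are required in the index table")
    res <- do.call(rbind, lapply(colnames(ch), function(cn) {
        a <- ch[grp == "MolO", cn]
        b <- ch[grp == "NoMO", cn]
        data.frame(channel = cn,
                   median_molo = stats::median(a),
                   median_nomo = stats::median(b),
                   p = suppressWarnings(stats::wilcox.test(a, b)$p.value))
    }))
    res$direction <- ifelse(res$median_molo > res$median_nomo, "up", "down")
    res$q <- stats::p.adjust(res$p, "BH")
    res$significant <- res$q <= fdr
    res <- res[order(res$q, res$p), ]
    attr(res, "n_unjoined") <- n_unjoined
    res
}
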