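#' Housekeeper-normalize a Ct matrix
#'
#' Computes per-cell delta-Ct values by subtracting the mean Ct of the
#' detected housekeeping assays from every other assay of that cell:
#' `dCt[g, i] = Ct[g, i] - mean(Ct[HK, i])`. Lower delta-Ct means higher
#' expression, and the transform is invariant to adding a constant to all of
#' a cell's Ct values. Cells in which fewer than `min_hk_detected`
#' housekeepers amplified are dropped and recorded. Housekeeper assays are
#' removed from the result; undetected entries map to
#' `lod_ct - mean(Ct[HK, i])`.
#'
#' @param ct a [CtExperiment-class].
#' @param housekeepers housekeeper assay names to normalize against;
#'   defaults to all assays flagged `is_housekeeper`. In the canonical
#'   panel, two of the three housekeepers (Ubc and Polr2a) are used.
#' @param min_hk_detected minimum detected housekeepers per retained cell.
#' @return a [DeltaCtExperiment-class]; dropped cells in
#'   `metadata(x)$dropped_cells`, removed assays in `excludedAssays(x)`.
#' @examples
#' # a cell with housekeeper Cts (14, 16) and a gene Ct of 20 has dCt = 5
#' @export
deltaCtNormalize <- function(ct, housekeepers = NULL,
                             min_hk_detected = NULL) {
    stopifnot(is(ct, "CtExperiment"))
    all_hk <- rowData(ct)$gene_name[rowData(ct)$is_housekeeper]
    if (is.null(housekeepers)) housekeepers <- all_hk
    miss <- setdiff(housekeepers, rowData(ct)$gene_name)
    if (length(miss))
        stop("housekeeper(s) not on the panel: ", paste(miss, collapse = ", "))
    if (is.null(min_hk_detected)) min_hk_detected <- length(housekeepers)
    hk_idx <- match(housekeepers, rowData(ct)$gene_name)
    vals <- ctValues(ct)
    det <- isDetected(ct)

    hk_ok <- colSums(det[hk_idx, , drop = FALSE]) >= min_hk_detected
    if (!any(hk_ok))
        stop("no cells with ", min_hk_detected, " detected housekeepers")
    dropped <- colData(ct)$cell_id[!hk_ok]

    keep_cells <- which(hk_ok)
    hk_mean <- colMeans(vals[hk_idx, keep_cells, drop = FALSE])
    keep_assays <- which(!rowData(ct)$gene_name %in% all_hk)
    dct <- sweep(vals[keep_assays, keep_cells, drop = FALSE], 2, hk_mean)

    se <- SummarizedExperiment(
        assays = list(dct = dct,
                      detected = det[keep_assays, keep_cells, drop = FALSE]),
        rowData = rowData(ct)[keep_assays, , drop = FALSE],
        colData = colData(ct)[keep_cells, , drop = FALSE])
    out <- new("DeltaCtExperiment", se)
    metadata(out)$excluded_assays <- data.frame(
        gene_name = all_hk, reason = "housekeeper")
    metadata(out)$dropped_cells <- dropped
    metadata(out)$housekeepers_used <- housekeepers
    out
}

#' Remove assays from a delta-Ct matrix
#'
#' Drops named genes (e.g. assays that failed technically or are silent in
#' all populations) before downstream analysis, recording each removal with
#' a reason. With the canonical 48-assay panel — 3 housekeepers removed at
#' normalization, then Cdkn2a and Egfl7 dropped here — 43 analysis genes
#' remain.
#'
#' @param dct a [DeltaCtExperiment-class].
#' @param drop gene names to remove; absent names produce a warning.
#' @param reason recorded reason string.
#' @return the trimmed [DeltaCtExperiment-class].
#' @export
applyGeneExclusions <- function(dct, drop, reason = "excluded") {
    stopifnot(is(dct, "DeltaCtExperiment"))
    if (!length(drop)) return(dct)
    present <- drop[drop %in% rowData(dct)$gene_name]
    absent <- setdiff(drop, present)
    if (length(absent))
        warning("gene(s) not on the panel, skipped: ",
                paste(absent, collapse = ", "))
    out <- dct[!rowData(dct)$gene_name %in% present, ]
    out <- new("DeltaCtExperiment", out)
    metadata(out)$excluded_assays <- rbind(
        metadata(dct)$excluded_assays,
        if (length(present)) data.frame(gene_name = present, reason = reason))
    out
}

#' Spearman correlation distance between cell profiles
#'
#' `d(i, j) = 1 - rho(x_i, x_j)` with Spearman's rank correlation, so the
#' distance lies in `[0, 2]`, is zero on identical rank profiles, and is
#' invariant to monotone transforms of a cell's profile. Cells with a
#' constant profile (undefined rank correlation) are placed at the
#' uninformative distance 1 from everything, with a warning.
#'
#' @param m numeric matrix, cells in rows.
#' @return a [stats::dist] object.
#' @export
spearmanDistance <- function(m) {
    constant <- apply(m, 1, function(x) stats::sd(x) == 0)
    rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    if (any(constant)) {
        warning(sum(constant),
                " constant-profile cell(s) placed at neutral distance 1")
        rho[constant, ] <- 0
        rho[, constant] <- 0
        diag(rho) <- 1
    }
    stats::as.dist(1 - rho)
}

#' Hierarchically cluster cells on delta-Ct profiles
#'
#' Ward linkage on the Spearman correlation distance between cell profiles,
#' cut into `n_cell_clusters` groups; the tree is also serialized as Newick
#' text.
#'
#' @param dct a [DeltaCtExperiment-class] or numeric matrix (cells x genes).
#' @param n_cell_clusters number of clusters to cut the tree into.
#' @return list with `labels` (named integer cluster per cell), `hclust`
#'   (the tree), and `newick` (Newick serialization).
#' @export
hierarchicalCluster <- function(dct, n_cell_clusters = 2) {
    m <- if (is(dct, "DeltaCtExperiment")) t(dctValues(dct)) else as.matrix(dct)
    if (nrow(m) < 2 || ncol(m) < 2)
        stop("need at least 2 cells and 2 genes")
    d <- spearmanDistance(m)
    hc <- stats::hclust(d, method = "ward.D2")
    labels <- stats::cutree(hc, k = n_cell_clusters)
    phy <- ape::as.phylo(hc)
    list(labels = labels, hclust = hc, newick = ape::write.tree(phy))
}
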