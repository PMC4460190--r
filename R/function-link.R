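#' Joint embedding of sequenced and transplanted cells on surface markers
#'
#' Pools the index-sort phenotypes of the RNA-seq cells and the transplanted
#' cells, z-scores each channel jointly (channels matched by name, so column
#' order is irrelevant), and embeds the pooled matrix with t-SNE. Per-point
#' provenance (`"seq"` vs `"tx"`) is recorded.
#'
#' @param idx_seq,idx_tx [IndexSortTable-class]s sharing the same channel
#'   set (e.g. the 11 recorded parameters).
#' @param perplexity,seed,init_dims passed to [embedTSNE()].
#' @return an [Embedding2D-class] with `attr(coords(x), "provenance")`
#'   giving the source table per point.
#' @export
jointMarkerEmbedding <- function(idx_seq, idx_tx, perplexity = 30,
                                 seed = 0L, init_dims = 30L) {
    ch_s <- sort(channelNames(idx_seq))
    ch_t <- sort(channelNames(idx_tx))
    if (!identical(ch_s, ch_t)) {
        asym <- c(setdiff(ch_s, ch_t), setdiff(ch_t, ch_s))
        stop("channel sets differ between tables: ",
             paste(asym, collapse = ", "))
    }
    pooled <- rbind(channelData(idx_seq)[, ch_s, drop = FALSE],
                    channelData(idx_tx)[, ch_s, drop = FALSE])
    rownames(pooled) <- c(cellIds(idx_seq), cellIds(idx_tx))
    if (anyDuplicated(rownames(pooled)))
        stop("cell ids overlap between the two tables")
    z <- .zscoreCols(pooled)
    emb <- embedTSNE(z, perplexity = perplexity, seed = seed,
                     init_dims = init_dims, input_kind = "surface_markers")
    attr(emb@coords, "provenance") <- rep(c("seq", "tx"),
                                          c(nrow(channelData(idx_seq)),
                                            nrow(channelData(idx_tx))))
    emb
}

#' Fit the SuMO axis and score cells
#'
#' The surface-marker overlap (SuMO) score is the signed projection of each
#' cell onto the first total-least-squares direction (leading eigenvector of
#' the 2x2 coordinate covariance) of the joint marker embedding — a linear
#' model through the cells in 2D, symmetric in the two arbitrary axes. The
#' sign is fixed so that the Spearman correlation between SuMO and the
#' available MolO scores (on the sequenced subset) is non-negative; up to
#' that sign the score is invariant to rotation and translation of the
#' embedding.
#'
#' @param emb an [Embedding2D-class] (at least 3 points).
#' @param molo a [MolOScore-class] or named numeric covering at least 3
#'   embedded cells.
#' @return a [SuMOScore-class].
#' @export
fitSumoAxis <- function(emb, molo) {
    xy <- coords(emb)
    if (nrow(xy) < 3) stop("need at least 3 embedded points")
    s <- if (is(molo, "MolOScore")) cellScores(molo) else molo
    common <- intersect(rownames(xy), names(s))
    if (length(common) < 3)
        stop("MolO scores available for fewer than 3 embedded cells")
    ctr <- colMeans(xy)
    cv <- stats::cov(xy)
    eig <- eigen(cv, symmetric = TRUE)
    if (eig$values[2] > 0 && eig$values[1] / eig$values[2] < 1.05)
        warning("near-isotropic cloud (eigenvalue ratio < 1.05); ",
                "SuMO axis is weakly determined")
    axis <- eig$vectors[, 1]
    proj <- as.numeric(sweep(xy, 2, ctr) %*% axis)
    names(proj) <- rownames(xy)
    rho <- suppressWarnings(
        stats::cor(proj[common], s[common], method = "spearman"))
    flipped <- isTRUE(rho < 0)
    if (flipped) {
        axis <- -axis
        proj <- -proj
    }
    prov <- attr(xy, "provenance") %||% rep("seq", nrow(xy))
    new("SuMOScore", cell_id = rownames(xy), score = unname(proj),
        axis = axis, center = unname(ctr), flipped = flipped,
        provenance = prov)
}

#' Test enrichment of values across the two embedding regions
#'
#' Partitions the embedding into two regions by Ward clustering of the
#' coordinates, then tests each supplied per-cell variable across regions:
#' numeric variables by two-sided Wilcoxon rank-sum, binary/logical
#' outcomes by Fisher's exact test; BH correction across all variables
#' tested.
#'
#' @param emb an [Embedding2D-class].
#' @param values data.frame of per-cell variables (rownames = cell ids, or
#'   aligned with the embedding); or a single named vector.
#' @param partition optional precomputed 2-level per-cell labels; default
#'   Ward 2-cut of the coordinates.
#' @return data.frame (variable, test, p, q) plus `attr(x, "partition")`.
#' @export
regionEnrichment <- function(emb, values, partition = NULL) {
    xy <- coords(emb)
    if (is.null(partition)) {
        hc <- stats::hclust(stats::dist(xy), method = "ward.D2")
        partition <- stats::cutree(hc, k = 2)
    }
    partition <- factor(partition)
    if (nlevels(partition) != 2 || any(table(partition) == 0))
        stop("partition must define two non-empty regions")
    if (!is.data.frame(values)) {
        nm <- deparse(substitute(values))
        values <- stats::setNames(data.frame(values), nm)
    }
    if (!is.null(rownames(values)) &&
        all(rownames(xy) %in% rownames(values)))
        values <- values[rownames(xy), , drop = FALSE]
    res <- do.call(rbind, lapply(names(values), function(v) {
        x <- values[[v]]
        if (is.logical(x) || all(x %in% c(0, 1), na.rm = TRUE)) {
            p <- stats::fisher.test(table(factor(as.integer(x),
                                                 levels = 0:1),
                                          partition))$p.value
            test <- "fisher"
        } else {
            p <- suppressWarnings(
                stats::wilcox.test(x[partition == levels(partition)[1]],
                                   x[partition == levels(partition)[2]])$p.value)
            test <- "wilcoxon"
        }
        data.frame(variable = v, test = test, p = p)
    }))
    res$q <- stats::p.adjust(res$p, "BH")
    attr(res, "partition") <- stats::setNames(partition, rownames(xy))
    res
}

#' Call repopulation and lineage-bias subtype per mouse
#'
#' Donor chimerism is `100 * donor / (donor + recipient)` per lineage and
#' timepoint. A mouse is repopulated when donor WBC chimerism reaches the
#' threshold (inclusive) at week 16 and/or week 24. Among repopulated mice,
#' the subtype follows the myeloid-to-lymphoid contribution ratio at week
#' 16, `rho = donor% GM / mean(donor% B, donor% T)`: `alpha` when
#' `rho > hi`, `beta` when `lo <= rho <= hi`, `gamma` when `rho < lo` with
#' WBC chimerism at threshold, `delta` otherwise among mice repopulated in
#' any lineage. Mice missing a lineage needed for the ratio are flagged
#' subtype `none`. Increasing donor counts can never flip a repopulated
#' call to not-repopulated.
#'
#' @param tx long transplant data.frame (see [readTransplantTable()]).
#' @param threshold_pct chimerism threshold in percent (default 1).
#' @param hi,lo subtype ratio cutoffs (defaults 2 and 0.25).
#' @return data.frame (mouse_id, dose, wbc16, wbc24, repopulated, ratio,
#'   subtype).
#' @export
callRepopulation <- function(tx, threshold_pct = 1, hi = 2, lo = 0.25) {
    tx$pct <- 100 * tx$donor / (tx$donor + tx$recipient)
    per_mouse <- split(tx, tx$mouse_id)
    out <- do.call(rbind, lapply(per_mouse, function(d) {
        get_pct <- function(wk, lin) {
            v <- d$pct[d$week == wk & d$lineage == lin]
            if (length(v)) v[1] else NA_real_
        }
        wbc16 <- get_pct(16, "WBC")
        wbc24 <- get_pct(24, "WBC")
        if (is.na(wbc16) && is.na(wbc24))
            stop("mouse ", d$mouse_id[1],
                 ": no WBC counts at week 16 or 24")
        repop <- isTRUE(wbc16 >= threshold_pct) ||
            isTRUE(wbc24 >= threshold_pct)
        gm <- get_pct(16, "GM")
        bl <- get_pct(16, "B")
        tl <- get_pct(16, "T")
        ratio <- gm / mean(c(bl, tl))
        subtype <- "none"
        if (repop) {
            if (anyNA(c(gm, bl, tl))) subtype <- "none"
            else if (ratio > hi) subtype <- "alpha"
            else if (ratio >= lo) subtype <- "beta"
            else subtype <- "gamma"
        } else {
            # lineage-restricted output without WBC repopulation
            any_lineage <- any(d$pct[d$week %in% c(16, 24) &
                                     d$lineage != "WBC"] >= threshold_pct)
            if (isTRUE(any_lineage)) subtype <- "delta"
        }
        data.frame(mouse_id = d$mouse_id[1], dose = d$dose[1],
                   wbc16 = wbc16, wbc24 = wbc24, repopulated = repop,
                   ratio = ratio, subtype = subtype)
    }))
    rownames(out) <- NULL
    out
}

# log-likelihood of frequency f under the single-hit Poisson model
.ldaLogLik <- function(f, dose, n_mice, n_neg) {
    p_neg <- exp(-f * dose)
    n_pos <- n_mice - n_neg
    ll <- n_neg * (-f * dose)
    pos_term <- ifelse(n_pos > 0, n_pos * log(pmax(1 - p_neg, 1e-300)), 0)
    sum(ll + pos_term)
}

#' Limiting-dilution frequency estimate
#'
#' Single-hit Poisson model: a recipient of dose `d` stays negative with
#' probability `exp(-f * d)`. The frequency `f` of active cells is
#' estimated by maximum likelihood with a 95% confidence interval from
#' likelihood-ratio inversion. With every recipient negative the estimate
#' is 0; with every recipient positive the likelihood is unbounded above,
#' so the point estimate is flagged and the lower bound is the actionable
#' quantity (a frequency of at least so-many per cell).
#'
#' @param doses integer vector of cells transplanted per dose group.
#' @param n_mice recipients per dose group.
#' @param n_negative non-repopulated recipients per dose group.
#' @return an [LDAResult-class].
#' @examples
#' limitingDilution(10, 5, 1)  # f = -log(1/5)/10 ~ 0.161, "1 in 6.2"
#' @export
limitingDilution <- function(doses, n_mice, n_negative) {
    stopifnot(length(doses) == length(n_mice),
              length(doses) == length(n_negative),
              all(n_negative >= 0), all(n_negative <= n_mice))
    if (any(doses <= 0 & (n_mice - n_negative) > 0))
        stop("a positive recipient at dose 0 violates the single-hit model")
    design <- data.frame(dose = doses, n_mice = n_mice,
                         n_negative = n_negative)
    if (sum(n_mice - n_negative) == 0)      # all negative
        return(new("LDAResult", estimate = 0, lower = 0,
                   upper = .ldaBound(doses, n_mice, n_negative, 0, "upper"),
                   design = design, unbounded = FALSE))
    if (sum(n_negative) == 0)               # all positive: unbounded MLE
        return(new("LDAResult", estimate = NA_real_,
                   lower = .ldaBound(doses, n_mice, n_negative, 1, "lower"),
                   upper = 1, design = design, unbounded = TRUE))
    opt <- stats::optimize(function(lf)
        -.ldaLogLik(exp(lf), doses, n_mice, n_negative),
        interval = c(log(1e-9), log(1)), tol = 1e-12)
    f_hat <- min(exp(opt$minimum), 1)
    ll_max <- .ldaLogLik(f_hat, doses, n_mice, n_negative)
    crit <- stats::qchisq(0.95, df = 1) / 2
    g <- function(f) .ldaLogLik(f, doses, n_mice, n_negative) -
        (ll_max - crit)
    lower <- if (g(1e-12) > 0) 0 else
        stats::uniroot(g, c(1e-12, f_hat), tol = 1e-12)$root
    upper <- if (g(1) > 0) 1 else
        stats::uniroot(g, c(f_hat, 1), tol = 1e-12)$root
    new("LDAResult", estimate = f_hat, lower = lower, upper = upper,
        design = design, unbounded = FALSE)
}

# LR bound when the MLE sits on a boundary
.ldaBound <- function(doses, n_mice, n_neg, f_hat, side) {
    ll_max <- .ldaLogLik(f_hat, doses, n_mice, n_neg)
    crit <- stats::qchisq(0.95, df = 1) / 2
    g <- function(f) .ldaLogLik(f, doses, n_mice, n_neg) - (ll_max - crit)
    if (side == "upper") {
        if (g(1) > 0) return(1)
        stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    } else {
        if (g(1e-12) > 0) return(0)
        stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    }
}

#' Mammary colony pipeline: index phenotype to colony formation
#'
#' Generalizes the marker-to-function linkage to a colony assay with
#' patient batches: channels are z-scored within each patient, the pooled
#' normalized data are embedded with t-SNE and Ward-clustered into
#' `k_clusters` groups; per patient, the cluster with the highest
#' colony-forming efficiency (CFE = colonies / cells) is reported with its
#' fold enrichment over the patient's overall CFE, and each marker is
#' tested (two-sided Wilcoxon, BH across markers) between that cluster and
#' the patient's remaining cells.
#'
#' @param colony_table data.frame from [readColonyTable()] (or the
#'   simulator): `cell_id`, `patient_id`, binary `colony`, plus channel
#'   columns.
#' @param k_clusters clusters to cut the pooled tree into.
#' @param perplexity,seed t-SNE settings.
#' @param min_cells_per_patient required cells per patient.
#' @return list with `embedding`, `clusters` (named per-cell), `per_patient`
#'   (data.frame patient, best_cluster, cfe_cluster, cfe_overall, fold),
#'   and `marker_tests` (per patient x marker).
#' @export
mammaryPipeline <- function(colony_table, k_clusters = 2, perplexity = 30,
                            seed = 0L, min_cells_per_patient = 20) {
    channels <- attr(colony_table, "channel_names")
    if (is.null(channels))
        channels <- setdiff(names(colony_table),
                            c("cell_id", "patient_id", "colony"))
    tab <- table(colony_table$patient_id)
    if (any(tab < min_cells_per_patient))
        stop("patient(s) with fewer than ", min_cells_per_patient,
             " cells: ", paste(names(tab)[tab < min_cells_per_patient],
                               collapse = ", "))
    z <- do.call(rbind, lapply(split(seq_len(nrow(colony_table)),
                                     colony_table$patient_id), function(i)
        cbind(i, .zscoreCols(as.matrix(colony_table[i, channels])))))
    z <- z[order(z[, 1]), ]
    zmat <- z[, -1, drop = FALSE]
    rownames(zmat) <- colony_table$cell_id

    emb <- embedTSNE(zmat, perplexity = perplexity, seed = seed,
                     input_kind = "surface_markers")
    hc <- stats::hclust(stats::dist(coords(emb)), method = "ward.D2")
    cl <- stats::cutree(hc, k = k_clusters)
    names(cl) <- colony_table$cell_id

    per_patient <- do.call(rbind, lapply(
        split(seq_len(nrow(colony_table)), colony_table$patient_id),
        function(i) {
            d <- colony_table[i, ]
            cli <- cl[i]
            cfe_all <- mean(d$colony)
            cfe_by <- tapply(d$colony, cli, mean)
            best <- names(cfe_by)[which.max(cfe_by)]
            data.frame(patient = d$patient_id[1],
                       best_cluster = as.integer(best),
                       cfe_cluster = unname(cfe_by[best]),
                       cfe_overall = cfe_all,
                       fold = if (cfe_all > 0)
                           unname(cfe_by[best]) / cfe_all else NA_real_)
        }))
    rownames(per_patient) <- NULL

    marker_tests <- do.call(rbind, lapply(
        split(seq_len(nrow(colony_table)), colony_table$patient_id),
        function(i) {
            d <- colony_table[i, ]
            best <- per_patient$best_cluster[
                per_patient$patient == d$patient_id[1]]
            inb <- cl[i] == best
            res <- do.call(rbind, lapply(channels, function(ch) {
                data.frame(patient = d$patient_id[1], channel = ch,
                           median_in = stats::median(d[[ch]][inb]),
                           median_out = stats::median(d[[ch]][!inb]),
                           p = suppressWarnings(
                               stats::wilcox.test(d[[ch]][inb],
                                                  d[[ch]][!inb])$p.value))
            }))
            res$q <- stats::p.adjust(res$p, "BH")
            res
        }))
    rownames(marker_tests) <- NULL
    list(embedding = emb, clusters = cl, per_patient = per_patient,
         marker_tests = marker_tests)
}
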