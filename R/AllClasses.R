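#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("factorOrNULL", c("factor", "NULL"))

#' Single-cell qPCR Ct container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays: `"ct"`
#' (raw Ct cycles, assays in rows, cells in columns; lower Ct means more
#' transcript) and `"detected"` (logical mask; undetected reactions carry
#' `detected = FALSE` and the limit-of-detection sentinel in `"ct"`).
#' `rowData` holds `gene_name` and `is_housekeeper`; `colData` holds
#' `cell_id`, `population` (sorting strategy) and `well_id`. The sentinel Ct
#' used at load time is stored in `metadata(x)$lod_ct`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [CtExperiment()], [deltaCtNormalize()]
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
    msg <- NULL
    if (!all(c("ct", "detected") %in% names(assays(object))))
        msg <- c(msg, "assays 'ct' and 'detected' are required")
    else {
        if (!is.logical(assay(object, "detected")))
            msg <- c(msg, "'detected' assay must be logical")
        if (any(!is.finite(assay(object, "ct"))))
            msg <- c(msg, "'ct' assay must be finite (undetected entries carry the lod sentinel)")
    }
    cid <- colData(object)$cell_id
    if (is.null(cid))
        msg <- c(msg, "colData must contain 'cell_id'")
    else if (anyDuplicated(cid))
        msg <- c(msg, "duplicate cell_id values")
    hk <- rowData(object)$is_housekeeper
    if (is.null(hk) || !any(hk))
        msg <- c(msg, "rowData$is_housekeeper must flag at least one assay")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values, assays x cells.
#' @param detected logical matrix, same shape; `FALSE` marks reactions that
#'   did not amplify (their `ct` entry must hold `lod_ct`).
#' @param cell_meta data.frame with columns `cell_id`, `population`, and
#'   optionally `well_id`; one row per column of `ct`.
#' @param assay_meta data.frame with columns `gene_name`, `is_housekeeper`;
#'   one row per row of `ct`.
#' @param lod_ct limit-of-detection sentinel assigned to undetected entries.
#' @return A [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(14, 16, 20, 22), 4, 1,
#'              dimnames = list(c("Ubc", "Polr2a", "GeneA", "GeneB"), "c1"))
#' x <- CtExperiment(ct, detected = ct < 40,
#'     cell_meta = data.frame(cell_id = "c1", population = "HSC1"),
#'     assay_meta = data.frame(gene_name = rownames(ct),
#'                             is_housekeeper = c(TRUE, TRUE, FALSE, FALSE)))
#' @export
CtExperiment <- function(ct, detected = NULL, cell_meta, assay_meta,
                         lod_ct = 40) {
    ct <- as.matrix(ct)
    if (is.null(detected)) detected <- is.finite(ct) & ct < lod_ct
    ct[!detected] <- lod_ct
    if (is.null(cell_meta$well_id)) cell_meta$well_id <- cell_meta$cell_id
    rownames(ct) <- assay_meta$gene_name
    colnames(ct) <- cell_meta$cell_id
    dimnames(detected) <- dimnames(ct)
    se <- SummarizedExperiment(
        assays = list(ct = ct, detected = detected),
        rowData = DataFrame(assay_meta),
        colData = DataFrame(cell_meta, row.names = cell_meta$cell_id))
    out <- new("CtExperiment", se)
    metadata(out)$lod_ct <- lod_ct
    out
}

#' Housekeeper-normalized qPCR container
#'
#' Holds the `"dct"` assay (delta-Ct = Ct minus the per-cell mean Ct of the
#' detected housekeepers; lower delta-Ct means higher expression), after
#' removal of housekeeper assays. `metadata()$excluded_assays` records every
#' removed assay with the reason; `metadata()$dropped_cells` records cells
#' discarded because a housekeeper failed to amplify.
#'
#' @seealso [deltaCtNormalize()], [applyGeneExclusions()]
#' @export
setClass("DeltaCtExperiment", contains = "SummarizedExperiment")

setValidity("DeltaCtExperiment", function(object) {
    msg <- NULL
    if (!"dct" %in% names(assays(object)))
        msg <- c(msg, "assay 'dct' is required")
    hk <- rowData(object)$is_housekeeper
    if (!is.null(hk) && any(hk))
        msg <- c(msg, "housekeeper assays must not remain after normalization")
    if (is.null(msg)) TRUE else msg
})

#' Index-sort table
#'
#' One row per sorted cell, holding the recorded instrument channel
#' intensities (e.g. the 11 parameters FSC, SSC, 7AAD, Sca-1, Lin, CD34,
#' EPCR, FLT3, CD48, CD150, c-Kit), a batch identifier (sort session or
#' patient), and an optional per-cell functional outcome. Rows with missing
#' channel values are dropped at load time and counted in
#' `n_dropped(object)`.
#'
#' @slot channels numeric matrix, cells x channels, no missing values.
#' @slot cell_id character vector of unique cell identifiers.
#' @slot batch_id character vector, one entry per cell.
#' @slot outcome optional factor of per-cell outcomes (or NULL).
#' @slot n_dropped integer, rows discarded for missing channel values.
#' @export
setClass("IndexSortTable",
    representation(channels = "matrix", cell_id = "character",
                   batch_id = "character", outcome = "factorOrNULL",
                   n_dropped = "integer"))

setValidity("IndexSortTable", function(object) {
    msg <- NULL
    n <- nrow(object@channels)
    if (length(object@cell_id) != n || length(object@batch_id) != n)
        msg <- c(msg, "cell_id/batch_id length must match channel rows")
    if (anyDuplicated(object@cell_id))
        msg <- c(msg, "duplicate cell_id values")
    if (anyNA(object@channels))
        msg <- c(msg, "channel matrix must not contain missing values")
    if (is.null(colnames(object@channels)))
        msg <- c(msg, "channels must be named")
    if (!is.null(object@outcome) && length(object@outcome) != n)
        msg <- c(msg, "outcome length must match channel rows")
    if (is.null(msg)) TRUE else msg
})

#' Construct an IndexSortTable
#'
#' @param channels numeric matrix of intensities (cells x named channels).
#' @param cell_id,batch_id per-cell identifiers.
#' @param outcome optional per-cell categorical outcome.
#' @param n_dropped rows removed upstream for missing channel values.
#' @return An [IndexSortTable-class].
#' @export
IndexSortTable <- function(channels, cell_id, batch_id = "batch1",
                           outcome = NULL, n_dropped = 0L) {
    channels <- as.matrix(channels)
    rownames(channels) <- cell_id
    if (!is.null(outcome) && !is.factor(outcome)) outcome <- factor(outcome)
    new("IndexSortTable", channels = channels,
        cell_id = as.character(cell_id),
        batch_id = rep_len(as.character(batch_id), nrow(channels)),
        outcome = outcome, n_dropped = as.integer(n_dropped))
}

#' 2D embedding of cells
#'
#' Coordinates of a t-SNE map (arbitrary units), with the settings that
#' produced it, so downstream neighborhood statistics consume only
#' coordinates plus metadata, never the raw features.
#'
#' @slot coords numeric matrix, cells x 2, rownames = cell ids.
#' @slot input_kind `"qpcr_genes"` or `"surface_markers"`.
#' @slot perplexity,seed,init_dims settings used.
#' @export
setClass("Embedding2D",
    representation(coords = "matrix", input_kind = "character",
                   perplexity = "numeric", seed = "integer",
                   init_dims = "integer"))

setValidity("Embedding2D", function(object) {
    msg <- NULL
    if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
    if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
    if (is.null(rownames(object@coords)))
        msg <- c(msg, "coords must carry cell ids as rownames")
    if (is.null(msg)) TRUE else msg
})

#' MolO / NoMO assignment
#'
#' Per-cell partition of the HSC-gated cells into the molecular overlapping
#' population (MolO: the cell's local neighborhood matches the
#' repopulation-probability mixture) and cells with no molecular overlap
#' (NoMO); cells from non-HSC strategies are labeled `non-HSC`.
#'
#' @slot cell_id character cell identifiers.
#' @slot label factor with levels MolO, NoMO, non-HSC.
#' @slot divergence Jensen-Shannon divergence (nats) of each HSC cell's
#'   neighborhood composition from the target weights (NA for non-HSC).
#' @slot p_perm permutation p-value per HSC cell (NA for non-HSC).
#' @slot k neighborhood size used.
#' @slot weights normalized per-strategy target weights (sum to 1).
#' @slot alpha,n_perm decision level and permutation count.
#' @export
setClass("MolOAssignment",
    representation(cell_id = "character", label = "factor",
                   divergence = "numeric", p_perm = "numeric",
                   k = "integer", weights = "numeric", alpha = "numeric",
                   n_perm = "integer"))

setValidity("MolOAssignment", function(object) {
    msg <- NULL
    n <- length(object@cell_id)
    if (length(object@label) != n || length(object@divergence) != n ||
        length(object@p_perm) != n)
        msg <- c(msg, "per-cell slots must have equal length")
    if (!identical(levels(object@label), c("MolO", "NoMO", "non-HSC")))
        msg <- c(msg, "label levels must be MolO, NoMO, non-HSC")
    hsc <- object@label != "non-HSC"
    if (any(!is.na(object@divergence[hsc]) & object@divergence[hsc] < 0))
        msg <- c(msg, "divergence must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative and sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Per-cell classifier MolO score
#'
#' The fraction of random-forest trees voting MolO for each cell: the
#' confidence that the cell belongs to the molecular overlapping population,
#' transferable across platforms over the shared variable-gene panel.
#'
#' @slot cell_id character identifiers.
#' @slot score numeric in `[0, 1]`.
#' @slot platform source platform tag (e.g. `"qpcr"`, `"rnaseq"`).
#' @slot features gene panel used, in model order.
#' @export
setClass("MolOScore",
    representation(cell_id = "character", score = "numeric",
                   platform = "character", features = "character"))

setValidity("MolOScore", function(object) {
    msg <- NULL
    if (length(object@score) != length(object@cell_id))
        msg <- c(msg, "score and cell_id lengths differ")
    if (any(object@score < 0 | object@score > 1, na.rm = TRUE))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Fitted MolO classifier
#'
#' Random forest trained on per-platform z-scored expression of the shared
#' variable-gene panel, with the feature order and seed pinned for
#' reproducible scoring.
#'
#' @slot forest the fitted [randomForest::randomForest] object.
#' @slot features gene panel in training order.
#' @slot seed integer seed used for training.
#' @slot importance named numeric, mean decrease in Gini impurity, ranked.
#' @export
setClass("MolOClassifier",
    representation(forest = "ANY", features = "character", seed = "integer",
                   importance = "numeric"))

#' Surface-marker overlap (SuMO) score
#'
#' Signed projection of each cell onto the principal (total-least-squares)
#' axis of the joint 2D marker embedding, oriented so that its Spearman
#' correlation with available MolO scores is non-negative.
#'
#' @slot cell_id character identifiers.
#' @slot score numeric projection (arbitrary units).
#' @slot axis unit 2-vector of the fitted direction.
#' @slot center 2-vector, embedding centroid.
#' @slot flipped logical; TRUE if the orientation rule reversed the axis.
#' @slot provenance per-cell source tag (e.g. `"seq"`, `"tx"`).
#' @export
setClass("SuMOScore",
    representation(cell_id = "character", score = "numeric",
                   axis = "numeric", center = "numeric", flipped = "logical",
                   provenance = "character"))

setValidity("SuMOScore", function(object) {
    msg <- NULL
    if (length(object@score) != length(object@cell_id))
        msg <- c(msg, "score and cell_id lengths differ")
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
        msg <- c(msg, "axis must be a unit vector")
    if (is.null(msg)) TRUE else msg
})

#' Spike-in technical noise fit
#'
#' Parameters of the mean / squared-coefficient-of-variation relation fitted
#' on spike-in genes: `CV2_tech(mu) = a1 / mu + a0` (gamma-family GLM with
#' identity link on normalized counts).
#'
#' @slot a0 asymptotic CV2 offset (multiplicative noise floor).
#' @slot a1 shot-noise coefficient of `1/mu`.
#' @slot se_a0,se_a1 standard errors of the two coefficients.
#' @slot min_mean fit domain: spike-ins below this normalized mean excluded.
#' @slot n_spikeins number of spike-ins used.
#' @slot spike_stats data.frame of per-spike-in (mean, cv2) used in the fit.
#' @export
setClass("NoiseFit",
    representation(a0 = "numeric", a1 = "numeric", se_a0 = "numeric",
                   se_a1 = "numeric", min_mean = "numeric",
                   n_spikeins = "integer", spike_stats = "data.frame"))

setValidity("NoiseFit", function(object) {
    if (object@a1 <= 0) "a1 must be positive" else TRUE
})

#' Limiting-dilution frequency estimate
#'
#' Single-hit Poisson model: the probability that a recipient is negative
#' after a dose of `d` cells is `exp(-f * d)`. The active-cell frequency `f`
#' is estimated by maximum likelihood with a 95% likelihood-ratio interval.
#'
#' @slot estimate point estimate of `f` (per cell); `NA` when every recipient
#'   is positive (unbounded likelihood), with the lower bound actionable.
#' @slot lower,upper 95% likelihood-ratio confidence bounds.
#' @slot design data.frame (dose, n_mice, n_negative) used.
#' @slot unbounded TRUE when all recipients were positive.
#' @export
setClass("LDAResult",
    representation(estimate = "numeric", lower = "numeric", upper = "numeric",
                   design = "data.frame", unbounded = "logical"))

setValidity("LDAResult", function(object) {
    msg <- NULL
    est <- object@estimate
    if (!is.na(est) && (est < 0 || est > 1))
        msg <- c(msg, "estimate must lie in [0, 1]")
    if (!is.na(est) && !object@unbounded &&
        (est < object@lower - 1e-9 || est > object@upper + 1e-9))
        msg <- c(msg, "confidence interval must contain the estimate")
    if (is.null(msg)) TRUE else msg
})
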