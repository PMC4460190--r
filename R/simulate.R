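#' Simulation specification
#'
#' Defines the generative model for all five input kinds the pipeline
#' consumes, with a planted molecular overlapping (MolO) subpopulation
#' shared across sorting strategies. Each strategy contributes
#' `cells_per_strategy` cells; a cell is MolO with its strategy's
#' repopulation probability, so the strategy composition inside the planted
#' subpopulation is proportional to `repop_prob` — exactly the mixture the
#' weighted neighborhood search looks for.
#'
#' @slot n_strategies number of HSC sorting strategies.
#' @slot cells_per_strategy cells sorted per strategy.
#' @slot repop_prob per-strategy probability of durable repopulation, the
#'   mixture-weight source. Defaults are plausible synthetic placeholders
#'   (published per-strategy repopulation data are a config input).
#' @slot n_genes analysis genes on the qPCR panel (housekeepers and the two
#'   excluded assays are appended on top of these).
#' @slot molo_shift per-gene mean Ct shift of MolO cells (negative = more
#'   expressed); length `n_genes`.
#' @slot dropout_logistic `c(midpoint, slope)`: detection probability is
#'   `plogis(slope * (midpoint - true_ct))`, tying dropout to mean
#'   expression.
#' @slot noise_sd_ct per-cell Gaussian noise on the Ct scale.
#' @slot strategy_sd_ct spread of strategy-specific (non-MolO) profiles.
#' @slot nb_dispersion negative-binomial dispersion of planted variable
#'   genes in the RNA-seq simulation.
#' @slot nb_dispersion_null dispersion of flat (technical-noise-only) genes.
#' @slot n_rna_genes,n_signature_genes biological genes simulated, and how
#'   many of them carry a MolO-dependent mean.
#' @slot rna_log2fc log2 fold change of signature genes between MolO states.
#' @slot size_factor_sd log-normal spread of per-cell size factors.
#' @slot spikein_means true spike-in abundances.
#' @slot marker_effect named per-channel log-intensity shift of MolO cells
#'   (defaults: CD150 and Sca1 up, CD48 down, EPCR up).
#' @slot outcome_logit `c(intercept, coef)` mapping the latent MolO state to
#'   the repopulation probability via a logistic model.
#' @slot seed integer; all generator randomness flows from it.
#' @export
setClass("SimSpec",
    representation(n_strategies = "integer", cells_per_strategy = "integer",
                   repop_prob = "numeric", n_genes = "integer",
                   molo_shift = "numeric", dropout_logistic = "numeric",
                   noise_sd_ct = "numeric", strategy_sd_ct = "numeric",
                   nb_dispersion = "numeric", nb_dispersion_null = "numeric",
                   n_rna_genes = "integer", n_signature_genes = "integer",
                   rna_log2fc = "numeric", size_factor_sd = "numeric",
                   spikein_means = "numeric", marker_effect = "numeric",
                   outcome_logit = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
    msg <- NULL
    if (length(object@repop_prob) != object@n_strategies)
        msg <- c(msg, "repop_prob must have one entry per strategy")
    if (any(object@repop_prob < 0 | object@repop_prob > 1))
        msg <- c(msg, "repop_prob entries must lie in [0, 1]")
    if (object@cells_per_strategy < 1)
        msg <- c(msg, "cells_per_strategy must be >= 1")
    if (length(object@molo_shift) != object@n_genes)
        msg <- c(msg, "molo_shift must have one entry per analysis gene")
    if (object@nb_dispersion <= 0 || object@nb_dispersion_null <= 0)
        msg <- c(msg, "dispersions must be positive")
    if (length(object@dropout_logistic) != 2)
        msg <- c(msg, "dropout_logistic must be c(midpoint, slope)")
    if (object@n_signature_genes > object@n_rna_genes)
        msg <- c(msg, "n_signature_genes cannot exceed n_rna_genes")
    if (is.null(msg)) TRUE else msg
})

.indexChannels <- c("FSC", "SSC", "7AAD", "Sca1", "Lin", "CD34", "EPCR",
                    "FLT3", "CD48", "CD150", "cKit")

#' @rdname SimSpec-class
#' @param ... slot overrides, by name.
#' @return a validated `SimSpec`.
#' @examples
#' spec <- SimSpec(seed = 7L)
#' @export
SimSpec <- function(...) {
    defaults <- list(
        n_strategies = 5L, cells_per_strategy = 210L,
        repop_prob = c(0.85, 0.65, 0.5, 0.35, 0.15),
        n_genes = 43L,
        molo_shift = c(rep(-3, 15), rep(0, 28)),
        dropout_logistic = c(midpoint = 30, slope = 0.8),
        noise_sd_ct = 1, strategy_sd_ct = 2,
        nb_dispersion = 0.5, nb_dispersion_null = 1e-6,
        n_rna_genes = 300L, n_signature_genes = 30L, rna_log2fc = 1.5,
        size_factor_sd = 0.3,
        spikein_means = 2^seq(0, 12, length.out = 50),
        marker_effect = c(FSC = 0, SSC = 0, `7AAD` = 0, Sca1 = 1.8, Lin = 0,
                          CD34 = 0, EPCR = 1.2, FLT3 = 0, CD48 = -1.5,
                          CD150 = 1.5, cKit = 0),
        outcome_logit = c(intercept = -2, coef = 4),
        seed = 1L)
    args <- utils::modifyList(defaults, list(...))
    if (length(args$molo_shift) != args$n_genes && args$n_genes != 43L)
        args$molo_shift <- rep_len(args$molo_shift, args$n_genes)
    args$n_strategies <- as.integer(args$n_strategies)
    args$cells_per_strategy <- as.integer(args$cells_per_strategy)
    args$n_genes <- as.integer(args$n_genes)
    args$n_rna_genes <- as.integer(args$n_rna_genes)
    args$n_signature_genes <- as.integer(args$n_signature_genes)
    args$seed <- as.integer(args$seed)
    do.call(new, c("SimSpec", args))
}

setMethod("show", "SimSpec", function(object) {
    cat("SimSpec:", object@n_strategies, "strategies x",
        object@cells_per_strategy, "cells,", object@n_genes,
        "panel genes, seed", object@seed, "\n")
    cat("  repop_prob:", paste(object@repop_prob, collapse = ", "), "\n")
})

# strategy labels "HSC1".."HSCn"
.strategyNames <- function(spec) paste0("HSC", seq_len(spec@n_strategies))

#' Simulate a single-cell qPCR panel with a planted MolO subpopulation
#'
#' Each strategy contributes `cells_per_strategy` cells; a cell is MolO with
#' probability `repop_prob[s]`. MolO cells share one Gaussian Ct profile
#' (the base panel shifted by `molo_shift`); non-MolO cells follow
#' strategy-specific profiles. Detection is logistic in the true mean Ct, so
#' weakly expressed assays drop out. The panel comprises `n_genes` analysis
#' genes plus housekeepers `Ubc`, `Polr2a`, `Actb` and the two
#' to-be-excluded assays `Cdkn2a` (never expressed) and `Egfl7` (erratic),
#' mirroring a 48-assay design at the defaults.
#'
#' @param spec a [SimSpec-class].
#' @return list with `ct` (a [CtExperiment-class]) and `truth` (data.frame
#'   `cell_id`, `strategy`, `molo`).
#' @export
simulateQPCR <- function(spec) {
    set.seed(stageSeed(spec@seed, "simulate_qpcr"))
    S <- spec@n_strategies
    n <- S * spec@cells_per_strategy
    strategies <- rep(.strategyNames(spec), each = spec@cells_per_strategy)
    molo <- stats::rbinom(n, 1,
                          rep(spec@repop_prob,
                              each = spec@cells_per_strategy)) == 1

    genes <- sprintf("Gene%02d", seq_len(spec@n_genes))
    base <- stats::runif(spec@n_genes, 18, 28)
    molo_profile <- base + spec@molo_shift
    strat_profiles <- vapply(seq_len(S), function(s)
        base + stats::rnorm(spec@n_genes, 0, spec@strategy_sd_ct),
        numeric(spec@n_genes))

    truth_ct <- matrix(NA_real_, spec@n_genes, n)
    for (i in seq_len(n)) {
        prof <- if (molo[i]) molo_profile
                else strat_profiles[, match(strategies[i],
                                            .strategyNames(spec))]
        truth_ct[, i] <- prof
    }
    ct <- truth_ct + matrix(stats::rnorm(spec@n_genes * n, 0,
                                         spec@noise_sd_ct), spec@n_genes, n)
    mid <- spec@dropout_logistic[1]
    slope <- spec@dropout_logistic[2]
    p_det <- stats::plogis(slope * (mid - truth_ct))
    detected <- matrix(stats::runif(length(p_det)) < p_det,
                       spec@n_genes, n)

    hk <- rbind(Ubc = 14 + stats::rnorm(n, 0, 0.3),
                Polr2a = 16 + stats::rnorm(n, 0, 0.3),
                Actb = 15 + stats::rnorm(n, 0, 0.3))
    cdkn2a <- rep(40, n)                       # never expressed
    egfl7 <- stats::runif(n, 15, 39)           # erratic assay
    full <- rbind(ct, hk, Cdkn2a = cdkn2a, Egfl7 = egfl7)
    rownames(full) <- c(genes, rownames(hk), "Cdkn2a", "Egfl7")
    det_full <- rbind(detected,
                      matrix(TRUE, 3, n),
                      matrix(FALSE, 1, n),
                      matrix(stats::runif(n) < 0.5, 1, n))
    lod <- 40
    full[!det_full] <- lod
    full[det_full] <- pmin(full[det_full], lod - 0.01)

    cell_id <- sprintf("%s_c%03d", strategies,
                       unlist(lapply(rle(strategies)$lengths, seq_len)))
    ctx <- CtExperiment(full, det_full,
        cell_meta = data.frame(cell_id = cell_id, population = strategies,
                               well_id = sprintf("W%04d", seq_len(n))),
        assay_meta = data.frame(
            gene_name = rownames(full),
            is_housekeeper = rownames(full) %in% c("Ubc", "Polr2a", "Actb")),
        lod_ct = lod)
    list(ct = ctx,
         truth = data.frame(cell_id = cell_id, strategy = strategies,
                            molo = molo))
}

#' Simulate an scRNA-seq counts matrix with spike-ins
#'
#' Biological genes follow a negative binomial with a per-cell size factor;
#' the first `n_signature_genes` have MolO-state-dependent means (half up,
#' half down by `rna_log2fc`) and dispersion `nb_dispersion`, the remaining
#' genes are flat with near-Poisson dispersion `nb_dispersion_null`.
#' Spike-ins are Poisson at `spikein_means` scaled by the same size factor,
#' so their excess variance is purely technical.
#'
#' @param spec a [SimSpec-class].
#' @param truth data.frame with a logical/0-1 `molo` column, one row per
#'   cell to simulate (typically a subset of the qPCR truth table).
#' @return a [SingleCellExperiment::SingleCellExperiment] with `rowData`
#'   columns `is_spikein` and `is_signature`, and true size factors in
#'   `colData()$true_size_factor`.
#' @export
simulateCounts <- function(spec, truth) {
    set.seed(stageSeed(spec@seed, "simulate_counts"))
    n <- nrow(truth)
    molo <- as.logical(truth$molo)
    G <- spec@n_rna_genes
    nsig <- spec@n_signature_genes

    sf <- exp(stats::rnorm(n, 0, spec@size_factor_sd))
    sf <- sf / .geomean(sf)
    base_mu <- exp(stats::runif(G, log(20), log(500)))
    lfc <- rep(0, G)
    if (nsig > 0) {
        lfc[seq_len(nsig)] <- rep(c(spec@rna_log2fc, -spec@rna_log2fc),
                                  length.out = nsig)
        # shared panel genes keep the direction of the qPCR MolO shift
        # (lower Ct = higher expression), so the platforms agree
        shared <- seq_len(min(nsig, spec@n_genes))
        shifted <- shared[spec@molo_shift[shared] != 0]
        lfc[shifted] <- -sign(spec@molo_shift[shifted]) * spec@rna_log2fc
    }
    disp <- c(rep(spec@nb_dispersion, nsig),
              rep(spec@nb_dispersion_null, G - nsig))

    mu <- outer(base_mu, rep(1, n))
    mu[seq_len(nsig), molo] <- mu[seq_len(nsig), molo, drop = FALSE] *
        2^lfc[seq_len(nsig)]
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / disp, n)),
                     G, n)
    spikes <- matrix(stats::rpois(length(spec@spikein_means) * n,
                                  outer(spec@spikein_means, sf)),
                     length(spec@spikein_means), n)
    m <- rbind(counts, spikes)
    # the first panel-sized block reuses the qPCR gene names so the two
    # platforms share a feature space for classifier transfer
    bio_names <- sprintf("BioGene%03d", seq_len(G))
    n_shared <- min(spec@n_genes, G)
    bio_names[seq_len(n_shared)] <- sprintf("Gene%02d", seq_len(n_shared))
    rownames(m) <- c(bio_names,
                     sprintf("ERCC-%05d", seq_along(spec@spikein_means)))
    colnames(m) <- truth$cell_id
    storage.mode(m) <- "integer"
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        rowData = DataFrame(
            gene_id = rownames(m),
            is_spikein = startsWith(rownames(m), "ERCC-"),
            is_signature = c(seq_len(G) <= nsig,
                             rep(FALSE, length(spec@spikein_means)))),
        colData = DataFrame(cell_id = truth$cell_id, molo = molo,
                            true_size_factor = sf,
                            row.names = truth$cell_id))
}

#' Simulate index-sort phenotypes, transplant outcomes and a colony assay
#'
#' Channel intensities are log-normal around per-channel baselines with the
#' MolO effect added on the log scale (`marker_effect`). Each transplanted
#' cell repopulates with probability
#' `plogis(outcome_logit[1] + outcome_logit[2] * molo)`; repopulated mice
#' receive donor lineage counts yielding at least 1% chimerism at week 16,
#' the rest stay below 1%. The mammary colony table mirrors the construction
#' with per-patient batch shifts and an EpCAM-high / SSC-low colony-forming
#' subpopulation.
#'
#' @param spec a [SimSpec-class].
#' @param truth truth table from [simulateQPCR()] (or any data.frame with
#'   `cell_id` and `molo`).
#' @param n_tx number of single-cell transplants to simulate.
#' @param tx_candidates cell ids eligible for transplantation (default all
#'   truth cells); lets callers keep sequenced and transplanted cells
#'   disjoint.
#' @param n_patients,cells_per_patient mammary assay dimensions.
#' @return list with `index` ([IndexSortTable-class] covering all truth
#'   cells), `transplants` (long data.frame, see [readTransplantTable()]),
#'   `tx_cells` (cell ids transplanted), and `colonies` (mammary table).
#' @export
simulateIndexAndFunction <- function(spec, truth, n_tx = 29L,
                                     tx_candidates = NULL,
                                     n_patients = 5L,
                                     cells_per_patient = 192L) {
    set.seed(stageSeed(spec@seed, "simulate_index_function"))
    n <- nrow(truth)
    molo <- as.logical(truth$molo)

    base_log <- stats::setNames(
        c(5.5, 5.0, 2.0, 4.0, 2.5, 3.0, 3.5, 2.8, 3.2, 4.2, 4.8),
        .indexChannels)
    eff <- spec@marker_effect[.indexChannels]
    eff[is.na(eff)] <- 0
    logint <- matrix(rep(base_log, each = n), n, length(base_log),
                     dimnames = list(truth$cell_id, .indexChannels))
    logint <- logint + outer(as.numeric(molo), as.numeric(eff)) +
        matrix(stats::rnorm(n * length(base_log), 0, 0.5), n)
    idx <- IndexSortTable(exp(logint), truth$cell_id, batch_id = "sort1")

    if (is.null(tx_candidates)) tx_candidates <- truth$cell_id
    tx_cells <- sample(tx_candidates, n_tx)
    tx_molo <- molo[match(tx_cells, truth$cell_id)]
    p_rep <- stats::plogis(spec@outcome_logit[1] +
                           spec@outcome_logit[2] * as.numeric(tx_molo))
    repop <- stats::runif(n_tx) < p_rep
    tx <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
        rows <- expand.grid(week = c(16, 24),
                            lineage = c("WBC", "GM", "B", "T"),
                            stringsAsFactors = FALSE)
        total <- 10000
        if (repop[i]) {
            pct_wbc <- stats::runif(1, 3, 60)
            # balanced myeloid/lymphoid output with mild noise
            pct <- pmin(95, pmax(1.2, pct_wbc *
                stats::rlnorm(nrow(rows), 0, 0.2)))
        } else {
            pct <- stats::runif(nrow(rows), 0, 0.5)
        }
        donor <- round(total * pct / 100)
        data.frame(mouse_id = sprintf("m%03d", i), dose = 1L,
                   cell_id = tx_cells[i], rows,
                   donor = donor, recipient = total - donor)
    }))

    colonies <- .simulateMammary(spec, n_patients, cells_per_patient)
    list(index = idx, transplants = tx, tx_cells = tx_cells,
         truth_repop = stats::setNames(repop, tx_cells), colonies = colonies)
}

# mammary colony assay: per-patient batch shifts; EpCAM-high / SSC-low
# progenitors form colonies at a much higher rate
.simulateMammary <- function(spec, n_patients, cells_per_patient) {
    channels <- c("FSC", "SSC", "7AAD", "CD31", "CD45", "EpCAM", "CD49f",
                  "ALDH")
    base_log <- stats::setNames(c(5.5, 5.0, 2.0, 2.5, 2.6, 3.8, 3.4, 3.0),
                                channels)
    out <- lapply(seq_len(n_patients), function(p) {
        n <- cells_per_patient
        batch_shift <- stats::rnorm(length(channels), 0, 0.5)
        prog <- stats::runif(n) < 0.3
        eff <- stats::setNames(rep(0, length(channels)), channels)
        eff["EpCAM"] <- 1.5
        eff["SSC"] <- -1.5
        eff["CD49f"] <- 1.0
        eff["ALDH"] <- 1.0
        logint <- matrix(rep(base_log + batch_shift, each = n), n,
                         length(channels),
                         dimnames = list(NULL, channels))
        logint <- logint + outer(as.numeric(prog), as.numeric(eff)) +
            matrix(stats::rnorm(n * length(channels), 0, 0.5), n)
        colony <- stats::runif(n) <
            stats::plogis(-2.2 + 3.2 * as.numeric(prog))
        data.frame(cell_id = sprintf("P%d_w%03d", p, seq_len(n)),
                   patient_id = paste0("patient", p),
                   colony = as.integer(colony),
                   exp(logint), check.names = FALSE)
    })
    df <- do.call(rbind, out)
    attr(df, "channel_names") <- channels
    df
}
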