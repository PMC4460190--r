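#' @importFrom utils read.delim write.table head
NULL

.delimFor <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

.readTable <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    read.delim(path, sep = .delimFor(path), check.names = FALSE,
               stringsAsFactors = FALSE)
}

# Write a data.frame as TSV/CSV with full-precision numerics so that
# write-then-read round-trips finite doubles bit-exactly.
.writeTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    write.table(out, path, sep = .delimFor(path), quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a single-cell qPCR Ct table
#'
#' Parses a delimited Fluidigm-style export with cells in rows and assays in
#' columns. Entries of `999`, blanks/NA, or Ct at or above `lod_ct` are
#' treated as undetected: they are flagged `detected = FALSE` and assigned
#' the sentinel `lod_ct`, keeping the matrix dense with undetected = least
#' expressed.
#'
#' @param path delimited file (TSV, or CSV when the name ends in `.csv`)
#'   with a `cell_id` column, a population-label column, optionally a
#'   `well_id` column, and one column per assay.
#' @param housekeepers gene names to flag as housekeeping assays; all must
#'   be present among the assay columns.
#' @param lod_ct limit-of-detection Ct (default 40).
#' @param population_col name of the population-label column.
#' @return a [CtExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cell_id,population,Ubc,Polr2a,GeneA",
#'              "c1,HSC1,14,16,20", "c2,HSC1,15,15,999"), tf)
#' x <- readCtTable(tf, housekeepers = c("Ubc", "Polr2a"))
#' @export
readCtTable <- function(path, housekeepers, lod_ct = 40,
                        population_col = "population") {
    df <- .readTable(path)
    if (!"cell_id" %in% names(df)) stop("column 'cell_id' is required")
    if (!population_col %in% names(df))
        stop("population column '", population_col, "' not found")
    if (anyDuplicated(df$cell_id))
        stop("duplicate cell_id: ",
             paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
    meta_cols <- intersect(c("cell_id", population_col, "well_id"), names(df))
    assay_cols <- setdiff(names(df), meta_cols)
    missing_hk <- setdiff(housekeepers, assay_cols)
    if (length(missing_hk))
        stop("housekeeper column(s) missing from table: ",
             paste(missing_hk, collapse = ", "))
    ct <- t(as.matrix(as.data.frame(
        lapply(df[assay_cols], function(x) suppressWarnings(as.numeric(x))))))
    rownames(ct) <- assay_cols
    detected <- is.finite(ct) & ct != 999 & ct < lod_ct
    ct[!detected] <- lod_ct
    cell_meta <- data.frame(cell_id = df$cell_id,
                            population = df[[population_col]])
    if ("well_id" %in% names(df)) cell_meta$well_id <- df$well_id
    CtExperiment(ct, detected, cell_meta,
                 assay_meta = data.frame(
                     gene_name = assay_cols,
                     is_housekeeper = assay_cols %in% housekeepers),
                 lod_ct = lod_ct)
}

#' Write a CtExperiment back to a delimited table
#'
#' Undetected entries are exported as `999` so that
#' `readCtTable(writeCtTable(x))` round-trips values, flags and metadata.
#'
#' @param x a [CtExperiment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(x, path) {
    ct <- ctValues(x)
    ct[!isDetected(x)] <- 999
    df <- data.frame(cell_id = colData(x)$cell_id,
                     population = colData(x)$population,
                     well_id = colData(x)$well_id,
                     t(ct), check.names = FALSE)
    .writeTable(df, path)
}

#' Read a gene x cell counts matrix
#'
#' Accepts either a dense TSV (first column `gene_id`, one column per cell)
#' or a MatrixMarket triplet file (`.mtx`) with `<path>.rows` / `<path>.cols`
#' sidecar files of row and column names. Genes whose identifier starts with
#' `spikein_prefix` are flagged as spike-ins.
#'
#' @param path TSV or `.mtx` file.
#' @param spikein_prefix prefix marking spike-in genes (default `"ERCC-"`).
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"counts"` and `rowData(x)$is_spikein`.
#' @export
readCountsMatrix <- function(path, spikein_prefix = "ERCC-") {
    if (!file.exists(path)) stop("input file not found: ", path)
    if (grepl("\\.mtx$", path)) {
        m <- as.matrix(Matrix::readMM(path))
        rn <- readLines(paste0(path, ".rows"))
        cn <- readLines(paste0(path, ".cols"))
        if (length(rn) != nrow(m) || length(cn) != ncol(m))
            stop("sidecar row/col name counts do not match matrix shape")
        dimnames(m) <- list(rn, cn)
    } else {
        df <- .readTable(path)
        if (!"gene_id" %in% names(df)) stop("column 'gene_id' is required")
        m <- as.matrix(df[setdiff(names(df), "gene_id")])
        rownames(m) <- df$gene_id
    }
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("negative or non-integer count at (row ", bad[1, 1], ", col ",
             bad[1, 2], "): ", m[bad[1, 1], bad[1, 2]])
    storage.mode(m) <- "integer"
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        rowData = DataFrame(gene_id = rownames(m),
                            is_spikein = startsWith(rownames(m),
                                                    spikein_prefix)),
        colData = DataFrame(cell_id = colnames(m), row.names = colnames(m)))
}

#' Write a counts matrix as TSV or MatrixMarket
#'
#' @param x a `SingleCellExperiment` (assay `"counts"`) or integer matrix.
#' @param path output file; a `.mtx` suffix selects MatrixMarket with
#'   `.rows`/`.cols` sidecars, anything else a dense TSV.
#' @return `path`, invisibly.
#' @export
writeCountsMatrix <- function(x, path) {
    m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    if (grepl("\\.mtx$", path)) {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        writeLines(rownames(m), paste0(path, ".rows"))
        writeLines(colnames(m), paste0(path, ".cols"))
    } else {
        .writeTable(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                    path)
    }
    invisible(path)
}

#' Read an index-sort table
#'
#' One row per sorted well: `cell_id`, optional `batch_id` and `outcome`
#' columns, and one column per recorded instrument channel. Rows with any
#' missing channel value are dropped and counted.
#'
#' @param path delimited file.
#' @return an [IndexSortTable-class]; dropped-row count available via
#'   `x@n_dropped`.
#' @export
readIndexTable <- function(path) {
    df <- .readTable(path)
    if (!"cell_id" %in% names(df)) stop("column 'cell_id' is required")
    meta <- intersect(c("cell_id", "batch_id", "outcome"), names(df))
    ch_cols <- setdiff(names(df), meta)
    if (!length(ch_cols)) stop("no channel columns found")
    ch <- as.matrix(df[ch_cols])
    keep <- stats::complete.cases(ch)
    IndexSortTable(ch[keep, , drop = FALSE], df$cell_id[keep],
                   batch_id = if ("batch_id" %in% meta) df$batch_id[keep]
                              else "batch1",
                   outcome = if ("outcome" %in% meta) df$outcome[keep]
                             else NULL,
                   n_dropped = sum(!keep))
}

#' Write an index-sort table
#' @param x an [IndexSortTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIndexTable <- function(x, path) {
    df <- data.frame(cell_id = x@cell_id, batch_id = x@batch_id,
                     check.names = FALSE)
    if (!is.null(x@outcome)) df$outcome <- as.character(x@outcome)
    .writeTable(cbind(df, as.data.frame(x@channels)), path)
}

#' Read a transplant outcome table
#'
#' Long format, one row per mouse / week / lineage:
#' `mouse_id, dose, week, lineage, donor, recipient` with lineages among
#' WBC, GM, B, T and counts distinguishing donor from recipient cells
#' (CD45.1 vs CD45.2 in the hematopoietic setting).
#'
#' @param path delimited file.
#' @return validated data.frame.
#' @export
readTransplantTable <- function(path) {
    df <- .readTable(path)
    need <- c("mouse_id", "dose", "week", "lineage", "donor", "recipient")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    if (any(df$dose < 1)) stop("dose must be a positive cell count")
    if (any(df$donor < 0 | df$recipient < 0))
        stop("donor/recipient counts must be non-negative")
    if (any(df$donor + df$recipient <= 0))
        stop("donor + recipient must be positive for every reported entry")
    df
}

#' Write a transplant outcome table
#' @param df transplant data.frame (see [readTransplantTable()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTransplantTable <- function(df, path) .writeTable(df, path)

#' Read a mammary colony table
#'
#' One row per sorted well: `cell_id`, `patient_id`, binary `colony`
#' outcome, and one column per index channel.
#'
#' @param path delimited file.
#' @return data.frame with attribute `channel_names`.
#' @export
readColonyTable <- function(path) {
    df <- .readTable(path)
    need <- c("cell_id", "patient_id", "colony")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    if (!all(df$colony %in% c(0, 1)))
        stop("colony outcome must be binary 0/1")
    attr(df, "channel_names") <- setdiff(names(df), need)
    df
}

#' Write a mammary colony table
#' @param df colony data.frame (see [readColonyTable()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeColonyTable <- function(df, path) .writeTable(df, path)

#' Pipeline configuration
#'
#' Bundles every tunable setting of the pipeline with validated defaults.
#' Serializes losslessly to YAML via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @param tsne list: `perplexity` (> 0), `seed`, `init_dims` (PCA
#'   pre-reduction dimensionality).
#' @param molo list: `k` nearest neighbors, decision level `alpha` in (0,1),
#'   permutation count `n_perm`.
#' @param hvg list: `fdr` in (0,1), `min_mean` normalized-count floor for
#'   spike-ins entering the noise fit.
#' @param classifier list: `trees`, `folds`, `seed`.
#' @param thresholds list: `chimerism_pct` (repopulation cutoff, percent),
#'   `subtype_hi` and `subtype_lo` myeloid/lymphoid ratio cutoffs.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(tsne = list(), molo = list(), hvg = list(),
                           classifier = list(), thresholds = list()) {
    cfg <- list(
        tsne = utils::modifyList(
            list(perplexity = 30, seed = 0L, init_dims = 30L), tsne),
        molo = utils::modifyList(
            list(k = 50L, alpha = 0.05, n_perm = 999L), molo),
        hvg = utils::modifyList(list(fdr = 0.1, min_mean = 10), hvg),
        classifier = utils::modifyList(
            list(trees = 1000L, folds = 10L, seed = 0L), classifier),
        thresholds = utils::modifyList(
            list(chimerism_pct = 1, subtype_hi = 2, subtype_lo = 0.25),
            thresholds))
    validatePipelineConfig(cfg)
    class(cfg) <- c("PipelineConfig", "list")
    cfg
}

#' @rdname pipelineConfig
#' @param cfg a config list.
#' @export
validatePipelineConfig <- function(cfg) {
    stopifnot(cfg$tsne$perplexity > 0,
              cfg$molo$k >= 1, cfg$molo$alpha > 0, cfg$molo$alpha < 1,
              cfg$molo$n_perm >= 1,
              cfg$hvg$fdr > 0, cfg$hvg$fdr < 1, cfg$hvg$min_mean >= 0,
              cfg$classifier$trees >= 1, cfg$classifier$folds >= 2,
              cfg$thresholds$chimerism_pct >= 0,
              cfg$thresholds$subtype_hi > cfg$thresholds$subtype_lo)
    invisible(cfg)
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(pipelineConfig, raw[intersect(names(raw),
        c("tsne", "molo", "hvg", "classifier", "thresholds"))])
}

#' @rdname pipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}
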