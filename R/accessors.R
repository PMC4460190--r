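#' @rdname CtExperiment-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname CtExperiment-class
#' @export
setMethod("ctValues", "CtExperiment", function(x) assay(x, "ct"))

#' @rdname CtExperiment-class
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname CtExperiment-class
#' @export
setMethod("isDetected", "CtExperiment", function(x) assay(x, "detected"))

#' @rdname DeltaCtExperiment-class
#' @param x a `DeltaCtExperiment`.
#' @export
setGeneric("dctValues", function(x) standardGeneric("dctValues"))

#' @rdname DeltaCtExperiment-class
#' @export
setMethod("dctValues", "DeltaCtExperiment", function(x) assay(x, "dct"))

#' @rdname DeltaCtExperiment-class
#' @export
setGeneric("excludedAssays", function(x) standardGeneric("excludedAssays"))

#' @rdname DeltaCtExperiment-class
#' @export
setMethod("excludedAssays", "DeltaCtExperiment",
    function(x) metadata(x)$excluded_assays)

#' @rdname IndexSortTable-class
#' @param x an `IndexSortTable`.
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))

#' @rdname IndexSortTable-class
#' @export
setMethod("channelData", "IndexSortTable", function(x) x@channels)

#' @rdname IndexSortTable-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname IndexSortTable-class
#' @export
setMethod("channelNames", "IndexSortTable", function(x) colnames(x@channels))

#' @rdname IndexSortTable-class
#' @export
setGeneric("batchId", function(x) standardGeneric("batchId"))

#' @rdname IndexSortTable-class
#' @export
setMethod("batchId", "IndexSortTable", function(x) x@batch_id)

#' @rdname IndexSortTable-class
#' @export
setGeneric("sortOutcome", function(x) standardGeneric("sortOutcome"))

#' @rdname IndexSortTable-class
#' @export
setMethod("sortOutcome", "IndexSortTable", function(x) x@outcome)

#' Cell identifiers of an object
#' @param x a container with per-cell entries.
#' @return character vector of cell ids.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellIds
#' @export
setMethod("cellIds", "IndexSortTable", function(x) x@cell_id)

#' @rdname cellIds
#' @export
setMethod("cellIds", "Embedding2D", function(x) rownames(x@coords))

#' @rdname cellIds
#' @export
setMethod("cellIds", "MolOAssignment", function(x) x@cell_id)

#' @rdname cellIds
#' @export
setMethod("cellIds", "MolOScore", function(x) x@cell_id)

#' @rdname cellIds
#' @export
setMethod("cellIds", "SuMOScore", function(x) x@cell_id)

#' @rdname Embedding2D-class
#' @param x an `Embedding2D`.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Embedding2D-class
#' @export
setMethod("coords", "Embedding2D", function(x) x@coords)

#' @rdname MolOAssignment-class
#' @param x a `MolOAssignment`.
#' @export
setGeneric("moloLabels", function(x) standardGeneric("moloLabels"))

#' @rdname MolOAssignment-class
#' @export
setMethod("moloLabels", "MolOAssignment",
    function(x) setNames(x@label, x@cell_id))

#' @rdname MolOAssignment-class
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))

#' @rdname MolOAssignment-class
#' @export
setMethod("divergence", "MolOAssignment",
    function(x) setNames(x@divergence, x@cell_id))

#' Per-cell scores of a score object
#' @param x a `MolOScore` or `SuMOScore`.
#' @return named numeric vector of per-cell scores.
#' @export
setGeneric("cellScores", function(x) standardGeneric("cellScores"))

#' @rdname cellScores
#' @export
setMethod("cellScores", "MolOScore", function(x) setNames(x@score, x@cell_id))

#' @rdname cellScores
#' @export
setMethod("cellScores", "SuMOScore", function(x) setNames(x@score, x@cell_id))

#' @rdname NoiseFit-class
#' @param x a `NoiseFit`.
#' @export
setGeneric("noiseParams", function(x) standardGeneric("noiseParams"))

#' @rdname NoiseFit-class
#' @export
setMethod("noiseParams", "NoiseFit", function(x) c(a0 = x@a0, a1 = x@a1))

#' Technical CV2 expected at a given normalized mean
#' @param x a `NoiseFit`.
#' @param mu normalized mean counts.
#' @return numeric vector `a1 / mu + a0`.
#' @export
setGeneric("technicalCV2", function(x, mu) standardGeneric("technicalCV2"))

#' @rdname technicalCV2
#' @export
setMethod("technicalCV2", "NoiseFit", function(x, mu) x@a1 / mu + x@a0)

#' @rdname LDAResult-class
#' @param x an `LDAResult`.
#' @export
setGeneric("frequency95", function(x) standardGeneric("frequency95"))

#' @rdname LDAResult-class
#' @export
setMethod("frequency95", "LDAResult",
    function(x) c(estimate = x@estimate, lower = x@lower, upper = x@upper))

setMethod("show", "CtExperiment", function(object) {
    cat("CtExperiment:", nrow(object), "assays x", ncol(object), "cells\n")
    cat("  housekeepers:",
        paste(rowData(object)$gene_name[rowData(object)$is_housekeeper],
              collapse = ", "), "\n")
    cat("  populations:",
        paste(names(table(colData(object)$population)), collapse = ", "), "\n")
    cat("  detected:",
        sprintf("%.1f%%", 100 * mean(assay(object, "detected"))),
        " (lod Ct =", metadata(object)$lod_ct, ")\n")
})

setMethod("show", "DeltaCtExperiment", function(object) {
    cat("DeltaCtExperiment:", nrow(object), "genes x", ncol(object), "cells\n")
    exc <- metadata(object)$excluded_assays
    if (!is.null(exc) && nrow(exc))
        cat("  excluded assays:", nrow(exc),
            paste0("(", paste(utils::head(exc$gene_name, 5), collapse = ", "),
                   if (nrow(exc) > 5) ", ..." else "", ")"), "\n")
})

setMethod("show", "IndexSortTable", function(object) {
    cat("IndexSortTable:", nrow(object@channels), "cells x",
        ncol(object@channels), "channels\n")
    cat("  channels:", paste(colnames(object@channels), collapse = ", "), "\n")
    cat("  batches:", length(unique(object@batch_id)),
        " dropped rows:", object@n_dropped, "\n")
})

setMethod("show", "Embedding2D", function(object) {
    cat("Embedding2D:", nrow(object@coords), "cells (", object@input_kind,
        "), perplexity", object@perplexity, ", seed", object@seed, "\n")
})

setMethod("show", "MolOAssignment", function(object) {
    tab <- table(object@label)
    cat("MolOAssignment:", length(object@cell_id), "cells —",
        paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    cat("  k =", object@k, ", alpha =", object@alpha,
        ", permutations =", object@n_perm, "\n")
})

setMethod("show", "MolOScore", function(object) {
    cat("MolOScore:", length(object@score), "cells (platform:",
        object@platform, ")\n")
    cat("  score range:",
        sprintf("[%.3f, %.3f]", min(object@score), max(object@score)), "\n")
})

setMethod("show", "MolOClassifier", function(object) {
    cat("MolOClassifier:", length(object@features), "features,",
        object@forest$ntree, "trees, seed", object@seed, "\n")
    cat("  top importances:",
        paste(utils::head(names(object@importance), 5), collapse = ", "), "\n")
})

setMethod("show", "SuMOScore", function(object) {
    cat("SuMOScore:", length(object@score), "cells; axis (",
        sprintf("%.3f, %.3f", object@axis[1], object@axis[2]),
        "), flipped:", object@flipped, "\n")
})

setMethod("show", "NoiseFit", function(object) {
    cat(sprintf("NoiseFit: CV2(mu) = %.4g/mu + %.4g  (%d spike-ins, min mean %.3g)\n",
                object@a1, object@a0, object@n_spikeins, object@min_mean))
})

setMethod("show", "LDAResult", function(object) {
    if (object@unbounded)
        cat(sprintf("LDAResult: all recipients positive; f >= %.4g (95%% LR lower bound)\n",
                    object@lower))
    else
        cat(sprintf("LDAResult: f = %.4g (1 in %.3g), 95%% CI [%.4g, %.4g]\n",
                    object@estimate,
                    ifelse(object@estimate > 0, 1 / object@estimate, Inf),
                    object@lower, object@upper))
})
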