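#' @importFrom randomForest randomForest importance
NULL

#' Expression-oriented qPCR feature matrix
#'
#' Features for classifier training: negative delta-Ct (so higher values
#' mean more transcript, matching the RNA-seq orientation), restricted to a
#' gene panel, cells in rows.
#'
#' @param dct a [DeltaCtExperiment-class].
#' @param genes panel to use; all must be present.
#' @return numeric matrix, cells x genes.
#' @export
qpcrFeatureMatrix <- function(dct, genes) {
    miss <- setdiff(genes, rowData(dct)$gene_name)
    if (length(miss))
        stop("feature gene(s) missing from the panel: ",
             paste(miss, collapse = ", "))
    t(-dctValues(dct)[match(genes, rowData(dct)$gene_name), , drop = FALSE])
}

#' Log-normalized RNA-seq feature matrix
#'
#' `log2(count / size_factor + 1)` over a gene panel, cells in rows.
#'
#' @param sce a `SingleCellExperiment` with assay `"counts"`.
#' @param sf per-cell size factors (see [computeSizeFactors()]).
#' @param genes panel to use; all must be present.
#' @return numeric matrix, cells x genes.
#' @export
rnaFeatureMatrix <- function(sce, sf, genes) {
    miss <- setdiff(genes, rownames(sce))
    if (length(miss))
        stop("feature gene(s) missing from the counts matrix: ",
             paste(miss, collapse = ", "))
    m <- assay(sce, "counts")[genes, , drop = FALSE]
    t(log2(sweep(m, 2, sf, "/") + 1))
}

#' Train the MolO random-forest classifier
#'
#' Fits a random forest to per-platform z-scored expression of the shared
#' variable-gene panel, labeled by the MolO/NoMO assignment. Training is
#' restricted to one sorting strategy (the one also profiled by RNA-seq) by
#' subsetting `features` before the call. Class weights are balanced and
#' the seed is pinned so the fit, the ranked impurity importances, and all
#' downstream scores are reproducible.
#'
#' @param features numeric matrix, training cells x genes, expression
#'   oriented (higher = more expressed); see [qpcrFeatureMatrix()].
#' @param assign a [MolOAssignment-class]; training cells must carry MolO or
#'   NoMO labels and both classes must be present.
#' @param n_trees number of trees.
#' @param seed integer training seed.
#' @return a [MolOClassifier-class].
#' @export
trainMoloClassifier <- function(features, assign, n_trees = 1000,
                                seed = 0L) {
    if (!ncol(features)) stop("feature panel is empty")
    lab <- moloLabels(assign)
    ids <- rownames(features)
    keep <- ids[ids %in% names(lab)[lab %in% c("MolO", "NoMO")]]
    y <- factor(as.character(lab[keep]), levels = c("NoMO", "MolO"))
    if (length(unique(y)) < 2)
        stop("training set contains a single class: ", unique(as.character(y)))
    x <- .zscoreCols(features[keep, , drop = FALSE])
    set.seed(as.integer(seed))
    cw <- 1 / table(y)
    fit <- randomForest(x, y, ntree = n_trees,
                        classwt = cw / sum(cw), importance = FALSE)
    imp <- sort(importance(fit)[, "MeanDecreaseGini"], decreasing = TRUE)
    new("MolOClassifier", forest = fit, features = colnames(features),
        seed = as.integer(seed), importance = imp)
}

#' Stratified k-fold cross-validation of the MolO classifier
#'
#' Folds are stratified by class and assigned deterministically from the
#' seed; per-fold accuracies, their mean and SD, and the held-out per-cell
#' predictions are returned so accuracy can be recounted from first
#' principles.
#'
#' @param features cells x genes matrix (expression oriented).
#' @param labels factor of class labels, aligned with rows.
#' @param folds number of folds (at least 2; each class must populate every
#'   fold).
#' @param n_trees trees per fold.
#' @param seed integer seed controlling folds and forests.
#' @return list with `fold_accuracy`, `mean`, `sd`, and `predictions`
#'   (data.frame cell_id, fold, truth, predicted).
#' @export
crossValidate <- function(features, labels, folds = 10, n_trees = 500,
                          seed = 0L) {
    stopifnot(folds >= 2)
    labels <- factor(labels)
    if (min(table(labels)) < folds)
        stop("cannot stratify: smallest class has ", min(table(labels)),
             " cells for ", folds, " folds")
    set.seed(as.integer(seed))
    fold_id <- integer(length(labels))
    for (cl in levels(labels)) {
        i <- which(labels == cl)
        fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    x <- .zscoreCols(features)
    preds <- character(length(labels))
    for (f in seq_len(folds)) {
        test <- fold_id == f
        set.seed(stageSeed(seed, paste0("cv_fold_", f)))
        fit <- randomForest(x[!test, , drop = FALSE], labels[!test],
                            ntree = n_trees)
        preds[test] <- as.character(
            stats::predict(fit, x[test, , drop = FALSE]))
    }
    df <- data.frame(cell_id = rownames(features) %||%
                         as.character(seq_along(labels)),
                     fold = fold_id, truth = as.character(labels),
                     predicted = preds)
    acc <- vapply(seq_len(folds), function(f)
        mean(df$predicted[df$fold == f] == df$truth[df$fold == f]),
        numeric(1))
    list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
         predictions = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score cells with a fitted MolO classifier
#'
#' Returns the MolO class probability (fraction of trees voting MolO) per
#' cell. Features are z-scored per gene within the supplied platform before
#' scoring, so qPCR-trained forests transfer to RNA-seq profiles over the
#' shared panel; feature columns are matched by name, so column order does
#' not matter.
#'
#' @param model a [MolOClassifier-class].
#' @param features cells x genes matrix on the scoring platform, expression
#'   oriented (see [rnaFeatureMatrix()]); must contain every model feature.
#' @param platform tag recorded on the result (e.g. `"rnaseq"`).
#' @return a [MolOScore-class] with scores in `[0, 1]`.
#' @export
scoreCells <- function(model, features, platform = "rnaseq") {
    miss <- setdiff(model@features, colnames(features))
    if (length(miss))
        stop("missing model feature(s): ", paste(miss, collapse = ", "))
    x <- .zscoreCols(features[, model@features, drop = FALSE])
    prob <- stats::predict(model@forest, x, type = "prob")[, "MolO"]
    new("MolOScore",
        cell_id = rownames(features) %||% as.character(seq_len(nrow(x))),
        score = unname(prob), platform = platform,
        features = model@features)
}
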