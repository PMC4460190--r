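#' Embed cells in 2D with t-SNE
#'
#' Barnes-Hut t-SNE with PCA pre-reduction, seed-pinned so the same input
#' and seed give identical coordinates. Axes are in arbitrary units; all
#' downstream neighborhood statistics consume only the coordinates plus
#' metadata, never the raw features.
#'
#' @param features numeric matrix, cells in rows (named), features in
#'   columns; no missing values.
#' @param perplexity t-SNE perplexity; requires `nrow(features) - 1 >=
#'   3 * perplexity`.
#' @param seed integer random seed.
#' @param init_dims PCA pre-reduction dimensionality (capped at the number
#'   of features).
#' @param input_kind provenance tag stored on the result
#'   (`"qpcr_genes"` or `"surface_markers"`).
#' @param theta Barnes-Hut accuracy trade-off; 0 runs exact t-SNE. The
#'   default uses the exact algorithm up to 500 cells (where it is cheap
#'   and places duplicate profiles faithfully) and the approximation above.
#' @return an [Embedding2D-class].
#' @export
embedTSNE <- function(features, perplexity = 30, seed = 0L,
                      init_dims = 30L, input_kind = "qpcr_genes",
                      theta = NULL) {
    features <- as.matrix(features)
    if (anyNA(features)) stop("features must not contain missing values")
    n <- nrow(features)
    if (n - 1 < 3 * perplexity)
        stop("perplexity ", perplexity, " too large for ", n,
             " cells; use perplexity <= ", floor((n - 1) / 3))
    if (is.null(rownames(features)))
        rownames(features) <- sprintf("cell%04d", seq_len(n))
    init_dims <- min(as.integer(init_dims), ncol(features))
    # column order must not matter: fix a canonical feature order
    if (!is.null(colnames(features)))
        features <- features[, order(colnames(features)), drop = FALSE]
    if (is.null(theta)) theta <- if (n <= 500) 0 else 0.5
    set.seed(as.integer(seed))
    fit <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                        initial_dims = init_dims, pca = TRUE, theta = theta,
                        check_duplicates = FALSE, verbose = FALSE)
    coords <- fit$Y
    rownames(coords) <- rownames(features)
    colnames(coords) <- c("x", "y")
    new("Embedding2D", coords = coords, input_kind = input_kind,
        perplexity = perplexity, seed = as.integer(seed),
        init_dims = init_dims)
}
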