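#' Jensen-Shannon divergence between two discrete distributions
#'
#' Symmetric, bounded smoothing of the Kullback-Leibler divergence:
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, computed
#' in nats. Defined for zero entries (`0 * log 0 = 0`) and bounded by
#' `log(2)`; zero iff `p == q`.
#'
#' @param p,q non-negative vectors of equal length; normalized internally.
#' @return a single non-negative number in `[0, log(2)]`.
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))  # log(2)
#' jsDivergence(c(.5, .5), c(.5, .5))  # 0
#' @export
jsDivergence <- function(p, q) {
    stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
    p <- p / sum(p)
    q <- q / sum(q)
    m <- (p + q) / 2
    kl <- function(a, b) {
        i <- a > 0
        sum(a[i] * log(a[i] / b[i]))
    }
    max(0, (kl(p, m) + kl(q, m)) / 2)
}

# JSD of each row of a composition matrix against a fixed weight vector,
# vectorized across rows (nats).
.jsdRows <- function(comp, w) {
    w <- w / sum(w)
    wmat <- matrix(w, nrow(comp), length(w), byrow = TRUE)
    m <- (comp + wmat) / 2
    t1 <- comp * log(comp / m)
    t1[comp == 0] <- 0
    t2 <- wmat * log(wmat / m)
    t2[wmat == 0] <- 0
    pmax(0, (rowSums(t1) + rowSums(t2)) / 2)
}

#' Derive a per-stage seed from a run seed
#'
#' All randomness in the pipeline flows from one run seed, fanned out per
#' stage by a stable string hash so stages are decoupled but reproducible.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003L
    as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# geometric mean of positive values; NA if any non-positive
.geomean <- function(x) exp(mean(log(x)))

# column-wise z-score; zero-variance columns map to 0
.zscoreCols <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sd, "/")
}

# match rows of two per-cell objects by id, erroring on missing ids
.matchCells <- function(query, target, what = "cells") {
    idx <- match(query, target)
    if (anyNA(idx))
        stop(sum(is.na(idx)), " ", what, " could not be matched by cell_id: ",
             paste(utils::head(query[is.na(idx)], 5), collapse = ", "))
    idx
}
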