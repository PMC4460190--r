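makeIdx <- function(m, ids, batch = "b1") IndexSortTable(m, ids, batch)

test_that("joint marker embedding pools, matches channels by name", {
    set.seed(1)
    ch <- c("CD150", "Sca1", "CD48")
    a <- matrix(rlnorm(92 * 3), 92, 3, dimnames = list(NULL, ch))
    b <- matrix(rlnorm(29 * 3), 29, 3, dimnames = list(NULL, ch))
    idx_a <- makeIdx(a, sprintf("s%02d", 1:92))
    idx_b <- makeIdx(b, sprintf("t%02d", 1:29))
    emb <- jointMarkerEmbedding(idx_a, idx_b, perplexity = 10, seed = 2L)
    expect_equal(nrow(coords(emb)), 121L)
    expect_equal(attr(coords(emb), "provenance"),
                 rep(c("seq", "tx"), c(92, 29)))
    # shuffling channel columns changes nothing
    emb2 <- jointMarkerEmbedding(idx_a, makeIdx(b[, c(3, 1, 2)],
                                                sprintf("t%02d", 1:29)),
                                 perplexity = 10, seed = 2L)
    expect_identical(coords(emb)[, ], coords(emb2)[, ])
    # asymmetric channel sets are a hard error naming the offender
    expect_error(jointMarkerEmbedding(idx_a,
        makeIdx(b[, 1:2], sprintf("t%02d", 1:29))), "CD48")
})

test_that("identical channel vectors give coincident embedded points", {
    set.seed(3)
    ch <- c("CD150", "Sca1")
    base <- matrix(rlnorm(60 * 2), 60, 2, dimnames = list(NULL, ch))
    idx_a <- makeIdx(base, sprintf("s%02d", 1:60))
    idx_b <- makeIdx(base[1:10, ], sprintf("t%02d", 1:10))
    emb <- jointMarkerEmbedding(idx_a, idx_b, perplexity = 10, seed = 4L)
    xy <- coords(emb)
    # duplicated profiles land at the local nearest-neighbor scale of the
    # map: far below the global span, with the twin as nearest neighbor
    D <- as.matrix(dist(xy))
    diag(D) <- Inf
    d_dup <- D[cbind(1:10, 61:70)]
    expect_true(all(d_dup < 0.05 * max(D[is.finite(D)])))
    expect_true(all(d_dup <= 1.5 * median(apply(D, 1, min))))
    expect_true(all(apply(D, 1, which.min)[1:10] == 61:70))
})

test_that("the SuMO axis equals the leading covariance eigenvector", {
    set.seed(5)
    xy <- cbind(rnorm(50, 0, 5), rnorm(50, 0, 1))
    rot <- matrix(c(cos(.6), sin(.6), -sin(.6), cos(.6)), 2)
    xy <- xy %*% rot
    rownames(xy) <- sprintf("c%02d", 1:50)
    emb <- new("Embedding2D", coords = xy, input_kind = "surface_markers",
               perplexity = 10, seed = 0L, init_dims = 2L)
    molo <- stats::setNames(xy %*% eigen(cov(xy))$vectors[, 1], rownames(xy))
    sumo <- fitSumoAxis(emb, molo)
    ev <- eigen(cov(xy), symmetric = TRUE)$vectors[, 1]
    expect_equal(abs(sum(sumo@axis * ev)), 1, tolerance = 1e-9)
    # orientation rule: correlation with the MolO score is non-negative
    expect_gte(cor(cellScores(sumo), molo, method = "spearman"), 0)
    # flipping the anchor flips the axis sign, never the magnitude
    sumo2 <- fitSumoAxis(emb, -molo)
    expect_equal(cellScores(sumo2), -cellScores(sumo))
})

test_that("collinear points project in their order along the line", {
    t <- seq_len(20)
    xy <- cbind(2 * t + 1, -t + 3)
    rownames(xy) <- sprintf("c%02d", t)
    emb <- new("Embedding2D", coords = xy, input_kind = "surface_markers",
               perplexity = 5, seed = 0L, init_dims = 2L)
    sumo <- fitSumoAxis(emb, stats::setNames(as.numeric(t), rownames(xy)))
    expect_equal(cor(cellScores(sumo), t, method = "spearman"), 1)
})

test_that("the SuMO score is rigid-motion invariant up to sign", {
    set.seed(6)
    xy <- cbind(rnorm(40, 0, 3), rnorm(40))
    rownames(xy) <- sprintf("c%02d", 1:40)
    theta <- 1.1
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    xy2 <- sweep(xy %*% rot, 2, c(10, -4), "+")
    rownames(xy2) <- rownames(xy)
    mk <- function(m) new("Embedding2D", coords = m,
                          input_kind = "surface_markers", perplexity = 5,
                          seed = 0L, init_dims = 2L)
    molo <- stats::setNames(rnorm(40), rownames(xy))
    s1 <- cellScores(fitSumoAxis(mk(xy), molo))
    s2 <- cellScores(fitSumoAxis(mk(xy2), molo))
    expect_true(max(abs(s1 - s2)) < 1e-8 || max(abs(s1 + s2)) < 1e-8)
})

test_that("region enrichment uses the exact tests on separated data", {
    set.seed(7)
    xy <- rbind(cbind(rnorm(6, 0, .1), rnorm(6, 0, .1)),
                cbind(rnorm(6, 10, .1), rnorm(6, 10, .1)))
    rownames(xy) <- sprintf("c%02d", 1:12)
    emb <- new("Embedding2D", coords = xy, input_kind = "surface_markers",
               perplexity = 2, seed = 0L, init_dims = 2L)
    vals <- data.frame(score = c(1:6, 101:106),
                       hit = c(rep(TRUE, 6), rep(FALSE, 6)),
                       row.names = rownames(xy))
    res <- regionEnrichment(emb, vals)
    # perfectly separated scalars: exact rank-sum enumeration value
    expect_equal(res$p[res$variable == "score"], 2 / choose(12, 6),
                 tolerance = 1e-12)
    # all-or-none binary outcome: exact Fisher value
    expect_equal(res$p[res$variable == "hit"],
                 fisher.test(matrix(c(6, 0, 0, 6), 2))$p.value,
                 tolerance = 1e-12)
    expect_equal(res$test, c("wilcoxon", "fisher"))
})

test_that("repopulation calls follow the inclusive 1% rule and subtypes", {
    mk <- function(id, wbc16, gm = wbc16, b = wbc16, t = wbc16,
                   wbc24 = wbc16) {
        data.frame(mouse_id = id, dose = 1L,
                   week = c(16, 16, 16, 16, 24),
                   lineage = c("WBC", "GM", "B", "T", "WBC"),
                   donor = c(wbc16, gm, b, t, wbc24) * 100,
                   recipient = 10000 - c(wbc16, gm, b, t, wbc24) * 100)
    }
    tx <- rbind(mk("none", 0),                       # no donor cells
                mk("five", 5),                       # balanced at 5%
                mk("edge", 1),                       # exactly 1.0%
                mk("alpha", 10, gm = 30, b = 5, t = 5),
                mk("gamma", 10, gm = 1, b = 20, t = 20),
                mk("late", 0.5, wbc24 = 2))          # repopulated at wk 24
    calls <- callRepopulation(tx, threshold_pct = 1)
    rownames(calls) <- calls$mouse_id
    expect_false(calls["none", "repopulated"])
    expect_equal(calls["none", "subtype"], "none")
    expect_true(calls["five", "repopulated"])
    expect_equal(calls["five", "subtype"], "beta")
    expect_true(calls["edge", "repopulated"])        # inclusive threshold
    expect_equal(calls["alpha", "subtype"], "alpha")
    expect_equal(calls["gamma", "subtype"], "gamma")
    expect_true(calls["late", "repopulated"])
    # donor 500 / recipient 9500 is 5% chimerism
    expect_equal(calls["five", "wbc16"], 5)
})

test_that("increasing donor counts never revokes a repopulation call", {
    set.seed(8)
    base <- data.frame(mouse_id = "m", dose = 1L, week = 16,
                       lineage = "WBC", donor = 150, recipient = 9850)
    before <- callRepopulation(base)$repopulated
    for (extra in c(1, 10, 1000)) {
        up <- base
        up$donor <- base$donor + extra
        expect_true(callRepopulation(up)$repopulated >= before)
    }
})

test_that("limiting dilution matches closed forms and the grid oracle", {
    # all negative: frequency zero
    expect_equal(limitingDilution(10, 5, 5)@estimate, 0)
    # single dose closed form: -log(1/5)/10
    fit <- limitingDilution(10, 5, 1)
    expect_equal(fit@estimate, -log(1 / 5) / 10, tolerance = 1e-6)
    expect_equal(round(fit@estimate, 4), 0.1609)
    expect_true(fit@lower < fit@estimate && fit@estimate < fit@upper)
    # all positive: unbounded point estimate, actionable lower bound
    ap <- limitingDilution(10, 5, 0)
    expect_true(ap@unbounded)
    expect_true(is.na(ap@estimate))
    expect_gt(ap@lower, 0)
    # dose zero with a positive recipient violates the model
    expect_error(limitingDilution(c(0, 10), c(2, 5), c(1, 2)), "dose 0")
    # two-dose designs agree with a likelihood grid search
    set.seed(9)
    for (i in 1:25) {
        doses <- sort(sample(c(1, 3, 10, 30, 100), 2))
        n_mice <- sample(3:8, 2, replace = TRUE)
        n_neg <- vapply(seq_len(2), function(j) {
            f <- runif(1, 0.005, 0.3)
            rbinom(1, n_mice[j], exp(-f * doses[j]))
        }, integer(1))
        if (sum(n_neg) == 0 || sum(n_mice - n_neg) == 0) next
        mine <- limitingDilution(doses, n_mice, n_neg)@estimate
        expect_equal(mine, bruteLdaGrid(doses, n_mice, n_neg),
                     tolerance = 1e-3)
    }
})

test_that("limiting dilution agrees with the ELDA reference implementation", {
    skip_if_not_installed("statmod")
    fit <- limitingDilution(c(10, 50), c(6, 6), c(4, 1))
    el <- statmod::elda(response = c(6 - 4, 6 - 1), dose = c(10, 50),
                        tested = c(6, 6))
    expect_equal(fit@estimate, 1 / el$CI[1, "Estimate"], tolerance = 1e-3)
})

test_that("the mammary pipeline recovers the planted colony phenotype", {
    spec <- SimSpec(seed = 15L)
    col <- simulateIndexAndFunction(spec,
        data.frame(cell_id = "c1", molo = TRUE), n_tx = 1L,
        n_patients = 3L, cells_per_patient = 80L)$colonies
    res <- mammaryPipeline(col, k_clusters = 2, perplexity = 20, seed = 3L)
    expect_true(all(res$per_patient$fold > 1))
    # the planted progenitor channels dominate the ranking in every
    # patient, led by EpCAM or side scatter
    planted <- c("EpCAM", "SSC", "CD49f", "ALDH")
    for (d in split(res$marker_tests, res$marker_tests$patient)) {
        top2 <- d$channel[order(d$q)][1:2]
        expect_true(all(top2 %in% planted))
        expect_true(any(top2 %in% c("EpCAM", "SSC")))
        expect_equal(d$median_in[d$channel == "EpCAM"] >
                     d$median_out[d$channel == "EpCAM"], TRUE)
        expect_lt(d$median_in[d$channel == "SSC"],
                  d$median_out[d$channel == "SSC"])
    }
    # per-patient z-scoring leaves mean 0 / sd 1 in every channel
    z <- scMolO:::.zscoreCols(as.matrix(
        col[col$patient_id == "patient1", attr(col, "channel_names")]))
    expect_true(all(abs(colMeans(z)) < 1e-8))
    expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-8))
})

test_that("without planted structure the colony fold shows only the
           max-selection bias", {
    # with a colony probability independent of phenotype the only lift in
    # the reported fold is the bias from picking the better of two
    # clusters, which stays well below the planted-effect fold
    folds <- c()
    for (s in 1:30) {
        set.seed(400 + s)
        n <- 70
        ch <- matrix(rlnorm(n * 4), n, 4,
                     dimnames = list(NULL, c("SSC", "EpCAM", "CD49f",
                                             "ALDH")))
        col <- data.frame(cell_id = sprintf("w%03d", 1:n),
                          patient_id = "p1",
                          colony = rbinom(n, 1, 0.3), ch,
                          check.names = FALSE)
        res <- mammaryPipeline(col, k_clusters = 2, perplexity = 10,
                               seed = s, min_cells_per_patient = 20)
        folds <- c(folds, res$per_patient$fold)
    }
    expect_gte(min(folds), 1)       # fold is a maximum over clusters
    expect_lt(mean(folds), 1.5)     # but carries no planted enrichment
})

test_that("patients with zero colonies are flagged instead of dividing by 0", {
    set.seed(16)
    n <- 40
    ch <- matrix(rlnorm(n * 2), n, 2, dimnames = list(NULL, c("SSC",
                                                              "EpCAM")))
    col <- data.frame(cell_id = sprintf("w%02d", 1:n), patient_id = "p1",
                      colony = 0L, ch, check.names = FALSE)
    res <- mammaryPipeline(col, perplexity = 10, seed = 1L,
                           min_cells_per_patient = 20)
    expect_true(is.na(res$per_patient$fold))
})
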