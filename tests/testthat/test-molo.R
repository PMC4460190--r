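test_that("Jensen-Shannon divergence has its defining properties", {
    expect_equal(jsDivergence(c(.5, .5), c(.5, .5)), 0)
    expect_equal(jsDivergence(c(1, 0), c(0, 1)), log(2))
    set.seed(1)
    for (i in 1:20) {
        p <- runif(4)
        q <- runif(4)
        d <- jsDivergence(p, q)
        expect_gte(d, 0)
        expect_lte(d, log(2) + 1e-12)
        expect_equal(d, jsDivergence(q, p))
    }
    expect_equal(jsDivergence(c(2, 2, 4), c(1, 1, 2)), 0)  # same after norm
})

test_that("neighborhood composition covers the limiting cases", {
    xy <- cbind(runif(30), runif(30))
    rownames(xy) <- sprintf("c%02d", 1:30)
    emb <- new("Embedding2D", coords = xy, input_kind = "qpcr_genes",
               perplexity = 5, seed = 0L, init_dims = 2L)
    one <- rep("S1", 30)
    comp <- neighborhoodComposition(emb, one, k = 5)
    expect_true(all(comp[, "S1"] == 1))
    # global neighborhood returns the global strategy frequencies
    labs <- rep(c("S1", "S2", "S3"), each = 10)
    compg <- neighborhoodComposition(emb, labs, k = 30)
    expect_true(all(abs(compg - 1 / 3) < 1e-12))
    expect_true(all(abs(rowSums(compg) - 1) < 1e-12))
})

test_that("compositions match a brute-force kNN on a checkerboard", {
    g <- expand.grid(x = 1:4, y = 1:4)
    xy <- as.matrix(g) + 0.01 * seq_len(16)   # break ties deterministically
    rownames(xy) <- sprintf("c%02d", 1:16)
    labs <- rep(c("A", "B"), 8)
    emb <- new("Embedding2D", coords = xy, input_kind = "qpcr_genes",
               perplexity = 2, seed = 0L, init_dims = 2L)
    comp <- neighborhoodComposition(emb, labs, k = 4)
    brute <- bruteKnnComposition(xy, labs, k = 4)
    expect_equal(unname(comp[, c("A", "B")]), unname(brute))
})

test_that("a neighborhood matching the weights is MolO, a disjoint one NoMO", {
    # two tight spatial clusters: one mixed to match w, one pure strategy 2
    set.seed(3)
    n1 <- 60
    mixed_labs <- rep(c("S1", "S2"), c(36, 24))       # 0.6 / 0.4 = w
    pure_labs <- rep("S2", 40)
    xy <- rbind(cbind(rnorm(n1, 0, .1), rnorm(n1, 0, .1)),
                cbind(rnorm(40, 50, .1), rnorm(40, 50, .1)))
    rownames(xy) <- sprintf("c%03d", 1:100)
    labs <- c(mixed_labs, pure_labs)
    emb <- new("Embedding2D", coords = xy, input_kind = "qpcr_genes",
               perplexity = 5, seed = 0L, init_dims = 2L)
    w <- c(S1 = 0.6, S2 = 0.4)
    asg <- identifyMolo(emb, labs, w, k = 30, alpha = 0.1, n_perm = 199,
                        seed = 1L)
    lab <- moloLabels(asg)
    # pure-strategy cluster is never MolO: its divergence is far in the tail
    expect_true(all(lab[61:100] == "NoMO"))
    # mixed cluster carries low divergence and is predominantly MolO
    d <- divergence(asg)
    expect_lt(median(d[1:60], na.rm = TRUE), median(d[61:100], na.rm = TRUE))
    expect_gt(mean(lab[1:60] == "MolO"), 0.8)
})

test_that("MolO calls are invariant to uniform rescaling of coordinates", {
    set.seed(4)
    xy <- cbind(runif(80), runif(80))
    rownames(xy) <- sprintf("c%02d", 1:80)
    labs <- sample(rep(c("S1", "S2"), 40))
    emb1 <- new("Embedding2D", coords = xy, input_kind = "qpcr_genes",
                perplexity = 5, seed = 0L, init_dims = 2L)
    emb2 <- new("Embedding2D", coords = xy * 37.5, input_kind = "qpcr_genes",
                perplexity = 5, seed = 0L, init_dims = 2L)
    w <- c(S1 = 0.7, S2 = 0.3)
    a1 <- identifyMolo(emb1, labs, w, k = 10, n_perm = 199, seed = 5L)
    a2 <- identifyMolo(emb2, labs, w, k = 10, n_perm = 199, seed = 5L)
    expect_identical(moloLabels(a1), moloLabels(a2))
    expect_equal(divergence(a1), divergence(a2))
})

test_that("under a true label null the MolO call rate matches alpha", {
    # random geometry + random labels: cells are exchangeable, so the
    # permutation p-values are uniform on their grid; a small random
    # subsample per round keeps the calls nearly independent
    alpha <- 0.05
    n_perm <- 199
    calls <- unlist(lapply(1:120, function(s) {
        set.seed(s)
        n <- 150
        xy <- cbind(runif(n), runif(n))
        rownames(xy) <- sprintf("c%03d", seq_len(n))
        labs <- sample(rep(c("S1", "S2", "S3"), each = 50))
        emb <- new("Embedding2D", coords = xy, input_kind = "qpcr_genes",
                   perplexity = 5, seed = 0L, init_dims = 2L)
        asg <- identifyMolo(emb, labs, c(S1 = .5, S2 = .3, S3 = .2),
                            k = 15, alpha = alpha, n_perm = n_perm,
                            seed = s)
        pick <- sample(cellIds(asg), 15)
        as.character(moloLabels(asg)[pick]) == "MolO"
    }))
    rate <- mean(calls)
    sd3 <- 3 * sqrt(alpha * (1 - alpha) / length(calls))
    expect_lt(abs(rate - alpha), sd3 + 0.01)
})

test_that("differential gene testing matches the exact rank-sum oracle", {
    sim <- runMoloRound(51, n_perm = 199)
    tab <- moloDifferentialGenes(sim$dct, sim$assign, fdr = 0.05)
    expect_true(all(c("gene", "p", "q", "direction") %in% names(tab)))
    # planted MolO-shifted genes (first 15, shifted down in Ct = up) rank top
    planted <- sprintf("Gene%02d", 1:15)
    expect_gte(mean(planted %in% tab$gene[tab$significant &
                                          tab$direction == "up"]), 0.8)
    # a gene identical across groups is never significant
    lab <- moloLabels(sim$assign)
    m <- dctValues(sim$dct)
    const <- m
    const["Gene20", ] <- 1
    dct2 <- sim$dct
    SummarizedExperiment::assay(dct2, "dct") <- const
    tab2 <- moloDifferentialGenes(dct2, sim$assign)
    expect_gte(tab2$p[tab2$gene == "Gene20"], 0.99)
    # exact-oracle agreement on small tie-free groups
    set.seed(9)
    for (i in 1:25) {
        a <- rnorm(7)
        b <- rnorm(6)
        expect_equal(wilcox.test(a, b)$p.value, bruteWilcoxP(a, b),
                     tolerance = 1e-10)
    }
    # fully separated ranks at n = 10 vs 10 hit the enumeration floor
    a <- 1:10
    b <- 21:30
    expect_equal(wilcox.test(a, b)$p.value, 2 / choose(20, 10),
                 tolerance = 1e-12)
})

test_that("too-small groups are a hard error naming the counts", {
    sim <- runMoloRound(52, n_perm = 199)
    lab <- moloLabels(sim$assign)
    keep <- c(names(lab)[lab == "MolO"][1:2], names(lab)[lab == "NoMO"])
    expect_error(moloDifferentialGenes(sim$dct[, keep], sim$assign),
                 "MolO = 2")
})

test_that("marker enrichment recovers the planted channel directions", {
    round <- runMoloRound(53, n_perm = 199)
    fx <- simulateIndexAndFunction(round$spec, round$sim$truth, n_tx = 5L,
                                   n_patients = 1L, cells_per_patient = 20L)
    tab <- indexMarkerEnrichment(fx$index, round$assign)
    top3 <- tab$channel[1:3]
    expect_setequal(intersect(top3, c("Sca1", "CD150", "CD48")), top3)
    expect_equal(tab$direction[tab$channel == "CD48"], "down")
    expect_equal(tab$direction[tab$channel == "CD150"], "up")
    expect_equal(tab$direction[tab$channel == "Sca1"], "up")
    # single-channel table gives a one-row result
    one <- IndexSortTable(channelData(fx$index)[, "CD150", drop = FALSE],
                          cellIds(fx$index))
    expect_equal(nrow(indexMarkerEnrichment(one, round$assign)), 1L)
})

test_that("marker enrichment is quiet when no effect is planted", {
    # under a null marker model, most rounds yield no BH discovery
    eff0 <- stats::setNames(rep(0, 11), names(SimSpec()@marker_effect))
    hits <- vapply(1:60, function(s) {
        spec <- SimSpec(seed = as.integer(2000 + s), marker_effect = eff0)
        truth <- data.frame(cell_id = sprintf("c%02d", 1:60),
                            strategy = "HSC1",
                            molo = rep(c(TRUE, FALSE), 30))
        fx <- simulateIndexAndFunction(spec, truth, n_tx = 2L,
                                       n_patients = 1L,
                                       cells_per_patient = 20L)
        asg <- new("MolOAssignment", cell_id = truth$cell_id,
                   label = factor(ifelse(truth$molo, "MolO", "NoMO"),
                                  levels = c("MolO", "NoMO", "non-HSC")),
                   divergence = rep(0, 60), p_perm = rep(1, 60), k = 1L,
                   weights = 1, alpha = 0.05, n_perm = 0L)
        any(indexMarkerEnrichment(fx$index, asg)$q < 0.05)
    }, logical(1))
    expect_gte(mean(!hits), 0.9)
})
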