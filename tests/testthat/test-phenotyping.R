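# Four Gaussian blobs at 5-SD centroid separation; the noise is clipped at
# 2.4 SD so the blobs are disjoint by construction and exact recovery is
# the only correct outcome.
blobData <- function(n = 25, p = 6, sep = 5, sd = 1, seed = 8) {
    set.seed(seed)
    centers <- matrix(0, 4, p)
    centers[1, 1] <- sep; centers[2, 2] <- sep; centers[3, 3] <- sep
    centers[4, 4] <- sep
    X <- do.call(rbind, lapply(1:4, function(k) {
        z <- pmin(pmax(rnorm(n * p), -2.4), 2.4)
        matrix(rep(centers[k, ], each = n) + sd * z, nrow = n)
    }))
    rownames(X) <- sprintf("b%03d", seq_len(4 * n))
    list(X = X, truth = rep(1:4, each = n))
}

test_that("consensus k-means resolves well-separated blobs cleanly", {
    bd <- blobData()
    cr <- consensusKmeans(bd$X, k = 4, nReps = 200, seed = 13)
    expect_s4_class(cr, "ConsensusResult")
    expect_equal(ari(clusterLabels(cr), bd$truth), 1)
    M <- consensusMatrix(cr)
    expect_true(isSymmetric(M))
    expect_true(all(M >= 0 & M <= 1))
    within <- unlist(lapply(1:4, function(k) {
        i <- which(bd$truth == k)
        M[i, i][lower.tri(M[i, i])]
    }))
    expect_gte(mean(within), 0.95)
})

test_that("duplicated samples always co-cluster and parameters are validated", {
    bd <- blobData(n = 10)
    X <- rbind(bd$X, dupA = bd$X[1, ], dupB = bd$X[1, ])
    rownames(X)[41:42] <- c("dupA", "dupB")
    cr <- consensusKmeans(X, k = 4, nReps = 150, seed = 3)
    expect_equal(consensusMatrix(cr)["dupA", "dupB"], 1.0)
    expect_error(consensusKmeans(bd$X, k = 1), "k must be >= 2")
    expect_error(consensusKmeans(bd$X[1:5, ], k = 4), "2k")
})

test_that("consensus clustering is order-invariant and seed-deterministic", {
    bd <- blobData(n = 15, seed = 21)
    cr1 <- consensusKmeans(bd$X, k = 4, nReps = 120, seed = 99)
    set.seed(1); perm <- sample(nrow(bd$X))
    cr2 <- consensusKmeans(bd$X[perm, ], k = 4, nReps = 120, seed = 99)
    expect_equal(ari(clusterLabels(cr1)[perm], clusterLabels(cr2)), 1)
    cr3 <- consensusKmeans(bd$X, k = 4, nReps = 120, seed = 99)
    expect_identical(clusterLabels(cr1), clusterLabels(cr3))
    expect_identical(consensusMatrix(cr1), consensusMatrix(cr3))
})

axisFixture <- function(labels, means) {
    # means: list of c(ar, prolif, ne) per cluster index
    do.call(rbind, lapply(seq_along(labels), function(i) {
        m <- means[[labels[i]]]
        data.frame(sample_id = names(labels)[i], ar_score = m[1],
                   prolif_score = m[2], ne_score = m[3])
    }))
}

fakeConsensus <- function(labels) {
    n <- length(labels)
    M <- outer(labels, labels, function(a, b) as.numeric(a == b))
    dimnames(M) <- list(names(labels), names(labels))
    new("ConsensusResult", consensus = M, labels = as.integer(labels) |>
            stats::setNames(names(labels)), k = 4L, nReps = 10L)
}

test_that("cluster-phenotype mapping follows the reported axis archetypes", {
    labels <- stats::setNames(rep(1:4, each = 2), sprintf("s%d", 1:8))
    means <- list(c(1, -1, -1), c(1, 1, -1), c(-1, -1, -1), c(-1, 1, 2))
    map <- mapClustersToPhenotypes(fakeConsensus(labels),
                                   axisFixture(labels, means))
    expect_equal(unname(map[as.character(1:4)]),
                 c("LumA", "LumB", "LP", "NE"))
    # permuting cluster indices permutes the map consistently
    perm <- c(3L, 1L, 4L, 2L)   # new index of old cluster i
    labP <- stats::setNames(perm[labels], names(labels))
    meansP <- means[order(perm)]
    mapP <- mapClustersToPhenotypes(fakeConsensus(labP),
                                    axisFixture(labP, meansP))
    expect_equal(unname(mapP[as.character(perm)]), unname(map))
    # AR-high pair sharing the proliferation sign: higher proliferation = LumB
    means2 <- list(c(1, 0.2, -1), c(1, 0.8, -1), c(-1, -1, -1), c(-1, 1, 2))
    map2 <- mapClustersToPhenotypes(fakeConsensus(labels),
                                    axisFixture(labels, means2))
    expect_equal(unname(map2[as.character(1:2)]), c("LumA", "LumB"))
    # exact tie -> error demanding a manual map
    means3 <- list(c(1, 1, -1), c(1, 1, -1), c(-1, -1, -1), c(-1, 1, 2))
    expect_error(mapClustersToPhenotypes(fakeConsensus(labels),
                                         axisFixture(labels, means3)),
                 "ambiguous")
})

test_that("phenotype assignment combines gate tiers with cluster labels", {
    tiers <- factor(c("high_purity", "high_purity", "high_purity",
                      "low_ctc_reclassifiable", "low_ctc"),
                    levels = c("high_purity", "low_ctc_reclassifiable",
                               "low_ctc"))
    names(tiers) <- sprintf("s%d", 1:5)
    labs <- stats::setNames(c(1L, 2L, 4L), sprintf("s%d", 1:3))
    map <- c(`1` = "LumA", `2` = "LumB", `3` = "LP", `4` = "NE")
    asg <- assignPhenotypes(tiers, labs, map)
    expect_equal(as.character(asg$phenotype),
                 c("LumA", "LumB", "NE", "Low_CTC", "Low_CTC"))
    expect_equal(asg$source, c("cluster", "cluster", "cluster", "gate",
                               "gate"))
    # all low tiers -> all Low_CTC
    tiers2 <- tiers; tiers2[] <- "low_ctc"
    asg2 <- assignPhenotypes(tiers2, stats::setNames(integer(0), character(0)),
                             map)
    expect_true(all(asg2$phenotype == "Low_CTC"))
    expect_error(assignPhenotypes(tiers, labs[1:2], map), "s3")
})

test_that("kNN classification is exact on training points and tie-broken deterministically", {
    tr <- matrix(c(0, 0, 1, 1, 4, 4, 5, 5), ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("t%d", 1:4), c("p1", "p2")))
    lab <- factor(c("LumA", "LumA", "NE", "NE"), levels = c("LumA", "NE"))
    model <- knnTrain(tr, lab, k = 1)
    expect_equal(as.character(knnClassify(model, tr)),
                 as.character(lab), ignore_attr = TRUE)
    # equidistant between the two classes: smallest class index wins
    q <- matrix(c(2.5, 2.5), ncol = 2,
                dimnames = list("q", c("p1", "p2")))
    expect_equal(as.character(knnClassify(model, q)), "LumA")
    # missing pathway reported by name
    expect_error(knnClassify(model, matrix(0, 1, 1,
                                           dimnames = list("q", "p1"))),
                 "p2")
    # k = 1 on the training set reproduces training labels exactly
    model5 <- knnTrain(tr, lab, k = 3)
    expect_s4_class(model5, "KnnModel")
    expect_error(knnTrain(tr, lab, k = 9), "exceeds")
})

test_that("kNN transfers phenotypes to a held-out synthetic cohort accurately", {
    cfg <- simulationConfig(seed = 71)
    sim <- simulateCohort(cfg)
    ps <- suppressMessages(scorePathways(sim$expression, sim$collection))
    model <- knnTrain(scaledScores(ps), factor(sim$truth$phenotype), k = 5)
    sim2 <- simulateCohort(simulationConfig(seed = 72))
    ps2 <- suppressMessages(scorePathways(sim2$expression, sim2$collection))
    pred <- knnClassify(model, scaledScores(ps2))
    expect_gte(mean(as.character(pred) == sim2$truth$phenotype), 0.9)
})
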