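test_that("ssGSEA matches the brute-force oracle and extreme placements", {
    # top-1 gene set: closed-form single-step sum, maximal over 1-gene sets
    expr <- structure(c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10),
                      names = sprintf("g%02d", 1:10))
    scores <- vapply(names(expr), function(g) ssgseaScore(expr, g),
                     numeric(1))
    n <- 10
    w <- (n:1)^0.25
    closed <- sum(1 - cumsum(c(0, rep(1, n - 1))) / (n - 1))
    expect_equal(unname(scores["g01"]), closed, tolerance = 1e-12)
    expect_equal(unname(which.max(scores)), 1L)

    for (i in 1:20) {
        e <- randomExpr(200, seed = 100 + i)
        genes <- sample(names(e), 20)
        expect_equal(ssgseaScore(e, genes), ssgseaOracle(e, genes),
                     tolerance = 1e-10)
    }
    expect_error(ssgseaScore(expr, c("absent1", "absent2")), "intersect")
    expect_error(ssgseaScore(rep(structure(1, names = "a"), 2) |>
                                 setNames(c("a", "b")), "a"), "equal")
})

test_that("ssGSEA is invariant under strictly monotone expression transforms", {
    for (i in 1:10) {
        e <- randomExpr(150, seed = 200 + i)
        genes <- sample(names(e), 15)
        base <- ssgseaScore(e, genes)
        expect_equal(ssgseaScore(e^3, genes), base, tolerance = 1e-12)
        expect_equal(ssgseaScore(log1p(e), genes), base, tolerance = 1e-12)
        expect_equal(ssgseaScore(rank(e) |> setNames(names(e)), genes),
                     base, tolerance = 1e-12)
    }
})

test_that("ESTIMATE scores are additive and respond to immune content", {
    e <- randomExpr(100, seed = 7)
    m <- cbind(s1 = e, s2 = e)
    m[, 2] <- m[, 2] * 2   # same ranks
    x <- ExpressionMatrix(m, tpmNormalized = FALSE)
    imm <- sample(names(e), 10)
    str <- setdiff(sample(names(e), 25), imm)[1:10]
    es <- estimateScores(x, imm, str)
    expect_equal(es$estimate_score, es$immune_score + es$stromal_score)
    expect_equal(es[1, -1], es[2, -1], ignore_attr = TRUE)
    # immune genes at the top ranks -> immune dominates stromal
    e2 <- sort(e, decreasing = TRUE)
    topImm <- names(e2)[1:10]
    botStr <- names(e2)[91:100]
    es2 <- estimateScores(ExpressionMatrix(cbind(s = e),
                                           tpmNormalized = FALSE),
                          topImm, botStr)
    expect_gt(es2$immune_score, es2$stromal_score)
})

test_that("conversion recalibration solves the anchors exactly and is monotone", {
    cal <- calibrateConversion(-2000, 3000, pHigh = 0.99, pLow = 0.01)
    bExp <- (acos(0.01) - acos(0.99)) / 5000
    expect_equal(cal@b, bExp, tolerance = 1e-14)
    expect_equal(cal@a, acos(0.99) + 2000 * bExp, tolerance = 1e-14)
    expect_equal(estimateToPurity(-2000, cal), 0.99, tolerance = 1e-12)
    expect_equal(estimateToPurity(3000, cal), 0.01, tolerance = 1e-12)
    expect_equal(estimateToPurity(500, cal),
                 cos((acos(0.99) + acos(0.01)) / 2), tolerance = 1e-12)
    grid <- estimateToPurity(seq(-2000, 3000, length.out = 101), cal)
    expect_true(all(diff(grid) < 0))
    # beyond the tumor anchor: clamped into [p_high, 1]
    expect_gte(estimateToPurity(-50000, cal), 0.99)
    expect_lte(estimateToPurity(-50000, cal), 1)
    expect_error(calibrateConversion(c(1, 3), c(3, 1)), "degenerate")
})

test_that("epithelial sum is plain marker arithmetic with strict gating", {
    m <- matrix(400, nrow = 5, ncol = 1,
                dimnames = list(c("EPCAM", "KRT8", "KRT18", "KRT19", "OTH"),
                                "s1"))
    x <- ExpressionMatrix(m, tpmNormalized = FALSE)
    expect_equal(unname(epithelialSum(x)), 1600)
    m2 <- m; m2[1:4, 1] <- 375
    x2 <- ExpressionMatrix(m2, tpmNormalized = FALSE)
    expect_equal(unname(epithelialSum(x2)), 1500)
    gate <- purityGate(data.frame(sample_id = "s1", tumor_fraction = 0.9,
                                  epithelial_sum = 1500,
                                  deconv_immune_score = 10))
    expect_equal(as.character(gate), "low_ctc_reclassifiable")  # 1500 fails > 1500
    m3 <- matrix(1, nrow = 2, ncol = 1, dimnames = list(c("A", "B"), "s1"))
    expect_error(epithelialSum(ExpressionMatrix(m3, FALSE)), "markers")
})

test_that("NNLS deconvolution recovers constructed mixtures", {
    genes <- sprintf("g%02d", 1:30)
    S <- cbind(Tcell = c(rep(50, 10), rep(1, 20)),
               Mono = c(rep(1, 10), rep(60, 10), rep(1, 10)),
               Tumor = c(rep(1, 20), rep(80, 10)))
    rownames(S) <- genes
    sig <- SignatureMatrix(S, immuneTypes = c("Tcell", "Mono"))
    mk <- function(v) ExpressionMatrix(matrix(v, ncol = 1,
                                              dimnames = list(genes, "s")),
                                       tpmNormalized = FALSE)
    expect_equal(unname(deconvolveImmune(mk(S[, "Tcell"]), sig)), 100,
                 tolerance = 1e-9)
    expect_equal(unname(deconvolveImmune(mk(S[, "Tumor"]), sig)), 0,
                 tolerance = 1e-9)
    mix <- 0.3 * S[, "Mono"] + 0.7 * S[, "Tumor"]
    expect_equal(unname(deconvolveImmune(mk(mix), sig)), 30,
                 tolerance = 1e-6)
    Sdef <- cbind(a = S[, 1], b = S[, 1])  # rank-deficient
    expect_error(deconvolveImmune(mk(S[, 1]),
                                  SignatureMatrix(Sdef, immuneTypes = "a")),
                 "rank-deficient")
})

gateFixture <- function() {
    data.frame(
        sample_id = sprintf("f%d", 1:8),
        tumor_fraction =      c(0.50, 0.41, 0.90, 0.45, 0.401, 0.40, 0.50, 0.05),
        epithelial_sum =      c(2000, 1600, 5000, 1501, 1502,  2000, 1500, 5),
        deconv_immune_score = c(50,   70,   10,   74,   74.9,  50,   50,   99))
}

test_that("purity gate tiers the engineered 8-sample fixture as 5/2/1", {
    tiers <- purityGate(gateFixture())
    expect_equal(unname(table(tiers)["high_purity"]), 5L, ignore_attr = TRUE)
    expect_equal(unname(table(tiers)["low_ctc_reclassifiable"]), 2L,
                 ignore_attr = TRUE)
    expect_equal(unname(table(tiers)["low_ctc"]), 1L, ignore_attr = TRUE)
    # boundary cases: 0.40 purity and 1500 TPM fail their strict thresholds
    expect_equal(as.character(tiers[["f6"]]), "low_ctc_reclassifiable")
    expect_equal(as.character(tiers[["f7"]]), "low_ctc_reclassifiable")
    # pure function of rows: permutation permutes tiers identically
    perm <- sample(8)
    tiers2 <- purityGate(gateFixture()[perm, ])
    expect_identical(as.character(tiers2), as.character(tiers)[perm])
    expect_error(purityGate(gateFixture()[, -2]), "tumor_fraction")
    broken <- gateFixture(); broken$epithelial_sum[3] <- NA
    expect_error(purityGate(broken), "f3")
})

test_that("synthetic immune samples score higher on ESTIMATE than tumor samples", {
    cfg <- simulationConfig(nPerPhenotype = 10, seed = 31)
    pure <- simulateCohort(cfg, phenotypes = "LumA", tumorFractions = 1)
    imm <- simulateCohort(cfg, phenotypes = "LumA", tumorFractions = 0)
    isg <- getGeneSet(pure$collection, "IMMUNE_SIG")
    ssg <- getGeneSet(pure$collection, "STROMAL_SIG")
    eT <- estimateScores(pure$expression, isg, ssg)$estimate_score
    eI <- estimateScores(imm$expression, isg, ssg)$estimate_score
    expect_gt(mean(eI), mean(eT))
})
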