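test_that("signature generation is disjoint, deterministic and epithelial-exact", {
    cfg <- simulationConfig(nGenes = 1000, setSize = 50, seed = 3)
    sigs <- makeSignatures(cfg)
    gc <- sigs$collection
    main <- c("AR_LUMINAL", "PROLIFERATION", "NEUROENDOCRINE", "IMMUNE_SIG",
              "STROMAL_SIG", "EPITHELIAL_MARKERS")
    expect_true(all(main %in% geneSetNames(gc)))
    glists <- lapply(main, function(nm) getGeneSet(gc, nm)@genes)
    expect_equal(length(unique(unlist(glists))), length(unlist(glists)))
    universe <- geneIds(simulateCohort(simulationConfig(nPerPhenotype = 1,
                                                        seed = 3))$expression)
    expect_true(all(unlist(glists) %in% universe))
    expect_setequal(getGeneSet(gc, "EPITHELIAL_MARKERS")@genes,
                    c("EPCAM", "KRT8", "KRT18", "KRT19"))
    expect_setequal(unname(geneSetGroups(gc)[c("AR_HELD_OUT", "NE_HELD_OUT")]),
                    "held_out")
    expect_true(all(getGeneSet(gc, "AR_HELD_OUT")@genes %in%
                    getGeneSet(gc, "AR_LUMINAL")@genes))
    expect_gte(length(sigs$signature@immuneTypes), 2)
    # same seed, identical objects
    expect_identical(makeSignatures(cfg), sigs)
    expect_error(makeSignatures(simulationConfig(nGenes = 100, setSize = 50)),
                 "exceed")
})

test_that("cohort simulation honors the mixture construction and TPM contract", {
    cfg0 <- simulationConfig(noiseSdlog = 0, nPerPhenotype = 2, seed = 5)
    sim <- simulateCohort(cfg0)
    v <- tpmValues(sim$expression)
    expect_equal(unname(colSums(v)), rep(1e6, ncol(v)), tolerance = 1e-9)
    # determinism: byte-identical on regeneration
    expect_identical(simulateCohort(cfg0), sim)

    # f = 1, zero noise, LumA: proliferation genes stay at baseline level
    # relative to a pure-LP sample (no proliferation up-regulation)
    lumA <- simulateCohort(cfg0, phenotypes = "LumA", tumorFractions = 1)
    lp <- simulateCohort(cfg0, phenotypes = "LP", tumorFractions = 1)
    prolif <- getGeneSet(sim$collection, "PROLIFERATION")@genes
    ar <- getGeneSet(sim$collection, "AR_LUMINAL")@genes
    a <- tpmValues(lumA$expression)[, 1]
    l <- tpmValues(lp$expression)[, 1]
    # same baseline draw (same seed): after TPM renormalization the AR
    # genes sit exactly 2^log2FC above the unperturbed background ratio,
    # and the proliferation genes exactly at it (no up-regulation)
    bg <- setdiff(names(a), ar)
    ratioBg <- a[bg][1] / l[bg][1]
    expect_equal(unname(a[prolif] / l[prolif]), rep(unname(ratioBg), 50),
                 tolerance = 1e-9)
    expect_equal(unname(a[ar] / l[ar]), rep(8 * unname(ratioBg), 50),
                 tolerance = 1e-9)

    # f = 0: expression equals the immune profile regardless of archetype
    i1 <- simulateCohort(cfg0, phenotypes = "LumA", tumorFractions = 0)
    i2 <- simulateCohort(cfg0, phenotypes = "NE", tumorFractions = 0)
    expect_equal(unname(tpmValues(i1$expression)[, 1]),
                 unname(tpmValues(i2$expression)[, 1]), tolerance = 1e-12)
})

test_that("epithelial-marker sum tracks tumor fraction and separates immune samples", {
    cfg <- simulationConfig(nPerPhenotype = 50, seed = 17)
    fr <- rep(seq(0, 1, length.out = 10), 20)
    sim <- simulateCohort(cfg, tumorFractions = fr)
    es <- epithelialSum(sim$expression)
    expect_gt(cor(es, sim$truth$tumor_fraction, method = "spearman"), 0.9)
    # f = 0 draws fall below the 1,500 TPM gate in >= 95% of 200 draws
    sim0 <- simulateCohort(simulationConfig(nPerPhenotype = 50, seed = 23),
                           tumorFractions = 0)
    es0 <- epithelialSum(sim0$expression)
    expect_length(es0, 200)
    expect_gte(mean(es0 < 1500), 0.95)
})

test_that("longitudinal simulation drifts archetype weights as stated", {
    cfg0 <- simulationConfig(noiseSdlog = 0, seed = 9)
    tp <- c(0, 50, 100, 150)
    sim <- simulateLongitudinal(cfg0, slopes = c(P1 = 0, P2 = 1 / 150),
                                timepoints = tp, startWeight = 0)
    # zero-slope patient: constant expression, hence constant scores
    v <- tpmValues(sim$expression)
    p1 <- v[, sim$truth$patient_id == "P1"]
    expect_equal(p1[, 1], p1[, 4], tolerance = 1e-12)
    # max-slope patient: NE genes rise monotonically, AR genes fall
    ne <- getGeneSet(sim$collection, "NEUROENDOCRINE")@genes
    ar <- getGeneSet(sim$collection, "AR_LUMINAL")@genes
    p2 <- v[, sim$truth$patient_id == "P2"]
    neSum <- colSums(p2[ne, ])
    arSum <- colSums(p2[ar, ])
    expect_true(all(diff(neSum) > 0))
    expect_true(all(diff(arSum) < 0))
    expect_error(simulateLongitudinal(cfg0, slopes = c(P1 = 0),
                                      timepoints = 0), "P1")
})

test_that("simulated cells honor the positivity ground truth at the extremes", {
    sc0 <- simulateCells(nCtc = 200, nWbc = 400, posFrac = 0, seed = 11)
    cells <- gateCtcs(quantileNormalizeMfi(sc0$cells))
    nullThr <- fitPositivity(cells[!cells$is_ctc, ])
    calls <- callPositive(cells[cells$is_ctc, ], nullThr)
    expect_lt(mean(calls$positive), 0.12)  # chance-level false positives only

    sc1 <- simulateCells(nCtc = 200, nWbc = 400, posFrac = 1, seed = 12)
    cells1 <- gateCtcs(quantileNormalizeMfi(sc1$cells))
    thr1 <- fitPositivity(cells1[!cells1$is_ctc, ])
    calls1 <- callPositive(cells1[cells1$is_ctc, ], thr1)
    expect_equal(mean(calls1$positive), 1)
    # determinism
    expect_identical(simulateCells(seed = 11, posFrac = 0.4),
                     simulateCells(seed = 11, posFrac = 0.4))
})

test_that("survival simulation delivers the requested censoring regime", {
    ph <- rep(c("A", "B"), each = 100)
    haz <- c(A = 0.05, B = 0.45)
    cl0 <- simulateSurvival(ph, haz, censorRate = 0, seed = 2)
    expect_true(all(cl0$os_event == 1))
    cl <- simulateSurvival(ph, haz, censorRate = 0.3, seed = 2)
    expect_gt(mean(cl$os_event == 0), 0.15)
    expect_lt(mean(cl$os_event == 0), 0.45)
    expect_error(simulateSurvival(ph, c(A = 0.05), censorRate = 0),
                 "no hazard")
})
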