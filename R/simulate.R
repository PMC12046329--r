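#' @importFrom stats rlnorm rnorm rexp runif uniroot
NULL

#' Simulation configuration for the synthetic CTC study
#'
#' Defines the generative conditions the pipeline is exercised under: a
#' log-normal baseline transcriptome, four tumor lineage archetypes
#' (AR-high/proliferation-low LumA, AR-high/proliferation-high LumB,
#' triple-low LP, NE-high/proliferation-high NE) mixed with an immune
#' (PBMC-like) background at a controlled tumor fraction, with
#' multiplicative log-normal noise applied before TPM renormalization.
#'
#' @param nGenes transcriptome size (default 1000).
#' @param setSize genes per axis signature (default 50).
#' @param log2FC axis up-regulation of signature genes, log2 fold-change
#'   (default 3, i.e. 8-fold).
#' @param epithelialLog2FC epithelial-marker up-regulation in tumor
#'   archetypes (default 5, i.e. 32-fold): keratins and EpCAM are among the
#'   most abundant transcripts of epithelial tumor cells, well above
#'   lineage-signature effect sizes.
#' @param baselineMeanlog,baselineSdlog natural-log parameters of the
#'   log-normal baseline expression (defaults 1 and 1).
#' @param noiseSdlog multiplicative log-normal noise sigma (default 0.25).
#' @param tumorFraction default tumor fraction of cohort samples
#'   (default 0.8).
#' @param nPerPhenotype samples per archetype (default 25).
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @return validated list of class \code{simConfig}.
#' @export
simulationConfig <- function(nGenes = 1000, setSize = 50, log2FC = 3,
                             epithelialLog2FC = 5,
                             baselineMeanlog = 1, baselineSdlog = 1,
                             noiseSdlog = 0.25, tumorFraction = 0.8,
                             nPerPhenotype = 25, seed = 1) {
    stopifnot(nGenes >= 1, setSize >= 1, nPerPhenotype >= 1,
              noiseSdlog >= 0, baselineSdlog >= 0)
    if (any(tumorFraction < 0 | tumorFraction > 1))
        stop("tumorFraction must lie in [0, 1]")
    if (5 * setSize + 4 > nGenes)
        stop("requested signature sizes exceed nGenes")
    structure(list(nGenes = nGenes, setSize = setSize, log2FC = log2FC,
                   epithelialLog2FC = epithelialLog2FC,
                   baselineMeanlog = baselineMeanlog,
                   baselineSdlog = baselineSdlog, noiseSdlog = noiseSdlog,
                   tumorFraction = tumorFraction,
                   nPerPhenotype = nPerPhenotype, seed = seed),
              class = "simConfig")
}

.EPITHELIAL_MARKERS <- c("EPCAM", "KRT8", "KRT18", "KRT19")

.geneUniverse <- function(config) {
    c(.EPITHELIAL_MARKERS,
      sprintf("G%05d", seq_len(config$nGenes - length(.EPITHELIAL_MARKERS))))
}

.signatureBlocks <- function(config) {
    universe <- .geneUniverse(config)
    pool <- setdiff(universe, .EPITHELIAL_MARKERS)
    s <- config$setSize
    list(universe = universe,
         ar = pool[seq_len(s)],
         prolif = pool[s + seq_len(s)],
         ne = pool[2 * s + seq_len(s)],
         immune = pool[3 * s + seq_len(s)],
         stromal = pool[4 * s + seq_len(s)],
         epithelial = .EPITHELIAL_MARKERS)
}

#' Generate the gene-set collection and signature matrix of the study
#'
#' Emits disjoint axis signatures (AR/luminal, proliferation,
#' neuroendocrine), the immune and stromal purity-scoring sets, the
#' epithelial marker set (exactly EPCAM, KRT8, KRT18, KRT19), held-out AR
#' and NE sets overlapping the main axes (excluded from clustering, used
#' for independent assessment), and a PBMC-style signature matrix with two
#' immune cell types and one tumor-like type. Deterministic given the
#' configuration.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{collection} ([GeneSetCollection-class]) and
#'   \code{signature} ([SignatureMatrix-class]).
#' @export
makeSignatures <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    b <- .signatureBlocks(config)
    odd <- function(x) x[seq_along(x) %% 2L == 1L]
    collection <- GeneSetCollection(list(
        GeneSet("AR_LUMINAL", b$ar, "ar_luminal"),
        GeneSet("PROLIFERATION", b$prolif, "proliferation"),
        GeneSet("NEUROENDOCRINE", b$ne, "neuroendocrine"),
        GeneSet("IMMUNE_SIG", b$immune, "other"),
        GeneSet("STROMAL_SIG", b$stromal, "other"),
        GeneSet("EPITHELIAL_MARKERS", b$epithelial, "other"),
        GeneSet("AR_HELD_OUT", odd(b$ar), "held_out"),
        GeneSet("NE_HELD_OUT", odd(b$ne), "held_out")))
    # tumor-like reference is an epithelial profile: the component every
    # tumor archetype shares, keeping the deconvolution lineage-agnostic
    sigGenes <- c(b$immune, b$epithelial)
    half <- seq_len(length(b$immune) %/% 2)
    S <- matrix(1, nrow = length(sigGenes), ncol = 3,
                dimnames = list(sigGenes, c("Tcell", "Monocyte", "Tumor")))
    S[b$immune[half], "Tcell"] <- 100
    S[setdiff(b$immune, b$immune[half]), "Monocyte"] <- 100
    S[b$epithelial, "Tumor"] <- 100
    list(collection = collection,
         signature = SignatureMatrix(S, immuneTypes = c("Tcell", "Monocyte")))
}

# Archetype expression profiles (TPM-normalized columns), deterministic
# given the baseline vector. Tumor archetypes carry high epithelial-marker
# expression; the immune (PBMC) profile is keratin/EpCAM-negative, so the
# epithelial TPM sum tracks tumor fraction.
.archetypeProfiles <- function(config, baseline) {
    b <- .signatureBlocks(config)
    fold <- 2^config$log2FC
    up <- function(genes, f, x = baseline) { x[genes] <- x[genes] * f; x }
    tumorBase <- up(b$epithelial, 2^config$epithelialLog2FC)
    profiles <- list(
        LP   = tumorBase,
        LumA = up(b$ar, fold, tumorBase),
        LumB = up(b$prolif, fold, up(b$ar, fold, tumorBase)),
        NE   = up(b$prolif, fold, up(b$ne, fold, tumorBase)),
        immune = up(b$epithelial, 2^-6,
                    up(b$stromal, 2, up(b$immune, fold))))
    lapply(profiles, function(p) p / sum(p) * 1e6)
}

.mixSample <- function(f, tumorTpm, immuneTpm, noiseSdlog) {
    x <- f * tumorTpm + (1 - f) * immuneTpm
    if (noiseSdlog > 0)
        x <- x * exp(rnorm(length(x), 0, noiseSdlog))
    x / sum(x) * 1e6
}

#' Simulate a cross-sectional CTC cohort with known ground truth
#'
#' Each sample is a TPM-normalized convex mixture
#' \code{f * archetype + (1 - f) * immune_profile} with multiplicative
#' log-normal noise applied before renormalization.
#'
#' @param config a [simulationConfig()].
#' @param phenotypes archetypes simulated (default all four).
#' @param tumorFractions optional explicit per-sample tumor fractions
#'   (recycled across the phenotype grid); defaults to
#'   \code{config$tumorFraction}.
#' @return list with \code{expression} ([ExpressionMatrix-class]),
#'   \code{truth} (data.frame sample_id, patient_id, phenotype,
#'   tumor_fraction), \code{collection}, \code{signature}.
#' @export
simulateCohort <- function(config, phenotypes = c("LP", "LumA", "LumB", "NE"),
                           tumorFractions = NULL) {
    stopifnot(inherits(config, "simConfig"))
    sigs <- makeSignatures(config)
    nSamp <- length(phenotypes) * config$nPerPhenotype
    f <- if (is.null(tumorFractions)) rep(config$tumorFraction,
                                          length.out = nSamp)
         else rep(tumorFractions, length.out = nSamp)
    set.seed(config$seed)
    baseline <- rlnorm(config$nGenes, config$baselineMeanlog,
                       config$baselineSdlog)
    names(baseline) <- .geneUniverse(config)
    prof <- .archetypeProfiles(config, baseline)
    phen <- rep(phenotypes, each = config$nPerPhenotype)
    ids <- sprintf("S%03d", seq_len(nSamp))
    m <- vapply(seq_len(nSamp), function(i)
        .mixSample(f[i], prof[[phen[i]]], prof$immune, config$noiseSdlog),
        numeric(config$nGenes))
    dimnames(m) <- list(names(baseline), ids)
    list(expression = ExpressionMatrix(m, tpmNormalized = TRUE),
         truth = data.frame(sample_id = ids,
                            patient_id = sprintf("P%03d", seq_len(nSamp)),
                            phenotype = phen, tumor_fraction = f,
                            stringsAsFactors = FALSE),
         collection = sigs$collection, signature = sigs$signature)
}

#' Simulate longitudinal CTC collections with AR-to-NE drift
#'
#' Per patient, the tumor component interpolates linearly in time between
#' the AR-dominant (LumA) and NE-dominant archetypes: the NE weight is
#' \code{clamp(startWeight + slope * day, 0, 1)}. Positive slopes emulate a
#' lineage transition (AR score falling, NE score rising); negative slopes
#' an AR-ward drift.
#'
#' @param config a [simulationConfig()].
#' @param slopes named numeric, NE-weight change per day per patient.
#' @param timepoints numeric vector of collection days shared by all
#'   patients, or a named list per patient (>= 2 each).
#' @param startWeight NE weight at day 0 (default 0.5).
#' @return list with \code{expression}, \code{truth} (per-sample rows:
#'   sample_id, patient_id, time, ne_weight, slope, transition),
#'   \code{collection}, \code{signature}.
#' @export
simulateLongitudinal <- function(config, slopes, timepoints,
                                 startWeight = 0.5) {
    stopifnot(inherits(config, "simConfig"))
    if (is.null(names(slopes))) stop("slopes must be named by patient")
    tp <- if (is.list(timepoints)) timepoints
          else setNames(rep(list(timepoints), length(slopes)), names(slopes))
    nPts <- vapply(tp[names(slopes)], length, integer(1))
    if (any(nPts < 2L))
        stop("patient(s) with < 2 timepoints: ",
             paste(names(slopes)[nPts < 2L], collapse = ", "))
    sigs <- makeSignatures(config)
    set.seed(config$seed)
    baseline <- rlnorm(config$nGenes, config$baselineMeanlog,
                       config$baselineSdlog)
    names(baseline) <- .geneUniverse(config)
    prof <- .archetypeProfiles(config, baseline)
    rows <- list()
    cols <- list()
    for (p in names(slopes)) {
        tt <- sort(tp[[p]])
        for (j in seq_along(tt)) {
            w <- min(max(startWeight + slopes[[p]] * tt[j], 0), 1)
            tumor <- (1 - w) * prof$LumA + w * prof$NE
            sid <- sprintf("%s_T%02d", p, j)
            cols[[sid]] <- .mixSample(config$tumorFraction, tumor,
                                      prof$immune, config$noiseSdlog)
            rows[[sid]] <- data.frame(sample_id = sid, patient_id = p,
                                      time = tt[j], ne_weight = w,
                                      slope = unname(slopes[[p]]),
                                      transition = unname(slopes[[p]] > 0),
                                      stringsAsFactors = FALSE)
        }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- names(baseline)
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(expression = ExpressionMatrix(m, tpmNormalized = TRUE),
         truth = truth, collection = sigs$collection,
         signature = sigs$signature)
}

#' Default single-cell immunofluorescence channel parameters
#'
#' log10-scale means and standard deviations of the four channels for CTCs
#' and white blood cells, plus the positive-marker shift (2 logs).
#' @return nested list.
#' @export
defaultChannelParams <- function() {
    list(sd = 0.2, target_sd = 0.3, shift = 2.0,
         ctc = c(nucleus = 3.0, pan_ck = 3.5, exclusion = 1.0, target = 1.5),
         wbc = c(nucleus = 3.0, pan_ck = 1.5, exclusion = 3.0, target = 1.5))
}

#' Simulate a single-cell immunofluorescence table
#'
#' CTCs are pan-cytokeratin-high / exclusion-low, WBCs the reverse; a
#' fraction \code{posFrac} of CTCs draw their target-channel MFI from a
#' distribution shifted up by \code{channelParams$shift} logs. Optional
#' per-sample gains emulate staining/imaging batch effects that 50%
#' quantile normalization should remove.
#'
#' @param nCtc,nWbc cell counts.
#' @param posFrac true marker-positive fraction among CTCs.
#' @param nSamples number of samples cells are spread over (round-robin).
#' @param channelParams see [defaultChannelParams()].
#' @param sampleGains optional numeric vector (length \code{nSamples}) of
#'   multiplicative per-sample gains applied to every channel.
#' @param seed RNG seed.
#' @return list with \code{cells} (data.frame cell_id, sample_id, nucleus,
#'   pan_ck, exclusion, target) and \code{truth} (cell_id, is_ctc,
#'   is_positive).
#' @export
simulateCells <- function(nCtc = 500, nWbc = 500, posFrac = 0.3,
                          nSamples = 5, channelParams = defaultChannelParams(),
                          sampleGains = NULL, seed = 1) {
    stopifnot(posFrac >= 0, posFrac <= 1, nCtc >= 0, nWbc >= 1)
    set.seed(seed)
    n <- nCtc + nWbc
    isCtc <- rep(c(TRUE, FALSE), c(nCtc, nWbc))
    nPos <- round(posFrac * nCtc)
    isPos <- isCtc & seq_len(n) <= nPos
    cp <- channelParams
    draw <- function(mu, sd) 10^rnorm(n, mu, sd)
    mu <- function(ch) ifelse(isCtc, cp$ctc[[ch]], cp$wbc[[ch]])
    cells <- data.frame(
        cell_id = sprintf("C%05d", seq_len(n)),
        sample_id = sprintf("SMP%02d", (seq_len(n) - 1L) %% nSamples + 1L),
        nucleus = draw(mu("nucleus"), cp$sd),
        pan_ck = draw(mu("pan_ck"), cp$sd),
        exclusion = draw(mu("exclusion"), cp$sd),
        target = draw(mu("target") + ifelse(isPos, cp$shift, 0),
                      cp$target_sd),
        stringsAsFactors = FALSE)
    if (!is.null(sampleGains)) {
        stopifnot(length(sampleGains) == nSamples, all(sampleGains > 0))
        g <- sampleGains[as.integer(factor(cells$sample_id))]
        for (ch in .CHANNELS) cells[[ch]] <- cells[[ch]] * g
    }
    # shuffle rows so class is not confounded with row order
    ord <- sample.int(n)
    list(cells = cells[ord, , drop = FALSE],
         truth = data.frame(cell_id = cells$cell_id[ord],
                            is_ctc = isCtc[ord], is_positive = isPos[ord],
                            stringsAsFactors = FALSE))
}

#' Simulate phenotype-dependent survival with uniform censoring
#'
#' Event times are exponential with a per-phenotype hazard (per month);
#' censoring times are independent Uniform(0, u), with u solved so the
#' expected censoring proportion equals \code{censorRate}.
#'
#' @param phenotypes factor/character of group labels, one per subject.
#' @param hazards named numeric, per-month hazard per phenotype.
#' @param censorRate target censoring proportion (default 0.2; 0 = all
#'   events observed).
#' @param seed RNG seed.
#' @return clinical data.frame: patient_id, sample_id, collection_time,
#'   disease_state, os_time (months), os_event.
#' @export
simulateSurvival <- function(phenotypes, hazards, censorRate = 0.2,
                             seed = 1) {
    phenotypes <- as.character(phenotypes)
    miss <- setdiff(unique(phenotypes), names(hazards))
    if (length(miss))
        stop("no hazard for phenotype(s): ", paste(miss, collapse = ", "))
    stopifnot(censorRate >= 0, censorRate < 1, all(hazards > 0))
    set.seed(seed)
    n <- length(phenotypes)
    lam <- unname(hazards[phenotypes])
    tEvent <- rexp(n, rate = lam)
    if (censorRate == 0) {
        time <- tEvent; event <- rep(1L, n)
    } else {
        censFrac <- function(u) mean((1 - exp(-lam * u)) / (lam * u))
        u <- uniroot(function(u) censFrac(u) - censorRate,
                     lower = 1e-8, upper = 1e8, tol = 1e-10)$root
        cens <- runif(n, 0, u)
        time <- pmin(tEvent, cens)
        event <- as.integer(tEvent <= cens)
    }
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               sample_id = sprintf("S%03d", seq_len(n)),
               collection_time = 0, disease_state = "mCRPC",
               os_time = time, os_event = event, stringsAsFactors = FALSE)
}
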