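#' @importFrom stats cor quantile
NULL

# Descending expression order with deterministic lexicographic tie-break on
# gene identifier; the package-wide rank convention for all rank scoring.
.rankOrder <- function(expr) {
    order(-expr, names(expr), method = "radix")
}

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' The weighted rank statistic used by the ESTIMATE immune/stromal scores.
#' Genes are ordered by decreasing expression (ties broken by gene
#' identifier); walking down the ranking, the in-set cumulative mass is
#' weighted by \code{rank^alpha} (rank counted from the bottom, so the top
#' gene carries weight \code{n^alpha}) and normalized by total in-set mass,
#' the out-of-set cumulative mass is uniform, and the score is the sum over
#' positions of their difference. Depends on ranks only, hence invariant
#' under strictly monotone transforms of expression.
#'
#' @param expr named numeric vector, one sample's expression (>= 2 genes,
#'   not all equal).
#' @param geneSet a [GeneSet-class] or character vector of gene ids.
#' @param alpha weight exponent (default 0.25, the published value).
#' @return a single unitless enrichment score.
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25) {
    genes <- if (is(geneSet, "GeneSet")) geneSet@genes else
        as.character(geneSet)
    setName <- if (is(geneSet, "GeneSet")) geneSet@name else "<gene set>"
    if (length(expr) < 2L) stop("need >= 2 genes to rank")
    if (is.null(names(expr))) stop("expression vector must be named by gene")
    n <- length(expr)
    inset <- names(expr) %in% genes
    m <- sum(inset)
    if (m == 0L)
        stop("gene set '", setName, "' does not intersect the matrix")
    if (m == n)
        stop("gene set '", setName, "' covers every gene; no background")
    if (length(unique(expr)) == 1L)
        stop("all expression values equal; ranks undefined")
    ord <- .rankOrder(expr)
    insetOrd <- inset[ord]
    w <- (n - seq_len(n) + 1)^alpha          # bottom-up rank value, weighted
    wIn <- ifelse(insetOrd, w, 0)
    pIn <- cumsum(wIn) / sum(wIn)
    pOut <- cumsum(!insetOrd) / (n - m)
    sum(pIn - pOut)
}

#' Immune, stromal and combined ESTIMATE scores per sample
#'
#' @param x an [ExpressionMatrix-class].
#' @param immuneSet,stromalSet [GeneSet-class] objects (or gene-id vectors).
#' @param alpha ssGSEA weight exponent (default 0.25).
#' @return a data.frame with columns \code{sample_id}, \code{immune_score},
#'   \code{stromal_score}, \code{estimate_score} (= immune + stromal,
#'   exactly).
#' @export
estimateScores <- function(x, immuneSet, stromalSet, alpha = 0.25) {
    v <- tpmValues(x)
    imm <- apply(v, 2, ssgseaScore, geneSet = immuneSet, alpha = alpha)
    str <- apply(v, 2, ssgseaScore, geneSet = stromalSet, alpha = alpha)
    data.frame(sample_id = colnames(v), immune_score = unname(imm),
               stromal_score = unname(str),
               estimate_score = unname(imm + str),
               stringsAsFactors = FALSE)
}

#' Recalibrate the ESTIMATE-score-to-purity conversion on control samples
#'
#' The conversion has the cosine form \code{purity = cos(a + b * E)}. Given
#' ESTIMATE scores of a pure-tumor control group (e.g. prostate cancer cell
#' line) and a pure-immune control group (e.g. PBMC), \code{a} and \code{b}
#' are re-solved exactly from the two anchor equations
#' \code{cos(a + b * mean(E_tumor)) = pHigh} and
#' \code{cos(a + b * mean(E_immune)) = pLow}, using principal arccos values,
#' so \code{a + b * E = arccos(p)} is linear in \code{E}.
#'
#' @param tumorControlScores numeric, ESTIMATE scores of pure-tumor controls.
#' @param immuneControlScores numeric, ESTIMATE scores of pure-immune
#'   controls.
#' @param pHigh purity at the tumor anchor (default 0.99; 1 would collapse
#'   the slope since arccos(1) = 0 pins the intercept).
#' @param pLow purity at the immune anchor (default 0.01).
#' @return a [CalibrationParams-class].
#' @export
calibrateConversion <- function(tumorControlScores, immuneControlScores,
                                pHigh = 0.99, pLow = 0.01) {
    if (length(tumorControlScores) == 0L || length(immuneControlScores) == 0L)
        stop("both control groups must be non-empty")
    eT <- mean(tumorControlScores)
    eI <- mean(immuneControlScores)
    if (eT == eI) stop("degenerate anchors: control group means are equal")
    b <- (acos(pLow) - acos(pHigh)) / (eI - eT)
    a <- acos(pHigh) - b * eT
    new("CalibrationParams", a = a, b = b, pHigh = pHigh, pLow = pLow,
        anchors = c(eT, eI))
}

#' Convert ESTIMATE scores to inferred tumor fraction
#'
#' Evaluates \code{cos(a + b * E)} with the angle clamped to the principal
#' branch \code{[0, pi]} and the purity clamped to \code{[0, 1]}; strictly
#' decreasing in \code{E} between the anchors.
#'
#' @param estimateScore numeric vector of combined ESTIMATE scores.
#' @param params a [CalibrationParams-class].
#' @return tumor fractions in [0, 1].
#' @export
estimateToPurity <- function(estimateScore, params) {
    stopifnot(is(params, "CalibrationParams"))
    theta <- pmin(pmax(params@a + params@b * estimateScore, 0), pi)
    pmin(pmax(cos(theta), 0), 1)
}

#' Per-sample epithelial-marker expression sum
#'
#' Sum of the four epithelial markers (EpCAM and keratins 8/18/19) in TPM;
#' the secondary epithelial/tumor-content filter of the purity gate.
#'
#' @param x an [ExpressionMatrix-class].
#' @param markers marker identifiers (default EPCAM, KRT8, KRT18, KRT19).
#' @return named numeric, TPM sum per sample.
#' @export
epithelialSum <- function(x, markers = c("EPCAM", "KRT8", "KRT18", "KRT19")) {
    v <- tpmValues(x)
    present <- intersect(markers, rownames(v))
    if (length(present) == 0L)
        stop("none of the epithelial markers (",
             paste(markers, collapse = ", "), ") are in the matrix")
    if (length(present) < length(markers))
        message(length(present), "/", length(markers),
                " epithelial markers present; absent markers contribute 0")
    colSums(v[present, , drop = FALSE])
}

#' Absolute immune score by non-negative least-squares deconvolution
#'
#' Orthogonal immune-content check: each sample's expression over the
#' signature genes is regressed (NNLS) on the cell-type reference columns;
#' the score is 100 times the immune share of the fitted coefficients.
#'
#' @param x an [ExpressionMatrix-class].
#' @param signature a [SignatureMatrix-class].
#' @return named numeric in [0, 100], one score per sample (0 when all
#'   coefficients vanish).
#' @export
deconvolveImmune <- function(x, signature) {
    stopifnot(is(signature, "SignatureMatrix"))
    v <- tpmValues(x)
    S <- signature@values
    shared <- intersect(rownames(S), rownames(v))
    if (length(shared) < ncol(S))
        stop("signature shares only ", length(shared),
             " gene(s) with the matrix; need >= ", ncol(S))
    S <- S[shared, , drop = FALSE]
    if (qr(S)$rank < ncol(S))
        stop("signature matrix is rank-deficient on the shared genes")
    isImm <- colnames(S) %in% signature@immuneTypes
    scores <- apply(v[shared, , drop = FALSE], 2, function(y) {
        coef <- pracma::lsqnonneg(S, y)$x
        tot <- sum(coef)
        if (tot > 0) 100 * sum(coef[isImm]) / tot else 0
    })
    scores
}

#' Apply the multi-criterion purity gate
#'
#' A sample is \code{high_purity} iff tumor fraction > minPurity AND
#' epithelial TPM sum > minEpithelialTpm AND deconvolution immune score <
#' maxImmuneScore (all strict); otherwise \code{low_ctc_reclassifiable} iff
#' its epithelial sum > minEpithelialTpmReclass; otherwise \code{low_ctc}.
#'
#' @param summary data.frame with columns \code{sample_id},
#'   \code{tumor_fraction}, \code{epithelial_sum}, \code{deconv_immune_score}.
#' @param thresholds a [GateThresholds-class].
#' @return factor of gate tiers, named by sample, levels
#'   \code{high_purity}, \code{low_ctc_reclassifiable}, \code{low_ctc}.
#' @export
purityGate <- function(summary, thresholds = GateThresholds()) {
    stopifnot(is(thresholds, "GateThresholds"))
    need <- c("sample_id", "tumor_fraction", "epithelial_sum",
              "deconv_immune_score")
    miss <- setdiff(need, names(summary))
    if (length(miss))
        stop("purity summary missing field(s): ", paste(miss, collapse = ", "))
    for (f in need[-1L]) {
        if (any(is.na(summary[[f]])))
            stop("missing ", f, " for sample(s): ",
                 paste(summary$sample_id[is.na(summary[[f]])], collapse = ", "))
    }
    high <- summary$tumor_fraction > thresholds@minPurity &
        summary$epithelial_sum > thresholds@minEpithelialTpm &
        summary$deconv_immune_score < thresholds@maxImmuneScore
    reclass <- !high & summary$epithelial_sum > thresholds@minEpithelialTpmReclass
    tier <- ifelse(high, "high_purity",
                   ifelse(reclass, "low_ctc_reclassifiable", "low_ctc"))
    out <- factor(tier,
                  levels = c("high_purity", "low_ctc_reclassifiable",
                             "low_ctc"))
    names(out) <- summary$sample_id
    out
}

#' Full per-sample purity summary
#'
#' Runs ESTIMATE scoring, the recalibrated purity conversion, the epithelial
#' sum, NNLS immune deconvolution and the gate, returning one row per sample.
#'
#' @param x an [ExpressionMatrix-class].
#' @param immuneSet,stromalSet purity-scoring [GeneSet-class] objects.
#' @param signature a [SignatureMatrix-class].
#' @param calibration a [CalibrationParams-class] from
#'   [calibrateConversion()].
#' @param thresholds a [GateThresholds-class].
#' @param alpha ssGSEA weight exponent.
#' @param markers epithelial marker ids.
#' @return an [S4Vectors::DataFrame] with columns sample_id, immune_score,
#'   stromal_score, estimate_score, tumor_fraction, epithelial_sum,
#'   deconv_immune_score, gate_tier.
#' @export
puritySummary <- function(x, immuneSet, stromalSet, signature, calibration,
                          thresholds = GateThresholds(), alpha = 0.25,
                          markers = c("EPCAM", "KRT8", "KRT18", "KRT19")) {
    es <- estimateScores(x, immuneSet, stromalSet, alpha = alpha)
    es$tumor_fraction <- estimateToPurity(es$estimate_score, calibration)
    es$epithelial_sum <- unname(epithelialSum(x, markers))
    es$deconv_immune_score <- unname(deconvolveImmune(x, signature))
    es$gate_tier <- unname(purityGate(es, thresholds))
    DataFrame(es)
}
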