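#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.GENE_SET_GROUPS <- c("ar_luminal", "proliferation", "neuroendocrine",
                      "hallmark", "held_out", "other")

.PHENOTYPE_LEVELS <- c("Low_CTC", "LP", "LumA", "LumB", "NE")

#' ExpressionMatrix: a TPM gene-by-sample expression container
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single non-negative assay \code{"tpm"} (genes in rows, samples in columns).
#' A matrix flagged TPM-normalized has every sample column summing to 1e6
#' within relative tolerance 1e-6; the flag lives in
#' \code{metadata(x)$tpm_normalized}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [ExpressionMatrix()], [readExpression()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

.validExpressionMatrix <- function(object) {
    msg <- NULL
    if (!"tpm" %in% names(assays(object)))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        v <- assay(object, "tpm")
        if (is.null(rownames(v)) || is.null(colnames(v)))
            msg <- c(msg, "gene (row) and sample (column) names are required")
        else {
            if (anyDuplicated(rownames(v)))
                msg <- c(msg, sprintf("duplicate gene identifier(s): %s",
                    paste(unique(rownames(v)[duplicated(rownames(v))]),
                          collapse = ", ")))
            if (anyDuplicated(colnames(v)))
                msg <- c(msg, sprintf("duplicate sample identifier(s): %s",
                    paste(unique(colnames(v)[duplicated(colnames(v))]),
                          collapse = ", ")))
        }
        if (any(!is.finite(v)))
            msg <- c(msg, "non-finite expression values")
        else if (any(v < 0))
            msg <- c(msg, "negative expression values")
        else if (isTRUE(metadata(object)$tpm_normalized) && ncol(v) > 0) {
            cs <- colSums(v)
            if (any(abs(cs - 1e6) > 1e-6 * 1e6))
                msg <- c(msg,
                    "matrix flagged TPM-normalized but columns do not sum to 1e6")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with unique dimnames.
#' @param tpmNormalized logical; assert (and validate) that each column sums
#'   to 1e6. Use [tpmNormalize()] to rescale arbitrary non-negative values.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(6e5, 4e5, 5e5, 5e5), nrow = 2,
#'             dimnames = list(c("KLK3", "SYP"), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, tpmNormalized = TRUE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(tpm = values))
    metadata(se)$tpm_normalized <- isTRUE(tpmNormalized)
    new("ExpressionMatrix", se)
}

#' GeneSet: a named set of gene identifiers with a group tag
#'
#' @slot name single character, the set name.
#' @slot genes character vector of unique gene identifiers.
#' @slot group one of \code{ar_luminal}, \code{proliferation},
#'   \code{neuroendocrine}, \code{hallmark}, \code{held_out}, \code{other}.
#' @export
setClass("GeneSet", representation(name = "character", genes = "character",
                                   group = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "genes must be unique within a set")
    if (length(object@group) != 1L || !object@group %in% .GENE_SET_GROUPS)
        msg <- c(msg, sprintf("group must be one of: %s",
                              paste(.GENE_SET_GROUPS, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSet-class
#' @param name,genes,group see slots.
#' @export
GeneSet <- function(name, genes, group = "other") {
    new("GeneSet", name = name, genes = unique(as.character(genes)),
        group = group)
}

#' GeneSetCollection: an ordered list of uniquely named GeneSets
#'
#' @slot sets list of [GeneSet-class] objects with unique names.
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- NULL
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        msg <- c(msg, "all elements must be GeneSet objects")
    else {
        nm <- vapply(object@sets, function(s) s@name, character(1))
        if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate gene-set name(s): %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSetCollection-class
#' @param sets list of [GeneSet-class] objects.
#' @export
GeneSetCollection <- function(sets = list()) {
    new("GeneSetCollection", sets = sets)
}

#' SignatureMatrix: cell-type reference profiles for deconvolution
#'
#' Stores non-negative reference expression, genes in rows and cell types in
#' columns, plus which cell types count as immune for the absolute immune
#' score.
#'
#' @slot values non-negative numeric matrix, genes x cell types.
#' @slot immuneTypes character, subset of colnames flagged immune.
#' @export
setClass("SignatureMatrix",
         representation(values = "matrix", immuneTypes = "character"))

setValidity("SignatureMatrix", function(object) {
    msg <- NULL
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "gene and cell-type names are required")
    else if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate cell types")
    if (any(v < 0)) msg <- c(msg, "reference expression must be non-negative")
    if (length(object@immuneTypes) == 0L)
        msg <- c(msg, "at least one immune cell type is required")
    else if (!all(object@immuneTypes %in% colnames(v)))
        msg <- c(msg, "immuneTypes must be cell types of the matrix")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SignatureMatrix-class
#' @param values,immuneTypes see slots.
#' @export
SignatureMatrix <- function(values, immuneTypes) {
    new("SignatureMatrix", values = as.matrix(values),
        immuneTypes = as.character(immuneTypes))
}

#' CalibrationParams: cosine conversion from ESTIMATE score to tumor purity
#'
#' Purity is \code{cos(a + b * E)} where \code{E} is the combined ESTIMATE
#' score; \code{a} and \code{b} solve the two control-anchor equations
#' exactly (see [calibrateConversion()]).
#'
#' @slot a intercept, radians.
#' @slot b slope, radians per score unit.
#' @slot pHigh purity assigned to the pure-tumor anchor.
#' @slot pLow purity assigned to the pure-immune anchor.
#' @slot anchors numeric length 2: mean ESTIMATE scores of the tumor and
#'   immune control groups, in that order.
#' @export
setClass("CalibrationParams",
         representation(a = "numeric", b = "numeric", pHigh = "numeric",
                        pLow = "numeric", anchors = "numeric"))

setValidity("CalibrationParams", function(object) {
    msg <- NULL
    if (length(object@anchors) != 2L || object@anchors[1] == object@anchors[2])
        msg <- c(msg, "anchors must be two distinct control means")
    if (!(object@pLow > 0 && object@pLow < object@pHigh && object@pHigh < 1))
        msg <- c(msg, "need 0 < pLow < pHigh < 1")
    ok <- isTRUE(all.equal(cos(object@a + object@b * object@anchors[1]),
                           object@pHigh, tolerance = 1e-9)) &&
          isTRUE(all.equal(cos(object@a + object@b * object@anchors[2]),
                           object@pLow, tolerance = 1e-9))
    if (length(msg) == 0L && !ok)
        msg <- c(msg, "(a, b) do not solve the anchor equations")
    if (is.null(msg)) TRUE else msg
})

#' GateThresholds: the multi-criterion tumor-purity gate
#'
#' All inequalities are strict: a sample is high purity iff inferred tumor
#' fraction > \code{minPurity}, epithelial-marker TPM sum >
#' \code{minEpithelialTpm}, and deconvolution immune score <
#' \code{maxImmuneScore}. Failing samples with epithelial sum >
#' \code{minEpithelialTpmReclass} remain eligible for kNN reclassification.
#'
#' @slot minPurity tumor-fraction threshold (default 0.40).
#' @slot minEpithelialTpm epithelial TPM-sum threshold (default 1500).
#' @slot maxImmuneScore deconvolution immune-score ceiling (default 75).
#' @slot minEpithelialTpmReclass reclassification floor (default 10).
#' @export
setClass("GateThresholds",
         representation(minPurity = "numeric", minEpithelialTpm = "numeric",
                        maxImmuneScore = "numeric",
                        minEpithelialTpmReclass = "numeric"))

setValidity("GateThresholds", function(object) {
    msg <- NULL
    vals <- c(object@minPurity, object@minEpithelialTpm,
              object@maxImmuneScore, object@minEpithelialTpmReclass)
    if (any(vals <= 0)) msg <- c(msg, "all thresholds must be positive")
    if (object@minEpithelialTpmReclass >= object@minEpithelialTpm)
        msg <- c(msg, "reclassification floor must be below the epithelial gate")
    if (is.null(msg)) TRUE else msg
})

#' @rdname GateThresholds-class
#' @param minPurity,minEpithelialTpm,maxImmuneScore,minEpithelialTpmReclass
#'   see slots.
#' @export
GateThresholds <- function(minPurity = 0.40, minEpithelialTpm = 1500,
                           maxImmuneScore = 75, minEpithelialTpmReclass = 10) {
    new("GateThresholds", minPurity = minPurity,
        minEpithelialTpm = minEpithelialTpm, maxImmuneScore = maxImmuneScore,
        minEpithelialTpmReclass = minEpithelialTpmReclass)
}

#' PathwayScores: raw and z-scaled single-sample pathway activity
#'
#' @slot raw matrix samples x pathways, AUCell scores in [0, 1].
#' @slot scaled matrix samples x pathways, per-pathway z-scores across the
#'   cohort (zero-variance pathways scale to 0).
#' @slot scalingStats data.frame (pathway, mean, sd) used for scaling.
#' @slot groups named character, group tag per pathway.
#' @export
setClass("PathwayScores",
         representation(raw = "matrix", scaled = "matrix",
                        scalingStats = "data.frame", groups = "character"))

setValidity("PathwayScores", function(object) {
    msg <- NULL
    if (!identical(dim(object@raw), dim(object@scaled)))
        msg <- c(msg, "raw and scaled matrices must share dimensions")
    if (any(object@raw < -1e-12 | object@raw > 1 + 1e-12))
        msg <- c(msg, "raw scores must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' ConsensusResult: consensus k-means clustering of samples
#'
#' @slot consensus samples x samples co-clustering frequency matrix in [0,1].
#' @slot labels named integer cluster labels 1..k.
#' @slot k number of clusters.
#' @slot nReps number of subsampling repetitions used.
#' @export
setClass("ConsensusResult",
         representation(consensus = "matrix", labels = "integer",
                        k = "integer", nReps = "integer"))

setValidity("ConsensusResult", function(object) {
    msg <- NULL
    M <- object@consensus
    if (nrow(M) != ncol(M) || !isTRUE(all.equal(M, t(M))))
        msg <- c(msg, "consensus matrix must be square and symmetric")
    if (any(M < -1e-12 | M > 1 + 1e-12))
        msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (!all(sort(unique(object@labels)) == seq_len(object@k)))
        msg <- c(msg, "labels must be exhaustive in 1..k")
    if (is.null(msg)) TRUE else msg
})

#' KnnModel: a k-nearest-neighbor phenotype reference
#'
#' Training scores are scaled pathway scores of high-purity CTC samples;
#' classification is by majority vote among the \code{k} Euclidean nearest
#' training samples, ties broken toward the smallest class index (factor
#' level order).
#'
#' @slot scores matrix, training samples x pathways (scaled).
#' @slot labels factor of training phenotypes.
#' @slot k number of neighbors (default 5, odd).
#' @export
setClass("KnnModel",
         representation(scores = "matrix", labels = "factor", k = "integer"))

setValidity("KnnModel", function(object) {
    msg <- NULL
    if (nrow(object@scores) != length(object@labels))
        msg <- c(msg, "one label per training sample required")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (is.null(colnames(object@scores)))
        msg <- c(msg, "pathway names are required")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ExpressionMatrix", function(object) {
    v <- assay(object, "tpm")
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
                nrow(v), ncol(v),
                if (isTRUE(metadata(object)$tpm_normalized))
                    "TPM-normalized" else "unnormalized"))
})

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' [%s]: %d genes\n", object@name, object@group,
                length(object@genes)))
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection of %d sets\n", length(object@sets)))
    for (s in object@sets)
        cat(sprintf("  %-24s %-14s %4d genes\n", s@name, s@group,
                    length(s@genes)))
})

setMethod("show", "SignatureMatrix", function(object) {
    cat(sprintf("SignatureMatrix: %d genes x %d cell types (immune: %s)\n",
                nrow(object@values), ncol(object@values),
                paste(object@immuneTypes, collapse = ", ")))
})

setMethod("show", "CalibrationParams", function(object) {
    cat(sprintf(
        "CalibrationParams: purity = cos(%.6g + %.6g * E); anchors E = (%.4g, %.4g) -> (%.2f, %.2f)\n",
        object@a, object@b, object@anchors[1], object@anchors[2],
        object@pHigh, object@pLow))
})

setMethod("show", "PathwayScores", function(object) {
    cat(sprintf("PathwayScores: %d samples x %d pathways\n",
                nrow(object@raw), ncol(object@raw)))
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: %d samples, k = %d, %d repetitions\n",
                nrow(object@consensus), object@k, object@nReps))
    print(table(cluster = object@labels))
})

setMethod("show", "KnnModel", function(object) {
    cat(sprintf("KnnModel: %d training samples, %d pathways, k = %d\n",
                nrow(object@scores), ncol(object@scores), object@k))
})
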