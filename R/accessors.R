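#' Accessors for ctclineage classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors TPM assay matrix of an [ExpressionMatrix-class].
#' @export
tpmValues <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    assay(x, "tpm")
}

#' @describeIn accessors is the matrix flagged TPM-normalized?
#' @export
isTpmNormalized <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    isTRUE(metadata(x)$tpm_normalized)
}

#' @describeIn accessors gene identifiers (rows).
#' @export
geneIds <- function(x) rownames(tpmValues(x))

#' @describeIn accessors sample identifiers (columns).
#' @export
sampleIds <- function(x) colnames(tpmValues(x))

#' Rescale each sample column to sum to one million
#'
#' @param x an [ExpressionMatrix-class] or a non-negative matrix.
#' @return an [ExpressionMatrix-class] flagged TPM-normalized.
#' @export
tpmNormalize <- function(x) {
    v <- if (is(x, "ExpressionMatrix")) tpmValues(x) else as.matrix(x)
    cs <- colSums(v)
    if (any(cs <= 0))
        stop("cannot TPM-normalize a sample with zero total expression: ",
             paste(colnames(v)[cs <= 0], collapse = ", "))
    ExpressionMatrix(sweep(v, 2, cs / 1e6, "/"), tpmNormalized = TRUE)
}

#' @describeIn accessors list of [GeneSet-class] in a collection.
#' @export
geneSets <- function(x) {
    stopifnot(is(x, "GeneSetCollection"))
    x@sets
}

#' @describeIn accessors gene-set names of a collection.
#' @export
geneSetNames <- function(x) {
    vapply(geneSets(x), function(s) s@name, character(1))
}

#' @describeIn accessors named vector of group tags of a collection.
#' @export
geneSetGroups <- function(x) {
    sets <- geneSets(x)
    structure(vapply(sets, function(s) s@group, character(1)),
              names = vapply(sets, function(s) s@name, character(1)))
}

#' Extract a gene set by name
#' @param x a [GeneSetCollection-class].
#' @param name set name.
#' @export
getGeneSet <- function(x, name) {
    nm <- geneSetNames(x)
    i <- match(name, nm)
    if (is.na(i)) stop("no gene set named '", name, "'")
    geneSets(x)[[i]]
}

#' Subset a collection by group tag
#' @param x a [GeneSetCollection-class].
#' @param groups character vector of group tags to keep.
#' @export
filterByGroup <- function(x, groups) {
    keep <- geneSetGroups(x) %in% groups
    GeneSetCollection(geneSets(x)[keep])
}

#' @describeIn accessors raw AUCell score matrix (samples x pathways).
#' @export
rawScores <- function(x) {
    stopifnot(is(x, "PathwayScores"))
    x@raw
}

#' @describeIn accessors z-scaled score matrix (samples x pathways).
#' @export
scaledScores <- function(x) {
    stopifnot(is(x, "PathwayScores"))
    x@scaled
}

#' @describeIn accessors per-pathway scaling mean and sd.
#' @export
scalingStats <- function(x) {
    stopifnot(is(x, "PathwayScores"))
    x@scalingStats
}

#' @describeIn accessors consensus co-clustering matrix.
#' @export
consensusMatrix <- function(x) {
    stopifnot(is(x, "ConsensusResult"))
    x@consensus
}

#' @describeIn accessors final cluster labels (named integer).
#' @export
clusterLabels <- function(x) {
    stopifnot(is(x, "ConsensusResult"))
    x@labels
}
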