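#' @importFrom stats sd
NULL

#' AUCell-style rank-AUC pathway activity score
#'
#' Area under the gene-set recovery curve within the top fraction of a
#' sample's expression ranking. With genes ordered by decreasing expression
#' (ties broken by gene identifier) and \code{T = ceiling(topFrac * n)}, the
#' recovery curve \code{h(r)} counts set genes at rank <= r; the raw AUC is
#' \code{sum(h(1..T))}, normalized by the maximal AUC
#' \code{sum(pmin(1:T, m))} attainable by an m-gene set, giving a score in
#' [0, 1]. Rank-based, hence invariant to strictly monotone expression
#' transforms.
#'
#' @param expr named numeric vector, one sample's expression.
#' @param geneSet a [GeneSet-class] or character vector of gene ids.
#' @param topFrac fraction of the ranking integrated (default 0.10, the
#'   published AUCell threshold).
#' @return score in [0, 1]; a set absent from the matrix scores 0 with a
#'   warning.
#' @export
aucellScore <- function(expr, geneSet, topFrac = 0.10) {
    genes <- if (is(geneSet, "GeneSet")) geneSet@genes else
        as.character(geneSet)
    setName <- if (is(geneSet, "GeneSet")) geneSet@name else "<gene set>"
    stopifnot(topFrac > 0, topFrac <= 1)
    n <- length(expr)
    if (n < ceiling(1 / topFrac))
        stop("matrix must have >= ", ceiling(1 / topFrac), " genes")
    if (is.null(names(expr))) stop("expression vector must be named by gene")
    inset <- names(expr) %in% genes
    m <- sum(inset)
    if (m == 0L) {
        warning("gene set '", setName,
                "' absent from the matrix; score set to 0")
        return(0)
    }
    top <- ceiling(topFrac * n)
    ord <- .rankOrder(expr)
    hits <- cumsum(inset[ord][seq_len(top)])
    raw <- sum(hits)
    maxAuc <- sum(pmin(seq_len(top), m))
    raw / maxAuc
}

#' Score every pathway in a collection across a cohort
#'
#' Raw AUCell scores per (sample, pathway) for all sets outside
#' \code{excludeGroups}, then z-scaled per pathway across the cohort's
#' samples. Genes of a set absent from the matrix are dropped for scoring
#' (standard single-sample enrichment behavior), with the retained count
#' logged. Zero-variance pathways scale to a column of zeros with a warning.
#'
#' @param x an [ExpressionMatrix-class] with >= 2 samples.
#' @param collection a [GeneSetCollection-class].
#' @param topFrac AUCell top fraction (default 0.10).
#' @param excludeGroups group tags left out of scoring (default
#'   \code{"held_out"}, the independent-assessment signatures).
#' @return a [PathwayScores-class].
#' @export
scorePathways <- function(x, collection, topFrac = 0.10,
                          excludeGroups = "held_out") {
    v <- tpmValues(x)
    if (ncol(v) < 2L) stop("need >= 2 samples for per-pathway scaling")
    keep <- !(geneSetGroups(collection) %in% excludeGroups)
    sets <- geneSets(collection)[keep]
    if (length(sets) == 0L) stop("no gene sets left after group exclusion")
    for (s in sets) {
        nIn <- sum(s@genes %in% rownames(v))
        if (nIn < length(s@genes))
            message(sprintf("set '%s': %d/%d genes in matrix", s@name, nIn,
                            length(s@genes)))
    }
    raw <- vapply(sets, function(s)
        apply(v, 2, aucellScore, geneSet = s, topFrac = topFrac),
        numeric(ncol(v)))
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = ncol(v))
    dimnames(raw) <- list(colnames(v), vapply(sets, function(s) s@name,
                                              character(1)))
    mu <- colMeans(raw)
    sdv <- apply(raw, 2, sd)
    zero <- sdv == 0
    if (any(zero))
        warning("zero-variance pathway(s) scaled to 0: ",
                paste(colnames(raw)[zero], collapse = ", "))
    scaled <- sweep(raw, 2, mu, "-")
    scaled[, !zero] <- sweep(scaled[, !zero, drop = FALSE], 2, sdv[!zero], "/")
    scaled[, zero] <- 0
    new("PathwayScores", raw = raw, scaled = scaled,
        scalingStats = data.frame(pathway = colnames(raw), mean = unname(mu),
                                  sd = unname(sdv)),
        groups = geneSetGroups(collection)[keep])
}

#' Consensus AR/luminal and neuroendocrine axis scores
#'
#' Per-sample arithmetic mean of the scaled scores of the member pathways of
#' each axis; averaging over several established signatures minimizes the
#' influence of any single gene set.
#'
#' @param scores a [PathwayScores-class].
#' @param arMembers,neMembers character vectors of pathway names forming the
#'   AR/luminal and neuroendocrine axes.
#' @return a data.frame with columns \code{sample_id}, \code{ar_score},
#'   \code{ne_score}.
#' @export
consensusAxis <- function(scores, arMembers, neMembers) {
    z <- scaledScores(scores)
    unknown <- setdiff(c(arMembers, neMembers), colnames(z))
    if (length(unknown))
        stop("unknown axis member pathway(s): ",
             paste(unknown, collapse = ", "))
    if (length(arMembers) == 0L || length(neMembers) == 0L)
        stop("each axis needs >= 1 member pathway")
    data.frame(
        sample_id = rownames(z),
        ar_score = rowMeans(z[, arMembers, drop = FALSE]),
        ne_score = rowMeans(z[, neMembers, drop = FALSE]),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean scaled score of an arbitrary pathway axis
#'
#' @param scores a [PathwayScores-class].
#' @param members pathway names.
#' @return named numeric, one value per sample.
#' @export
axisScore <- function(scores, members) {
    z <- scaledScores(scores)
    unknown <- setdiff(members, colnames(z))
    if (length(unknown))
        stop("unknown axis member pathway(s): ",
             paste(unknown, collapse = ", "))
    rowMeans(z[, members, drop = FALSE])
}
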