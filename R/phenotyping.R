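#' @importFrom stats kmeans hclust cutree as.dist dist
NULL

#' Consensus k-means clustering of scaled pathway scores
#'
#' Repeatedly subsamples the cohort without replacement, runs k-means on
#' each subsample (best of \code{innerRestarts} random starts by
#' within-cluster sum of squares), and records for every sample pair the
#' fraction of co-samplings in which the pair co-clustered. Final labels are
#' obtained by average-linkage hierarchical clustering of \code{1 - M} cut
#' at \code{k} (the standard consensus-clustering practice). Samples are
#' processed internally in lexicographic sample-id order, so the result is
#' independent of input column order for a given seed.
#'
#' @param scaled matrix, samples x pathways (z-scaled scores, no missing
#'   values), with row names.
#' @param k number of clusters (default 4, the reported cluster count).
#' @param nReps subsampling repetitions (default 1000).
#' @param subsampleFrac fraction of samples per repetition (default 0.8).
#' @param innerRestarts k-means random restarts per repetition (default 10).
#' @param seed RNG seed; fixed seed gives byte-identical results.
#' @return a [ConsensusResult-class].
#' @export
consensusKmeans <- function(scaled, k = 4, nReps = 1000, subsampleFrac = 0.8,
                            innerRestarts = 10, seed = 1) {
    scaled <- as.matrix(scaled)
    n <- nrow(scaled)
    if (is.null(rownames(scaled))) stop("sample (row) names are required")
    if (k < 2) stop("k must be >= 2")
    if (n < 2 * k) stop("need >= 2k samples")
    if (subsampleFrac <= 0 || subsampleFrac > 1)
        stop("subsampleFrac must be in (0, 1]")
    if (any(!is.finite(scaled))) stop("missing values in score matrix")
    ordIn <- order(rownames(scaled), method = "radix")
    X <- scaled[ordIn, , drop = FALSE]
    nSub <- max(ceiling(subsampleFrac * n), k + 1L)
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    set.seed(seed)
    for (rep in seq_len(nReps)) {
        idx <- sort(sample.int(n, nSub))
        km <- kmeans(X[idx, , drop = FALSE], centers = k,
                     nstart = innerRestarts, iter.max = 50)
        same <- outer(km$cluster, km$cluster, "==")
        co[idx, idx] <- co[idx, idx] + same
        tog[idx, idx] <- tog[idx, idx] + 1
    }
    if (any(tog == 0))
        stop("some sample pairs were never co-sampled; increase nReps")
    M <- co / tog
    M <- (M + t(M)) / 2
    diag(M) <- 1
    hc <- hclust(as.dist(1 - M), method = "average")
    lab <- cutree(hc, k = k)
    dimnames(M) <- list(rownames(X), rownames(X))
    names(lab) <- rownames(X)
    # back to input order
    backIdx <- match(rownames(scaled), rownames(X))
    new("ConsensusResult", consensus = M[backIdx, backIdx],
        labels = as.integer(lab[backIdx]) |>
            structure(names = rownames(scaled)),
        k = as.integer(k), nReps = as.integer(nReps))
}

#' Proportion of ambiguous clustering (PAC) across candidate k
#'
#' Transparency report for cluster-count choice: for each k the PAC is the
#' fraction of consensus-matrix entries falling in the ambiguous interval
#' (default (0.1, 0.9)); lower is cleaner. Reported for inspection only; it
#' does not override the configured k.
#'
#' @param scaled matrix, samples x pathways.
#' @param ks candidate cluster counts (default 2:6).
#' @param ... passed to [consensusKmeans()].
#' @return data.frame with columns \code{k} and \code{pac}.
#' @export
pacScan <- function(scaled, ks = 2:6, ...) {
    pac <- vapply(ks, function(k) {
        M <- consensusMatrix(consensusKmeans(scaled, k = k, ...))
        off <- M[lower.tri(M)]
        mean(off > 0.1 & off < 0.9)
    }, numeric(1))
    data.frame(k = ks, pac = pac)
}

#' Map consensus clusters to named lineage phenotypes
#'
#' Implements the archetype logic of the four reported clusters: the
#' cluster with maximal mean neuroendocrine axis score is \code{NE}; of the
#' remaining clusters the two with highest mean AR axis score are the
#' luminal pair, split into \code{LumB} (proliferation mean > 0, or the
#' higher-proliferation one when both share sign) and \code{LumA}; the
#' remaining cluster is \code{LP} (low AR / low NE / low proliferation).
#'
#' @param result a [ConsensusResult-class] with k = 4.
#' @param axisMeans data.frame with one row per sample: \code{sample_id},
#'   \code{ar_score}, \code{prolif_score}, \code{ne_score} (scaled axis
#'   scores, see [consensusAxis()] / [axisScore()]).
#' @return named character vector: phenotype per cluster index
#'   (\code{"1"}..\code{"4"}).
#' @export
mapClustersToPhenotypes <- function(result, axisMeans) {
    stopifnot(is(result, "ConsensusResult"))
    if (result@k != 4L) stop("phenotype mapping requires k = 4")
    lab <- clusterLabels(result)
    need <- c("sample_id", "ar_score", "prolif_score", "ne_score")
    miss <- setdiff(need, names(axisMeans))
    if (length(miss))
        stop("axisMeans missing column(s): ", paste(miss, collapse = ", "))
    ix <- match(names(lab), axisMeans$sample_id)
    if (any(is.na(ix))) stop("axis scores missing for some clustered samples")
    cl <- factor(lab, levels = 1:4)
    mAr <- tapply(axisMeans$ar_score[ix], cl, mean)
    mPr <- tapply(axisMeans$prolif_score[ix], cl, mean)
    mNe <- tapply(axisMeans$ne_score[ix], cl, mean)
    if (sum(mNe == max(mNe)) > 1L)
        stop("ambiguous cluster-phenotype map: exact tie in mean NE axis ",
             "scores; supply a manual map")
    ne <- which.max(mNe)
    rest <- setdiff(1:4, ne)
    arRest <- mAr[rest]
    ordAr <- rest[order(-arRest)]
    if (arRest[order(-arRest)][2] == arRest[order(-arRest)][3])
        stop("ambiguous cluster-phenotype map: exact tie in mean AR axis ",
             "scores between luminal pair and remainder; supply a manual map")
    pair <- ordAr[1:2]
    lp <- ordAr[3]
    prPair <- mPr[pair]
    if (prPair[1] == prPair[2])
        stop("ambiguous cluster-phenotype map: luminal pair tie in mean ",
             "proliferation axis scores; supply a manual map")
    lumB <- pair[which.max(prPair)]
    lumA <- pair[which.min(prPair)]
    map <- character(4)
    map[ne] <- "NE"; map[lumA] <- "LumA"; map[lumB] <- "LumB"; map[lp] <- "LP"
    names(map) <- as.character(1:4)
    map
}

#' Assign the five-level CTC phenotype per sample
#'
#' High-purity samples take their mapped cluster phenotype
#' (\code{source = "cluster"}); all other samples are \code{Low_CTC}
#' (\code{source = "gate"}) until (optionally) reclassified by
#' [knnClassify()].
#'
#' @param gateTiers named factor of gate tiers (see [purityGate()]).
#' @param clusterLabels named integer cluster labels covering every
#'   high-purity sample.
#' @param map cluster-to-phenotype map from [mapClustersToPhenotypes()].
#' @return data.frame with columns \code{sample_id}, \code{phenotype}
#'   (factor with levels Low_CTC, LP, LumA, LumB, NE) and \code{source}.
#' @export
assignPhenotypes <- function(gateTiers, clusterLabels, map) {
    ids <- names(gateTiers)
    high <- ids[gateTiers == "high_purity"]
    unlabeled <- setdiff(high, names(clusterLabels))
    if (length(unlabeled))
        stop("high-purity sample(s) without a cluster label: ",
             paste(unlabeled, collapse = ", "))
    phen <- rep("Low_CTC", length(ids))
    src <- rep("gate", length(ids))
    hi <- ids %in% high
    phen[hi] <- unname(map[as.character(clusterLabels[ids[hi]])])
    src[hi] <- "cluster"
    data.frame(sample_id = ids,
               phenotype = factor(phen, levels = .PHENOTYPE_LEVELS),
               source = src, row.names = NULL, stringsAsFactors = FALSE)
}

#' Train a kNN phenotype reference on high-purity samples
#'
#' @param scores matrix, training samples x pathways (scaled scores).
#' @param phenotypes factor (or character) of training phenotypes, one per
#'   row of \code{scores}.
#' @param k neighbors (default 5; odd recommended).
#' @return a [KnnModel-class].
#' @export
knnTrain <- function(scores, phenotypes, k = 5) {
    scores <- as.matrix(scores)
    phenotypes <- as.factor(phenotypes)
    phenotypes <- droplevels(phenotypes)
    if (k > nrow(scores)) stop("k exceeds the number of training samples")
    new("KnnModel", scores = scores, labels = phenotypes, k = as.integer(k))
}

#' Classify query samples by k-nearest neighbors
#'
#' Majority vote among the k Euclidean-nearest training samples on the
#' shared pathway columns. Ties are deterministic and resolve toward the
#' smallest class index (factor level order of the training labels): exact
#' distance ties at the neighborhood boundary admit the smaller class
#' first, then earlier training samples; vote ties likewise go to the
#' smallest class index. Intended for low-purity CTC samples passing the >10 TPM
#' epithelial floor and for metastatic tissue cohorts; by default queries
#' should be z-scaled within their own cohort.
#'
#' @param model a [KnnModel-class].
#' @param query matrix, query samples x pathways, with the model's pathway
#'   columns.
#' @return factor of predicted phenotypes, named by query sample.
#' @export
knnClassify <- function(model, query) {
    stopifnot(is(model, "KnnModel"))
    query <- as.matrix(query)
    if (is.null(colnames(query))) stop("query pathway names are required")
    miss <- setdiff(colnames(model@scores), colnames(query))
    if (length(miss))
        stop("query is missing model pathway(s): ",
             paste(miss, collapse = ", "))
    q <- query[, colnames(model@scores), drop = FALSE]
    tr <- model@scores
    lev <- levels(model@labels)
    pred <- apply(q, 1, function(row) {
        d <- sqrt(colSums((t(tr) - row)^2))
        nn <- order(d, as.integer(model@labels), seq_along(d))[seq_len(model@k)]
        votes <- tabulate(as.integer(model@labels[nn]), nbins = length(lev))
        lev[which.max(votes)]   # first max = smallest class index on ties
    })
    out <- factor(pred, levels = lev)
    names(out) <- rownames(q)
    out
}
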