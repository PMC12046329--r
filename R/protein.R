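#' @importFrom stats quantile kmeans
NULL

.CHANNELS <- c("nucleus", "pan_ck", "exclusion", "target")

#' 50% quantile (median) normalization of single-cell MFIs
#'
#' Per channel, every sample's MFIs are rescaled so its within-sample
#' quantile (default the median, i.e. 50% quantile normalization) matches
#' the global quantile over all cells; removes sample-to-sample gain
#' differences without distorting single-cell distributions. Idempotent.
#'
#' @param cells cell table (see [readCellTable()]).
#' @param channels channel columns to normalize.
#' @param q quantile to align (default 0.5).
#' @return the cell table with normalized channel columns.
#' @export
quantileNormalizeMfi <- function(cells, channels = .CHANNELS, q = 0.5) {
    for (ch in channels) {
        if (!ch %in% names(cells)) stop("missing channel column: ", ch)
        glob <- quantile(cells[[ch]], q, names = FALSE)
        for (s in unique(cells$sample_id)) {
            sel <- cells$sample_id == s
            med <- quantile(cells[[ch]][sel], q, names = FALSE)
            if (med <= 0)
                stop(sprintf("zero %g-quantile for sample '%s', channel '%s'",
                             q, s, ch))
            cells[[ch]][sel] <- cells[[ch]][sel] * (glob / med)
        }
    }
    cells
}

#' log10 MFI with a positivity floor
#'
#' Cells with MFI <= 0 (possible after upstream background subtraction) are
#' floored to the smallest positive observed value before log10.
#'
#' @param mfi numeric MFI vector.
#' @return log10-transformed values.
#' @export
logMfi <- function(mfi) {
    pos <- mfi[mfi > 0]
    if (length(pos) == 0L) stop("no positive MFI values")
    log10(pmax(mfi, min(pos)))
}

# Deterministic two-means split of a 1-D distribution: boundary is the
# midpoint of the two cluster centers, init at the 5th/95th percentiles.
.twoMeansThreshold <- function(x) {
    init <- quantile(x, c(0.05, 0.95), names = FALSE)
    if (init[1] == init[2]) return(init[1])
    km <- kmeans(x, centers = matrix(init, ncol = 1), iter.max = 100)
    mean(km$centers)
}

#' Gate CTCs from single-cell immunofluorescence
#'
#' A cell is a CTC iff pan-cytokeratin logMFI is above the pan-CK threshold
#' AND exclusion-channel (CD45/CD34/CD66b/CD14/CD27/CD16) logMFI is at or
#' below the exclusion threshold. Thresholds may be supplied; by default
#' each is derived from the full cell population by a deterministic
#' two-means split of that channel's logMFI.
#'
#' @param cells normalized cell table.
#' @param panckThreshold,exclusionThreshold logMFI cutoffs; \code{NULL}
#'   (default) derives them from the data.
#' @return the cell table with logical column \code{is_ctc} plus
#'   \code{panck_logmfi}, \code{exclusion_logmfi}.
#' @export
gateCtcs <- function(cells, panckThreshold = NULL, exclusionThreshold = NULL) {
    for (ch in c("pan_ck", "exclusion"))
        if (!ch %in% names(cells)) stop("missing channel column: ", ch)
    pk <- logMfi(cells$pan_ck)
    ex <- logMfi(cells$exclusion)
    if (is.null(panckThreshold)) panckThreshold <- .twoMeansThreshold(pk)
    if (is.null(exclusionThreshold)) exclusionThreshold <- .twoMeansThreshold(ex)
    cells$panck_logmfi <- pk
    cells$exclusion_logmfi <- ex
    cells$is_ctc <- pk > panckThreshold & ex <= exclusionThreshold
    cells
}

#' Fit the marker-positivity threshold on pooled non-CTCs
#'
#' The positivity threshold is the empirical percentile (default 95th,
#' linear interpolation) of target-channel logMFI pooled over all non-CTC
#' cells across samples; by construction ~5% of null cells exceed it.
#'
#' @param nonCtcCells cell table rows with \code{is_ctc == FALSE} (>= 20
#'   cells required), or a numeric vector of non-CTC target logMFI.
#' @param percentile percentile of the null distribution (default 95).
#' @param assay assay label stored with the model.
#' @return a list (class \code{positivityModel}) with \code{threshold},
#'   \code{percentile}, \code{n_null}, \code{assay}.
#' @export
fitPositivity <- function(nonCtcCells, percentile = 95, assay = "target") {
    x <- if (is.numeric(nonCtcCells)) nonCtcCells else
        logMfi(nonCtcCells$target)
    if (length(x) < 20L)
        stop("need >= 20 pooled non-CTC cells; got ", length(x))
    structure(list(threshold = quantile(x, percentile / 100, names = FALSE),
                   percentile = percentile, n_null = length(x),
                   assay = assay),
              class = "positivityModel")
}

#' Call marker positivity on CTCs
#'
#' A CTC is positive iff its target logMFI is strictly above the model
#' threshold.
#'
#' @param ctcCells cell table rows with \code{is_ctc == TRUE}, or a numeric
#'   vector of CTC target logMFI.
#' @param model a model from [fitPositivity()].
#' @return for a cell table: list with per-cell logical \code{positive} and
#'   data.frame \code{per_sample} (sample_id, n_ctc, n_positive,
#'   frac_positive); for a numeric vector: logical vector.
#' @export
callPositive <- function(ctcCells, model) {
    stopifnot(inherits(model, "positivityModel"))
    if (is.numeric(ctcCells)) return(ctcCells > model$threshold)
    x <- logMfi(ctcCells$target)
    pos <- x > model$threshold
    per <- do.call(rbind, lapply(split(pos, ctcCells$sample_id), function(p)
        data.frame(n_ctc = length(p), n_positive = sum(p),
                   frac_positive = mean(p))))
    per <- data.frame(sample_id = rownames(per), per, row.names = NULL,
                      stringsAsFactors = FALSE)
    list(positive = pos, per_sample = per)
}
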