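#' Ordinary least-squares slope of a score trajectory
#'
#' Slope of the linear regression of a consensus pathway score on calendar
#' time; exact on affine inputs.
#'
#' @param times numeric, days (>= 2 distinct values).
#' @param scores numeric, same length.
#' @return slope in score units per day.
#' @export
trajectorySlope <- function(times, scores) {
    if (length(times) != length(scores)) stop("times/scores length mismatch")
    if (length(times) < 2L || length(unique(times)) < 2L)
        stop("need >= 2 distinct timepoints")
    tc <- times - mean(times)
    sum(tc * (scores - mean(scores))) / sum(tc^2)
}

#' Flag a luminal-to-neuroendocrine transition
#'
#' TRUE iff the AR consensus score is falling and the NE consensus score is
#' rising: \code{arSlope < -eps} and \code{neSlope > eps}.
#'
#' @param arSlope,neSlope fitted slopes (any shared time unit).
#' @param eps slack around zero (default 0: any strict sign change).
#' @return logical.
#' @export
flagTransition <- function(arSlope, neSlope, eps = 0) {
    if (any(!is.finite(c(arSlope, neSlope)))) stop("slopes must be finite")
    arSlope < -eps & neSlope > eps
}

#' Liver-normalized PET SUVmax ratio
#'
#' The highest lesion SUVmax of an imaging study divided by the physiologic
#' liver SUVmax, making avidity comparable across images.
#'
#' @param lesionSuvmax numeric vector of per-lesion SUVmax values (>= 1).
#' @param liverSuvmax physiologic liver SUVmax (> 0).
#' @return single numeric ratio.
#' @export
suvRatio <- function(lesionSuvmax, liverSuvmax) {
    if (length(lesionSuvmax) == 0L) stop("need >= 1 lesion SUVmax")
    if (length(liverSuvmax) != 1L || !is.finite(liverSuvmax) ||
        liverSuvmax <= 0)
        stop("liver SUVmax must be a single positive value")
    max(lesionSuvmax) / liverSuvmax
}

#' Per-patient AR/NE score trajectories with slopes and transition flags
#'
#' Builds one trajectory per patient with >= 2 timepoints from a per-sample
#' table of consensus axis scores; patients with a single sample are
#' dropped with a message. Slopes are fitted per day and reported per 30
#' days for readability.
#'
#' @param axisScores data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{time} (days from treatment start or first
#'   collection), \code{ar_score}, \code{ne_score}, and optionally
#'   \code{folh1_tpm}.
#' @param eps transition slack passed to [flagTransition()].
#' @return data.frame, one row per eligible patient: \code{patient_id},
#'   \code{n_points}, \code{ar_slope_day}, \code{ne_slope_day},
#'   \code{ar_slope_30d}, \code{ne_slope_30d}, \code{transition}.
#' @export
buildTrajectories <- function(axisScores, eps = 0) {
    need <- c("sample_id", "patient_id", "time", "ar_score", "ne_score")
    miss <- setdiff(need, names(axisScores))
    if (length(miss))
        stop("axisScores missing column(s): ", paste(miss, collapse = ", "))
    out <- lapply(split(axisScores, axisScores$patient_id), function(d) {
        d <- d[order(d$time), , drop = FALSE]
        if (length(unique(d$time)) < 2L) return(NULL)
        if (any(duplicated(d$time)))
            stop("patient ", d$patient_id[1L],
                 " has duplicate collection times")
        arS <- trajectorySlope(d$time, d$ar_score)
        neS <- trajectorySlope(d$time, d$ne_score)
        data.frame(patient_id = d$patient_id[1L], n_points = nrow(d),
                   ar_slope_day = arS, ne_slope_day = neS,
                   ar_slope_30d = arS * 30, ne_slope_30d = neS * 30,
                   transition = flagTransition(arS, neS, eps = eps),
                   stringsAsFactors = FALSE)
    })
    dropped <- sum(vapply(out, is.null, logical(1)))
    if (dropped > 0)
        message(dropped, " patient(s) with < 2 timepoints dropped")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
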