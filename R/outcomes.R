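#' @importFrom survival Surv survfit survdiff coxph
#' @importFrom stats pchisq dhyper complete.cases as.formula setNames
NULL

#' Kaplan-Meier curves, log-rank test and pairwise hazard ratios
#'
#' Product-limit survival estimate per phenotype group, log-rank comparison
#' across groups, and pairwise Cox hazard ratios of each group against the
#' reference (default \code{Low_CTC}, the most favorable tier). Group labels
#' should be per subject, taken at the first CTC collection.
#'
#' @param clinical data.frame with \code{os_time} (months) and
#'   \code{os_event} (0/1), one row per subject.
#' @param groups factor/character of group labels, one per row.
#' @param reference reference group for pairwise hazard ratios.
#' @return list with \code{curves} (per-group data.frames time / surv /
#'   n_risk / n_event), \code{median} (named numeric, NA = not reached),
#'   \code{logrank} (chisq, df, p), \code{hazard_ratios} (data.frame group,
#'   hr, lower, upper, p vs reference), \code{n} per group.
#' @export
kmLogrank <- function(clinical, groups, reference = "Low_CTC") {
    time <- clinical$os_time
    event <- clinical$os_event
    if (any(is.na(time)) || any(time < 0)) stop("os_time must be >= 0")
    if (!all(event %in% c(0, 1))) stop("os_event must be 0/1")
    groups <- as.character(groups)
    if (length(groups) != nrow(clinical))
        stop("one group label per subject required")
    keep <- table(groups)
    empty <- setdiff(unique(groups), names(keep)[keep > 0])
    if (sum(event) == 0) stop("all subjects censored; log-rank undefined")
    g <- factor(groups)
    fit <- survfit(Surv(time, event) ~ g)
    strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                                paste0("g=", levels(g)[1]))
              else fit$strata
    idx <- rep(names(strata), strata)
    curves <- lapply(split(seq_along(fit$time), sub("^g=", "", idx)),
        function(i) data.frame(time = fit$time[i], surv = fit$surv[i],
                               n_risk = fit$n.risk[i],
                               n_event = fit$n.event[i]))
    med <- vapply(curves, function(cv) {
        hit <- cv$time[cv$surv <= 0.5]
        if (length(hit)) min(hit) else NA_real_
    }, numeric(1))
    lr <- if (nlevels(g) > 1) {
        sd <- survdiff(Surv(time, event) ~ g)
        list(chisq = sd$chisq, df = nlevels(g) - 1L,
             p = pchisq(sd$chisq, nlevels(g) - 1L, lower.tail = FALSE))
    } else list(chisq = NA_real_, df = 0L, p = NA_real_)
    hr <- NULL
    if (reference %in% levels(g) && nlevels(g) > 1) {
        others <- setdiff(levels(g), reference)
        hr <- do.call(rbind, lapply(others, function(gr) {
            sel <- groups %in% c(reference, gr)
            z <- factor(groups[sel], levels = c(reference, gr))
            cx <- coxph(Surv(time[sel], event[sel]) ~ z)
            s <- summary(cx)
            data.frame(group = gr, hr = unname(s$conf.int[1, "exp(coef)"]),
                       lower = unname(s$conf.int[1, "lower .95"]),
                       upper = unname(s$conf.int[1, "upper .95"]),
                       p = unname(s$coefficients[1, "Pr(>|z|)"]))
        }))
    }
    list(curves = curves, median = med, logrank = lr, hazard_ratios = hr,
         n = table(g))
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit (Efron tie handling) of overall survival on the
#' declared covariates plus the CTC phenotype; incomplete cases are dropped
#' with their count logged.
#'
#' @param clinical data.frame with \code{os_time}, \code{os_event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param phenotypes optional factor of phenotype labels added as a
#'   covariate (reference = first level).
#' @param ties tie handling, \code{"efron"} (default) or \code{"breslow"};
#'   note only Breslow leaves estimates exactly invariant to replicating
#'   the dataset, since replication creates tied event times.
#' @return data.frame: term, hr, lower, upper, p; attribute \code{fit}
#'   carries the coxph object.
#' @export
coxMultivariate <- function(clinical, covariates, phenotypes = NULL,
                            ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    d <- clinical[, c("os_time", "os_event", covariates), drop = FALSE]
    if (!is.null(phenotypes)) d$phenotype <- factor(phenotypes)
    cc <- complete.cases(d)
    if (sum(!cc) > 0)
        message(sum(!cc), " incomplete case(s) dropped")
    d <- d[cc, , drop = FALSE]
    terms <- c(covariates, if (!is.null(phenotypes)) "phenotype")
    for (v in terms) {
        x <- d[[v]]
        if (length(unique(x[!is.na(x)])) < 2L)
            stop("covariate '", v, "' has zero variance")
    }
    fml <- as.formula(paste("Surv(os_time, os_event) ~",
                            paste(terms, collapse = " + ")))
    fit <- tryCatch(coxph(fml, data = d, ties = ties),
                    warning = function(w) {
                        if (grepl("infinite|converge|beta", conditionMessage(w)))
                            stop("Cox fit did not converge (possible ",
                                 "separation): ", conditionMessage(w),
                                 call. = FALSE)
                        suppressWarnings(coxph(fml, data = d, ties = ties))
                    })
    s <- summary(fit)
    out <- data.frame(term = rownames(s$coefficients),
                      hr = unname(s$conf.int[, "exp(coef)"]),
                      lower = unname(s$conf.int[, "lower .95"]),
                      upper = unname(s$conf.int[, "upper .95"]),
                      p = unname(s$coefficients[, "Pr(>|z|)"]),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "fit") <- fit
    out
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact hypergeometric test: with margins fixed, sums the probabilities of
#' all tables no more probable than the observed one (standard two-sided
#' convention, with a 1e-7 relative guard against floating-point ties).
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisherExactP <- function(tbl) {
    tbl <- as.matrix(tbl)
    if (!all(dim(tbl) == c(2L, 2L)) || any(tbl < 0) ||
        any(tbl != round(tbl)))
        stop("need a 2x2 table of non-negative integer counts")
    m <- sum(tbl[1, ]); n <- sum(tbl[2, ]); k <- sum(tbl[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    pObs <- dhyper(tbl[1, 1], m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Clinical benefit rate by group with exact comparison
#'
#' Clinical benefit = best radiographic response of SD, PR or CR; the
#' non-evaluable (\code{NE}) responses are excluded with their count
#' logged. For two groups the 2x2 benefit-by-group table is compared by the
#' Fisher exact test.
#'
#' @param responses character/factor of best responses (CR/PR/SD/PD/NE).
#' @param groups group labels, one per subject.
#' @return list: \code{cbr} (named numeric, percent per group),
#'   \code{counts} (benefit x group table), \code{n_excluded},
#'   \code{fisher_p} (NA unless exactly two groups).
#' @export
clinicalBenefitRate <- function(responses, groups) {
    responses <- as.character(responses)
    groups <- as.character(groups)
    stopifnot(length(responses) == length(groups))
    bad <- setdiff(unique(responses), .RESPONSES)
    if (length(bad)) stop("unknown response(s): ", paste(bad, collapse = ", "))
    eval <- responses != "NE" & !is.na(responses)
    nExcluded <- sum(!eval)
    if (nExcluded > 0) message(nExcluded, " non-evaluable subject(s) excluded")
    responses <- responses[eval]; groups <- groups[eval]
    if (any(table(groups) == 0) || length(unique(groups)) == 0)
        stop("empty group after exclusion")
    benefit <- responses %in% c("SD", "PR", "CR")
    cbr <- vapply(split(benefit, groups), function(b) 100 * mean(b),
                  numeric(1))
    counts <- table(benefit = factor(benefit, levels = c(TRUE, FALSE)),
                    group = groups)
    fisherP <- if (ncol(counts) == 2L) fisherExactP(counts) else NA_real_
    list(cbr = cbr, counts = counts, n_excluded = nExcluded,
         fisher_p = fisherP)
}

#' Flag early progression on therapy
#'
#' TRUE iff therapy was discontinued for radiographic and/or PSA
#' progression within \code{maxWeek} weeks (default 18, i.e. three cycles)
#' of the first dose. Subjects discontinuing without a recorded reason are
#' flagged NA (unknown) with a warning and should be excluded.
#'
#' @param clinical data.frame with \code{discontinuation_week} (NA = still
#'   on therapy) and \code{discontinuation_reason} (e.g. "progression").
#' @param maxWeek week cutoff, inclusive (default 18).
#' @return logical vector (NA = unknown), one per row.
#' @export
flagEarlyProgression <- function(clinical, maxWeek = 18) {
    wk <- clinical$discontinuation_week
    rs <- clinical$discontinuation_reason
    out <- rep(FALSE, nrow(clinical))
    disc <- !is.na(wk)
    unknown <- disc & (is.na(rs) | !nzchar(rs))
    if (any(unknown)) {
        warning(sum(unknown),
                " discontinuation(s) without a reason flagged unknown")
        out[unknown] <- NA
    }
    known <- disc & !unknown
    out[known] <- rs[known] == "progression" & wk[known] <= maxWeek
    out
}
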