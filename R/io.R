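#' @importFrom utils read.delim write.table read.csv write.csv
NULL

.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("empty file: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
}

#' Read a gene-by-sample expression matrix
#'
#' Reads tab- or comma-separated text (first column gene identifiers, header
#' row sample identifiers). Gene matching throughout the package is exact,
#' case-sensitive string match; inputs must share one identifier namespace.
#'
#' @param path file path (.tsv/.txt tab-separated, .csv comma-separated).
#' @param assumeTpm if \code{TRUE} (default) values are taken as TPM and the
#'   TPM flag is set only when every column sums to 1e6 within 1e-6 relative
#'   tolerance; if \code{FALSE} columns are rescaled to sum to 1e6.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, assumeTpm = TRUE) {
    df <- .readTable(path)
    if (ncol(df) < 2L) stop("expected gene-id column plus >=1 sample column")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (any(!is.finite(m)))
        stop("non-numeric or missing expression values in ", path)
    if (any(m < 0)) {
        idx <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative expression at gene '%s', sample '%s'",
                     rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
    if (!assumeTpm) return(tpmNormalize(m))
    cs <- colSums(m)
    isTpm <- all(abs(cs - 1e6) <= 1e-6 * 1e6)
    if (!isTpm)
        warning("columns do not all sum to 1e6; matrix not flagged TPM-normalized")
    ExpressionMatrix(m, tpmNormalized = isTpm)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with full double precision so that a write/read
#' round-trip reproduces the matrix to better than 1e-9 relative.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
    v <- tpmValues(x)
    df <- data.frame(gene_id = rownames(v),
                     as.data.frame(format(v, digits = 17, trim = TRUE,
                                          scientific = TRUE)),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, \code{name TAB description TAB
#' gene TAB gene ...}. Duplicate genes within a line are deduplicated with a
#' warning (set semantics); duplicate set names are an error.
#'
#' @param path GMT file path.
#' @param groupMap optional named character vector mapping set names to group
#'   tags (\code{ar_luminal}, \code{proliferation}, \code{neuroendocrine},
#'   \code{hallmark}, \code{held_out}, \code{other}); unmapped sets get
#'   \code{"other"}.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path, groupMap = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty GMT file: ", path)
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                         i, length(f)))
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning(sprintf("duplicate gene(s) within set '%s'; deduplicated", f[1L]))
            genes <- unique(genes)
        }
        grp <- if (!is.null(groupMap) && f[1L] %in% names(groupMap))
            unname(groupMap[[f[1L]]]) else "other"
        sets[[i]] <- GeneSet(f[1L], genes, grp)
    }
    nm <- vapply(sets, function(s) s@name, character(1))
    if (anyDuplicated(nm))
        stop("duplicate gene-set name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    GeneSetCollection(sets)
}

#' Write a GeneSetCollection as GMT
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGmt <- function(x, path) {
    lines <- vapply(geneSets(x), function(s)
        paste(c(s@name, s@group, s@genes), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a cell-type signature matrix
#'
#' Expects tab-separated text with cell types in rows and genes in columns
#' (first column holds the cell-type label); the matrix is transposed to the
#' internal genes-by-cell-types orientation.
#'
#' @param path TSV path.
#' @param immuneTypes character vector naming the immune cell types.
#' @return a [SignatureMatrix-class].
#' @export
readSignatureMatrix <- function(path, immuneTypes) {
    df <- .readTable(path)
    types <- as.character(df[[1L]])
    if (anyDuplicated(types))
        stop("duplicate cell type(s): ",
             paste(unique(types[duplicated(types)]), collapse = ", "))
    m <- t(as.matrix(df[, -1L, drop = FALSE]))
    storage.mode(m) <- "double"
    colnames(m) <- types
    missing <- setdiff(immuneTypes, types)
    if (length(missing))
        stop("immune type(s) not in signature matrix: ",
             paste(missing, collapse = ", "))
    SignatureMatrix(m, immuneTypes)
}

#' Write a SignatureMatrix (cell types in rows) as TSV
#' @param x a [SignatureMatrix-class].
#' @param path output path.
#' @export
writeSignatureMatrix <- function(x, path) {
    df <- data.frame(cell_type = colnames(x@values),
                     as.data.frame(t(x@values)), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.DISEASE_STATES <- c("mCSPC", "mCRPC", "NEPC")
.SITE_CATEGORIES <- c("LN_only", "bone_LN", "nonliver_visceral", "liver",
                      "unknown")
.RESPONSES <- c("CR", "PR", "SD", "PD", "NE")

#' Read a per-sample clinical table
#'
#' CSV schema (one row per sample): \code{patient_id}, \code{sample_id},
#' \code{collection_time} (days from the patient's first collection),
#' \code{disease_state} (mCSPC/mCRPC/NEPC), \code{os_time} (months),
#' \code{os_event} (0/1); optional \code{serum_psa} (ng/mL),
#' \code{metastatic_site_category}, \code{treatment}, \code{rpfs_time},
#' \code{rpfs_event}, \code{best_response} (CR/PR/SD/PD/NE),
#' \code{discontinuation_week}, \code{discontinuation_reason}.
#'
#' @param path CSV path.
#' @return a validated data.frame.
#' @export
readClinical <- function(path) {
    df <- .readTable(path)
    mandatory <- c("patient_id", "sample_id", "collection_time",
                   "disease_state", "os_time", "os_event")
    miss <- setdiff(mandatory, names(df))
    if (length(miss))
        stop("missing mandatory clinical column(s): ",
             paste(miss, collapse = ", "))
    validateClinical(df)
}

#' Validate a clinical table against its invariants
#' @param df a clinical data.frame (see [readClinical()]).
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateClinical <- function(df) {
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id(s): ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    bad <- !df$disease_state %in% .DISEASE_STATES
    if (any(bad))
        stop("unknown disease_state: ",
             paste(unique(df$disease_state[bad]), collapse = ", "))
    if (any(is.na(df$os_time)))
        stop("os_time missing for sample(s): ",
             paste(df$sample_id[is.na(df$os_time)], collapse = ", "))
    if (any(df$os_time < 0)) stop("os_time must be >= 0")
    if (!all(df$os_event %in% c(0, 1)))
        stop("os_event must be 0/1; offending sample(s): ",
             paste(df$sample_id[!df$os_event %in% c(0, 1)], collapse = ", "))
    if ("metastatic_site_category" %in% names(df)) {
        bad <- !is.na(df$metastatic_site_category) &
            !df$metastatic_site_category %in% .SITE_CATEGORIES
        if (any(bad))
            stop("unknown metastatic_site_category: ",
                 paste(unique(df$metastatic_site_category[bad]), collapse = ", "))
    }
    if ("best_response" %in% names(df)) {
        bad <- !is.na(df$best_response) & !df$best_response %in% .RESPONSES
        if (any(bad))
            stop("unknown best_response: ",
                 paste(unique(df$best_response[bad]), collapse = ", "))
    }
    df
}

#' Read a single-cell immunofluorescence table
#'
#' CSV schema: \code{cell_id}, \code{sample_id}, and one MFI column per
#' channel (defaults \code{nucleus}, \code{pan_ck}, \code{exclusion},
#' \code{target}), arbitrary fluorescence units.
#'
#' @param path CSV path.
#' @param channels channel column names expected.
#' @return a validated data.frame.
#' @export
readCellTable <- function(path,
                          channels = c("nucleus", "pan_ck", "exclusion",
                                       "target")) {
    df <- .readTable(path)
    miss <- setdiff(c("cell_id", "sample_id", channels), names(df))
    if (length(miss))
        stop("missing cell-table column(s): ", paste(miss, collapse = ", "))
    for (ch in channels) {
        if (any(is.na(df[[ch]])) || any(df[[ch]] < 0))
            stop("channel '", ch, "' has missing or negative MFI values")
    }
    df
}

#' Default analysis configuration
#'
#' Every threshold used downstream, overridable via a YAML file
#' ([readConfig()]): purity gate, scoring exponents and fractions, consensus
#' clustering, kNN, transition and positivity settings.
#' @return a named list.
#' @export
defaultConfig <- function() {
    list(
        ssgsea_alpha = 0.25,
        aucell_top_frac = 0.10,
        calibration = list(p_high = 0.99, p_low = 0.01),
        gate = list(min_purity = 0.40, min_epithelial_tpm = 1500,
                    max_immune_score = 75, min_epithelial_tpm_reclass = 10),
        epithelial_markers = c("EPCAM", "KRT8", "KRT18", "KRT19"),
        consensus = list(k = 4, n_reps = 1000, subsample_frac = 0.8,
                         inner_restarts = 10, seed = 1),
        knn = list(k = 5),
        transition_eps = 0,
        positivity_percentile = 95,
        mfi_quantile = 0.5,
        early_progression_week = 18
    )
}

#' Read a YAML configuration, merged over [defaultConfig()]
#' @param path YAML file path (optional; \code{NULL} returns the defaults).
#' @return a named list.
#' @export
readConfig <- function(path = NULL) {
    cfg <- defaultConfig()
    if (is.null(path)) return(cfg)
    user <- yaml::read_yaml(path)
    modifyList(cfg, user)
}
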