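#' Read an expression table from disk
#'
#' Two dialects are supported. \code{plain_tsv} is a features x samples
#' tab-separated table whose first column holds feature ids and whose
#' header names the samples. \code{probe_profile} is a
#' GenomeStudio-final-report style table with a \code{ProbeID} column and,
#' per sample, an \code{<sample>.AVG_Signal} and an
#' \code{<sample>.Detection Pval} column; the detection p-values are kept
#' alongside the intensities. Values are returned on the raw intensity
#' scale; missing entries are encoded as \code{NA}.
#'
#' @param path path to a tab-separated file.
#' @param dialect \code{"plain_tsv"} or \code{"probe_profile"}.
#' @param datasetId cohort label to attach; defaults to the file name.
#' @return An [ExpressionCohort-class] with \code{scale = "raw_intensity"};
#'   for \code{probe_profile}, the \code{detectionP} assay is populated.
#' @export
readExpressionTable <- function(path, dialect = c("plain_tsv",
                                                  "probe_profile"),
                                datasetId = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(datasetId))
        datasetId <- sub("\\.[^.]*$", "", basename(path))
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = NA, na.strings = "NA")
    if (ncol(tab) < 2L)
        stop("format error: expected an id column plus data columns")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("format error: duplicated feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyNA(ids) || any(ids == ""))
        stop("format error: missing feature id")
    body <- tab[, -1L, drop = FALSE]
    .as_numeric_checked <- function(col, colname) {
        v <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(v) & !is.na(col) &
                     trimws(as.character(col)) != "NA" &
                     trimws(as.character(col)) != "")
        if (length(bad))
            stop(sprintf(
                "parse error: non-numeric value '%s' at row '%s', column '%s'",
                col[bad[1L]], ids[bad[1L]], colname))
        v
    }
    if (dialect == "plain_tsv") {
        m <- vapply(seq_len(ncol(body)),
                    function(j) .as_numeric_checked(body[[j]],
                                                    colnames(body)[j]),
                    numeric(nrow(body)))
        m <- matrix(m, nrow = nrow(body),
                    dimnames = list(ids, colnames(body)))
        return(ExpressionCohort(m, datasetId, scale = "raw_intensity"))
    }
    sig_cols <- grep("\\.AVG_Signal$", colnames(body), value = TRUE)
    det_cols <- grep("\\.Detection Pval$", colnames(body), value = TRUE)
    if (!length(sig_cols))
        stop("dialect error: no '<sample>.AVG_Signal' columns found")
    if (!length(det_cols))
        stop("dialect error: probe_profile requires ",
             "'<sample>.Detection Pval' columns")
    samples <- sub("\\.AVG_Signal$", "", sig_cols)
    det_expect <- paste0(samples, ".Detection Pval")
    if (!all(det_expect %in% det_cols))
        stop("dialect error: detection column missing for sample(s): ",
             paste(samples[!det_expect %in% det_cols], collapse = ", "))
    getm <- function(cols) {
        m <- vapply(cols,
                    function(cn) .as_numeric_checked(body[[cn]], cn),
                    numeric(nrow(body)))
        matrix(m, nrow = nrow(body), dimnames = list(ids, samples))
    }
    ExpressionCohort(getm(sig_cols), datasetId, scale = "raw_intensity",
                     detectionP = getm(det_expect))
}

#' Write an expression cohort as tab-separated text
#'
#' Inverse of [readExpressionTable()]: \code{plain_tsv} writes a
#' features x samples table; \code{probe_profile} writes
#' GenomeStudio-style signal and detection-p columns (requires the
#' \code{detectionP} assay). Values are printed at full precision so a
#' write/read round trip reproduces the matrix bit-identically.
#'
#' @param ds an [ExpressionCohort-class].
#' @param path output path.
#' @param dialect as in [readExpressionTable()].
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(ds, path, dialect = c("plain_tsv",
                                                       "probe_profile")) {
    dialect <- match.arg(dialect)
    m <- signalMatrix(ds)
    fmt <- function(x) vapply(x, function(v)
        if (is.na(v)) "NA" else sprintf("%.17g", v), character(1L))
    if (dialect == "plain_tsv") {
        out <- data.frame(feature_id = rownames(m),
                          apply(m, 2L, fmt), check.names = FALSE,
                          stringsAsFactors = FALSE)
        colnames(out) <- c("feature_id", colnames(m))
    } else {
        dp <- detectionP(ds)
        if (is.null(dp))
            stop("probe_profile output requires a detectionP assay")
        out <- data.frame(ProbeID = rownames(m), stringsAsFactors = FALSE)
        for (s in colnames(m)) {
            out[[paste0(s, ".AVG_Signal")]] <- fmt(m[, s])
            out[[paste0(s, ".Detection Pval")]] <- fmt(dp[, s])
        }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-sample clinical table
#'
#' Tab-separated with a header naming \code{sample_id} and
#' \code{tissue_class} (one of \code{normal}, \code{primary_tumor},
#' \code{cell_line}, \code{other}) and optionally \code{dfs_time}
#' (months) and \code{dfs_event} (1 = recurrence, 0 = censored).
#'
#' @param path path to the table.
#' @return A validated \code{data.frame}.
#' @export
readClinicalTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "tissue_class") %in% colnames(tab)))
        stop("clinical table must name sample_id and tissue_class")
    validateClinical(tab)
    tab
}

#' Validate a clinical annotation table
#'
#' Checks the closed tissue-class vocabulary and the survival-field
#' consistency rules (an event flag requires a nonnegative time).
#'
#' @param tab data.frame with \code{sample_id}, \code{tissue_class} and
#'   optional \code{dfs_time} / \code{dfs_event} columns.
#' @return \code{tab}, invisibly, or an error.
#' @export
validateClinical <- function(tab) {
    bad <- setdiff(unique(stats::na.omit(tab$tissue_class)),
                   .TISSUE_CLASSES)
    if (length(bad))
        stop("vocabulary error: unknown tissue_class token(s): ",
             paste(bad, collapse = ", "))
    if (!is.null(tab$dfs_event)) {
        ev <- tab$dfs_event
        if (!all(is.na(ev) | ev %in% c(0, 1)))
            stop("dfs_event must be 0/1")
        if (is.null(tab$dfs_time))
            stop("consistency error: dfs_event present without dfs_time")
        if (any(!is.na(ev) & is.na(tab$dfs_time)))
            stop("consistency error: dfs_event recorded without dfs_time ",
                 "for sample(s): ",
                 paste(tab$sample_id[!is.na(ev) & is.na(tab$dfs_time)],
                       collapse = ", "))
    }
    if (!is.null(tab$dfs_time) && any(tab$dfs_time < 0, na.rm = TRUE))
        stop("range error: dfs_time must be nonnegative")
    invisible(tab)
}

#' Read a probe-to-gene map
#'
#' Tab-separated with columns \code{probe_id}, \code{gene_symbol} and
#' optionally \code{isoform_label}. Each probe may map to at most one
#' gene symbol.
#'
#' @param path path to the table.
#' @return A \code{data.frame} with one row per probe.
#' @export
readProbeMap <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% colnames(tab)))
        stop("probe map must name probe_id and gene_symbol")
    if (anyDuplicated(tab$probe_id))
        stop("format error: probe_id maps to more than one gene: ",
             paste(unique(tab$probe_id[duplicated(tab$probe_id)]),
                   collapse = ", "))
    tab
}

# internal: probe ids mapping to `gene`, case-insensitively after trimming
.probesForGene <- function(map, gene) {
    hit <- tolower(trimws(map$gene_symbol)) == tolower(trimws(gene))
    map$probe_id[hit & !is.na(hit)]
}

#' Collapse isoform-level probes to a per-sample gene signal
#'
#' Averages all probes mapping to a gene (matched case-insensitively
#' after trimming) into one per-sample signal on the log2 scale; with a
#' single mapped probe the probe's row is returned unchanged. The
#' arithmetic mean is the default; the median is available for
#' robustness to a single aberrant isoform probe.
#'
#' @param ds an [ExpressionCohort-class] on the log2 scale.
#' @param map probe map \code{data.frame} (see [readProbeMap()]).
#' @param gene gene symbol.
#' @param method \code{"mean"} (default) or \code{"median"}.
#' @return Named numeric vector, one value per sample.
#' @export
collapseIsoforms <- function(ds, map, gene, method = c("mean", "median")) {
    method <- match.arg(method)
    if (exprScale(ds) != "log2")
        stop("scale error: isoform collapse expects log2-scale data")
    probes <- intersect(.probesForGene(map, gene), rownames(ds))
    if (!length(probes))
        stop("missing-gene error: no measured probe maps to gene '",
             gene, "'")
    m <- signalMatrix(ds)[probes, , drop = FALSE]
    if (method == "mean") colMeans(m, na.rm = TRUE)
    else apply(m, 2L, stats::median, na.rm = TRUE)
}

# internal: TRUE if the gene has at least one measured probe in ds
.geneMeasured <- function(ds, map, gene) {
    length(intersect(.probesForGene(map, gene), rownames(ds))) > 0L
}
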