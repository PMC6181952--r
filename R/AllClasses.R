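#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assays<- colData<-
#' @importFrom S4Vectors DataFrame metadata
NULL

.TISSUE_CLASSES <- c("normal", "primary_tumor", "cell_line", "other")
.EXPR_SCALES <- c("raw_intensity", "log2")

#' ExpressionCohort: an expression matrix with per-sample annotation
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} carrying one expression assay
#' (\code{"exprs"}, features x samples), an optional array detection
#' p-value assay (\code{"detectionP"}, same shape, values in [0, 1]),
#' per-sample clinical annotation in \code{colData} (columns
#' \code{tissue_class}, and optionally \code{dfs_time} / \code{dfs_event}
#' for disease-free survival), a short cohort label, and the scale the
#' values live on (\code{"raw_intensity"} or \code{"log2"}).
#'
#' @slot datasetId single character cohort label.
#' @slot exprScale \code{"raw_intensity"} or \code{"log2"}.
#'
#' @seealso [ExpressionCohort()] for construction,
#'   [readExpressionTable()] for reading from disk.
#' @export
setClass("ExpressionCohort",
    contains = "SummarizedExperiment",
    representation(datasetId = "character", exprScale = "character"))

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    if (length(object@datasetId) != 1L || is.na(object@datasetId))
        msg <- c(msg, "datasetId must be a single non-NA string")
    if (length(object@exprScale) != 1L ||
        !object@exprScale %in% .EXPR_SCALES)
        msg <- c(msg, sprintf("exprScale must be one of: %s",
                              paste(.EXPR_SCALES, collapse = ", ")))
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "an assay named 'exprs' is required")
    else {
        m <- assay(object, "exprs")
        fid <- rownames(m); sid <- colnames(m)
        if (is.null(fid) || anyDuplicated(fid) || anyNA(fid))
            msg <- c(msg, "feature ids must be present and unique")
        if (is.null(sid) || anyDuplicated(sid) || anyNA(sid))
            msg <- c(msg, "sample ids must be present and unique")
        if (identical(object@exprScale, "log2") &&
            any(!is.finite(m[!is.na(m)])))
            msg <- c(msg, "log2-scale values must be finite")
    }
    if ("detectionP" %in% assayNames(object)) {
        dp <- assay(object, "detectionP")
        if (!identical(dim(dp), dim(assay(object, "exprs"))))
            msg <- c(msg, "detectionP must match the exprs dimensions")
        else if (any(dp < 0 | dp > 1, na.rm = TRUE))
            msg <- c(msg, "detectionP values must lie in [0, 1]")
    }
    cd <- colData(object)
    if ("tissue_class" %in% colnames(cd)) {
        tc <- as.character(cd$tissue_class)
        if (!all(tc[!is.na(tc)] %in% .TISSUE_CLASSES))
            msg <- c(msg, sprintf("tissue_class must be one of: %s",
                                  paste(.TISSUE_CLASSES, collapse = ", ")))
    }
    if ("dfs_event" %in% colnames(cd)) {
        ev <- cd$dfs_event
        ok <- is.na(ev) | ev %in% c(0, 1)
        if (!all(ok)) msg <- c(msg, "dfs_event must be 0/1 or NA")
        if (!"dfs_time" %in% colnames(cd))
            msg <- c(msg, "dfs_event requires dfs_time")
        else {
            tt <- cd$dfs_time
            if (any(!is.na(ev) & is.na(tt)))
                msg <- c(msg, "dfs_event present but dfs_time missing")
            if (any(tt[!is.na(tt)] < 0))
                msg <- c(msg, "dfs_time must be nonnegative")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param exprs numeric matrix, features x samples, with unique row and
#'   column names.
#' @param datasetId short cohort label.
#' @param scale \code{"raw_intensity"} (default) or \code{"log2"}.
#' @param detectionP optional matrix of per-probe, per-sample detection
#'   p-values with the same shape as \code{exprs}.
#' @param colData optional per-sample annotation (data.frame or
#'   \link[S4Vectors]{DataFrame}); rows matched to columns of \code{exprs}.
#' @return An [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' ExpressionCohort(m, "toy", scale = "log2")
#' @export
ExpressionCohort <- function(exprs, datasetId = "cohort",
                             scale = c("raw_intensity", "log2"),
                             detectionP = NULL, colData = NULL) {
    scale <- match.arg(scale)
    exprs <- as.matrix(exprs)
    assays <- list(exprs = exprs)
    if (!is.null(detectionP)) assays$detectionP <- as.matrix(detectionP)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(exprs))
    else {
        colData <- as(colData, "DataFrame")
        if (!is.null(colData$sample_id) &&
            is.null(rownames(colData)))
            rownames(colData) <- colData$sample_id
        colData <- colData[colnames(exprs), , drop = FALSE]
        rownames(colData) <- colnames(exprs)
    }
    se <- SummarizedExperiment(assays = assays, colData = colData)
    new("ExpressionCohort", se, datasetId = datasetId, exprScale = scale)
}

#' @describeIn ExpressionCohort-class cohort label accessor.
#' @param object,x an \code{ExpressionCohort}.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionCohort-class
#' @export
setMethod("datasetId", "ExpressionCohort", function(object) object@datasetId)

#' @describeIn ExpressionCohort-class expression-scale accessor.
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @rdname ExpressionCohort-class
#' @export
setMethod("exprScale", "ExpressionCohort", function(object) object@exprScale)

#' @describeIn ExpressionCohort-class the expression matrix.
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname ExpressionCohort-class
#' @export
setMethod("signalMatrix", "ExpressionCohort",
    function(object) assay(object, "exprs"))

#' @describeIn ExpressionCohort-class detection p-value matrix, or NULL.
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))

#' @rdname ExpressionCohort-class
#' @export
setMethod("detectionP", "ExpressionCohort", function(object) {
    if ("detectionP" %in% assayNames(object)) assay(object, "detectionP")
    else NULL
})

#' @rdname ExpressionCohort-class
#' @export
setMethod("show", "ExpressionCohort", function(object) {
    cat(sprintf("ExpressionCohort '%s': %d features x %d samples [%s]\n",
                object@datasetId, nrow(object), ncol(object),
                object@exprScale))
    cd <- colData(object)
    if ("tissue_class" %in% colnames(cd)) {
        tab <- table(cd$tissue_class)
        cat("  tissue_class:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    if ("dfs_time" %in% colnames(cd))
        cat(sprintf("  survival: %d samples with DFS time, %d events\n",
                    sum(!is.na(cd$dfs_time)),
                    sum(cd$dfs_event == 1, na.rm = TRUE)))
    cat(sprintf("  detectionP: %s\n",
                if ("detectionP" %in% assayNames(object)) "present"
                else "absent"))
    invisible(object)
})

# internal: replace the expression assay, optionally changing scale
.setSignal <- function(object, m, scale = object@exprScale) {
    assays(object)[["exprs"]] <- m
    object@exprScale <- scale
    validObject(object)
    object
}
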