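#' Normalization configuration
#'
#' Parameters for bringing a cohort to the analysis scale. Probes are
#' called expressed when their detection p-value falls strictly below
#' \code{detection_p_max} in at least \code{min_detected_samples}
#' samples (the usual array convention: p < 0.01 in >= 1 sample).
#'
#' @param background_mode \code{"shift_to_positive"} (default) or
#'   \code{"none"}.
#' @param detection_p_max detection threshold in (0, 1); default 0.01.
#' @param min_detected_samples minimum samples detected; default 1.
#' @param rnaseq_pseudocount pseudocount added before log2 for RNA-seq
#'   counts; default 1.
#' @return A validated list of class \code{"NormalizationConfig"}.
#' @export
normalizationConfig <- function(background_mode = c("shift_to_positive",
                                                    "none"),
                                detection_p_max = 0.01,
                                min_detected_samples = 1L,
                                rnaseq_pseudocount = 1) {
    background_mode <- match.arg(background_mode)
    stopifnot(detection_p_max > 0, detection_p_max < 1,
              min_detected_samples >= 1, rnaseq_pseudocount > 0)
    structure(list(background_mode = background_mode,
                   detection_p_max = detection_p_max,
                   min_detected_samples = as.integer(min_detected_samples),
                   rnaseq_pseudocount = rnaseq_pseudocount),
              class = "NormalizationConfig")
}

#' Background-correct raw array intensities
#'
#' \code{shift_to_positive} subtracts \code{min(matrix) - 1} when the
#' minimum is at or below zero, so the corrected minimum is 1 and the
#' subsequent log2 transform is defined; intensities already positive
#' are returned unchanged. \code{none} is the identity.
#'
#' @param ds an [ExpressionCohort-class] on the raw intensity scale.
#' @param cfg a [normalizationConfig()].
#' @return The corrected cohort, still on the raw intensity scale.
#' @export
backgroundCorrect <- function(ds, cfg = normalizationConfig()) {
    if (exprScale(ds) != "raw_intensity")
        stop("scale error: background correction expects raw intensities")
    if (cfg$background_mode == "none") return(ds)
    m <- signalMatrix(ds)
    lo <- min(m, na.rm = TRUE)
    if (lo <= 0) m <- m - (lo - 1)
    .setSignal(ds, m)
}

#' Log2-transform positive intensities
#'
#' @param ds an [ExpressionCohort-class] with all values > 0.
#' @return The cohort on the log2 scale.
#' @export
log2Transform <- function(ds) {
    m <- signalMatrix(ds)
    bad <- rownames(m)[apply(m <= 0, 1L, any, na.rm = TRUE)]
    if (length(bad))
        stop("domain error: nonpositive value(s) in feature(s): ",
             paste(utils::head(bad, 5L), collapse = ", "),
             if (length(bad) > 5L) ", ..." else "")
    .setSignal(ds, log2(m), scale = "log2")
}

#' Quantile-normalize samples to a common distribution
#'
#' Maps every sample onto the reference distribution formed by the
#' row-wise mean of the column-sorted matrix; after normalization every
#' column holds the identical sorted value multiset. Tied values within
#' a column receive the mean of the reference values over their rank
#' span, so the operation is deterministic and idempotent. With a
#' single sample the data are returned unchanged with a warning.
#'
#' @param ds an [ExpressionCohort-class] without missing values.
#' @return The quantile-normalized cohort (scale unchanged).
#' @export
quantileNormalize <- function(ds) {
    m <- signalMatrix(ds)
    if (ncol(m) < 2L) {
        warning("quantile normalization needs >= 2 samples; returning ",
                "data unchanged")
        return(ds)
    }
    if (anyNA(m))
        stop("quantile normalization requires a complete matrix")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    .setSignal(ds, out)
}

#' Filter probes on array detection p-values
#'
#' Keeps exactly the features detected (p strictly below
#' \code{cfg$detection_p_max}) in at least
#' \code{cfg$min_detected_samples} samples; feature order is preserved.
#'
#' @param ds an [ExpressionCohort-class] with a \code{detectionP} assay.
#' @param cfg a [normalizationConfig()].
#' @return The filtered cohort.
#' @export
detectionFilter <- function(ds, cfg = normalizationConfig()) {
    dp <- detectionP(ds)
    if (is.null(dp))
        stop("missing-data error: no detectionP assay present")
    keep <- rowSums(dp < cfg$detection_p_max, na.rm = TRUE) >=
        cfg$min_detected_samples
    ds[keep, ]
}

#' Preprocess RNA-seq quantifications
#'
#' Applies \code{log2(value + pseudocount)} to nonnegative counts (for
#' example upper-quartile-normalized RSEM values); no quantile
#' normalization is applied on this branch.
#'
#' @param ds an [ExpressionCohort-class] on the raw scale, values >= 0.
#' @param cfg a [normalizationConfig()]; uses \code{rnaseq_pseudocount}.
#' @return The cohort on the log2 scale.
#' @export
preprocessRnaseq <- function(ds, cfg = normalizationConfig()) {
    if (exprScale(ds) != "raw_intensity")
        stop("scale error: expected raw-scale counts")
    m <- signalMatrix(ds)
    if (any(m < 0, na.rm = TRUE))
        stop("domain error: negative count values")
    .setSignal(ds, log2(m + cfg$rnaseq_pseudocount), scale = "log2")
}

#' Run the full array normalization chain on one cohort
#'
#' background correction, log2 transform, quantile normalization, then
#' detection-p filtering (when detection p-values are present). For
#' \code{platform = "rnaseq"} only the pseudocount log2 transform is
#' applied.
#'
#' @param ds an [ExpressionCohort-class] on the raw scale.
#' @param cfg a [normalizationConfig()].
#' @param platform \code{"array"} (default) or \code{"rnaseq"}.
#' @return The normalized cohort on the log2 scale.
#' @export
normalizeCohort <- function(ds, cfg = normalizationConfig(),
                            platform = c("array", "rnaseq")) {
    platform <- match.arg(platform)
    if (platform == "rnaseq") return(preprocessRnaseq(ds, cfg))
    ds <- backgroundCorrect(ds, cfg)
    ds <- log2Transform(ds)
    ds <- quantileNormalize(ds)
    if (!is.null(detectionP(ds))) ds <- detectionFilter(ds, cfg)
    ds
}
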