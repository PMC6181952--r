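#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, \code{dCt = target_ct - reference_ct} (housekeeping
#' normalization); \code{ddCt} subtracts the mean dCt of the reference
#' condition, and the fold change is \code{efficiency^(-ddCt)}. By
#' construction the reference condition's fold changes average 1 on the
#' log scale. The amplification efficiency defaults to the ideal 2.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{condition}, \code{target_ct}, \code{reference_ct}; all cycle
#'   thresholds positive and finite.
#' @param reference_condition the baseline condition label (e.g.
#'   \code{"no_dox"}); must be present.
#' @param efficiency amplification efficiency per cycle; default 2.
#' @return \code{records} with added \code{dct}, \code{ddct},
#'   \code{fold} columns.
#' @export
deltaDeltaCt <- function(records, reference_condition = "no_dox",
                         efficiency = 2) {
    need <- c("sample_id", "condition", "target_ct", "reference_ct")
    if (!all(need %in% colnames(records)))
        stop("records must name: ", paste(need, collapse = ", "))
    ct <- c(records$target_ct, records$reference_ct)
    if (any(!is.finite(ct) | ct <= 0))
        stop("domain error: cycle thresholds must be positive and finite")
    if (!reference_condition %in% records$condition)
        stop("configuration error: reference condition '",
             reference_condition, "' absent")
    records$dct <- records$target_ct - records$reference_ct
    ref_mean <- mean(records$dct[records$condition ==
                                 reference_condition])
    records$ddct <- records$dct - ref_mean
    records$fold <- efficiency^(-records$ddct)
    records
}

#' ChIP-qPCR fold enrichment over IgG, normalized to baseline
#'
#' Per region and condition, enrichment over the negative
#' immunoprecipitation control is \code{efficiency^-(Ct_ab - Ct_IgG)};
#' the reported value is the treated condition's enrichment divided by
#' the baseline condition's, so the baseline is 1 by construction. The
#' quantity is scale-free: a shared offset on all four Ct values of a
#' region cancels.
#'
#' @param records data.frame with columns \code{region},
#'   \code{condition}, \code{antibody} (\code{"target"} or
#'   \code{"IgG"}), \code{ct}.
#' @param treated,baseline condition labels; defaults \code{"dox"},
#'   \code{"no_dox"}.
#' @param efficiency amplification efficiency; default 2.
#' @return data.frame with one row per region: \code{region},
#'   \code{enrichment_treated}, \code{enrichment_baseline},
#'   \code{normalized_enrichment}.
#' @export
chipFoldEnrichment <- function(records, treated = "dox",
                               baseline = "no_dox", efficiency = 2) {
    need <- c("region", "condition", "antibody", "ct")
    if (!all(need %in% colnames(records)))
        stop("records must name: ", paste(need, collapse = ", "))
    one <- function(region, condition, antibody) {
        ct <- records$ct[records$region == region &
                         records$condition == condition &
                         records$antibody == antibody]
        if (length(ct) != 1L)
            stop("pairing error: region '", region,
                 "' lacks a unique ", antibody, " Ct in condition '",
                 condition, "'")
        ct
    }
    out <- lapply(unique(records$region), function(r) {
        e_t <- efficiency^-(one(r, treated, "target") -
                            one(r, treated, "IgG"))
        e_b <- efficiency^-(one(r, baseline, "target") -
                            one(r, baseline, "IgG"))
        data.frame(region = r, enrichment_treated = e_t,
                   enrichment_baseline = e_b,
                   normalized_enrichment = e_t / e_b,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' One-sample t test for fold changes
#'
#' The fold-change test used throughout perturbation figures: the
#' classical one-sample t of the observed fold changes against a
#' hypothesized mean of 1 (no change). Two-sided by default; a
#' one-sided alternative is available for hypothesis-driven
#' comparisons.
#'
#' @param values numeric fold changes (n >= 3, nonzero variance).
#' @param hypothesized_mean null value; default 1.
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   or \code{"less"}.
#' @return List with \code{t}, \code{p_value}, \code{df}.
#' @export
oneSampleT <- function(values, hypothesized_mean = 1,
                       alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    values <- values[is.finite(values)]
    if (length(values) < 3L)
        stop("sample-size error: need n >= 3 values")
    if (stats::var(values) == 0)
        stop("degenerate error: zero variance among fold changes")
    tt <- stats::t.test(values, mu = hypothesized_mean,
                        alternative = alternative)
    list(t = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter))
}
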