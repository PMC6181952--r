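#' Stratification configuration for disease-free survival
#'
#' Patients are split into the lowest expression quartile (Q1) versus
#' the rest of the cohort (Q2 + Q3 + Q4) on a single-gene signal or a
#' multi-gene composite.
#'
#' @param quartile_fraction the lower-tail fraction defining Q1, in
#'   (0, 0.5); default 0.25.
#' @param signature_combine \code{"mean_signal"} (default; unweighted
#'   mean of log2 gene signals) or \code{"zscore_mean"} (each gene
#'   standardized across samples first).
#' @return A validated list of class \code{"StratificationConfig"}.
#' @export
stratificationConfig <- function(quartile_fraction = 0.25,
                                 signature_combine = c("mean_signal",
                                                       "zscore_mean")) {
    signature_combine <- match.arg(signature_combine)
    stopifnot(quartile_fraction > 0, quartile_fraction < 0.5)
    structure(list(quartile_fraction = quartile_fraction,
                   signature_combine = signature_combine),
              class = "StratificationConfig")
}

#' Per-sample composite expression signal
#'
#' Each listed gene contributes its isoform-collapsed log2 signal; the
#' composite is the unweighted mean across genes
#' (\code{mean_signal}) or the mean of per-gene z-scores
#' (\code{zscore_mean}). A single gene returns that gene's signal
#' unchanged (under \code{mean_signal}).
#'
#' @param ds an [ExpressionCohort-class] on the log2 scale.
#' @param map probe map \code{data.frame}.
#' @param genes character vector of gene symbols, all measured.
#' @param cfg a [stratificationConfig()].
#' @return Named per-sample numeric vector.
#' @export
compositeSignal <- function(ds, map, genes,
                            cfg = stratificationConfig()) {
    missing <- genes[!vapply(genes, .geneMeasured, logical(1L),
                             ds = ds, map = map)]
    if (length(missing))
        stop("missing-gene error: not measured in cohort '",
             datasetId(ds), "': ", paste(missing, collapse = ", "))
    sig <- vapply(genes, function(g) collapseIsoforms(ds, map, g),
                  numeric(ncol(ds)))
    if (cfg$signature_combine == "zscore_mean")
        sig <- scale(sig)
    rowMeans(sig)
}

#' Assign samples to the low-expression quartile versus the rest
#'
#' Q1 holds the samples whose signal is at or below the empirical
#' \code{quartile_fraction}-quantile (linear-interpolation quantile
#' definition); boundary ties all go to Q1 so the low group is never
#' empty.
#'
#' @param signal per-sample numeric vector (>= 8 samples).
#' @param cfg a [stratificationConfig()].
#' @return Named character vector of \code{"Q1"} / \code{"rest"}.
#' @export
quartileGroups <- function(signal, cfg = stratificationConfig()) {
    if (length(signal) < 8L)
        stop("sample-size error: quartile stratification needs >= 8 ",
             "samples")
    if (length(unique(signal)) == 1L)
        stop("degenerate-stratification error: constant signal")
    q <- unname(stats::quantile(signal, cfg$quartile_fraction, type = 7))
    ifelse(signal <= q, "Q1", "rest")
}

#' Kaplan-Meier product-limit survival curve
#'
#' \code{S(t)} multiplies \code{1 - d_i/n_i} over the distinct event
#' times up to \code{t}; censored observations leave the risk set after
#' their time, and a censoring tied with an event at the same time is
#' handled events-first (the censored subject is still at risk for that
#' event). With no events the curve is identically 1 and a warning is
#' raised.
#'
#' @param time nonnegative event/censoring times.
#' @param event 0/1 event indicators (1 = event).
#' @return data.frame of class \code{"KMCurve"} with one row per
#'   distinct event time: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{survival}.
#' @export
kmCurve <- function(time, event) {
    stopifnot(length(time) == length(event), all(time >= 0),
              all(event %in% c(0, 1)))
    etimes <- sort(unique(time[event == 1]))
    if (!length(etimes)) {
        warning("no events observed; survival curve is identically 1")
        out <- data.frame(time = numeric(), n_risk = integer(),
                          n_event = integer(), survival = numeric())
        class(out) <- c("KMCurve", "data.frame")
        return(out)
    }
    surv <- 1
    rows <- lapply(etimes, function(t0) {
        n_risk <- sum(time >= t0)
        d <- sum(time == t0 & event == 1)
        surv <<- surv * (1 - d / n_risk)
        data.frame(time = t0, n_risk = n_risk, n_event = d,
                   survival = surv)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("KMCurve", "data.frame")
    out
}

#' Log-rank (Mantel-Cox) test with O/E hazard ratio
#'
#' At each distinct event time the expected events per group are
#' proportional to the group's share of the risk set, with the standard
#' hypergeometric variance term; the statistic is
#' \code{(O_a - E_a)^2 / V} on 1 degree of freedom. The hazard ratio is
#' the observed-over-expected ratio \code{(O_a/E_a) / (O_b/E_b)}; when
#' one group has expected but no observed events the ratio diverges and
#' is reported as \code{Inf} (or 0) with \code{hr_divergent = TRUE}.
#' In the Q1-versus-rest stratification, group a is Q1, so a hazard
#' ratio above 1 means the low-expression group recurs faster.
#'
#' @param time_a,event_a times and 0/1 event flags for group a.
#' @param time_b,event_b times and 0/1 event flags for group b.
#' @return List of class \code{"LogRankResult"}: \code{chi_sq},
#'   \code{p_value}, \code{observed} (length 2), \code{expected},
#'   \code{hazard_ratio}, \code{hr_divergent}, \code{n} (group sizes).
#' @export
logrankHR <- function(time_a, event_a, time_b, event_b) {
    if (!length(time_a) || !length(time_b))
        stop("degenerate-group error: both groups must be nonempty")
    time <- c(time_a, time_b)
    event <- c(event_a, event_b)
    grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
    if (sum(event) == 0)
        stop("degenerate-group error: no events in either group")
    etimes <- sort(unique(time[event == 1]))
    Oa <- 0; Ea <- 0; V <- 0
    for (t0 in etimes) {
        at_risk <- time >= t0
        n <- sum(at_risk); na <- sum(at_risk & grp_a)
        d <- sum(time == t0 & event == 1)
        da <- sum(time == t0 & event == 1 & grp_a)
        Oa <- Oa + da
        Ea <- Ea + d * na / n
        if (n > 1)
            V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
    }
    O <- c(Oa, sum(event) - Oa)
    E <- c(Ea, sum(event) - Ea)
    chi <- if (V > 0) (Oa - Ea)^2 / V else 0
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    rate <- O / E
    divergent <- any(O == 0 & E > 0)
    hr <- rate[1L] / rate[2L]
    structure(list(chi_sq = chi, p_value = p, observed = O,
                   expected = E, hazard_ratio = hr,
                   hr_divergent = divergent,
                   n = c(length(time_a), length(time_b))),
              class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
    cat(sprintf("Log-rank (Mantel-Cox): chi_sq = %.4g (1 df), p = %.4g\n",
                x$chi_sq, x$p_value))
    cat(sprintf("  O = (%g, %g), E = (%.3g, %.3g), HR (O/E) = %.3g%s\n",
                x$observed[1L], x$observed[2L], x$expected[1L],
                x$expected[2L], x$hazard_ratio,
                if (x$hr_divergent) " [divergent]" else ""))
    invisible(x)
}

#' Quartile-stratified disease-free-survival analysis
#'
#' End-to-end Q1-versus-rest evaluation of a single-gene or composite
#' signature in one cohort: restricts to primary-tumor samples with a
#' recorded disease-free-survival time, computes the composite signal,
#' splits at the lower quartile, builds a Kaplan-Meier curve per group,
#' and runs the log-rank test with the O/E hazard ratio (Q1 is group
#' a). A cohort without any recurrence event yields the group table and
#' curves but no test, with a warning.
#'
#' @param ds an [ExpressionCohort-class] on the log2 scale; survival
#'   fields are taken from \code{colData} unless \code{clin} is given.
#' @param map probe map \code{data.frame}.
#' @param genes gene symbols forming the signature.
#' @param cfg a [stratificationConfig()].
#' @param clin optional clinical \code{data.frame} (joined on
#'   \code{sample_id}) overriding the cohort's own annotation.
#' @return List of class \code{"DFSStratification"}: \code{groups}
#'   (per-sample data.frame with signal, group, time, event),
#'   \code{km_q1}, \code{km_rest}, \code{logrank} (NULL when no
#'   events), \code{n_q1}, \code{n_rest}.
#' @export
stratifyDFS <- function(ds, map, genes, cfg = stratificationConfig(),
                        clin = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(ds))
    cd$sample_id <- colnames(ds)
    if (!is.null(clin)) {
        validateClinical(clin)
        cd <- merge(cd[, "sample_id", drop = FALSE], clin,
                    by = "sample_id", sort = FALSE)
    }
    need <- c("tissue_class", "dfs_time", "dfs_event")
    if (!all(need %in% colnames(cd)))
        stop("survival annotation requires columns: ",
             paste(setdiff(need, colnames(cd)), collapse = ", "))
    eligible <- cd$sample_id[cd$tissue_class == "primary_tumor" &
                             !is.na(cd$dfs_time)]
    if (length(eligible) < 8L)
        stop("sample-size error: < 8 eligible primary-tumor samples ",
             "with DFS time")
    sig <- compositeSignal(ds, map, genes, cfg)[eligible]
    grp <- quartileGroups(sig, cfg)
    idx <- match(eligible, cd$sample_id)
    tab <- data.frame(sample_id = eligible, signal = unname(sig),
                      group = unname(grp),
                      dfs_time = cd$dfs_time[idx],
                      dfs_event = cd$dfs_event[idx],
                      stringsAsFactors = FALSE)
    q1 <- tab$group == "Q1"
    res <- list(groups = tab,
                km_q1 = suppressWarnings(
                    kmCurve(tab$dfs_time[q1], tab$dfs_event[q1])),
                km_rest = suppressWarnings(
                    kmCurve(tab$dfs_time[!q1], tab$dfs_event[!q1])),
                logrank = NULL,
                n_q1 = sum(q1), n_rest = sum(!q1))
    if (sum(tab$dfs_event) == 0) {
        warning("no recurrence events; log-rank test not performed")
    } else {
        res$logrank <- logrankHR(tab$dfs_time[q1], tab$dfs_event[q1],
                                 tab$dfs_time[!q1], tab$dfs_event[!q1])
    }
    class(res) <- "DFSStratification"
    res
}

#' @export
print.DFSStratification <- function(x, ...) {
    cat(sprintf("Q1 vs rest DFS stratification: n_Q1 = %d, n_rest = %d\n",
                x$n_q1, x$n_rest))
    if (!is.null(x$logrank)) print(x$logrank)
    else cat("  (no events; no test)\n")
    invisible(x)
}
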