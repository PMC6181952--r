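#' Screen criteria
#'
#' Thresholds for the multi-cohort candidate screen: per-cohort Spearman
#' correlation with the anchor gene must reach \code{rho_min} at
#' \code{p <= p_max} (both boundaries inclusive), tumor-vs-normal
#' alteration must reach \code{p <= p_max} in the required direction,
#' and each criterion must hold in strictly more than
#' \code{consistency_fraction} of the cohorts in which the gene is
#' evaluable.
#'
#' @param rho_min minimum Spearman coefficient; default 0.2.
#' @param p_max per-cohort p-value ceiling; default 0.05.
#' @param consistency_fraction strict-majority fraction in (0, 1];
#'   default 0.5.
#' @param require_positive_rho if \code{TRUE} (default) only positive
#'   correlations can pass; otherwise \code{|rho| >= rho_min} passes.
#' @param alteration_direction \code{"down"} (default), \code{"up"}, or
#'   \code{"any"} (majority direction across cohorts is used).
#' @param tumor_only restrict correlations to primary-tumor samples
#'   (default \code{TRUE}).
#' @return A validated list of class \code{"ScreenCriteria"}.
#' @export
screenCriteria <- function(rho_min = 0.2, p_max = 0.05,
                           consistency_fraction = 0.5,
                           require_positive_rho = TRUE,
                           alteration_direction = c("down", "up", "any"),
                           tumor_only = TRUE) {
    alteration_direction <- match.arg(alteration_direction)
    stopifnot(rho_min > 0, rho_min <= 1, p_max > 0, p_max < 1,
              consistency_fraction > 0, consistency_fraction <= 1)
    structure(list(rho_min = rho_min, p_max = p_max,
                   consistency_fraction = consistency_fraction,
                   require_positive_rho = isTRUE(require_positive_rho),
                   alteration_direction = alteration_direction,
                   tumor_only = isTRUE(tumor_only)),
              class = "ScreenCriteria")
}

# internal: all permutations of 1..n as an n! x n matrix (n <= 8)
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    r <- 0L
    for (k in seq_len(n)) {
        block <- cbind(k, sub + (sub >= k))
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks. The
#' two-sided p-value is exact by enumeration of all n! rank
#' permutations for n <= 8 (valid with ties, since mid-ranks are
#' permuted wholesale), and otherwise uses the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of
#' freedom. Incomplete pairs are removed first.
#'
#' @param x,y numeric vectors of equal length (n >= 3 after removing
#'   incomplete pairs).
#' @return List with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearmanTest <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("sample-size error: need n >= 3 complete pairs")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("undefined-correlation error: constant input vector")
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= 8L) {
        perms <- .permutations(n)
        rxc <- rx - mean(rx)
        # rows of `perms` index permutations of the y ranks
        num <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rxc)
        den <- sqrt(sum(rxc^2)) *
            sqrt(sum((ry - mean(ry))^2))
        rho_all <- num / den
        p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    } else {
        r2 <- min(rho^2, 1)
        if (1 - r2 < 1e-15) {
            p <- 0
        } else {
            tstat <- rho * sqrt((n - 2) / (1 - r2))
            p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        }
    }
    list(rho = rho, p_value = p, n = n)
}

#' Mann-Whitney U test with median shift
#'
#' Two-sided rank-sum comparison of two groups: exact by enumeration
#' when the smaller group has at most 8 observations and there are no
#' ties, and otherwise a normal approximation with tie and continuity
#' corrections. The reported shift is \code{median(a) - median(b)}
#' (tumor minus normal in the screen). A fully tied comparison has
#' degenerate variance and reports p = 1 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @return List with \code{u_statistic}, \code{p_value},
#'   \code{median_shift}.
#' @export
mannWhitneyU <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3L || length(b) < 3L)
        stop("sample-size error: each group needs n >= 3")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- !ties && min(length(a), length(b)) <= 8L
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    p <- wt$p.value
    if (!is.finite(p)) {
        warning("degenerate rank variance (all values tied); p set to 1")
        p <- 1
    }
    list(u_statistic = unname(wt$statistic), p_value = min(p, 1),
         median_shift = stats::median(a) - stats::median(b))
}

# internal: collapse every mapped gene at once into a gene x sample
# matrix (mean over isoform probes, NA-tolerant); rownames are the
# trimmed lower-cased gene symbols used for case-insensitive lookup
.collapseAllGenes <- function(ds, map) {
    m <- signalMatrix(ds)
    probes <- intersect(map$probe_id, rownames(m))
    mm <- m[probes, , drop = FALSE]
    f <- tolower(trimws(map$gene_symbol[match(probes, map$probe_id)]))
    ok <- !is.na(mm)
    sums <- rowsum(ifelse(ok, mm, 0), f)
    cnt <- rowsum(ok + 0, f)
    sums / cnt
}

#' Correlate candidate genes with an anchor gene across cohorts
#'
#' For every cohort in which both the anchor and the candidate are
#' measured, computes the Spearman correlation between their
#' isoform-collapsed signals (on primary-tumor samples when
#' \code{crit$tumor_only}) and flags whether the cohort passes the
#' screen thresholds. Cohorts lacking a gene do not enter that gene's
#' denominator; cohorts where the correlation is undefined (constant
#' signal, too few samples) are likewise skipped.
#'
#' @param cohorts list of log2-scale [ExpressionCohort-class] objects.
#' @param map probe map \code{data.frame}.
#' @param anchor anchor gene symbol (must be measured in >= 1 cohort).
#' @param candidates character vector of candidate gene symbols.
#' @param crit a [screenCriteria()].
#' @return data.frame with one row per evaluable (cohort, candidate):
#'   \code{dataset_id}, \code{gene}, \code{rho}, \code{p_value},
#'   \code{n_samples}, \code{passes}.
#' @export
correlateWithAnchor <- function(cohorts, map, anchor, candidates,
                                crit = screenCriteria()) {
    if (!any(vapply(cohorts, .geneMeasured, logical(1L), map = map,
                    gene = anchor)))
        stop("screen-configuration error: anchor gene '", anchor,
             "' absent from every cohort")
    rows <- list()
    for (ds in cohorts) {
        samples <- colnames(ds)
        if (crit$tumor_only && "tissue_class" %in%
            colnames(SummarizedExperiment::colData(ds)))
            samples <- samples[SummarizedExperiment::colData(
                ds)$tissue_class == "primary_tumor"]
        G <- .collapseAllGenes(ds, map)[, samples, drop = FALSE]
        akey <- tolower(trimws(anchor))
        if (!akey %in% rownames(G)) next
        av <- G[akey, ]
        for (g in candidates) {
            gkey <- tolower(trimws(g))
            if (!gkey %in% rownames(G)) next
            cv <- G[gkey, ]
            res <- tryCatch(spearmanTest(av, cv), error = function(e) NULL)
            if (is.null(res)) next
            pass <- if (crit$require_positive_rho)
                res$rho >= crit$rho_min else abs(res$rho) >= crit$rho_min
            rows[[length(rows) + 1L]] <- data.frame(
                dataset_id = datasetId(ds), gene = g, rho = res$rho,
                p_value = res$p_value, n_samples = res$n,
                passes = pass && res$p_value <= crit$p_max,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(dataset_id = character(), gene = character(),
                          rho = numeric(), p_value = numeric(),
                          n_samples = integer(), passes = logical()))
    do.call(rbind, rows)
}

#' Tumor-versus-normal alteration tests across cohorts
#'
#' For every cohort with at least 3 normal and 3 primary-tumor samples
#' measuring the gene, runs a two-sided Mann-Whitney comparison of
#' tumor versus normal isoform-collapsed signals. A record's direction
#' is \code{down} when the tumor median is below the normal median at
#' \code{p <= p_max} (symmetrically \code{up}); otherwise \code{none}.
#' With \code{crit$alteration_direction = "any"}, only the majority
#' direction across a gene's significant cohorts counts as passing, so
#' mixed directions never jointly accumulate.
#'
#' @inheritParams correlateWithAnchor
#' @return data.frame with one row per evaluable (cohort, gene):
#'   \code{dataset_id}, \code{gene}, \code{median_shift},
#'   \code{p_value}, \code{direction}, \code{passes}.
#' @export
tumorVsNormal <- function(cohorts, map, candidates,
                          crit = screenCriteria()) {
    rows <- list()
    for (ds in cohorts) {
        cd <- SummarizedExperiment::colData(ds)
        if (!"tissue_class" %in% colnames(cd)) next
        tum <- colnames(ds)[cd$tissue_class == "primary_tumor"]
        nor <- colnames(ds)[cd$tissue_class == "normal"]
        if (length(tum) < 3L || length(nor) < 3L) next
        G <- .collapseAllGenes(ds, map)
        for (g in candidates) {
            gkey <- tolower(trimws(g))
            if (!gkey %in% rownames(G)) next
            sig <- G[gkey, ]
            mw <- tryCatch(
                suppressWarnings(mannWhitneyU(sig[tum], sig[nor])),
                error = function(e) NULL)
            if (is.null(mw)) next
            dir <- if (mw$p_value > crit$p_max) "none"
                   else if (mw$median_shift < 0) "down"
                   else if (mw$median_shift > 0) "up"
                   else "none"
            rows[[length(rows) + 1L]] <- data.frame(
                dataset_id = datasetId(ds), gene = g,
                median_shift = mw$median_shift, p_value = mw$p_value,
                direction = dir, passes = NA, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(dataset_id = character(), gene = character(),
                          median_shift = numeric(), p_value = numeric(),
                          direction = character(), passes = logical()))
    alt <- do.call(rbind, rows)
    for (g in unique(alt$gene)) {
        i <- alt$gene == g
        req <- crit$alteration_direction
        if (req == "any") {
            sigdir <- alt$direction[i & alt$direction != "none"]
            if (length(sigdir)) {
                tab <- table(factor(sigdir, c("down", "up")))
                req <- if (tab["up"] > tab["down"]) "up" else "down"
            }
        }
        alt$passes[i] <- alt$p_value[i] <= crit$p_max &
            alt$direction[i] == req
    }
    alt
}

#' Aggregate per-cohort records into consistency verdicts
#'
#' A gene is selected when it passes the correlation criterion in
#' strictly more than \code{consistency_fraction} of its evaluable
#' cohorts AND the alteration criterion in strictly more than
#' \code{consistency_fraction} of its evaluable cohorts. Genes with an
#' empty denominator on either arm are not evaluable and are excluded.
#' The verdict table is sorted by the correlation pass fraction
#' (descending), then gene label.
#'
#' @param corr correlation records from [correlateWithAnchor()].
#' @param alt alteration records from [tumorVsNormal()].
#' @param crit a [screenCriteria()].
#' @return data.frame with columns \code{gene}, \code{n_evaluable_corr},
#'   \code{n_pass_corr}, \code{n_evaluable_alt}, \code{n_pass_alt},
#'   \code{selected}.
#' @export
aggregateScreen <- function(corr, alt, crit = screenCriteria()) {
    if (!nrow(corr) || !nrow(alt))
        stop("both correlation and alteration record sets are required")
    genes <- intersect(unique(corr$gene), unique(alt$gene))
    out <- do.call(rbind, lapply(genes, function(g) {
        ci <- corr$gene == g; ai <- alt$gene == g
        data.frame(gene = g,
                   n_evaluable_corr = sum(ci),
                   n_pass_corr = sum(corr$passes[ci]),
                   n_evaluable_alt = sum(ai),
                   n_pass_alt = sum(alt$passes[ai]),
                   stringsAsFactors = FALSE)
    }))
    f <- crit$consistency_fraction
    out$selected <- out$n_pass_corr > f * out$n_evaluable_corr &
        out$n_pass_alt > f * out$n_evaluable_alt
    frac <- out$n_pass_corr / out$n_evaluable_corr
    out <- out[order(-frac, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
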