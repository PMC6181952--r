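#' Fit a two-group linear contrast per probe
#'
#' Ordinary least squares for a treated-versus-control design on
#' log2-scale data: per probe, the log2 fold change is the treated mean
#' minus the control mean, with the pooled within-group variance on
#' \code{n_treated + n_control - 2} residual degrees of freedom.
#'
#' @param ds an [ExpressionCohort-class] on the log2 scale.
#' @param group_labels character vector over samples, values
#'   \code{"treated"} / \code{"control"}, each group with >= 2 samples.
#' @return List with vectors \code{log2_fc}, \code{s_sq}, and scalars
#'   \code{residual_df}, \code{n_treated}, \code{n_control},
#'   \code{probe_id}.
#' @export
fitTwoGroup <- function(ds, group_labels) {
    if (exprScale(ds) != "log2")
        stop("scale error: differential expression expects log2 data")
    if (length(group_labels) != ncol(ds))
        stop("design error: one group label per sample required")
    t_idx <- group_labels == "treated"
    c_idx <- group_labels == "control"
    nt <- sum(t_idx); nc <- sum(c_idx)
    if (nt < 2L || nc < 2L)
        stop("design error: each group needs >= 2 samples")
    m <- signalMatrix(ds)
    mt <- rowMeans(m[, t_idx, drop = FALSE])
    mc <- rowMeans(m[, c_idx, drop = FALSE])
    ssq_t <- rowSums((m[, t_idx, drop = FALSE] - mt)^2)
    ssq_c <- rowSums((m[, c_idx, drop = FALSE] - mc)^2)
    df <- nt + nc - 2L
    list(probe_id = rownames(m), log2_fc = mt - mc,
         s_sq = (ssq_t + ssq_c) / df, residual_df = df,
         n_treated = nt, n_control = nc)
}

# internal: inverse of trigamma by Newton iteration on the strictly
# decreasing trigamma (in terms of y = trigamma(x), solve for x > 0)
.trigammaInverse <- function(y) {
    if (y <= 0) return(Inf)
    x <- 0.5 + 1 / y   # good starting point: trigamma(x) ~ 1/x + 1/(2x^2)
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2L)
        x <- x + dif
        if (x <= 0) x <- 1e-8
        if (abs(dif) < 1e-10 * x) break
    }
    x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled-inverse-chi-square prior to the
#' per-probe residual variances, worked on \code{z = log(s^2)}: the
#' prior degrees of freedom solve
#' \code{trigamma(d0/2) = var(z) - trigamma(df/2)} by monotone Newton
#' inversion of the trigamma function, and the prior variance follows
#' from \code{mean(z)} via the digamma offsets. When the observed
#' log-variance dispersion does not exceed the sampling dispersion,
#' \code{d0 = Inf} (no excess dispersion) and \code{s0_sq} is the
#' bias-corrected geometric mean of the variances.
#'
#' Probes with zero variance are excluded from the moment fit (they
#' carry no log-variance information); all-zero variances are an error.
#'
#' @param s_sq per-probe residual variances (>= 0).
#' @param residual_df shared residual degrees of freedom.
#' @return List of class \code{"ModeratedTParams"} with \code{d0},
#'   \code{s0_sq}.
#' @export
estimateVariancePrior <- function(s_sq, residual_df) {
    pos <- s_sq[s_sq > 0 & is.finite(s_sq)]
    if (!length(pos))
        stop("degenerate-data error: all residual variances are zero")
    if (length(pos) < 50L)
        warning("fewer than 50 positive variances; prior estimate is ",
                "unstable")
    z <- log(pos)
    df2 <- residual_df / 2
    excess <- stats::var(z) - trigamma(df2)
    if (length(z) < 2L || !is.finite(excess) || excess <= 0) {
        d0 <- Inf
        log_s0 <- mean(z) - digamma(df2) + log(df2)
    } else {
        d0 <- 2 * .trigammaInverse(excess)
        log_s0 <- mean(z) - digamma(df2) + log(df2) +
            digamma(d0 / 2) - log(d0 / 2)
    }
    structure(list(d0 = d0, s0_sq = exp(log_s0)),
              class = "ModeratedTParams")
}

#' Moderated t-statistics with empirical-Bayes shrunken variances
#'
#' The posterior variance is the prior-weighted combination
#' \code{(d0*s0_sq + df*s_sq) / (d0 + df)} and the moderated t is the
#' fold change over its shrunken standard error, tested on
#' \code{d0 + df} degrees of freedom. \code{d0 = 0} reduces exactly to
#' the ordinary pooled two-sample t; \code{d0 = Inf} uses the prior
#' variance with the normal limit.
#'
#' @param fit output of [fitTwoGroup()].
#' @param params a \code{"ModeratedTParams"} list (\code{d0},
#'   \code{s0_sq}), e.g. from [estimateVariancePrior()].
#' @return List with vectors \code{t_mod}, \code{p_value}, and scalar
#'   \code{df_total}.
#' @export
moderatedTTest <- function(fit, params) {
    d0 <- params$d0; s0 <- params$s0_sq
    df <- fit$residual_df
    if (d0 < 0) stop("d0 must be nonnegative")
    if (d0 > 0 && (!is.finite(s0) || s0 <= 0))
        stop("s0_sq must be positive when d0 > 0")
    s_tilde <- if (is.infinite(d0)) rep(s0, length(fit$s_sq))
               else if (d0 == 0) fit$s_sq
               else (d0 * s0 + df * fit$s_sq) / (d0 + df)
    se <- sqrt(s_tilde * (1 / fit$n_treated + 1 / fit$n_control))
    t_mod <- ifelse(se > 0, fit$log2_fc / se,
                    ifelse(fit$log2_fc == 0, 0, sign(fit$log2_fc) * Inf))
    df_total <- d0 + df
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    list(t_mod = t_mod, p_value = p, df_total = df_total)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with running-minimum monotonicity, clipped to 1;
#' the input order is preserved.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p_values) {
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
        stop("domain error: p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}

#' Run the full two-group moderated-t differential expression pipeline
#'
#' Fits the two-group contrast, estimates the variance prior (unless
#' \code{params} is supplied, e.g. \code{d0 = 0} for the classical
#' pooled t), computes moderated t p-values, adjusts them by
#' Benjamini-Hochberg, and attaches signed linear fold changes
#' (\code{2^log2_fc}, reported as \code{-2^(-log2_fc)} for ratios below
#' 1, so the magnitude is always >= 1).
#'
#' @inheritParams fitTwoGroup
#' @param map optional probe map for gene annotation.
#' @param params optional \code{"ModeratedTParams"} override.
#' @return data.frame of class \code{"DEResult"}: \code{probe_id},
#'   \code{gene_symbol}, \code{log2_fc}, \code{linear_fc}, \code{s_sq},
#'   \code{t_mod}, \code{p_value}, \code{adj_p}.
#' @export
runModeratedDE <- function(ds, group_labels, map = NULL, params = NULL) {
    fit <- fitTwoGroup(ds, group_labels)
    if (is.null(params))
        params <- estimateVariancePrior(fit$s_sq, fit$residual_df)
    mt <- moderatedTTest(fit, params)
    gene <- rep(NA_character_, length(fit$probe_id))
    if (!is.null(map)) {
        idx <- match(fit$probe_id, map$probe_id)
        gene <- map$gene_symbol[idx]
    }
    lfc <- fit$log2_fc
    res <- data.frame(probe_id = fit$probe_id, gene_symbol = gene,
                      log2_fc = lfc,
                      linear_fc = ifelse(lfc >= 0, 2^lfc, -2^(-lfc)),
                      s_sq = fit$s_sq, t_mod = mt$t_mod,
                      p_value = mt$p_value,
                      adj_p = bhAdjust(mt$p_value),
                      stringsAsFactors = FALSE)
    attr(res, "params") <- params
    attr(res, "df_total") <- mt$df_total
    class(res) <- c("DEResult", "data.frame")
    res
}

#' Differential-expression selection criteria
#'
#' @param adj_p_max adjusted-p ceiling (strict); default 0.05.
#' @param fc_min minimum linear fold-change magnitude (> 1);
#'   default 1.5.
#' @return A validated list of class \code{"DESelectionCriteria"}.
#' @export
deSelectionCriteria <- function(adj_p_max = 0.05, fc_min = 1.5) {
    stopifnot(adj_p_max > 0, adj_p_max <= 1, fc_min > 1)
    structure(list(adj_p_max = adj_p_max, fc_min = fc_min),
              class = "DESelectionCriteria")
}

#' Select differentially expressed probes and candidate genes
#'
#' Two staged selections: \code{significant} probes have
#' \code{adj_p < adj_p_max}; \code{fc_filtered} probes are additionally
#' required to reach \code{|linear_fc| >= fc_min}. Candidate genes are
#' the unique annotated gene symbols among the fold-change-filtered
#' probes (unannotated probes stay in the probe lists but contribute no
#' gene). Up/down counts refer to the significant probes.
#'
#' @param results a \code{"DEResult"} from [runModeratedDE()].
#' @param crit a [deSelectionCriteria()].
#' @return List with \code{significant} (probe ids),
#'   \code{fc_filtered} (probe ids), \code{candidate_genes},
#'   \code{n_up}, \code{n_down}.
#' @export
selectDECandidates <- function(results, crit = deSelectionCriteria()) {
    sig <- results$adj_p < crit$adj_p_max
    fcf <- sig & abs(results$linear_fc) >= crit$fc_min
    genes <- unique(results$gene_symbol[fcf])
    genes <- genes[!is.na(genes) & genes != ""]
    list(significant = results$probe_id[sig],
         fc_filtered = results$probe_id[fcf],
         candidate_genes = sort(genes),
         n_up = sum(sig & results$log2_fc > 0),
         n_down = sum(sig & results$log2_fc < 0))
}
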