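#' Configuration of the synthetic multi-cohort world
#'
#' Describes a seeded simulated study: several expression cohorts with
#' normal and primary-tumor samples, an anchor gene, planted candidate
#' genes whose tumor-sample expression follows a bivariate-Gaussian
#' latent model calibrated so the population Spearman correlation with
#' the anchor equals \code{target_rho} (via the Gaussian
#' Pearson-Spearman relation \code{rho_P = 2 sin(pi rho_S / 6)}),
#' tumor-versus-normal log2 shifts, isoform-level probe duplication
#' with independent probe noise, array detection p-values, and
#' disease-free-survival times from an exponential
#' proportional-hazards model with independent uniform censoring.
#'
#' Each planted candidate is present (measured, correlated and
#' shifted) in its first \code{n_active} cohorts and absent from the
#' remaining cohorts' probe sets, so those cohorts do not enter the
#' gene's consistency denominator -- mirroring real multi-platform
#' studies where not every gene is measured everywhere. The latent
#' correlation is inflated to compensate for the independent isoform
#' probe noise, so the target Spearman rho holds for the
#' isoform-collapsed gene signal that downstream analyses actually
#' use.
#'
#' @param n_cohorts number of cohorts; default 7.
#' @param n_normal,n_tumor samples per cohort; defaults 12 and 50.
#' @param n_genes total genes per cohort (incl. anchor and planted);
#'   default 200.
#' @param isoform_range integer range of probes per gene; default
#'   \code{c(1, 4)}.
#' @param anchor_gene anchor label; default \code{"ANCHOR"}.
#' @param planted data.frame with columns \code{gene},
#'   \code{target_rho} (|rho| < 1), \code{tumor_shift} (log2 units),
#'   \code{n_active} (cohorts in which the gene is present). Default:
#'   one candidate with rho 0.45 and shift -1, present in 5 cohorts
#'   (or all cohorts when fewer than 5 are simulated).
#' @param base_mean baseline log2 expression; default 8.
#' @param noise_sd per-gene biological SD in log2 units; default 1.
#' @param iso_noise_sd independent per-probe noise SD; default 0.25.
#' @param detection_noise fraction of probes given detection p-values
#'   that never pass the 0.01 filter; default 0.05.
#' @param survival list with \code{baseline_hazard} (events per month),
#'   \code{coefficients} (named per-gene log-hazard per SD of
#'   expression; positive = protective expression when negative... sign
#'   convention: the linear predictor is
#'   \code{sum(coef * z_gene)}, so a negative coefficient makes high
#'   expression protective), \code{censoring_rate} target in [0, 1),
#'   \code{max_follow_up} (months; truncation counts as censoring).
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_cohorts = 7L, n_normal = 12L,
                            n_tumor = 50L, n_genes = 200L,
                            isoform_range = c(1L, 4L),
                            anchor_gene = "ANCHOR",
                            planted = NULL,
                            base_mean = 8, noise_sd = 1,
                            iso_noise_sd = 0.25,
                            detection_noise = 0.05,
                            survival = list(baseline_hazard = 0.02,
                                            coefficients = c(CAND01 = -0.5),
                                            censoring_rate = 0.5,
                                            max_follow_up = 120)) {
    if (is.null(planted))
        planted <- data.frame(gene = "CAND01", target_rho = 0.45,
                              tumor_shift = -1,
                              n_active = min(5L, n_cohorts),
                              stringsAsFactors = FALSE)
    stopifnot(n_cohorts >= 1, n_normal >= 3, n_tumor >= 3,
              n_genes >= nrow(planted) + 1,
              all(abs(planted$target_rho) < 1),
              all(planted$n_active <= n_cohorts),
              detection_noise >= 0, detection_noise < 1,
              survival$censoring_rate >= 0, survival$censoring_rate < 1,
              survival$baseline_hazard > 0, survival$max_follow_up > 0)
    structure(list(n_cohorts = as.integer(n_cohorts),
                   n_normal = as.integer(n_normal),
                   n_tumor = as.integer(n_tumor),
                   n_genes = as.integer(n_genes),
                   isoform_range = as.integer(isoform_range),
                   anchor_gene = anchor_gene, planted = planted,
                   base_mean = base_mean, noise_sd = noise_sd,
                   iso_noise_sd = iso_noise_sd,
                   detection_noise = detection_noise,
                   survival = survival),
              class = "SyntheticConfig")
}

# internal: deterministic sub-seed scheme -- one stream per
# (cohort, gene) so adding a gene never perturbs other genes' draws
.subSeed <- function(seed, cohort, item) {
    as.integer((as.numeric(seed) * 7919 + cohort * 524287 + item * 101) %%
               2147483647)
}

# internal: gene labels for a config (anchor, planted, then nulls)
.geneLabels <- function(cfg) {
    n_null <- cfg$n_genes - nrow(cfg$planted) - 1L
    c(cfg$anchor_gene, cfg$planted$gene,
      sprintf("NULL%04d", seq_len(n_null)))
}

#' Simulate the multi-cohort expression world
#'
#' Generates \code{n_cohorts} raw-intensity cohorts (intensities are
#' \code{2^log2value}, so the standard normalization chain recovers the
#' simulated scale), a shared probe-to-gene map with 1-4 isoform probes
#' per gene, per-sample clinical annotation including exponential
#' proportional-hazards disease-free survival for tumor samples, and
#' the planted ground truth. Fully reproducible from \code{seed}.
#'
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed.
#' @return List with \code{cohorts} (list of
#'   [ExpressionCohort-class]), \code{probe_map}, \code{ground_truth}
#'   (list with \code{per_gene} data.frame and \code{expected_selected}
#'   computed analytically from the configuration, never from the
#'   generated data).
#' @export
simulateCohorts <- function(cfg = syntheticConfig(), seed = 1L) {
    genes <- .geneLabels(cfg)
    n_s <- cfg$n_normal + cfg$n_tumor
    tumor <- c(rep(FALSE, cfg$n_normal), rep(TRUE, cfg$n_tumor))
    # shared probe map: isoform count per gene is cohort-independent
    set.seed(.subSeed(seed, 0L, 0L))
    n_iso <- sample(seq(cfg$isoform_range[1L], cfg$isoform_range[2L]),
                    length(genes), replace = TRUE)
    probe_map <- do.call(rbind, lapply(seq_along(genes), function(g)
        data.frame(probe_id = sprintf("%s_iso%d", genes[g],
                                      seq_len(n_iso[g])),
                   gene_symbol = genes[g],
                   isoform_label = sprintf("iso%d", seq_len(n_iso[g])),
                   stringsAsFactors = FALSE)))
    planted_idx <- match(cfg$planted$gene, genes)
    cohorts <- vector("list", cfg$n_cohorts)
    for (k in seq_len(cfg$n_cohorts)) {
        sample_ids <- sprintf("C%d_S%03d", k, seq_len(n_s))
        set.seed(.subSeed(seed, k, 1L))
        z_anchor <- stats::rnorm(n_s)
        probe_rows <- vector("list", length(genes))
        # attenuation of the collapsed-signal correlation caused by
        # the independent isoform noise (mean over k probes)
        atten <- function(g) sqrt(1 + cfg$iso_noise_sd^2 /
                                  (n_iso[g] * cfg$noise_sd^2))
        for (g in seq_along(genes)) {
            set.seed(.subSeed(seed, k, 1L + g))
            pi_ <- match(g, planted_idx)
            present <- is.na(pi_) || k <= cfg$planted$n_active[pi_]
            if (!present) {
                probe_rows[g] <- list(NULL)
                next
            }
            if (g == 1L) {
                z <- z_anchor
                shift <- 0
            } else {
                eps <- stats::rnorm(n_s)
                if (!is.na(pi_)) {
                    rho_p <- 2 * sin(pi * cfg$planted$target_rho[pi_] /
                                     6) * atten(1L) * atten(g)
                    if (abs(rho_p) >= 1)
                        stop("configuration error: target correlation ",
                             "infeasible after isoform-noise ",
                             "compensation")
                    z <- rho_p * z_anchor + sqrt(1 - rho_p^2) * eps
                    shift <- cfg$planted$tumor_shift[pi_]
                } else {
                    z <- eps
                    shift <- 0
                }
            }
            val <- cfg$base_mean + cfg$noise_sd * z +
                shift * as.numeric(tumor)
            iso <- matrix(rep(val, each = n_iso[g]), nrow = n_iso[g]) +
                matrix(stats::rnorm(n_iso[g] * n_s, 0,
                                    cfg$iso_noise_sd),
                       nrow = n_iso[g])
            rownames(iso) <- sprintf("%s_iso%d", genes[g],
                                     seq_len(n_iso[g]))
            probe_rows[[g]] <- iso
        }
        m <- do.call(rbind, probe_rows)
        colnames(m) <- sample_ids
        # detection p-values: a noise fraction of probes never detected
        set.seed(.subSeed(seed, k, length(genes) + 10L))
        n_probes <- nrow(m)
        noisy <- sample(n_probes, round(cfg$detection_noise * n_probes))
        dp <- matrix(stats::runif(n_probes * n_s, 0, 0.009),
                     n_probes, n_s, dimnames = dimnames(m))
        if (length(noisy))
            dp[noisy, ] <- stats::runif(length(noisy) * n_s, 0.02, 0.95)
        clin <- S4Vectors::DataFrame(
            tissue_class = ifelse(tumor, "primary_tumor", "normal"),
            row.names = sample_ids)
        ds <- ExpressionCohort(2^m, datasetId = sprintf("cohort%d", k),
                               scale = "raw_intensity", detectionP = dp,
                               colData = clin)
        ds <- .addSurvival(ds, cfg, probe_map,
                           seed = .subSeed(seed, k,
                                           length(genes) + 20L))
        cohorts[[k]] <- ds
    }
    per_gene <- data.frame(gene = genes,
                           target_rho = 0, tumor_shift = 0,
                           n_active = 0L,
                           log_hazard = 0, stringsAsFactors = FALSE)
    per_gene$target_rho[planted_idx] <- cfg$planted$target_rho
    per_gene$tumor_shift[planted_idx] <- cfg$planted$tumor_shift
    per_gene$n_active[planted_idx] <- cfg$planted$n_active
    coefs <- cfg$survival$coefficients
    per_gene$log_hazard[match(names(coefs), genes)] <- unname(coefs)
    list(cohorts = cohorts, probe_map = probe_map,
         ground_truth = list(per_gene = per_gene,
                             expected_selected = expectedSelected(cfg)))
}

#' Genes that satisfy the screen criteria by construction
#'
#' Evaluates the screen's selection rule on the configuration's
#' population-level truths: a planted gene is expected to be selected
#' when its target Spearman correlation clears \code{rho_min} and its
#' tumor shift matches the required direction in the cohorts where it
#' is present (absent cohorts do not enter the denominator, so a gene
#' whose planted effects hold wherever it is measured satisfies the
#' strict-majority rule by construction). This is analytic -- no
#' generated data are consulted.
#'
#' @param cfg a [syntheticConfig()].
#' @param crit a [screenCriteria()].
#' @return Character vector of gene labels.
#' @export
expectedSelected <- function(cfg, crit = screenCriteria()) {
    p <- cfg$planted
    rho_ok <- if (crit$require_positive_rho)
        p$target_rho >= crit$rho_min else abs(p$target_rho) >= crit$rho_min
    dir_ok <- switch(crit$alteration_direction,
                     down = p$tumor_shift < 0,
                     up = p$tumor_shift > 0,
                     any = p$tumor_shift != 0)
    p$gene[rho_ok & dir_ok & p$n_active >= 1L]
}

# internal: attach exponential PH disease-free survival to the tumor
# samples of a cohort (on the log2 scale of the raw intensities)
.addSurvival <- function(ds, cfg, map, seed) {
    sv <- cfg$survival
    cd <- SummarizedExperiment::colData(ds)
    tum <- which(cd$tissue_class == "primary_tumor")
    cd$dfs_time <- NA_real_
    cd$dfs_event <- NA_real_
    if (length(tum) >= 2L && length(sv$coefficients)) {
        logds <- if (exprScale(ds) == "log2") ds
                 else .setSignal(ds, log2(signalMatrix(ds)),
                                 scale = "log2")
        lp <- rep(0, length(tum))
        for (g in names(sv$coefficients)) {
            if (!.geneMeasured(logds, map, g)) next
            sig <- collapseIsoforms(logds, map, g)[tum]
            lp <- lp + sv$coefficients[[g]] * as.numeric(scale(sig))
        }
    } else lp <- rep(0, length(tum))
    lambda <- sv$baseline_hazard * exp(lp)
    set.seed(seed)
    t_event <- stats::rexp(length(tum), rate = lambda)
    u <- .calibrateCensoring(lambda, sv$max_follow_up,
                             sv$censoring_rate)
    c_unif <- if (is.finite(u)) stats::runif(length(tum), 0, u)
              else rep(Inf, length(tum))
    horizon <- pmin(c_unif, sv$max_follow_up)
    cd$dfs_time[tum] <- pmin(t_event, horizon)
    cd$dfs_event[tum] <- as.numeric(t_event <= horizon)
    SummarizedExperiment::colData(ds) <- cd
    ds
}

# internal: choose the uniform-censoring upper bound u so the expected
# censored fraction (uniform censoring + follow-up truncation) matches
# the target; exponential event times with rates `lambda`
.calibrateCensoring <- function(lambda, max_follow_up, target) {
    p_event <- function(u) {
        L <- pmin(u, max_follow_up)
        mean((1 - exp(-lambda * L)) -
             (1 / (u * lambda)) * (1 - exp(-lambda * L) *
                                   (1 + lambda * L)))
    }
    floor_cens <- mean(exp(-lambda * max_follow_up))
    if (target <= floor_cens + 1e-9) {
        if (target > 0 && target < floor_cens - 0.05)
            warning("target censoring rate below the follow-up ",
                    "truncation floor; no uniform censoring applied")
        return(Inf)
    }
    f <- function(log_u) (1 - p_event(exp(log_u))) - target
    stats::uniroot(f, lower = -10, upper = 25, tol = 1e-8)$root |> exp()
}

#' Simulate a two-group perturbation array experiment
#'
#' Per-probe variances are drawn from a scaled-inverse-chi-square prior
#' with \code{d0} prior degrees of freedom and prior variance
#' \code{s0_sq} (constant variances when \code{d0 = Inf}); the first
#' \code{n_de} probes receive a mean shift of \code{lfc} log2 units in
#' the treated group. A \code{detection_noise} fraction of probes is
#' given detection p-values that fail the standard filter. Data are on
#' the log2 scale, ready for [runModeratedDE()].
#'
#' @param n_probes number of probes; default 1000.
#' @param n_de number of truly shifted probes.
#' @param lfc true treated-minus-control shift (log2).
#' @param n_treated,n_control samples per group; defaults 3 and 3.
#' @param d0,s0_sq variance-prior parameters; defaults 4 and 0.05.
#' @param probes_per_gene probes mapping to each annotated gene;
#'   default 1.
#' @param detection_noise fraction of never-detected probes; default 0.
#' @param base_mean baseline log2 intensity; default 8.
#' @param seed integer seed.
#' @return List with \code{ds} (log2-scale [ExpressionCohort-class]
#'   with \code{detectionP}), \code{groups} (label vector),
#'   \code{probe_map}, \code{true_de} (logical per probe).
#' @export
simulatePerturbationArrays <- function(n_probes = 1000L, n_de = 0L,
                                       lfc = 0, n_treated = 3L,
                                       n_control = 3L, d0 = 4,
                                       s0_sq = 0.05,
                                       probes_per_gene = 1L,
                                       detection_noise = 0,
                                       base_mean = 8, seed = 1L) {
    stopifnot(n_de <= n_probes, n_treated >= 2, n_control >= 2)
    set.seed(seed)
    n_s <- n_treated + n_control
    sigma2 <- if (is.infinite(d0)) rep(s0_sq, n_probes)
              else s0_sq * d0 / stats::rchisq(n_probes, df = d0)
    m <- base_mean + matrix(stats::rnorm(n_probes * n_s), n_probes,
                            n_s) * sqrt(sigma2)
    groups <- rep(c("treated", "control"), c(n_treated, n_control))
    true_de <- seq_len(n_probes) <= n_de
    m[true_de, groups == "treated"] <- m[true_de, groups == "treated",
                                         drop = FALSE] + lfc
    probe_ids <- sprintf("P%05d", seq_len(n_probes))
    dimnames(m) <- list(probe_ids,
                        sprintf("%s%d", substr(groups, 1, 1),
                                seq_len(n_s)))
    dp <- matrix(stats::runif(n_probes * n_s, 0, 0.009), n_probes, n_s,
                 dimnames = dimnames(m))
    noisy <- sample(n_probes, round(detection_noise * n_probes))
    if (length(noisy))
        dp[noisy, ] <- stats::runif(length(noisy) * n_s, 0.02, 0.95)
    probe_map <- data.frame(
        probe_id = probe_ids,
        gene_symbol = sprintf("GENE%05d",
                              ceiling(seq_len(n_probes) /
                                      probes_per_gene)),
        isoform_label = NA_character_, stringsAsFactors = FALSE)
    list(ds = ExpressionCohort(m, "perturbation", scale = "log2",
                               detectionP = dp),
         groups = groups, probe_map = probe_map, true_de = true_de)
}

#' Simulate one survival cohort on given expression data
#'
#' Standalone access to the proportional-hazards survival generator:
#' attaches disease-free-survival fields to the tumor samples of an
#' existing cohort using the configuration's hazard model (linear
#' predictor = sum of coefficient times standardized collapsed gene
#' signal; exponential baseline; uniform censoring calibrated to the
#' target rate; follow-up truncation counts as censoring).
#'
#' @param cfg a [syntheticConfig()].
#' @param ds an [ExpressionCohort-class] with \code{tissue_class}.
#' @param map probe map covering the coefficient-bearing genes.
#' @param seed integer seed.
#' @return The cohort with \code{dfs_time} / \code{dfs_event} columns.
#' @export
simulateSurvivalCohort <- function(cfg, ds, map, seed = 1L) {
    for (g in names(cfg$survival$coefficients))
        if (!.geneMeasured(ds, map, g))
            stop("coefficient-bearing gene '", g,
                 "' not measured in the cohort")
    .addSurvival(ds, cfg, map, seed)
}
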