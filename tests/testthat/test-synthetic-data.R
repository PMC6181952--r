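test_that("generators are pure functions of (config, seed)", {
    cfg <- syntheticConfig(n_cohorts = 2, n_genes = 25)
    w1 <- simulateCohorts(cfg, seed = 123)
    w2 <- simulateCohorts(cfg, seed = 123)
    expect_identical(signalMatrix(w1$cohorts[[1]]),
                     signalMatrix(w2$cohorts[[1]]))
    expect_identical(
        as.data.frame(SummarizedExperiment::colData(w1$cohorts[[2]])),
        as.data.frame(SummarizedExperiment::colData(w2$cohorts[[2]])))
    w3 <- simulateCohorts(cfg, seed = 124)
    expect_false(identical(signalMatrix(w1$cohorts[[1]]),
                           signalMatrix(w3$cohorts[[1]])))
    s1 <- simulatePerturbationArrays(n_probes = 50, seed = 9)
    s2 <- simulatePerturbationArrays(n_probes = 50, seed = 9)
    expect_identical(signalMatrix(s1$ds), signalMatrix(s2$ds))
})

test_that("adding genes does not perturb other genes' draws", {
    base <- syntheticConfig(n_cohorts = 1, n_genes = 20)
    more <- syntheticConfig(n_cohorts = 1, n_genes = 30)
    w1 <- simulateCohorts(base, seed = 77)
    w2 <- simulateCohorts(more, seed = 77)
    shared <- intersect(rownames(w1$cohorts[[1]]),
                        rownames(w2$cohorts[[1]]))
    expect_gt(length(shared), 0)
    expect_identical(signalMatrix(w1$cohorts[[1]])[shared, ],
                     signalMatrix(w2$cohorts[[1]])[shared, ])
})

test_that("planted correlation is realized near its target", {
    # At n = 150 the Spearman estimate of a true rho of 0.45 has a
    # sampling SD near 0.07 (Fisher-z), so single-cohort estimates
    # land within +/- 0.10 about 85% of the time; the calibration
    # check is therefore on the mean across seeds, plus that
    # theory-level coverage bound.
    cfg <- syntheticConfig(
        n_cohorts = 1, n_normal = 3, n_tumor = 150, n_genes = 10,
        planted = data.frame(gene = "CAND01", target_rho = 0.45,
                             tumor_shift = 0, n_active = 1))
    rhos <- vapply(1:60, function(s) {
        w <- simulateCohorts(cfg, seed = s)
        ds <- log2Transform(w$cohorts[[1]])
        tum <- colnames(ds)[SummarizedExperiment::colData(
            ds)$tissue_class == "primary_tumor"]
        a <- collapseIsoforms(ds, w$probe_map, "ANCHOR")[tum]
        g <- collapseIsoforms(ds, w$probe_map, "CAND01")[tum]
        spearmanTest(a, g)$rho
    }, numeric(1))
    expect_lt(abs(mean(rhos) - 0.45), 0.03)
    expect_gte(mean(abs(rhos - 0.45) <= 0.10), 0.75)
})

test_that("presence masks remove the gene from inactive cohorts only", {
    cfg <- syntheticConfig(n_cohorts = 4, n_genes = 15,
                           planted = data.frame(gene = "CAND01",
                                                target_rho = 0.45,
                                                tumor_shift = -1,
                                                n_active = 2))
    w <- simulateCohorts(cfg, seed = 5)
    measured <- vapply(w$cohorts, function(ds)
        any(grepl("^CAND01_", rownames(ds))), logical(1))
    expect_identical(measured, c(TRUE, TRUE, FALSE, FALSE))
    expect_identical(w$ground_truth$expected_selected, "CAND01")
})

test_that("detection noise removes about the configured probe fraction", {
    cfg <- syntheticConfig(n_cohorts = 1, n_genes = 150,
                           detection_noise = 0.1)
    w <- simulateCohorts(cfg, seed = 3)
    ds <- w$cohorts[[1]]
    kept <- detectionFilter(ds)
    frac_removed <- 1 - nrow(kept) / nrow(ds)
    expect_gt(frac_removed, 0.06); expect_lt(frac_removed, 0.14)
})

test_that("survival generator calibrates censoring and responds to hazards", {
    cfg <- syntheticConfig(
        n_cohorts = 1, n_normal = 3, n_tumor = 200, n_genes = 10,
        planted = data.frame(gene = "PROG", target_rho = 0,
                             tumor_shift = 0, n_active = 1),
        survival = list(baseline_hazard = 0.02,
                        coefficients = c(PROG = -0.8),
                        censoring_rate = 0.5, max_follow_up = 120))
    cens <- vapply(1:30, function(s) {
        w <- simulateCohorts(cfg, seed = s)
        cd <- SummarizedExperiment::colData(w$cohorts[[1]])
        mean(cd$dfs_event[!is.na(cd$dfs_event)] == 0)
    }, numeric(1))
    expect_lt(abs(mean(cens) - 0.5), 0.05)
    # a stronger protective coefficient lengthens event times for the
    # high-expression samples (monotone hazard response)
    cfg2 <- cfg; cfg2$survival$coefficients <- c(PROG = -2)
    med_ev <- function(cc) {
        w <- simulateCohorts(cc, seed = 42)
        ds <- log2Transform(w$cohorts[[1]])
        cd <- SummarizedExperiment::colData(ds)
        sig <- collapseIsoforms(ds, w$probe_map, "PROG")
        hi <- sig > stats::median(sig)
        tt <- cd$dfs_time[hi & cd$tissue_class == "primary_tumor" &
                          cd$dfs_event == 1]
        stats::median(tt, na.rm = TRUE)
    }
    expect_gt(med_ev(cfg2), med_ev(cfg))
})

test_that("null perturbation arrays yield calibrated false positives", {
    fpr <- vapply(1:20, function(s) {
        sim <- simulatePerturbationArrays(n_probes = 400, n_de = 0,
                                          d0 = 4, s0_sq = 0.05,
                                          seed = s)
        de <- runModeratedDE(sim$ds, sim$groups)
        mean(de$adj_p < 0.05)
    }, numeric(1))
    expect_lte(max(fpr), 0.02)
    # strong planted shifts are recovered by both filters
    pow <- vapply(1:10, function(s) {
        sim <- simulatePerturbationArrays(n_probes = 400, n_de = 40,
                                          lfc = 2, d0 = 4,
                                          s0_sq = 0.05, seed = s)
        de <- runModeratedDE(sim$ds, sim$groups)
        sel <- selectDECandidates(de)
        mean(sim$probe_map$probe_id[sim$true_de] %in% sel$fc_filtered)
    }, numeric(1))
    expect_gt(mean(pow), 0.9)
})
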