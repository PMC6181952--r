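test_that("two-group fit recovers fold change and pooled variance", {
    m <- rbind(p1 = c(3, 5, 1, 3), p2 = c(2, 2, 2, 2))
    colnames(m) <- c("t1", "t2", "c1", "c2")
    ds <- ExpressionCohort(m, "de", scale = "log2")
    groups <- c("treated", "treated", "control", "control")
    fit <- fitTwoGroup(ds, groups)
    expect_equal(unname(fit$log2_fc["p1"]), 2)
    expect_equal(unname(fit$s_sq["p1"]), 2)   # pooled var by hand
    expect_equal(fit$residual_df, 2)
    expect_equal(unname(fit$log2_fc["p2"]), 0)
    expect_error(fitTwoGroup(ds, c("treated", "treated", "treated",
                                   "control")), "design error")
})

test_that("moderated t matches the hand example and its two limits", {
    fit <- list(log2_fc = 1, s_sq = 0.25, residual_df = 4,
                n_treated = 3, n_control = 3)
    mt <- moderatedTTest(fit, list(d0 = 4, s0_sq = 0.25))
    expect_equal(mt$t_mod, 1 / sqrt(0.25 * (2 / 3)), tolerance = 1e-12)
    expect_equal(mt$df_total, 8)
    # d0 = 0 reduces exactly to the classical pooled two-sample t
    set.seed(21)
    sim <- simulatePerturbationArrays(n_probes = 200, n_de = 20,
                                      lfc = 1, seed = 21)
    f <- fitTwoGroup(sim$ds, sim$groups)
    mt0 <- moderatedTTest(f, list(d0 = 0, s0_sq = 1))
    tcl <- f$log2_fc / sqrt(f$s_sq * (1 / 3 + 1 / 3))
    expect_equal(mt0$t_mod, tcl, tolerance = 1e-12)
    expect_equal(mt0$p_value, 2 * pt(-abs(tcl), 4), tolerance = 1e-12)
    # d0 = Inf uses the prior variance with normal-limit df
    mtI <- moderatedTTest(list(log2_fc = 1, s_sq = 99, residual_df = 4,
                               n_treated = 3, n_control = 3),
                          list(d0 = Inf, s0_sq = 0.25))
    expect_equal(mtI$t_mod, 1 / sqrt(0.25 * (2 / 3)))
    expect_equal(mtI$p_value,
                 2 * pnorm(-abs(mtI$t_mod)), tolerance = 1e-12)
    # zero fold change gives t = 0, p = 1
    mtz <- moderatedTTest(list(log2_fc = 0, s_sq = 0.25,
                               residual_df = 4, n_treated = 3,
                               n_control = 3),
                          list(d0 = 4, s0_sq = 0.25))
    expect_equal(mtz$t_mod, 0)
    expect_equal(mtz$p_value, 1)
})

test_that("variance-prior estimator recovers planted hyperparameters", {
    # equal variances carry no excess dispersion -> d0 = Inf
    prior <- suppressWarnings(estimateVariancePrior(rep(0.3, 10), 4))
    expect_identical(prior$d0, Inf)
    set.seed(31)
    s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 4) / 4
    est <- estimateVariancePrior(s2, 4)
    expect_gt(est$d0, 2.5); expect_lt(est$d0, 6.5)
    expect_lt(abs(est$s0_sq - 0.05) / 0.05, 0.3)
    expect_warning(estimateVariancePrior(c(0.1, 0.2, 0.3), 4),
                   "fewer than 50")
    expect_error(estimateVariancePrior(rep(0, 5), 4),
                 "degenerate-data")
})

test_that("the estimator agrees with limma's eBayes on the same data", {
    set.seed(33)
    sim <- simulatePerturbationArrays(n_probes = 800, n_de = 40,
                                      lfc = 1.5, d0 = 6, s0_sq = 0.1,
                                      seed = 33)
    mine <- runModeratedDE(sim$ds, sim$groups)
    design <- stats::model.matrix(
        ~ factor(sim$groups, c("control", "treated")))
    ref <- limma::eBayes(limma::lmFit(signalMatrix(sim$ds), design))
    expect_equal(attr(mine, "params")$d0, ref$df.prior,
                 tolerance = 1e-6)
    expect_equal(attr(mine, "params")$s0_sq, ref$s2.prior,
                 tolerance = 1e-6)
    expect_equal(mine$p_value, unname(ref$p.value[, 2]),
                 tolerance = 1e-10)
    expect_equal(mine$log2_fc, unname(ref$coefficients[, 2]),
                 tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up hand example and bounds", {
    expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
                 c(0.02, 0.02, 0.04, 0.04))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_error(bhAdjust(c(0.5, 1.2)), "domain error")
    set.seed(41)
    p <- runif(200)
    adj <- bhAdjust(p)
    m <- length(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(1, m * p) + 1e-12))
    # monotone when input sorted ascending
    expect_true(!is.unsorted(bhAdjust(sort(p))))
})

test_that("DE selection separates significance from the fold-change cut", {
    res <- data.frame(
        probe_id = sprintf("p%d", 1:5),
        gene_symbol = c("G1", "G1", "G2", NA, "G3"),
        log2_fc = c(1, 0.9, -1.2, 2, 0.2),
        linear_fc = c(2^1, 2^0.9, -2^1.2, 2^2, 2^0.2),
        adj_p = c(0.01, 0.01, 0.02, 0.03, 0.2))
    sel <- selectDECandidates(res)
    expect_setequal(sel$significant, c("p1", "p2", "p3", "p4"))
    expect_setequal(sel$fc_filtered, c("p1", "p2", "p3", "p4"))
    # two probes on one gene collapse to one candidate; NA-annotated
    # probe stays in the probe list but adds no gene
    expect_identical(sel$candidate_genes, c("G1", "G2"))
    expect_equal(sel$n_up, 3); expect_equal(sel$n_down, 1)
    # |fc| below the cut is significant but not fc-filtered
    res$linear_fc[1] <- 1.3; res$log2_fc[1] <- log2(1.3)
    sel2 <- selectDECandidates(res)
    expect_true("p1" %in% sel2$significant)
    expect_false("p1" %in% sel2$fc_filtered)
})

test_that("signed linear fold changes always have magnitude >= 1", {
    set.seed(51)
    sim <- simulatePerturbationArrays(n_probes = 300, n_de = 30,
                                      lfc = -1, seed = 51)
    de <- runModeratedDE(sim$ds, sim$groups)
    expect_true(all(abs(de$linear_fc) >= 1))
    expect_true(all(sign(de$linear_fc) == sign(de$log2_fc) |
                    de$log2_fc == 0))
    expect_true(all(de$adj_p >= de$p_value - 1e-15))
})
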