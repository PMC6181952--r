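test_that("composite signal averages gene signals as specified", {
    ds <- twoGeneCohort()
    map <- toyProbeMap()
    # per-sample means: GA = (p1+p2)/2, GB = p3
    expect_equal(unname(compositeSignal(ds, map, "GA")), c(3, 5, 7, 9))
    expect_equal(unname(compositeSignal(ds, map, c("GA", "GB"))),
                 c(2, 3.5, 5, 6.5))
    # z-scored mean of two perfectly anticorrelated genes cancels
    m <- rbind(p1 = c(1, 2, 3, 4), p3 = c(8, 6, 4, 2))
    colnames(m) <- sprintf("s%d", 1:4)
    ds2 <- ExpressionCohort(m, "anti", scale = "log2")
    z <- compositeSignal(ds2, map, c("GA", "GB"),
                         stratificationConfig(
                             signature_combine = "zscore_mean"))
    expect_equal(unname(z), rep(0, 4), tolerance = 1e-12)
    expect_error(compositeSignal(ds, map, c("GA", "NOPE")), "NOPE")
})

test_that("quartile groups split at the interpolated lower quantile", {
    g <- quartileGroups(setNames(1:8, sprintf("s%d", 1:8)))
    expect_identical(unname(g), c("Q1", "Q1", rep("rest", 6)))
    # n = 131 tie-free signal -> |Q1| = 33 under the type-7 quantile
    set.seed(14)
    sig <- rnorm(131)
    expect_equal(sum(quartileGroups(sig) == "Q1"), 33L)
    expect_error(quartileGroups(rep(1, 10)), "degenerate")
    expect_error(quartileGroups(1:5), "sample-size")
    # boundary ties all go to Q1
    g2 <- quartileGroups(c(1, 1, 1, 1, 5, 6, 7, 8))
    expect_equal(sum(g2 == "Q1"), 4L)
})

test_that("km curve matches hand-computed product limits and survfit", {
    km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
    km2 <- kmCurve(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km2$survival, c(2 / 3, 0))
    expect_equal(km2$n_risk, c(3, 1))
    expect_warning(km3 <- kmCurve(c(1, 2), c(0, 0)), "no events")
    expect_equal(nrow(km3), 0L)
    # equals 1 - ECDF with no censoring
    set.seed(15)
    tt <- rexp(40)
    km4 <- kmCurve(tt, rep(1, 40))
    expect_equal(km4$survival,
                 1 - ecdf(tt)(km4$time), tolerance = 1e-12)
    # oracle: survival::survfit on censored data
    set.seed(16)
    time <- round(rexp(60, 0.1), 1); event <- rbinom(60, 1, 0.6)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    mine <- kmCurve(time, event)
    at <- fit$time %in% mine$time
    expect_equal(mine$survival, fit$surv[at], tolerance = 1e-12)
})

test_that("log-rank matches the hand example, survdiff, and is antisymmetric", {
    lr <- logrankHR(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
    expect_equal(lr$expected[1], 5 / 6)
    expect_equal(lr$chi_sq, 49 / 17, tolerance = 1e-12)
    expect_equal(lr$hazard_ratio, 3.8, tolerance = 1e-12)
    # label permutation of one pooled set: chi = 0, HR = 1
    t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 1, 1)
    lr0 <- logrankHR(t0, e0, t0, e0)
    expect_equal(lr0$chi_sq, 0)
    expect_equal(lr0$hazard_ratio, 1)
    # antisymmetry: swapping groups inverts HR, preserves chi and p
    set.seed(17)
    ta <- rexp(25, 0.2); ea <- rbinom(25, 1, 0.7)
    tb <- rexp(30, 0.1); eb <- rbinom(30, 1, 0.7)
    ab <- logrankHR(ta, ea, tb, eb)
    ba <- logrankHR(tb, eb, ta, ea)
    expect_equal(ab$chi_sq, ba$chi_sq, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$hazard_ratio, 1 / ba$hazard_ratio,
                 tolerance = 1e-12)
    # oracle: survival::survdiff O, E and chi-square
    sd <- survival::survdiff(
        survival::Surv(c(ta, tb), c(ea, eb)) ~
            rep(c("a", "b"), c(25, 30)))
    expect_equal(ab$observed, unname(sd$obs))
    expect_equal(ab$expected, unname(sd$exp), tolerance = 1e-12)
    expect_equal(ab$chi_sq, unname(sd$chisq), tolerance = 1e-12)
    # divergent HR is flagged when one group has no observed events
    lrD <- logrankHR(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(0, 0, 0))
    expect_true(lrD$hr_divergent)
    expect_equal(lrD$hazard_ratio, Inf)
    expect_error(logrankHR(numeric(), numeric(), 1, 1),
                 "degenerate-group")
})

test_that("dfs stratification composes signal, quartiles, km, and log-rank", {
    cfg <- syntheticConfig(
        n_cohorts = 1, n_normal = 3, n_tumor = 60, n_genes = 12,
        planted = data.frame(gene = "PROG", target_rho = 0,
                             tumor_shift = 0, n_active = 1),
        survival = list(baseline_hazard = 0.03,
                        coefficients = c(PROG = -1),
                        censoring_rate = 0.3, max_follow_up = 120))
    world <- simulateCohorts(cfg, seed = 19)
    ds <- normalizeCohort(world$cohorts[[1]])
    st <- stratifyDFS(ds, world$probe_map, "PROG")
    expect_s3_class(st$groups, "data.frame")
    expect_equal(st$n_q1 + st$n_rest, 60)
    # strongly protective gene: low-expression Q1 recurs faster
    expect_gt(st$logrank$hazard_ratio, 1)
    # single-gene signature equals the composite of one gene
    st2 <- stratifyDFS(ds, world$probe_map, c("PROG"))
    expect_equal(st2$logrank$chi_sq, st$logrank$chi_sq)
    # too few eligible samples is an error
    small <- ds[, 1:7]
    expect_error(stratifyDFS(small, world$probe_map, "PROG"),
                 "sample-size")
})
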