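test_that("spearman coefficient matches the classical formula and identity", {
    expect_equal(spearmanTest(1:5, 1:5)$rho, 1)
    # Sum d^2 = 4 at n = 5 -> rho = 1 - 6*4/(5*24) = 0.8
    res <- spearmanTest(1:5, c(2, 1, 4, 3, 5))
    expect_equal(res$rho, 0.8)
    # rank-based: invariant under strictly monotone transforms
    set.seed(2)
    x <- rnorm(30); y <- x + rnorm(30)
    expect_equal(spearmanTest(exp(x), y^3 + 5 * y)$rho,
                 spearmanTest(x, y)$rho)
    expect_error(spearmanTest(rep(1, 5), 1:5), "constant")
    expect_error(spearmanTest(1:2, 2:1), "sample-size")
})

test_that("exact spearman p comes from full rank-permutation enumeration", {
    # n = 3, y = x: only identity and reversal reach |rho| = 1 -> 2/6
    expect_equal(spearmanTest(1:3, 1:3)$p_value, 2 / 6)
    # cross-check the exact branch against cor.test's exact algorithm
    set.seed(7)
    for (n in c(5, 7)) {
        x <- rnorm(n); y <- rnorm(n)
        mine <- spearmanTest(x, y)
        ref <- cor.test(x, y, method = "spearman", exact = TRUE)
        expect_equal(mine$rho, unname(ref$estimate))
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
    # t-approximation branch against cor.test's asymptotic branch
    set.seed(8)
    x <- rnorm(40); y <- x + rnorm(40)
    mine <- spearmanTest(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("mann-whitney matches the exact enumeration and handles degeneracy", {
    res <- mannWhitneyU(c(4, 5, 6), c(1, 2, 3))
    expect_equal(res$u_statistic, 9)
    expect_equal(res$p_value, 2 / 20)   # 2 of C(6,3)=20 assignments
    expect_equal(res$median_shift, 3)
    # symmetric inputs give p = 1
    expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
    expect_warning(res0 <- mannWhitneyU(rep(2, 4), rep(2, 5)),
                   "degenerate")
    expect_equal(res0$p_value, 1)
    expect_error(mannWhitneyU(1:2, 1:5), "sample-size")
    # exact and approximate p agree closely at n = 8 per group
    set.seed(11)
    diffs <- replicate(40, {
        a <- rnorm(8); b <- rnorm(8)
        exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
        approx <- stats::wilcox.test(a, b, exact = FALSE,
                                     correct = TRUE)$p.value
        abs(exact - approx)
    })
    expect_lt(max(diffs), 0.02)
})

test_that("anchor correlation records apply inclusive thresholds", {
    crit <- screenCriteria()
    # construct a cohort pair with a known-perfect and a known-null gene
    set.seed(3)
    n <- 20
    anchor <- rnorm(n)
    m <- rbind(A_1 = anchor, G_1 = anchor + rnorm(n, 0, 0.3),
               H_1 = rnorm(n))
    colnames(m) <- sprintf("s%d", 1:n)
    map <- data.frame(probe_id = c("A_1", "G_1", "H_1"),
                      gene_symbol = c("ANC", "G", "H"))
    ds <- ExpressionCohort(m, "c1", scale = "log2",
        colData = data.frame(tissue_class = rep("primary_tumor", n),
                             row.names = colnames(m)))
    rec <- correlateWithAnchor(list(ds), map, "ANC", c("G", "H"), crit)
    expect_equal(nrow(rec), 2L)
    expect_true(rec$passes[rec$gene == "G"])
    expect_false(rec$passes[rec$gene == "H"])
    # boundary rho and p are inclusive; negative rho fails under the
    # positive-only default
    rec2 <- data.frame(rho = c(0.2, -0.4), p_value = c(0.05, 0.001))
    pass <- rec2$rho >= crit$rho_min & rec2$p_value <= crit$p_max
    expect_identical(pass, c(TRUE, FALSE))
    expect_error(correlateWithAnchor(list(ds), map, "NOPE", "G", crit),
                 "screen-configuration")
})

test_that("alteration records carry direction and respect the required one", {
    set.seed(5)
    nn <- 10; nt <- 12
    m <- rbind(D_1 = c(rnorm(nn, 8), rnorm(nt, 6)),   # down in tumor
               U_1 = c(rnorm(nn, 6), rnorm(nt, 8)),   # up in tumor
               F_1 = rnorm(nn + nt, 7))               # flat
    colnames(m) <- sprintf("s%d", seq_len(nn + nt))
    map <- data.frame(probe_id = rownames(m),
                      gene_symbol = c("D", "U", "F"))
    ds <- ExpressionCohort(m, "c1", scale = "log2",
        colData = data.frame(
            tissue_class = rep(c("normal", "primary_tumor"),
                               c(nn, nt)),
            row.names = colnames(m)))
    alt <- tumorVsNormal(list(ds), map, c("D", "U", "F"),
                         screenCriteria())
    expect_identical(alt$direction[alt$gene == "D"], "down")
    expect_identical(alt$direction[alt$gene == "U"], "up")
    expect_true(alt$passes[alt$gene == "D"])
    expect_false(alt$passes[alt$gene == "U"])  # wrong direction
    expect_false(alt$passes[alt$gene == "F"])  # not significant
    # with direction = any, both altered genes pass
    alt2 <- tumorVsNormal(list(ds), map, c("D", "U"),
                          screenCriteria(alteration_direction = "any"))
    expect_true(all(alt2$passes))
})

test_that("verdicts follow the strict-majority rule and ignore cohort order", {
    mk <- function(gene, n_eval, n_pass, what) {
        data.frame(dataset_id = sprintf("c%d", seq_len(n_eval)),
                   gene = gene, rho = 0.5, p_value = 0.01,
                   n_samples = 20, median_shift = -1,
                   direction = "down",
                   passes = seq_len(n_eval) <= n_pass)[,
            if (what == "corr") c("dataset_id", "gene", "rho",
                                  "p_value", "n_samples", "passes")
            else c("dataset_id", "gene", "median_shift", "p_value",
                   "direction", "passes")]
    }
    corr <- rbind(mk("g44", 7, 4, "corr"), mk("g37", 7, 3, "corr"),
                  mk("g46", 6, 4, "corr"))
    alt <- rbind(mk("g44", 7, 4, "alt"), mk("g37", 7, 7, "alt"),
                 mk("g46", 3, 2, "alt"))
    v <- aggregateScreen(corr, alt, screenCriteria())
    sel <- setNames(v$selected, v$gene)
    expect_true(sel[["g44"]])    # 4/7 and 4/7
    expect_false(sel[["g37"]])   # 3/7 fails despite 7/7 alteration
    expect_true(sel[["g46"]])    # 4/6 and 2/3
    # cohort (row) order cannot change the verdicts
    v2 <- aggregateScreen(corr[sample(nrow(corr)), ],
                          alt[sample(nrow(alt)), ], screenCriteria())
    expect_identical(v2[order(v2$gene), ], v[order(v$gene), ])
})
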