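test_that("the sigmoid mean follows its closed form and limits", {
    expect_equal(sigmoidMean(0.5, mu0 = 3, k = 7, t0 = 0.5), 3)
    expect_equal(sigmoidMean(log(3), mu0 = 1, k = 1, t0 = 0), 1.5)
    expect_equal(sigmoidMean(0, mu0 = 1, k = 1, t0 = 0), 1)
    ## step-function limit for large |k|
    expect_equal(sigmoidMean(0.6, mu0 = 2, k = 1e9, t0 = 0.5), 4)
    expect_equal(sigmoidMean(0.4, mu0 = 2, k = 1e9, t0 = 0.5), 0)
    expect_false(any(!is.finite(sigmoidMean(seq(0, 1, 0.1), 1, 1e12, 0.5))))
})

test_that("single-gene fits recover planted parameters", {
    set.seed(42)
    t <- runif(500)
    y <- sigmoidMean(t, 2, 10, 0.5) + rnorm(500, 0, 0.1)
    f <- fitSwitchGene(y, t)
    expect_lt(abs(f$t0 - 0.5), 0.05)
    expect_gt(f$k, 0)
    expect_identical(f$direction, "activation")
    expect_lt(abs(f$mu0 - 2), 0.2)

    ## constant gene: the switch model finds no signal (the LRT sits in
    ## the bulk of its 2-df null distribution, far from significance)
    yc <- rnorm(200, 1, 0.2) + 1
    fc <- fitSwitchGene(yc, runif(200))
    expect_lt(fc$lrt, qchisq(0.95, df = 2))
    expect_gt(fc$p, 0.05)

    expect_error(fitSwitchGene(y[1:5], t[1:5]), "10 cells")
    expect_error(fitSwitchGene(y[1:20], rep(0.3, 20)), "constant")
})

test_that("time reversal flips the switch direction and point", {
    set.seed(3)
    t <- runif(300)
    y <- sigmoidMean(t, 1.5, 8, 0.4) + rnorm(300, 0, 0.1)
    f1 <- fitSwitchGene(y, t)
    f2 <- fitSwitchGene(y, -t)
    expect_equal(f2$k, -f1$k, tolerance = 0.05)
    expect_equal(f2$t0, -f1$t0, tolerance = 0.01)
    expect_equal(f2$loglik_sigmoid, f1$loglik_sigmoid, tolerance = 1e-4)
})

test_that("the sigmoid fit never falls below the nested constant model", {
    set.seed(17)
    t <- runif(60)
    for (i in 1:25) {
        y <- pmax(rnorm(60, runif(1, 0, 2), runif(1, 0.05, 0.5)), 0)
        f <- fitSwitchGene(y, t)
        expect_gte(f$loglik_sigmoid, f$loglik_constant - 1e-9)
        expect_gte(f$p, 0)
        expect_lte(f$p, 1)
    }
})

test_that("gene-level pre-filters gate the fitted and reported sets", {
    set.seed(5)
    n <- 200
    lv <- runif(n)
    m <- rbind(
        ## expressed in exactly 29 cells: below the prevalence filter
        sparse29 = ifelse(seq_len(n) <= 29, 1.5, 0),
        ## strong switch gene, within range
        good = sigmoidMean(lv, 1.5, 12, 0.5) + abs(rnorm(n, 0, 0.1)),
        ## monotone but with its midpoint far outside the lv range
        edge = sigmoidMean(lv, 1.5, 2, 3) + abs(rnorm(n, 0, 0.05)),
        flat = abs(rnorm(n, 1, 0.3)))
    colnames(m) <- paste0("c", 1:n)
    fits <- fitAllSwitchGenes(m, lv, min_cells = 30, min_abs_corr = 0.1)
    expect_false("sparse29" %in% fits$gene)
    g <- fits[fits$gene == "good", ]
    expect_true(g$reported)
    expect_lt(abs(g$t0 - 0.5), 0.1)
    if ("edge" %in% fits$gene) {
        e <- fits[fits$gene == "edge", ]
        expect_true(e$t0 > max(lv) || !e$reported)
        if (e$t0 > max(lv)) expect_false(e$reported)
    }
    ## BH q over the fitted set
    expect_equal(fits$q, p.adjust(fits$p, "BH"))

    expect_warning(
        empty <- fitAllSwitchGenes(m, lv, min_cells = 1000),
        "no genes")
    expect_identical(nrow(empty), 0L)

    ## exclusion list removes genes before testing
    fits2 <- fitAllSwitchGenes(m, lv, min_cells = 30, min_abs_corr = 0.1,
                               exclude_genes = "good")
    expect_false("good" %in% fits2$gene)
})

test_that("subsample-median fitting matches its documented mechanics", {
    sce <- logNormalize(simulateTrajectoryDataset(
        smallTrajConfig(seed = 6, n_cells = 60, n_switch = 10,
                        n_flat = 10, n_bg = 15)))
    lv <- sce$true_t
    grp <- sce$group

    ## degenerate case: one full-size round equals the single fit
    one <- subsampleMedianFit(sce, lv, grp, n_rounds = 1, seed = 1,
                              min_cells = 20, min_abs_corr = 0.2)
    expect_identical(attr(one, "subsample_size"), 60L)

    ## unbalanced groups: every round samples the smallest group's size
    keep <- c(which(grp == "LT"), which(grp == "NLT")[1:25])
    med <- subsampleMedianFit(sce[, keep], lv[keep], grp[keep],
                              n_rounds = 6, seed = 2, min_cells = 10,
                              min_abs_corr = 0.2)
    expect_identical(attr(med, "subsample_size"), 25L)
    expect_true(all(med$n_rounds_fitted <= 6))
    expect_identical(med$reported, med$n_rounds_passed > 3)

    ## deterministic under the seed
    med2 <- subsampleMedianFit(sce[, keep], lv[keep], grp[keep],
                               n_rounds = 6, seed = 2, min_cells = 10,
                               min_abs_corr = 0.2)
    expect_identical(med, med2)

    expect_error(subsampleMedianFit(sce, lv, rep("a", ncol(sce))),
                 "2 groups")
})

test_that("shared switch genes intersect reported sets", {
    ta <- data.frame(gene = c("a", "b", "c"), t0 = c(0.1, 0.5, 0.9),
                     reported = c(TRUE, TRUE, FALSE))
    tb <- data.frame(gene = c("b", "c", "d"), t0 = c(0.55, 0.8, 0.2),
                     reported = c(TRUE, TRUE, TRUE))
    sh <- sharedSwitchGenes(ta, tb)
    expect_identical(sh$shared$gene, "b")
    expect_equal(sh$shared$t0_a, 0.5)
    expect_equal(sh$shared$t0_b, 0.55)
    expect_identical(c(sh$n_a, sh$n_b, sh$n_shared), c(2L, 3L, 1L))

    ## disjoint and identical tables
    expect_identical(sharedSwitchGenes(
        ta[1, ], tb[3, ])$n_shared, 0L)
    expect_identical(sharedSwitchGenes(tb, tb)$n_shared, 3L)
})
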