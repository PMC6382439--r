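test_that("generator is deterministic and validates its configuration", {
    cfg <- smallTrajConfig(seed = 1, n_cells = 40, n_switch = 10,
                           n_flat = 10)
    a <- simulateTrajectoryDataset(cfg)
    b <- simulateTrajectoryDataset(cfg)
    expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))
    expect_identical(geneTruth(a), geneTruth(b))

    expect_error(simConfig(n_switch_genes = 0, n_flat_genes = 0,
                           n_marker_genes_per_group = 0,
                           n_background_genes = 0), "zero genes")
    expect_error(simConfig(groups = data.frame(
        name = "a", tissue = "x", t_lo = 0.5, t_hi = 0.2)), "t-windows")
    expect_error(simConfig(nb_dispersion = -1), "nb_dispersion")
})

test_that("planted truth respects the gene-class contracts", {
    sce <- simulateTrajectoryDataset(smallTrajConfig(seed = 2))
    tru <- geneTruth(sce)
    sw <- tru[tru$class == "switch", ]
    expect_true(all(sw$k != 0))
    expect_true(all(sw$t0 >= 0 & sw$t0 <= 1))
    expect_true(all(tru$k[tru$class == "flat"] == 0))
    expect_true(all(sce$true_t >= 0 & sce$true_t <= 1))
})

test_that("an extreme activation strength yields a step in the planted mean", {
    cfg <- smallTrajConfig(seed = 4, n_cells = 60, n_switch = 3, n_flat = 5)
    tru <- switchtraj:::withSeed(4, switchtraj:::.drawGeneTruth(cfg))
    tru$k[1] <- 1e6
    tru$t0[1] <- 0.5
    sce <- simulateTrajectoryDataset(cfg, tru)
    S <- assay(sce, "expected_lognorm")[1, ]
    t <- sce$true_t
    expect_true(all(S[t < 0.49] < 1e-6))
    expect_equal(unname(S[t > 0.51]),
                 rep(2 * tru$mu0[1], sum(t > 0.51)), tolerance = 1e-6)
})

test_that("empirical normalised expression at the switch point matches mu0", {
    ## Monte-Carlo check against the closed-form mean S(t0) = mu0
    cfg <- simConfig(n_cells_per_group = 250, n_switch_genes = 50,
                     n_flat_genes = 60, nb_dispersion = 0.5, seed = 7)
    sce <- logNormalize(simulateTrajectoryDataset(cfg))
    tru <- geneTruth(sce)
    norm <- as.matrix(assay(sce, "logcounts"))
    devs <- unlist(lapply(which(tru$class == "switch"), function(i) {
        sel <- abs(sce$true_t - tru$t0[i]) <= 0.01
        norm[i, sel] - tru$mu0[i]
    }))
    expect_gt(length(devs), 100)
    se <- sd(devs) / sqrt(length(devs))
    expect_lt(abs(mean(devs)), 3 * se)
})

test_that("counts are over-dispersed and planted order is monotone", {
    sce <- simulateTrajectoryDataset(smallTrajConfig(seed = 8, n_cells = 200))
    cnt <- as.matrix(counts(sce))
    m <- rowMeans(cnt)
    v <- apply(cnt, 1, var)
    expect_gte(mean(v[m >= 1] >= m[m >= 1]), 0.95)

    ## strictly monotone planted gene: expected expression rank tracks t
    tru <- geneTruth(sce)
    S <- assay(sce, "expected_lognorm")
    for (i in which(tru$class == "switch")[1:5]) {
        rho <- cor(S[i, ], sce$true_t, method = "spearman")
        expect_equal(abs(rho), 1, tolerance = 1e-12)
        expect_equal(sign(rho), sign(tru$k[i]))
    }
})

test_that("TCR table generator plants the receptor classes it reports", {
    cells <- sprintf("c%03d", 1:400)

    ## no doublets requested: no locus exceeds two recombinants
    tcr0 <- simulateTCRTable(cells, doublet_rate = 0, gd_rate = 0.1,
                             no_tcr_rate = 0.1, seed = 2)
    rec <- unique(tcr0$chains[, c("cell_id", "locus", "cdr3")])
    expect_true(all(table(rec$cell_id, rec$locus) <= 2))

    ## all gamma/delta: each cell has G and D chains and no alpha/beta pair
    tcr1 <- simulateTCRTable(cells, doublet_rate = 0, gd_rate = 1,
                             no_tcr_rate = 0, seed = 3)
    byc <- split(tcr1$chains$locus, tcr1$chains$cell_id)
    expect_length(byc, length(cells))
    for (l in byc) {
        expect_true(any(l == "G") && any(l == "D"))
        expect_false(any(l == "A") && any(l == "B"))
    }

    ## planted label counts reproducible under the seed
    t1 <- simulateTCRTable(cells, 0.05, 0.05, 0.05, seed = 9)
    t2 <- simulateTCRTable(cells, 0.05, 0.05, 0.05, seed = 9)
    expect_identical(t1$truth, t2$truth)
    expect_identical(t1$chains, t2$chains)
    expect_true(all(c("ab", "doublet", "gd", "no_tcr") %in%
                        t1$truth$tcr_class))

    expect_error(simulateTCRTable(cells, 0.6, 0.3, 0.3), "sum")
})

test_that("condition pairs share switch genes with the configured overlap", {
    cfg <- smallTrajConfig(seed = 1, n_cells = 30, n_switch = 100,
                           n_flat = 10)
    pair <- simulateConditionPair(cfg, shared_gene_fraction = 0.5,
                                  t0_jitter_sd = 0, seed = 5)
    expect_identical(sum(pair$shared$shared), 50L)
    ga <- geneTruth(pair$A); gb <- geneTruth(pair$B)
    shared_ids <- pair$shared$gene[pair$shared$shared]
    expect_identical(intersect(ga$gene[ga$class == "switch"],
                               gb$gene[gb$class == "switch"]),
                     shared_ids)
    ## jitter 0: per-gene delta t0 is exactly zero in truth
    expect_identical(pair$shared$t0_a[pair$shared$shared],
                     pair$shared$t0_b[pair$shared$shared])
    ## non-shared genes carry distinct ids
    expect_false(any(pair$shared$gene[!pair$shared$shared] %in% gb$gene))
})

test_that("species pairs plant the marker overlap and paralog swaps", {
    sp <- simulateSpeciesPair(n_orthologs = 300, n_markers_a = 60,
                              n_markers_b = 50, n_shared_markers = 20,
                              n_paralog_swaps = 5, n_decoy_families = 20,
                              seed = 6)
    ov <- markerOverlap(sp$markers_a, sp$markers_b, sp$orthologs)
    expect_identical(ov$n_shared, 20L)
    expect_identical(ov$n_a, 60L)
    expect_identical(ov$n_b, 50L)

    ## no swaps planted: the detector returns an empty table
    sp0 <- simulateSpeciesPair(n_paralog_swaps = 0, seed = 6)
    det0 <- detectParalogSubstitution(sp0$stats_a, sp0$stats_b,
                                      sp0$markers_a, sp0$markers_b,
                                      sp0$families)
    expect_identical(nrow(det0), 0L)
})
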