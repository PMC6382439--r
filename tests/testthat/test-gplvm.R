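test_that("duplicated genes leave the dominant ordering unchanged", {
    fx <- oneFactorMatrix(n_cells = 100, n_genes = 40, seed = 5)
    e1 <- suppressWarnings(fitGPLVM(fx$mat, q_latent = 4, seed = 1,
                                    maxit = 400))
    dup <- rbind(fx$mat, fx$mat)
    rownames(dup) <- sprintf("g%03d", seq_len(nrow(dup)))
    e2 <- suppressWarnings(fitGPLVM(dup, q_latent = 4, seed = 1,
                                    maxit = 400))
    d1 <- which.max(relevance(e1))
    d2 <- which.max(relevance(e2))
    rho <- cor(latentCoords(e1)[, d1], latentCoords(e2)[, d2],
               method = "spearman")
    expect_gte(abs(rho), 0.98)
})

test_that("surplus dimensions collapse on one-factor data", {
    fx <- oneFactorMatrix(n_cells = 150, n_genes = 50, seed = 5)
    emb <- suppressWarnings(fitGPLVM(fx$mat, q_latent = 6, seed = 1,
                                     maxit = 2000))
    rel <- relevance(emb)
    expect_lt(1 - max(rel) / sum(rel), 0.2)   # dims 2..6 jointly < 20%
    rho <- cor(latentCoords(emb)[, which.max(rel)], fx$t,
               method = "spearman")
    expect_gte(abs(rho), 0.9)
})

test_that("isotropic noise gives no dominant relevance weight", {
    set.seed(99)
    Y <- matrix(rnorm(150 * 50), 50, 150,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("c%03d", 1:150)))
    emb <- suppressWarnings(fitGPLVM(Y, q_latent = 6, seed = 1,
                                     maxit = 800))
    rel <- relevance(emb)
    expect_lt(max(rel), 3 * median(rel))
})

test_that("degenerate input is rejected", {
    const <- matrix(1, 10, 30,
                    dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
    expect_error(suppressWarnings(fitGPLVM(const)), "constant")
    fx <- oneFactorMatrix(n_cells = 15, n_genes = 20)
    expect_error(fitGPLVM(fx$mat), "20 cells")
})

test_that("training cells project back onto themselves", {
    fx <- oneFactorMatrix(n_cells = 80, n_genes = 40, seed = 6)
    emb <- suppressWarnings(fitGPLVM(fx$mat, q_latent = 4, seed = 1,
                                     maxit = 500))
    d <- which.max(relevance(emb))
    Xp <- projectCells(emb, fx$mat)
    expect_gte(cor(Xp[, d], latentCoords(emb)[, d], method = "spearman"),
               0.99)
})

test_that("pure-noise cells project near the latent prior mean", {
    fx <- oneFactorMatrix(n_cells = 80, n_genes = 40, seed = 6)
    emb <- suppressWarnings(fitGPLVM(fx$mat, q_latent = 4, seed = 1,
                                     maxit = 500))
    d <- which.max(relevance(emb))
    set.seed(3)
    noise <- matrix(rnorm(40 * 30), 40, 30,
                    dimnames = list(rownames(fx$mat), paste0("n", 1:30)))
    Xn <- projectCells(emb, noise)
    spread_train <- sd(latentCoords(emb)[, d])
    expect_lt(median(abs(Xn[, d])), spread_train)
})

test_that("adaptation-dimension selection and orientation are stable", {
    sce <- logNormalize(simulateTrajectoryDataset(
        smallTrajConfig(seed = 3)))
    hv <- selectVariableGenes(sce, 60)
    emb <- suppressWarnings(fitGPLVM(sce, genes = hv, q_latent = 6,
                                     seed = 1, maxit = 600))
    emb <- selectAdaptationLV(emb, sce$tissue, nlt = "NLT")
    lv <- adaptationLV(emb)
    ## orientation: the non-lymphoid pole is high
    expect_gt(mean(lv[sce$tissue == "NLT"]), mean(lv[sce$tissue == "LN"]))
    expect_gte(abs(cor(lv, sce$true_t, method = "spearman")), 0.9)
    expect_error(selectAdaptationLV(emb, rep("NLT", ncol(sce))), "both")
})

test_that("partition bookkeeping is validated", {
    fx <- oneFactorMatrix(n_cells = 40, n_genes = 30)
    g <- rownames(fx$mat)
    expect_error(fitPartitionedGPLVM(fx$mat, list(g[1:5], g[6:10])),
                 "named")
    expect_error(fitPartitionedGPLVM(
        fx$mat, list(a = g[1:5], b = character())), "empty")
    expect_error(fitPartitionedGPLVM(
        fx$mat, list(a = g[1:5], b = g[5:10])), "disjoint")
})

test_that("a flat cell-cycle partition reduces selection to plain relevance", {
    sce <- logNormalize(simulateTrajectoryDataset(
        smallTrajConfig(seed = 9, n_cells = 60, n_switch = 25,
                        n_flat = 30, n_bg = 10)))
    tru <- geneTruth(sce)
    parts <- list(cellcycle = tru$gene[tru$class == "flat"][1:15],
                  tissue_markers = tru$gene[tru$class == "switch"],
                  rest = c(tru$gene[tru$class == "flat"][16:30],
                           tru$gene[tru$class == "background"]))
    emb <- suppressWarnings(fitPartitionedGPLVM(sce, parts, q_latent = 6,
                                                seed = 1, maxit = 400))
    sel <- selectAdaptationLV(emb, sce$tissue)
    ## flat "cycle" genes have no factor of their own, so the tissue
    ## dimension passes the cycle-dominance filter and is selected
    expect_identical(sel@adaptationDim,
                     selectAdaptationLV(emb, sce$tissue,
                                        cycle_max_frac = Inf)@adaptationDim)
    lv <- adaptationLV(sel)
    expect_gte(abs(cor(lv, sce$true_t, method = "spearman")), 0.8)
})

test_that("the cell-cycle factor does not perturb the adaptation ordering", {
    ## two independent planted factors (adaptation coordinate + binary
    ## cycling state) with Gaussian measurement noise, so the ordering
    ## estimate itself is precise enough to expose any cross-talk
    set.seed(11)
    N <- 160
    t <- runif(N)
    cycling <- runif(N) < 0.25
    mkGene <- function(kind) {
        if (kind == "tissue") {
            2 * runif(1, 0.5, 1.5) *
                plogis(sample(c(-1, 1), 1) * runif(1, 6, 18) *
                           (t - runif(1, 0.2, 0.8))) + rnorm(N, 0, 0.2)
        } else if (kind == "cycle") {
            0.2 + 1.2 * cycling * runif(1, 0.8, 1.2) + rnorm(N, 0, 0.2)
        } else rnorm(N, 1, 0.3)
    }
    Y <- rbind(t(sapply(1:15, function(i) mkGene("cycle"))),
               t(sapply(1:30, function(i) mkGene("tissue"))),
               t(sapply(1:15, function(i) mkGene("rest"))))
    rownames(Y) <- c(sprintf("cc%02d", 1:15), sprintf("tm%02d", 1:30),
                     sprintf("rr%02d", 1:15))
    colnames(Y) <- sprintf("c%03d", 1:N)
    parts <- list(cellcycle = sprintf("cc%02d", 1:15),
                  tissue_markers = sprintf("tm%02d", 1:30),
                  rest = sprintf("rr%02d", 1:15))
    tissue <- ifelse(t > 0.5, "NLT", "LN")
    fitOrdering <- function(x) {
        emb <- suppressWarnings(fitPartitionedGPLVM(x, parts, q_latent = 8,
                                                    seed = 1, maxit = 600))
        adaptationLV(selectAdaptationLV(emb, tissue))
    }
    lv0 <- fitOrdering(Y)
    expect_gte(abs(cor(lv0, t, method = "spearman")), 0.95)
    ## permute cells within the cell-cycle partition only
    perm <- switchtraj:::withSeed(5, sample(N))
    Y2 <- Y
    Y2[parts$cellcycle, ] <- Y[parts$cellcycle, perm]
    lv1 <- fitOrdering(Y2)
    expect_gte(abs(cor(lv0, lv1, method = "spearman")), 0.95)
})

test_that("gene-LV correlations and shared proportions behave", {
    set.seed(8)
    lv <- rnorm(200)
    m <- rbind(self = lv,
               noisy = lv + rnorm(200, 0, 1),
               flat = rnorm(200))
    colnames(m) <- paste0("c", 1:200)
    gc <- lvGeneCorrelation(m, lv)
    expect_equal(gc$r[gc$gene == "self"], 1, tolerance = 1e-12)
    expect_true(gc$flagged[gc$gene == "self"])

    ## planted monotone switch gene correlates beyond the threshold
    sce <- logNormalize(simulateTrajectoryDataset(
        smallTrajConfig(seed = 13, n_cells = 250, n_switch = 20,
                        n_flat = 10)))
    gc2 <- lvGeneCorrelation(sce, sce$true_t)
    sw <- geneTruth(sce)$class == "switch"
    expect_gte(mean(abs(gc2$r[sw]) > 0.25), 0.9)

    sh <- sharedCorrelatedFraction(c("a", "b", "c"), c("a", "b", "c"))
    expect_equal(sh$frac_a, 100)
    expect_equal(sh$frac_b, 100)
    expect_error(lvGeneCorrelation(m, rep(1, 200)), "zero variance")
})
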