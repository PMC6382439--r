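## ten constructed cells straddling every count bound; pass/fail enumerated
## by hand against umi in [1000, 15000], genes in [700, 3500]
makeBoundaryCounts <- function() {
    n_genes <- 4000
    specs <- list(
        c1 = list(umi = 999, genes = 700),    # low_umi
        c2 = list(umi = 1000, genes = 700),   # pass (both lower bounds)
        c3 = list(umi = 15000, genes = 3500), # pass (both upper bounds)
        c4 = list(umi = 15001, genes = 3500), # high_umi
        c5 = list(umi = 5000, genes = 699),   # low_genes
        c6 = list(umi = 5000, genes = 700),   # pass
        c7 = list(umi = 5000, genes = 3501),  # high_genes
        c8 = list(umi = 5000, genes = 1500),  # pass
        c9 = list(umi = 900, genes = 650),    # low_umi (count order first)
        c10 = list(umi = 16000, genes = 3600) # high_umi before high_genes
    )
    m <- sapply(specs, function(s) {
        v <- integer(n_genes)
        v[seq_len(s$genes)] <- 1L
        extra <- s$umi - s$genes
        v[1] <- v[1] + extra
        v
    })
    rownames(m) <- sprintf("g%04d", seq_len(n_genes))
    m
}

test_that("count filters reproduce the hand enumeration at the bounds", {
    m <- makeBoundaryCounts()
    fc <- filterByCounts(m)
    expect_identical(
        fc$report$reason,
        c("low_umi", "pass", "pass", "high_umi", "low_genes", "pass",
          "high_genes", "pass", "low_umi", "high_umi"))
    expect_identical(colnames(fc$filtered), c("c2", "c3", "c6", "c8"))

    ## idempotence: filtering twice equals once
    fc2 <- filterByCounts(fc$filtered)
    expect_identical(colnames(fc2$filtered), colnames(fc$filtered))
    expect_true(all(fc2$report$pass))

    expect_error(filterByCounts(m[, 0, drop = FALSE]), "empty")
    expect_error(filterByCounts(m, umi_min = 2000, umi_max = 1000))
    expect_warning(filterByCounts(m, umi_min = 14990, umi_max = 14999),
                   "all cells")
})

test_that("TCR rules classify doublets, gamma-delta and TCR-less cells", {
    tcr <- rbind(
        tcrRows("d1", c("B", "B", "B")),            # 3 distinct B recombinants
        tcrRows("g1", c("G", "D")),                 # gamma-delta
        tcrRows("a1", c("A", "B", "G")),            # has alpha/beta pair
        tcrRows("a2", c("A", "B")),
        tcrRows("u1", c("A", "A"), productive = 0L),# unproductive still counts
        tcrRows("d2", c("A", "A", "A", "B"))        # >2 on A
    )
    cls <- classifyTCRCells(tcr, c("d1", "g1", "a1", "a2", "u1", "d2", "n1"))
    expect_identical(unname(cls),
                     c("doublet", "gd", "ab", "ab", "ab", "doublet",
                       "no_tcr"))

    ## repeated identical chains are one recombinant, not a doublet
    same <- tcrRows("s1", c("B", "B", "B"), cdr3 = rep("CASSX", 3))
    expect_identical(unname(classifyTCRCells(same, "s1")), "ab")

    ## precedence: a doublet on G with a D chain is a doublet, not gd
    dg <- tcrRows("p1", c("G", "G", "G", "D"))
    expect_identical(unname(classifyTCRCells(dg, "p1")), "doublet")

    expect_error(classifyTCRCells(tcrRows("x", "Z"), "x"), "locus")
})

test_that("TCR classification recovers planted labels exactly", {
    cells <- sprintf("c%03d", 1:500)
    sim <- simulateTCRTable(cells, doublet_rate = 0.08, gd_rate = 0.07,
                            no_tcr_rate = 0.05, seed = 12)
    cls <- classifyTCRCells(sim$chains, cells)
    expect_identical(unname(cls), sim$truth$tcr_class)
})

test_that("qcReport applies count reasons before TCR reasons", {
    m <- makeBoundaryCounts()
    tcr <- rbind(tcrRows("c2", c("A", "B")),
                 tcrRows("c3", c("G", "D")),
                 tcrRows("c6", c("B", "B", "B")),
                 tcrRows("c9", c("A", "B")))  # c9 already fails on counts
    qc <- qcReport(m, tcr)
    rep <- setNames(qc$report$reason, qc$report$cell_id)
    expect_identical(unname(rep[c("c2", "c3", "c6", "c8", "c9")]),
                     c("pass", "gd_tcell", "tcr_doublet", "no_tcr",
                       "low_umi"))
    expect_identical(colnames(qc$filtered), "c2")
})

test_that("log-normalisation closed forms, oracle match and monotonicity", {
    m <- matrix(c(1, 9999, 0, 2500, 2500, 5000), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
    norm <- logNormalize(m)
    expect_equal(norm["g1", "c1"], log(2))       # count 1 of total 10000
    expect_equal(norm["g3", "c1"], 0)            # zero count maps to zero
    expect_equal(norm["g1", "c2"], log(1 + 1e4 * 0.25))

    ## independent oracle on a random 5x5 integer fixture
    set.seed(11)
    r <- matrix(rpois(25, 5) + 1L, 5, 5,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:5)))
    expected <- log1p(1e4 * sweep(r, 2, colSums(r), `/`))
    expect_equal(logNormalize(r), expected)
    seurat_oracle <- as.matrix(
        Seurat::LogNormalize(r, scale.factor = 1e4, verbose = FALSE))
    expect_equal(unname(logNormalize(r)), unname(seurat_oracle),
                 tolerance = 1e-10)

    ## order-preserving within a cell
    ord <- order(r[, 1])
    expect_identical(order(logNormalize(r)[, 1]), ord)

    expect_error(logNormalize(matrix(0, 3, 2)), "zero total")
})

test_that("variable-gene selection ranks dispersion within mean bins", {
    ## all genes identical: z-scores zero, fallback to gene-id order
    flat <- matrix(rep(c(5, 1, 3), each = 4), nrow = 12, ncol = 30,
                   byrow = FALSE,
                   dimnames = list(sprintf("g%02d", 12:1), NULL))
    sel <- selectVariableGenes(log1p(flat * 0 + 1), n_top = 3)
    expect_identical(sel, c("g01", "g02", "g03"))

    ## a gene with inflated variance at equal mean ranks first
    set.seed(2)
    base <- matrix(rnorm(20 * 200, 5, 0.5), 20, 200)
    base[7, ] <- rnorm(200, 5, sqrt(10) * 0.5)
    base <- abs(base)
    rownames(base) <- sprintf("g%02d", 1:20)
    expect_identical(selectVariableGenes(base, n_top = 1, n_bins = 2),
                     "g07")

    ## planted switch genes dominate the selection on synthetic data
    sce <- logNormalize(simulateTrajectoryDataset(
        smallTrajConfig(seed = 3, n_cells = 150)))
    top <- selectVariableGenes(sce, n_top = 60)
    expect_gte(mean(grepl("^SW", top)), 0.9)

    expect_error(selectVariableGenes(base, n_top = 50), "n_top")
})
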