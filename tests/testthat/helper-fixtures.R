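## Shared fixtures, built in code at test time.

## small two-group trajectory configuration used by several suites
smallTrajConfig <- function(seed = 3, n_cells = 100, n_switch = 60,
                            n_flat = 30, n_marker = 0, n_cc = 0,
                            n_bg = 10) {
    simConfig(n_cells_per_group = n_cells, n_switch_genes = n_switch,
              n_flat_genes = n_flat, n_marker_genes_per_group = n_marker,
              n_cellcycle_genes = n_cc, n_background_genes = n_bg,
              seed = seed)
}

## three well-separated subpopulations with distinct marker blocks
threeGroupConfig <- function(seed = 21, n_cells = 150) {
    simConfig(n_cells_per_group = n_cells,
              groups = data.frame(name = c("g1", "g2", "g3"),
                                  tissue = c("LN", "LN", "NLT"),
                                  t_lo = c(0, 0.3, 0.6),
                                  t_hi = c(0.4, 0.7, 1)),
              n_switch_genes = 0, n_flat_genes = 60,
              n_marker_genes_per_group = 12, n_background_genes = 30,
              seed = seed)
}

## clean one-factor expression matrix: smooth sigmoidal curves of a single
## coordinate plus iid Gaussian noise, standardized; genes x cells
oneFactorMatrix <- function(n_cells = 150, n_genes = 50, noise_sd = 0.3,
                            seed = 5) {
    set.seed(seed)
    t <- sort(runif(n_cells))
    Y <- sapply(seq_len(n_genes), function(d) {
        2 * runif(1, 0.5, 1.5) *
            plogis(sample(c(-1, 1), 1) * runif(1, 6, 18) *
                       (t - runif(1, 0.2, 0.8)))
    })
    Y <- Y + matrix(rnorm(n_cells * n_genes, 0, noise_sd), n_cells, n_genes)
    m <- t(scale(Y))
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("c%03d", seq_len(n_cells)))
    list(mat = m, t = t)
}

## rank-based AUC of a score separating a binary truth
rankAUC <- function(score, truth) {
    r <- rank(score)
    auc <- (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
    max(auc, 1 - auc)
}

## TCR chain-table row builder
tcrRows <- function(cell, loci, cdr3 = NULL, productive = 1L) {
    data.frame(cell_id = cell, locus = loci,
               productive = rep_len(productive, length(loci)),
               cdr3 = if (is.null(cdr3)) {
                   paste0("C", cell, seq_along(loci))
               } else cdr3)
}
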