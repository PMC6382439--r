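## Synthetic trajectory data with planted ground truth.
##
## Cells live on a true adaptation coordinate t in [0,1] spanning a lymphoid
## and a non-lymphoid group. Gene classes: switch (sigmoidal in t), flat,
## per-group marker blocks, a cell-cycle program, and constant high-expression
## "background" genes that fill the library to a realistic total so that
## log-normalisation behaves as it does on real droplet data.
##
## Planted mean expression S_g(t) is defined on the log-normalised scale
## (ln(1 + 1e4 * count / total)); the generator numerically inverts the
## NB measurement model so that E[log-normalised expression | t] = S_g(t).

.SIM_SCALE <- 1e4      # scale factor assumed by the calibration
.SIM_MARKER_BASE <- 0.1

## Mean of ln(1 + scale*X/total) for X ~ NB(mu = lambda, size = 1/dispersion),
## tabulated on a lambda grid; returns forward and inverse interpolators.
.nbCalibration <- function(dispersion, total, scale = .SIM_SCALE,
                           s_max = 6.5) {
    size <- 1 / dispersion
    lam_max <- (exp(s_max) - 1) * total / scale * 4
    lam <- c(0, 10^seq(-4, log10(lam_max), length.out = 160))
    m <- vapply(lam, function(l) {
        if (l == 0) return(0)
        xmax <- max(5, ceiling(stats::qnbinom(1e-12, size = size, mu = l,
                                              lower.tail = FALSE)))
        xs <- 0:xmax
        sum(dnbinom(xs, size = size, mu = l) * log1p(scale * xs / total))
    }, numeric(1))
    list(fwd = approxfun(lam, m, rule = 2),
         inv = approxfun(m, lam, rule = 2))
}

## Draw the planted gene-parameter table for a configuration. Uses the
## caller's RNG stream.
.drawGeneTruth <- function(config) {
    rows <- list()
    nsw <- config@n_switch_genes
    if (nsw > 0) {
        sgn <- rep(c(1, -1), length.out = nsw)
        rows$switch <- data.frame(
            gene = sprintf("SW%04d", seq_len(nsw)),
            class = "switch",
            mu0 = runif(nsw, 0.5, 1.5),
            k = sgn * runif(nsw, 6, 18),
            t0 = runif(nsw, 0.15, 0.85),
            owner = NA_character_)
    }
    nfl <- config@n_flat_genes
    if (nfl > 0) {
        rows$flat <- data.frame(
            gene = sprintf("FL%04d", seq_len(nfl)),
            class = "flat",
            mu0 = runif(nfl, 0.1, 1.0),
            k = 0, t0 = NA_real_, owner = NA_character_)
    }
    nmk <- config@n_marker_genes_per_group
    if (nmk > 0) {
        for (g in config@groups$name) {
            rows[[paste0("mk_", g)]] <- data.frame(
                gene = sprintf("MK_%s_%03d", g, seq_len(nmk)),
                class = "marker",
                mu0 = runif(nmk, 1.0, 1.6),
                k = 0, t0 = NA_real_, owner = g)
        }
    }
    ncc <- config@n_cellcycle_genes
    if (ncc > 0) {
        rows$cc <- data.frame(
            gene = sprintf("CC%04d", seq_len(ncc)),
            class = "cellcycle",
            mu0 = runif(ncc, 1.0, 1.6),
            k = 0, t0 = NA_real_, owner = NA_character_)
    }
    nbg <- config@n_background_genes
    if (nbg > 0) {
        rows$bg <- data.frame(
            gene = sprintf("BG%04d", seq_len(nbg)),
            class = "background",
            mu0 = NA_real_,   # filled once the library deficit is known
            k = 0, t0 = NA_real_, owner = NA_character_)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## Planted mean log-normalised expression for one gene over coordinates t.
.plantedMean <- function(truth_row, t, cycling, own) {
    switch(truth_row$class,
        switch = 2 * truth_row$mu0 *
            plogis(truth_row$k * (t - truth_row$t0)),
        flat = rep(truth_row$mu0, length(t)),
        marker = .SIM_MARKER_BASE +
            (truth_row$mu0 - .SIM_MARKER_BASE) * as.numeric(own),
        cellcycle = .SIM_MARKER_BASE +
            (truth_row$mu0 - .SIM_MARKER_BASE) * as.numeric(cycling),
        background = rep(truth_row$mu0, length(t)),
        stop("unknown gene class: ", truth_row$class))
}

#' Generate a synthetic adaptation-trajectory dataset with planted truth
#'
#' Cells receive a true coordinate `t ~ Uniform(window of their group)`;
#' switch genes follow the sigmoid mean
#' \eqn{S(t) = 2\mu_0 / (1 + e^{-k(t - t_0)})} on the log-normalised scale;
#' counts are negative-binomial with log-normal library-size variation. The
#' generator numerically inverts the count measurement model so planted means
#' live on the same scale downstream fits use (see the vignette).
#'
#' @param config a [SimConfig-class].
#' @param geneTruth optional pre-built gene-truth table (as produced
#'   internally); used by [simulateConditionPair()] to share genes across
#'   datasets.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (sparse integer) and `expected_lognorm` (planted means),
#'   per-cell metadata (`group`, `tissue`, `true_t`, `cycling`) in `colData`
#'   and the gene-truth table (`class`, `mu0`, `k`, `t0`, `owner`) in
#'   `rowData`.
#' @examples
#' sce <- simulateTrajectoryDataset(simConfig(n_cells_per_group = 50, seed = 1))
#' sce
#' @export
simulateTrajectoryDataset <- function(config, geneTruth = NULL) {
    validObject(config)
    withSeed(config@seed, {
        truth <- if (is.null(geneTruth)) .drawGeneTruth(config) else geneTruth
        ng <- nrow(truth)
        ngr <- nrow(config@groups)
        ncell <- config@n_cells_per_group * ngr
        if (ncell == 0L || ng == 0L) stop("zero cells or zero genes")

        grp <- rep(config@groups$name, each = config@n_cells_per_group)
        tis <- rep(config@groups$tissue, each = config@n_cells_per_group)
        lo <- rep(config@groups$t_lo, each = config@n_cells_per_group)
        hi <- rep(config@groups$t_hi, each = config@n_cells_per_group)
        t_true <- runif(ncell, lo, hi)
        cycling <- if (config@n_cellcycle_genes > 0) {
            runif(ncell) < config@cycling_fraction
        } else rep(FALSE, ncell)
        lib_factor <- exp(rnorm(ncell, 0, config@library_size_log_sd))

        t_ref <- exp(config@library_size_log_mean)
        calib <- .nbCalibration(config@nb_dispersion, t_ref)

        ## planted means (log-normalised scale), genes x cells
        S <- matrix(0, ng, ncell)
        panel <- which(truth$class != "background")
        for (i in panel) {
            S[i, ] <- .plantedMean(truth[i, ], t_true, cycling,
                                   own = grp == truth$owner[i])
        }
        lambda <- matrix(0, ng, ncell)
        lambda[panel, ] <- calib$inv(S[panel, ])

        ## background genes fill the library to the reference total
        bg <- which(truth$class == "background")
        if (length(bg)) {
            deficit <- max(t_ref - mean(colSums(lambda)), 0)
            lam_bg <- deficit / length(bg)
            lambda[bg, ] <- lam_bg
            truth$mu0[bg] <- calib$fwd(lam_bg)
            S[bg, ] <- truth$mu0[bg]
        }

        lambda <- sweep(lambda, 2, lib_factor, `*`)
        counts <- matrix(
            rnbinom(ng * ncell, size = 1 / config@nb_dispersion, mu = lambda),
            ng, ncell)
        if (config@dropout_extra > 0) {
            keep <- matrix(rbinom(ng * ncell, 1, 1 - config@dropout_extra),
                           ng, ncell)
            counts <- counts * keep
        }

        gene_id <- truth$gene
        cell_id <- sprintf("cell%05d", seq_len(ncell))
        dimnames(counts) <- list(gene_id, cell_id)
        dimnames(S) <- list(gene_id, cell_id)

        cd <- S4Vectors::DataFrame(
            cell_id = cell_id, group = grp, tissue = tis,
            cell_type = "Treg", condition = "control", cluster = grp,
            true_t = t_true, cycling = cycling, lib_factor = lib_factor,
            row.names = cell_id)
        rd <- S4Vectors::DataFrame(truth, row.names = gene_id)
        SingleCellExperiment(
            assays = list(counts = as(counts, "CsparseMatrix"),
                          expected_lognorm = S),
            colData = cd, rowData = rd)
    })
}

#' Planted gene-truth table of a simulated dataset
#'
#' @param sce a dataset from [simulateTrajectoryDataset()].
#' @return data.frame with columns `gene`, `class`, `mu0`, `k`, `t0`, `owner`.
#' @export
geneTruth <- function(sce) {
    as.data.frame(SummarizedExperiment::rowData(sce))
}

#' Generate a synthetic reconstructed-TCR chain table
#'
#' Emulates the per-cell chain summaries of TCR-reconstruction tools: clean
#' alpha/beta cells carry 1-2 productive A and 1-2 B chains, doublets more
#' than two recombinants on at least one locus, gamma/delta cells at least
#' one G and one D chain and no alpha/beta pair, and a fraction of cells no
#' chains at all. CDR3 strings are arbitrary identifiers, not realistic
#' sequences.
#'
#' @param x a dataset from [simulateTrajectoryDataset()] or a character
#'   vector of cell ids.
#' @param doublet_rate,gd_rate,no_tcr_rate class probabilities (must sum to
#'   at most 1; the remainder are clean alpha/beta cells).
#' @param seed RNG seed.
#' @return list with `chains` (data.frame `cell_id`, `locus` in A/B/G/D,
#'   `productive` in 0/1, `cdr3`) and `truth` (data.frame `cell_id`,
#'   `tcr_class` in ab/doublet/gd/no_tcr).
#' @export
simulateTCRTable <- function(x, doublet_rate = 0.05, gd_rate = 0.05,
                             no_tcr_rate = 0.05, seed = 1) {
    cells <- if (is.character(x)) x else colnames(x)
    rates <- c(doublet_rate, gd_rate, no_tcr_rate)
    if (any(rates < 0) || sum(rates) > 1) {
        stop("rates must be >= 0 and sum to at most 1")
    }
    withSeed(seed, {
        n <- length(cells)
        cls <- sample(c("ab", "doublet", "gd", "no_tcr"), n, replace = TRUE,
                      prob = c(1 - sum(rates), rates))
        pool_i <- 0L
        nextCdr3 <- function(k) {
            ids <- pool_i + seq_len(k)
            pool_i <<- pool_i + k
            sprintf("CASS%06d", ids)
        }
        out <- vector("list", n)
        for (i in seq_len(n)) {
            ci <- cells[i]
            out[[i]] <- switch(cls[i],
                no_tcr = NULL,
                ab = {
                    na <- sample(1:2, 1); nb <- sample(1:2, 1)
                    df <- data.frame(
                        cell_id = ci,
                        locus = c(rep("A", na), rep("B", nb)),
                        productive = 1L,
                        cdr3 = nextCdr3(na + nb))
                    ## occasionally one unproductive extra A recombinant
                    if (na == 1L && runif(1) < 0.2) {
                        df <- rbind(df, data.frame(
                            cell_id = ci, locus = "A", productive = 0L,
                            cdr3 = nextCdr3(1)))
                    }
                    df
                },
                doublet = {
                    loc <- sample(c("A", "B"), 1)
                    nl <- sample(3:4, 1)
                    other <- setdiff(c("A", "B"), loc)
                    no <- sample(1:2, 1)
                    data.frame(
                        cell_id = ci,
                        locus = c(rep(loc, nl), rep(other, no)),
                        productive = rbinom(nl + no, 1, 0.8),
                        cdr3 = nextCdr3(nl + no))
                },
                gd = {
                    ng <- sample(1:2, 1); nd <- sample(1:2, 1)
                    data.frame(
                        cell_id = ci,
                        locus = c(rep("G", ng), rep("D", nd)),
                        productive = 1L,
                        cdr3 = nextCdr3(ng + nd))
                })
        }
        chains <- do.call(rbind, out)
        if (is.null(chains)) {
            chains <- data.frame(cell_id = character(), locus = character(),
                                 productive = integer(), cdr3 = character())
        }
        rownames(chains) <- NULL
        list(chains = chains,
             truth = data.frame(cell_id = cells, tcr_class = cls))
    })
}

#' Generate a matched pair of trajectory datasets (e.g. control vs tumour)
#'
#' Both datasets are drawn from the same configuration; a configurable
#' fraction of switch genes is shared between them (same identity, same
#' `mu0`/`k`), with the shared genes' activation times `t0` jittered by
#' Gaussian noise of the given standard deviation in the second condition.
#'
#' @param config a [SimConfig-class] (its `seed` is ignored in favour of
#'   `seed`).
#' @param shared_gene_fraction fraction of switch genes shared in [0,1].
#' @param t0_jitter_sd standard deviation of the planted between-condition
#'   `t0` shift (0 means identical activation times in truth).
#' @param seed RNG seed.
#' @return list with datasets `A` and `B` and `shared`, a data.frame over
#'   A's switch genes with columns `gene`, `t0_a`, `t0_b`, `shared`.
#' @export
simulateConditionPair <- function(config, shared_gene_fraction = 0.5,
                                  t0_jitter_sd = 0.02, seed = 1) {
    stopifnot(shared_gene_fraction >= 0, shared_gene_fraction <= 1)
    nsw <- config@n_switch_genes
    n_shared <- round(shared_gene_fraction * nsw)
    pieces <- withSeed(seed, {
        truthA <- .drawGeneTruth(config)
        truthB <- truthA
        sw <- which(truthA$class == "switch")
        shared_idx <- sw[seq_len(n_shared)]
        if (n_shared > 0) {
            truthB$t0[shared_idx] <- pmin(pmax(
                truthA$t0[shared_idx] + rnorm(n_shared, 0, t0_jitter_sd),
                0), 1)
        }
        priv <- setdiff(sw, shared_idx)
        if (length(priv)) {
            sgn <- rep(c(1, -1), length.out = length(priv))
            truthB$gene[priv] <- paste0(truthA$gene[priv], "b")
            truthB$mu0[priv] <- runif(length(priv), 0.5, 1.5)
            truthB$k[priv] <- sgn * runif(length(priv), 6, 18)
            truthB$t0[priv] <- runif(length(priv), 0.15, 0.85)
        }
        list(truthA = truthA, truthB = truthB, shared_idx = shared_idx,
             sw = sw)
    })
    cfgA <- config; cfgA@seed <- as.integer(seed + 11L)
    cfgB <- config; cfgB@seed <- as.integer(seed + 12L)
    shared <- data.frame(
        gene = pieces$truthA$gene[pieces$sw],
        t0_a = pieces$truthA$t0[pieces$sw],
        t0_b = ifelse(pieces$sw %in% pieces$shared_idx,
                      pieces$truthB$t0[pieces$sw], NA_real_),
        shared = pieces$sw %in% pieces$shared_idx)
    list(A = simulateTrajectoryDataset(cfgA, pieces$truthA),
         B = simulateTrajectoryDataset(cfgB, pieces$truthB),
         shared = shared)
}

#' Generate a paired-species marker comparison with planted paralog swaps
#'
#' Builds marker tables and NLT expression-fraction statistics for two
#' species linked by a one-to-one ortholog map, with a configured number of
#' shared markers and planted paralog-substitution events: gene g is an NLT
#' marker in species A and essentially unexpressed in B, while its
#' within-family paralog g' shows the mirror pattern.
#'
#' @param n_orthologs number of one-to-one ortholog pairs.
#' @param n_markers_a,n_markers_b marker-list sizes per species.
#' @param n_shared_markers planted size of the cross-species marker overlap.
#' @param n_paralog_swaps planted substitution events.
#' @param n_decoy_families paralog families without a substitution pattern.
#' @param seed RNG seed.
#' @return list with `markers_a`, `markers_b` (gene, avg_logFC, pct_in,
#'   pct_out, p_adj), `stats_a`, `stats_b` (gene, pct_nlt), `orthologs`
#'   (gene_a, gene_b), `families` (family, gene_a, gene_b; one row per
#'   ortholog pair in the family) and `truth` (planted swaps: family,
#'   gene_a, gene_b).
#' @export
simulateSpeciesPair <- function(n_orthologs = 300, n_markers_a = 60,
                                n_markers_b = 50, n_shared_markers = 20,
                                n_paralog_swaps = 5, n_decoy_families = 20,
                                seed = 1) {
    stopifnot(n_paralog_swaps >= 0, n_shared_markers >= 0)
    n_only_a <- n_markers_a - n_shared_markers - n_paralog_swaps
    n_only_b <- n_markers_b - n_shared_markers - n_paralog_swaps
    stopifnot(n_only_a >= 0, n_only_b >= 0)
    need <- n_shared_markers + n_only_a + n_only_b + 4 * n_paralog_swaps +
        2 * n_decoy_families
    if (n_orthologs < need) {
        stop("n_orthologs too small for the requested design (need >= ",
             need, ")")
    }
    withSeed(seed, {
        ga <- sprintf("GA%04d", seq_len(n_orthologs))
        gb <- sprintf("GB%04d", seq_len(n_orthologs))
        idx <- seq_len(n_orthologs)
        take <- function(k) {
            if (k == 0) return(integer(0))
            out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out
        }
        i_shared <- take(n_shared_markers)
        i_only_a <- take(n_only_a)
        i_only_b <- take(n_only_b)
        i_swap_m <- take(n_paralog_swaps)   # marker in A, silent in B
        i_swap_p <- take(n_paralog_swaps)   # paralog: silent in A, marker in B
        i_decoy <- take(2 * n_decoy_families)
        i_rest <- idx

        pct_hi <- function(n) runif(n, 0.3, 0.9)
        pct_mid <- function(n) runif(n, 0.1, 0.5)
        pct_silent <- function(n) runif(n, 0, 0.04)

        pa <- pb <- numeric(n_orthologs)
        pa[i_shared] <- pct_hi(n_shared_markers)
        pb[i_shared] <- pct_hi(n_shared_markers)
        pa[i_only_a] <- pct_hi(n_only_a); pb[i_only_a] <- pct_mid(n_only_a)
        pa[i_only_b] <- pct_mid(n_only_b); pb[i_only_b] <- pct_hi(n_only_b)
        pa[i_swap_m] <- pct_hi(n_paralog_swaps)
        pb[i_swap_m] <- pct_silent(n_paralog_swaps)
        pa[i_swap_p] <- pct_silent(n_paralog_swaps)
        pb[i_swap_p] <- pct_hi(n_paralog_swaps)
        pa[i_decoy] <- pct_mid(length(i_decoy))
        pb[i_decoy] <- pct_mid(length(i_decoy))
        pa[i_rest] <- pct_mid(length(i_rest))
        pb[i_rest] <- pct_mid(length(i_rest))

        mk_a <- sort(c(i_shared, i_only_a, i_swap_m))
        mk_b <- sort(c(i_shared, i_only_b, i_swap_p))
        markerTable <- function(ii, pct) data.frame(
            gene = ii, avg_logFC = runif(length(ii), 0.3, 2),
            pct_in = pct[ii], pct_out = runif(length(ii), 0.01, 0.2),
            p_adj = runif(length(ii), 0, 0.01))

        ma <- markerTable(mk_a, pa); ma$gene <- ga[ma$gene]
        mb <- markerTable(mk_b, pb); mb$gene <- gb[mb$gene]

        fam <- list()
        if (n_paralog_swaps > 0) {
            fam$swap <- data.frame(
                family = rep(sprintf("famS%03d", seq_len(n_paralog_swaps)),
                             each = 2),
                gene_a = ga[as.vector(rbind(i_swap_m, i_swap_p))],
                gene_b = gb[as.vector(rbind(i_swap_m, i_swap_p))])
        }
        if (n_decoy_families > 0) {
            fam$decoy <- data.frame(
                family = rep(sprintf("famD%03d", seq_len(n_decoy_families)),
                             each = 2),
                gene_a = ga[i_decoy], gene_b = gb[i_decoy])
        }
        families <- do.call(rbind, fam)
        if (is.null(families)) {
            families <- data.frame(family = character(),
                                   gene_a = character(),
                                   gene_b = character())
        }
        rownames(families) <- NULL

        list(markers_a = ma, markers_b = mb,
             stats_a = data.frame(gene = ga, pct_nlt = pa),
             stats_b = data.frame(gene = gb, pct_nlt = pb),
             orthologs = data.frame(gene_a = ga, gene_b = gb),
             families = families,
             truth = if (n_paralog_swaps > 0) data.frame(
                 family = sprintf("famS%03d", seq_len(n_paralog_swaps)),
                 gene_a = ga[i_swap_m], gene_b = gb[i_swap_p])
             else data.frame(family = character(), gene_a = character(),
                             gene_b = character()))
    })
}
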