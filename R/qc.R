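## Cell-level quality control: UMI/gene count bounds, TCR-based rules,
## log-normalisation and equal-frequency variable-gene selection.

.QC_REASONS <- c("low_umi", "high_umi", "low_genes", "high_genes",
                 "no_tcr", "tcr_doublet", "gd_tcell", "pass")

#' Filter cells by total UMI and detected-gene counts
#'
#' Retains cells whose total UMI count and number of genes with at least one
#' UMI fall inside the given bounds. Bounds are inclusive ("between ... and"
#' read as closed intervals) and configurable. Reasons are assigned in the
#' fixed order low_umi, high_umi, low_genes, high_genes; each cell gets
#' exactly one reason.
#'
#' @param x a `SingleCellExperiment` (or genes x cells count matrix).
#' @param umi_min,umi_max bounds on the per-cell UMI total.
#' @param genes_min,genes_max bounds on the per-cell detected-gene count.
#' @return list with `filtered` (the retained subset of `x`) and `report`,
#'   a data.frame (`cell_id`, `total_umi`, `n_genes`, `reason`, `pass`).
#' @export
filterByCounts <- function(x, umi_min = 1000, umi_max = 15000,
                           genes_min = 700, genes_max = 3500) {
    stopifnot(umi_min > 0, genes_min > 0,
              umi_min < umi_max, genes_min < genes_max)
    counts <- .getCounts(x)
    if (ncol(counts) == 0L || nrow(counts) == 0L) stop("empty count matrix")
    total <- Matrix::colSums(counts)
    ngene <- Matrix::colSums(counts > 0)
    reason <- rep("pass", ncol(counts))
    reason[ngene > genes_max] <- "high_genes"
    reason[ngene < genes_min] <- "low_genes"
    reason[total > umi_max] <- "high_umi"
    reason[total < umi_min] <- "low_umi"
    pass <- reason == "pass"
    if (!any(pass)) warning("all cells removed by count filters")
    report <- data.frame(cell_id = colnames(counts), total_umi = total,
                         n_genes = ngene, reason = reason, pass = pass,
                         row.names = NULL)
    list(filtered = x[, pass, drop = FALSE], report = report)
}

#' Classify cells from a reconstructed-TCR chain table
#'
#' Applies the receptor-based rules used during quality control: cells with
#' no detected chain are `no_tcr`; cells with more than two distinct
#' recombinants (distinct (locus, CDR3) pairs, productive or not) on any
#' locus are `doublet`; cells with at least one gamma (G) and one delta (D)
#' chain and no alpha/beta pair are `gd`; all remaining cells are `ab`.
#' Precedence: no_tcr > doublet > gd > ab.
#'
#' @param tcr data.frame with columns `cell_id`, `locus` (A/B/G/D),
#'   `productive`, `cdr3`; cell ids repeat across chains.
#' @param cells character vector of cell ids to classify (cells absent from
#'   `tcr` are `no_tcr`).
#' @return named character vector over `cells` with values in
#'   `c("no_tcr", "doublet", "gd", "ab")`.
#' @export
classifyTCRCells <- function(tcr, cells) {
    need <- c("cell_id", "locus", "productive", "cdr3")
    if (!all(need %in% names(tcr))) {
        stop("tcr table needs columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(unique(tcr$locus), c("A", "B", "G", "D"))
    if (length(bad)) stop("unknown TCR locus code(s): ",
                          paste(bad, collapse = ", "))
    tcr <- tcr[tcr$cell_id %in% cells, , drop = FALSE]
    ## distinct recombinants per (cell, locus)
    rec <- unique(tcr[, c("cell_id", "locus", "cdr3")])
    tab <- table(factor(rec$cell_id, levels = cells),
                 factor(rec$locus, levels = c("A", "B", "G", "D")))
    n_a <- tab[, "A"]; n_b <- tab[, "B"]
    n_g <- tab[, "G"]; n_d <- tab[, "D"]
    cls <- rep("ab", length(cells))
    cls[n_g >= 1 & n_d >= 1 & !(n_a >= 1 & n_b >= 1)] <- "gd"
    cls[pmax(n_a, n_b, n_g, n_d) > 2] <- "doublet"
    cls[n_a + n_b + n_g + n_d == 0] <- "no_tcr"
    setNames(cls, cells)
}

#' Full per-cell QC report combining count and TCR rules
#'
#' Count-bound reasons are applied first (in the order documented in
#' [filterByCounts()]), then TCR reasons (`no_tcr`, `tcr_doublet`,
#' `gd_tcell`); each cell receives exactly one reason.
#'
#' @param x a `SingleCellExperiment` or genes x cells count matrix.
#' @param tcr optional TCR chain table (see [classifyTCRCells()]).
#' @param umi_min,umi_max,genes_min,genes_max count bounds.
#' @return list with `filtered` (retained subset) and `report` data.frame.
#' @export
qcReport <- function(x, tcr = NULL, umi_min = 1000, umi_max = 15000,
                     genes_min = 700, genes_max = 3500) {
    fc <- filterByCounts(x, umi_min, umi_max, genes_min, genes_max)
    report <- fc$report
    if (!is.null(tcr)) {
        cls <- classifyTCRCells(tcr, report$cell_id)
        tcr_reason <- c(no_tcr = "no_tcr", doublet = "tcr_doublet",
                        gd = "gd_tcell", ab = "pass")[cls]
        upd <- report$reason == "pass" & tcr_reason != "pass"
        report$reason[upd] <- tcr_reason[upd]
        report$pass <- report$reason == "pass"
    }
    list(filtered = x[, report$pass, drop = FALSE], report = report)
}

#' Log-normalise counts
#'
#' Per-cell normalisation `x = ln(1 + scale * count / total)` with the
#' conventional scale factor of 10,000 and the natural logarithm; zero
#' counts map to zero.
#'
#' @param x `SingleCellExperiment` or genes x cells count matrix.
#' @param scale scale factor.
#' @return for an SCE input, the SCE with a `logcounts` assay added;
#'   otherwise the normalised matrix.
#' @export
logNormalize <- function(x, scale = 10000) {
    counts <- .getCounts(x)
    total <- Matrix::colSums(counts)
    if (any(total == 0)) {
        stop("cells with zero total counts; filter before normalising")
    }
    if (is(counts, "sparseMatrix")) {
        norm <- counts
        norm@x <- log1p(scale * counts@x / rep.int(total, diff(counts@p)))
    } else {
        norm <- log1p(sweep(counts, 2, scale / total, `*`))
    }
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "logcounts") <- norm
        x
    } else {
        norm
    }
}

#' Select highly variable genes by binned dispersion z-scores
#'
#' Genes are placed into `n_bins` equal-frequency bins of mean normalised
#' expression; dispersion (variance / mean of normalised values) is z-scored
#' within each bin and the top `n_top` genes by z-score are returned, with a
#' deterministic tie-break by gene id. Bins whose dispersion is constant get
#' z-scores of zero.
#'
#' @param x `SingleCellExperiment` with `logcounts` or a normalised genes x
#'   cells matrix.
#' @param n_top number of genes to return.
#' @param n_bins number of equal-frequency mean bins; capped so every bin
#'   holds at least thirty expressed genes (z-scores within sparser bins
#'   are dominated by their own estimation noise).
#' @return character vector of `n_top` gene ids, ordered by decreasing
#'   dispersion z-score.
#' @export
selectVariableGenes <- function(x, n_top, n_bins = 100) {
    norm <- .getLogcounts(x)
    if (n_top > nrow(norm)) stop("n_top exceeds the number of genes")
    mu <- Matrix::rowMeans(norm)
    v <- Matrix::rowMeans(norm^2) - mu^2
    v <- v * ncol(norm) / max(ncol(norm) - 1, 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    expressed <- mu > 0
    ## keep bins populated enough for a meaningful within-bin z-score
    n_bins <- max(1L, min(n_bins, floor(sum(expressed) / 30)))
    ## equal-frequency binning of the mean
    bin <- integer(length(mu))
    ord <- order(mu[expressed], rownames(norm)[expressed])
    bin[expressed][ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
    z <- numeric(length(mu))
    for (b in unique(bin[expressed])) {
        ii <- which(bin == b)
        s <- sd(disp[ii])
        z[ii] <- if (is.na(s) || s == 0) 0 else (disp[ii] - mean(disp[ii])) / s
    }
    genes <- rownames(norm)
    sel <- order(-z, genes)[seq_len(n_top)]
    genes[sel]
}
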