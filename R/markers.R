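## Differential expression by Wilcoxon rank-sum with the conventional
## thresholds (|avg logFC| >= 0.25, Bonferroni-adjusted p <= 0.05), plus the
## NLT/LT signature ratio score.

## natural-log fold-change on de-logged means + 1
.avgLogFC <- function(norm, cellsA, cellsB) {
    ma <- Matrix::rowMeans(expm1(norm[, cellsA, drop = FALSE]))
    mb <- Matrix::rowMeans(expm1(norm[, cellsB, drop = FALSE]))
    log(ma + 1) - log(mb + 1)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Genes are tested only if expressed (normalised value > 0) in at least
#' `min_frac` of either group; p-values come from the two-sided, tie-
#' corrected normal approximation of the rank-sum test and are Bonferroni-
#' adjusted over the tested genes. The average log fold-change is
#' `ln(mean(e^x - 1) + 1)` in group A minus the same in group B. A gene is
#' `significant` if `|avg_logFC| >= logfc_min` and `p_adj <= alpha`.
#'
#' @param x `SingleCellExperiment` with `logcounts` or normalised genes x
#'   cells matrix.
#' @param cellsA,cellsB disjoint, non-empty cell-id (or index) vectors.
#' @param min_frac minimum expression fraction in either group.
#' @param logfc_min fold-change threshold for significance flagging.
#' @param alpha adjusted-p threshold for significance flagging.
#' @param genes optional gene universe overriding the `min_frac` filter
#'   (used by the two-pass union scheme).
#' @param contrast label stored in the output.
#' @return data.frame (`gene`, `contrast`, `avg_logFC`, `pct_in`, `pct_out`,
#'   `p_raw`, `p_adj`, `significant`).
#' @export
wilcoxonDE <- function(x, cellsA, cellsB, min_frac = 0.05,
                       logfc_min = 0.25, alpha = 0.05, genes = NULL,
                       contrast = "A_vs_B") {
    norm <- .getLogcounts(x)
    if (is.character(cellsA)) cellsA <- match(cellsA, colnames(norm))
    if (is.character(cellsB)) cellsB <- match(cellsB, colnames(norm))
    if (!length(cellsA) || !length(cellsB)) stop("both groups must be non-empty")
    if (anyNA(cellsA) || anyNA(cellsB)) stop("unknown cell ids")
    if (length(intersect(cellsA, cellsB))) stop("groups overlap")

    pct_a <- Matrix::rowMeans(norm[, cellsA, drop = FALSE] > 0)
    pct_b <- Matrix::rowMeans(norm[, cellsB, drop = FALSE] > 0)
    tested <- if (is.null(genes)) {
        which(pmax(pct_a, pct_b) >= min_frac)
    } else {
        match(intersect(genes, rownames(norm)), rownames(norm))
    }
    if (!length(tested)) {
        return(data.frame(gene = character(), contrast = character(),
                          avg_logFC = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p_raw = numeric(),
                          p_adj = numeric(), significant = logical()))
    }
    sub <- as.matrix(norm[tested, c(cellsA, cellsB), drop = FALSE])
    ia <- seq_along(cellsA)
    p <- apply(sub, 1, function(v) {
        suppressWarnings(
            wilcox.test(v[ia], v[-ia], exact = FALSE, correct = TRUE)$p.value)
    })
    p[is.na(p)] <- 1     # all-tied genes carry no evidence
    lfc <- .avgLogFC(norm, cellsA, cellsB)[tested]
    p_adj <- pmin(1, p * length(tested))
    data.frame(gene = rownames(norm)[tested], contrast = contrast,
               avg_logFC = lfc, pct_in = pct_a[tested],
               pct_out = pct_b[tested], p_raw = p, p_adj = p_adj,
               significant = abs(lfc) >= logfc_min & p_adj <= alpha,
               row.names = NULL)
}

#' Two-pass union differential expression across several contrasts
#'
#' The first pass records, per contrast, the genes passing the expression
#' filter; the second pass re-tests every contrast on the union of those
#' sets (so a gene expressed in only one comparison still receives a
#' p-value in all of them).
#'
#' @param x as in [wilcoxonDE()].
#' @param contrasts named list of `list(A = cells, B = cells)` pairs
#'   (at least two).
#' @param ... thresholds passed on to [wilcoxonDE()].
#' @return combined marker table over all contrasts (second-pass results).
#' @export
twoPassUnionDE <- function(x, contrasts, ...) {
    if (length(contrasts) < 2) stop("need at least 2 contrasts")
    pass1 <- lapply(names(contrasts), function(nm) {
        wilcoxonDE(x, contrasts[[nm]]$A, contrasts[[nm]]$B,
                   contrast = nm, ...)$gene
    })
    universe <- Reduce(union, pass1)
    out <- lapply(names(contrasts), function(nm) {
        wilcoxonDE(x, contrasts[[nm]]$A, contrasts[[nm]]$B,
                   genes = universe, contrast = nm, ...)
    })
    do.call(rbind, out)
}

#' One-vs-rest marker detection for every cluster
#'
#' Runs [wilcoxonDE()] for each cluster against all remaining cells;
#' upregulated markers have positive `avg_logFC`. Singleton clusters are
#' skipped with a warning.
#'
#' @param x as in [wilcoxonDE()].
#' @param clusters per-cell cluster labels.
#' @param ... thresholds passed on to [wilcoxonDE()].
#' @return marker table with one block per cluster (`contrast` = cluster).
#' @export
findClusterMarkers <- function(x, clusters, ...) {
    clusters <- as.character(clusters)
    norm <- .getLogcounts(x)
    stopifnot(length(clusters) == ncol(norm))
    lv <- unique(clusters)
    if (length(lv) < 2) stop("need at least 2 clusters")
    out <- list()
    for (cl in lv) {
        ii <- which(clusters == cl)
        if (length(ii) < 2) {
            warning("singleton cluster '", cl, "' skipped")
            next
        }
        out[[cl]] <- wilcoxonDE(x, ii, setdiff(seq_along(clusters), ii),
                                contrast = cl, ...)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' NLT/LT signature score per cluster
#'
#' The ratio between the number of non-lymphoid-signature and lymphoid-
#' signature genes among each cluster's significantly upregulated markers.
#' The denominator is floored at 1 (both raw counts are reported so other
#' conventions can be recomputed).
#'
#' @param markers marker table from [findClusterMarkers()].
#' @param nlt_genes,lt_genes disjoint signature gene sets.
#' @return data.frame (`cluster`, `n_nlt_up`, `n_lt_up`, `score`).
#' @export
nltLtScore <- function(markers, nlt_genes, lt_genes) {
    if (!length(nlt_genes) || !length(lt_genes)) {
        stop("signature sets must be non-empty")
    }
    if (length(intersect(nlt_genes, lt_genes))) {
        stop("signature sets must be disjoint")
    }
    up <- markers[markers$significant & markers$avg_logFC > 0, ]
    out <- lapply(unique(markers$contrast), function(cl) {
        g <- up$gene[up$contrast == cl]
        n_nlt <- length(intersect(g, nlt_genes))
        n_lt <- length(intersect(g, lt_genes))
        data.frame(cluster = cl, n_nlt_up = n_nlt, n_lt_up = n_lt,
                   score = n_nlt / max(n_lt, 1))
    })
    do.call(rbind, out)
}
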