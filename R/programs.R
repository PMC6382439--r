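## Gene-program temporal ordering: hypergeometric gene-set enrichment of the
## switch genes, mean activation time per term, and comparisons of program
## order across trajectories and conditions.

#' Hypergeometric gene-set enrichment of a switch-gene list
#'
#' One-sided hypergeometric test of each set's overlap with the switch
#' genes against the background universe, Benjamini-Hochberg adjusted. Gene
#' sets are intersected with the background before testing; sets are taken
#' verbatim (no ontology-hierarchy filtering).
#'
#' @param switch_genes genes of interest (must lie in `background`).
#' @param background the tested gene universe (non-empty).
#' @param gene_sets named list of gene-id vectors (e.g. from [readGMT()]).
#' @param q_max enrichment cutoff.
#' @return data.frame (`term`, `n_set`, `n_overlap`, `p`, `q`, `enriched`)
#'   ordered by p.
#' @export
hypergeometricEnrichment <- function(switch_genes, background, gene_sets,
                                     q_max = 0.05) {
    if (!length(background)) stop("empty background")
    if (!all(switch_genes %in% background)) {
        stop("switch genes must be a subset of the background")
    }
    N <- length(background)
    K <- length(switch_genes)
    rows <- lapply(names(gene_sets), function(nm) {
        set <- intersect(gene_sets[[nm]], background)
        k <- length(intersect(set, switch_genes))
        p <- phyper(k - 1, K, N - K, length(set), lower.tail = FALSE)
        data.frame(term = nm, n_set = length(set), n_overlap = k, p = p)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out$enriched <- out$q <= q_max
    out[order(out$p), ]
}

#' Mean activation time per gene program
#'
#' For each term, the mean `t0` over its member genes that are in the
#' reported switch set; terms with fewer than `min_genes` switch members
#' are dropped. The mean is taken over activations and deactivations
#' together; per-direction means are also emitted.
#'
#' @param switch_table a table from [fitAllSwitchGenes()] /
#'   [subsampleMedianFit()]; only rows with `reported = TRUE` are used.
#' @param gene_sets named list of member-gene vectors.
#' @param min_genes minimum switch members per reported term.
#' @return data.frame (`term`, `n_genes`, `mean_t0`, `mean_t0_activation`,
#'   `mean_t0_inhibition`, `dominant_direction`) ordered by `mean_t0`.
#' @export
termActivationTimes <- function(switch_table, gene_sets, min_genes = 2) {
    rep_tab <- switch_table[switch_table$reported, , drop = FALSE]
    rows <- lapply(names(gene_sets), function(nm) {
        hit <- rep_tab[rep_tab$gene %in% gene_sets[[nm]], , drop = FALSE]
        if (nrow(hit) < min_genes) return(NULL)
        act <- hit$t0[hit$direction == "activation"]
        inh <- hit$t0[hit$direction == "inhibition"]
        data.frame(term = nm, n_genes = nrow(hit), mean_t0 = mean(hit$t0),
                   mean_t0_activation = if (length(act)) mean(act) else NA,
                   mean_t0_inhibition = if (length(inh)) mean(inh) else NA,
                   dominant_direction = if (length(act) >= length(inh))
                       "activation" else "inhibition")
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
        return(data.frame(term = character(), n_genes = integer(),
                          mean_t0 = numeric()))
    }
    out[order(out$mean_t0), ]
}

#' Compare program orderings between two trajectories
#'
#' Spearman correlation of the mean activation times of the terms present
#' in both trajectories; p-values are exact for up to 10 shared terms and
#' asymptotic otherwise.
#'
#' @param timingA,timingB outputs of [termActivationTimes()].
#' @return list (`rho`, `p`, `n_terms`, `shared`).
#' @export
compareOrderings <- function(timingA, timingB) {
    common <- intersect(timingA$term, timingB$term)
    if (length(common) < 3) stop("need at least 3 shared terms")
    ta <- timingA$mean_t0[match(common, timingA$term)]
    tb <- timingB$mean_t0[match(common, timingB$term)]
    ct <- suppressWarnings(
        cor.test(ta, tb, method = "spearman",
                 exact = length(common) <= 10))
    list(rho = unname(ct$estimate), p = ct$p.value,
         n_terms = length(common),
         shared = data.frame(term = common, mean_t0_a = ta, mean_t0_b = tb))
}

#' Compare switch times between two conditions
#'
#' For genes with fits in both conditions: per-gene t0 differences, a
#' two-sided Welch two-sample t test between the conditions' t0 values
#' (plus a paired variant, reported separately), the Spearman correlation
#' of the per-gene (t0_A, t0_B) pairs, and mean +/- standard error of the
#' difference per gene category when one is supplied.
#'
#' @param fitsA,fitsB switch tables restricted to a shared reported set, or
#'   the `shared` data.frame of [sharedSwitchGenes()] split into columns;
#'   both must carry `gene` and `t0`.
#' @param categories optional named vector mapping gene -> class (e.g.
#'   skin/LN/cell-cycle marker) for the per-category summary.
#' @return list (`delta`, `t_test_p`, `t_test_p_paired`, `rho`,
#'   `group_means`, `n_genes`).
#' @export
compareConditionT0 <- function(fitsA, fitsB, categories = NULL) {
    common <- intersect(fitsA$gene, fitsB$gene)
    if (length(common) < 3) stop("need at least 3 shared genes")
    ta <- fitsA$t0[match(common, fitsA$gene)]
    tb <- fitsB$t0[match(common, fitsB$gene)]
    delta <- data.frame(gene = common, t0_a = ta, t0_b = tb,
                        delta_t0 = tb - ta)
    tw <- t.test(ta, tb)
    ## degenerate when all per-gene differences are identical
    tp <- tryCatch(t.test(ta, tb, paired = TRUE),
                   error = function(e) list(p.value = NA_real_))
    rho <- suppressWarnings(
        cor.test(ta, tb, method = "spearman", exact = FALSE))
    gm <- NULL
    if (!is.null(categories)) {
        cls <- categories[common]
        cls[is.na(cls)] <- "other"
        gm <- do.call(rbind, lapply(split(delta$delta_t0, cls), function(v) {
            data.frame(n = length(v), mean_delta_t0 = mean(v),
                       se = sd(v) / sqrt(length(v)))
        }))
        gm <- data.frame(category = rownames(gm), gm, row.names = NULL)
    }
    list(delta = delta, t_test_p = tw$p.value,
         t_test_p_paired = tp$p.value, rho = unname(rho$estimate),
         group_means = gm, n_genes = length(common))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: name, description, members).
#' @return named list of gene-id vectors.
#' @export
readGMT <- function(path) {
    fgsea::gmtPathways(path)
}
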