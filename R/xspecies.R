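## Cross-species marker comparison through one-to-one orthologs, and
## detection of paralog-substitution events (the non-lymphoid-marker role
## carried by different members of a paralog family in the two species).

.checkMap <- function(map) {
    if (!nrow(map)) stop("empty ortholog map")
    if (!all(c("gene_a", "gene_b") %in% names(map))) {
        stop("ortholog map needs columns gene_a, gene_b")
    }
    if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
        stop("map is not one-to-one (duplicated genes)")
    }
    map
}

#' Cross-species marker overlap through one-to-one orthologs
#'
#' @param markersA,markersB marker tables (or gene-id vectors) for the two
#'   species.
#' @param map one-to-one ortholog map, data.frame (`gene_a`, `gene_b`).
#' @return list (`n_a`, `n_b`, `n_shared`, `shared`) where `shared` is a
#'   data.frame of the overlapping ortholog pairs. Counts refer to markers
#'   restricted to mapped genes.
#' @export
markerOverlap <- function(markersA, markersB, map) {
    map <- .checkMap(map)
    ga <- if (is.data.frame(markersA)) markersA$gene else markersA
    gb <- if (is.data.frame(markersB)) markersB$gene else markersB
    ga <- intersect(ga, map$gene_a)
    gb <- intersect(gb, map$gene_b)
    shared <- map[map$gene_a %in% ga & map$gene_b %in% gb, , drop = FALSE]
    list(n_a = length(ga), n_b = length(gb), n_shared = nrow(shared),
         shared = shared)
}

#' Fold-change concordance between species
#'
#' Joins the two species' non-lymphoid vs lymphoid fold-changes over
#' one-to-one orthologs and reports the sign-concordance fraction.
#'
#' @param deA,deB DE tables with `gene` and `avg_logFC`.
#' @param map one-to-one ortholog map.
#' @return list with `pairs` (gene_a, gene_b, logFC_a, logFC_b) and
#'   `sign_concordance` (fraction in \[0,1\]).
#' @export
foldChangeConcordance <- function(deA, deB, map) {
    map <- .checkMap(map)
    ia <- match(map$gene_a, deA$gene)
    ib <- match(map$gene_b, deB$gene)
    keep <- !is.na(ia) & !is.na(ib)
    if (!any(keep)) stop("no joinable genes")
    pairs <- data.frame(gene_a = map$gene_a[keep], gene_b = map$gene_b[keep],
                        logFC_a = deA$avg_logFC[ia[keep]],
                        logFC_b = deB$avg_logFC[ib[keep]])
    list(pairs = pairs,
         sign_concordance = mean(sign(pairs$logFC_a) == sign(pairs$logFC_b)))
}

#' Detect paralog-substitution events between two species
#'
#' Reports ortholog pairs (g, g') from the same paralog family where g is a
#' significant non-lymphoid marker in species A while its B ortholog is
#' detected in fewer than `silent_frac` of B's non-lymphoid cells, and the
#' paralog g' shows the mirror pattern (marker in B, silent in A).
#' "Not expressed" is operationalised as detection below `silent_frac`.
#'
#' @param statsA,statsB per-gene expression fractions in the species' NLT
#'   cells: data.frame (`gene`, `pct_nlt`).
#' @param markersA,markersB marker tables or gene-id vectors.
#' @param families data.frame (`family`, `gene_a`, `gene_b`), one row per
#'   ortholog pair belonging to a paralog family.
#' @param silent_frac expression fraction below which a gene counts as not
#'   expressed.
#' @return data.frame of substitution pairs (`family`, `gene_a` the species-A
#'   marker, `gene_b` the species-B paralog marker, supporting fractions).
#' @export
detectParalogSubstitution <- function(statsA, statsB, markersA, markersB,
                                      families, silent_frac = 0.05) {
    ga <- if (is.data.frame(markersA)) markersA$gene else markersA
    gb <- if (is.data.frame(markersB)) markersB$gene else markersB
    pctA <- setNames(statsA$pct_nlt, statsA$gene)
    pctB <- setNames(statsB$pct_nlt, statsB$gene)
    out <- list()
    for (fam in unique(families$family)) {
        rows <- families[families$family == fam, , drop = FALSE]
        miss <- is.na(pctA[rows$gene_a]) | is.na(pctB[rows$gene_b])
        if (any(miss)) {
            warning("family ", fam,
                    ": gene(s) without expression stats skipped")
            rows <- rows[!miss, , drop = FALSE]
        }
        if (nrow(rows) < 2) next
        ## pair i carries the A-marker role, pair j the B-marker role
        for (i in seq_len(nrow(rows))) for (j in seq_len(nrow(rows))) {
            if (i == j) next
            a_marker <- rows$gene_a[i] %in% ga &&
                pctB[rows$gene_b[i]] < silent_frac
            b_marker <- rows$gene_b[j] %in% gb &&
                pctA[rows$gene_a[j]] < silent_frac
            if (a_marker && b_marker) {
                out[[length(out) + 1L]] <- data.frame(
                    family = fam,
                    gene_a = rows$gene_a[i], gene_b = rows$gene_b[j],
                    pct_nlt_a = unname(pctA[rows$gene_a[i]]),
                    pct_nlt_b_ortholog = unname(pctB[rows$gene_b[i]]),
                    pct_nlt_b = unname(pctB[rows$gene_b[j]]),
                    pct_nlt_a_ortholog = unname(pctA[rows$gene_a[j]]))
            }
        }
    }
    if (!length(out)) {
        return(data.frame(family = character(), gene_a = character(),
                          gene_b = character()))
    }
    do.call(rbind, out)
}
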