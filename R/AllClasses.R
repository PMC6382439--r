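#' Simulation configuration for the trajectory dataset generator
#'
#' Describes the study design emulated by [simulateTrajectoryDataset()]:
#' groups of cells (each tied to a tissue and a window of the true adaptation
#' coordinate \eqn{t \in [0,1]}), gene classes, negative-binomial noise and
#' library-size variation.
#'
#' @slot n_cells_per_group integer, cells drawn per group.
#' @slot groups data.frame with columns `name`, `tissue`, `t_lo`, `t_hi`;
#'   each group's true coordinate is Uniform(`t_lo`, `t_hi`). Windows of
#'   consecutive groups overlap by default, emulating a continuous
#'   lymphoid-to-non-lymphoid transition.
#' @slot n_switch_genes,n_flat_genes,n_marker_genes_per_group,n_cellcycle_genes
#'   gene-class sizes.
#' @slot n_background_genes constant high-expression genes that fill each
#'   cell's library to the reference total, emulating the unmodelled bulk of
#'   the transcriptome so log-normalisation behaves as on real data.
#' @slot cycling_fraction fraction of cells in the planted cycling state
#'   (only relevant when `n_cellcycle_genes > 0`).
#' @slot nb_dispersion negative-binomial dispersion (1/size).
#' @slot library_size_log_mean,library_size_log_sd log-normal library size.
#' @slot dropout_extra extra Bernoulli dropout probability applied to counts.
#' @slot seed integer RNG seed; identical config implies identical output.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    n_cells_per_group = "integer",
    groups = "data.frame",
    n_switch_genes = "integer",
    n_flat_genes = "integer",
    n_marker_genes_per_group = "integer",
    n_cellcycle_genes = "integer",
    n_background_genes = "integer",
    cycling_fraction = "numeric",
    nb_dispersion = "numeric",
    library_size_log_mean = "numeric",
    library_size_log_sd = "numeric",
    dropout_extra = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    g <- object@groups
    need <- c("name", "tissue", "t_lo", "t_hi")
    if (!all(need %in% names(g))) {
        msg <- c(msg, "groups needs columns name, tissue, t_lo, t_hi")
    } else {
        if (any(g$t_lo < 0 | g$t_hi > 1 | g$t_lo >= g$t_hi)) {
            msg <- c(msg, "group t-windows must satisfy 0 <= t_lo < t_hi <= 1")
        }
        if (anyDuplicated(g$name)) msg <- c(msg, "group names must be unique")
    }
    if (object@n_cells_per_group < 1L) msg <- c(msg, "need >= 1 cell per group")
    cnt <- c(object@n_switch_genes, object@n_flat_genes,
             object@n_marker_genes_per_group, object@n_cellcycle_genes,
             object@n_background_genes)
    if (any(cnt < 0L)) msg <- c(msg, "gene counts must be >= 0")
    if (sum(cnt) == 0L) msg <- c(msg, "configuration yields zero genes")
    if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
    if (object@dropout_extra < 0 || object@dropout_extra > 1) {
        msg <- c(msg, "dropout_extra must be in [0,1]")
    }
    if (object@cycling_fraction < 0 || object@cycling_fraction > 1) {
        msg <- c(msg, "cycling_fraction must be in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param n_cells_per_group cells per group.
#' @param groups data.frame (`name`, `tissue`, `t_lo`, `t_hi`). The default
#'   places a lymphoid-tissue group on `[0, 0.55]` and a non-lymphoid group on
#'   `[0.45, 1]`, overlapping to emulate the continuous transition.
#' @param n_switch_genes,n_flat_genes,n_marker_genes_per_group,n_cellcycle_genes
#'   gene-class sizes.
#' @param n_background_genes library-filling constant genes (see
#'   [SimConfig-class]).
#' @param cycling_fraction fraction of planted cycling cells.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_size_log_mean,library_size_log_sd log-normal library sizes.
#' @param dropout_extra extra Bernoulli dropout probability.
#' @param seed RNG seed.
#' @return a validated `SimConfig`.
#' @export
simConfig <- function(n_cells_per_group = 250,
                      groups = data.frame(
                          name = c("LT", "NLT"),
                          tissue = c("LN", "NLT"),
                          t_lo = c(0.00, 0.45),
                          t_hi = c(0.55, 1.00)),
                      n_switch_genes = 60,
                      n_flat_genes = 120,
                      n_marker_genes_per_group = 10,
                      n_cellcycle_genes = 0,
                      n_background_genes = 40,
                      cycling_fraction = 0.2,
                      nb_dispersion = 0.5,
                      library_size_log_mean = log(5000),
                      library_size_log_sd = 0.3,
                      dropout_extra = 0,
                      seed = 1L) {
    new("SimConfig",
        n_cells_per_group = as.integer(n_cells_per_group),
        groups = groups,
        n_switch_genes = as.integer(n_switch_genes),
        n_flat_genes = as.integer(n_flat_genes),
        n_marker_genes_per_group = as.integer(n_marker_genes_per_group),
        n_cellcycle_genes = as.integer(n_cellcycle_genes),
        n_background_genes = as.integer(n_background_genes),
        cycling_fraction = cycling_fraction,
        nb_dispersion = nb_dispersion,
        library_size_log_mean = library_size_log_mean,
        library_size_log_sd = library_size_log_sd,
        dropout_extra = dropout_extra,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", nrow(object@groups), "groups x",
        object@n_cells_per_group, "cells;",
        object@n_switch_genes, "switch /", object@n_flat_genes, "flat /",
        nrow(object@groups) * object@n_marker_genes_per_group, "marker /",
        object@n_cellcycle_genes, "cell-cycle genes;",
        "dispersion", object@nb_dispersion, "; seed", object@seed, "\n")
})

#' Latent embedding from the (partitioned) GPLVM
#'
#' Per-cell latent coordinates with per-dimension ARD relevance weights,
#' the selected adaptation dimension and its orientation, and the frozen
#' pieces of the fitted model needed to project new cells.
#'
#' @slot X numeric matrix, cells x latent dimensions.
#' @slot relevance numeric vector of effective ARD weights
#'   `w_q * Var(X_q)` — the inverse squared lengthscale after unit-scaling
#'   the dimension, so the value is invariant to the latent scale — one per
#'   latent dimension; for the partitioned fit this is the column sum of
#'   `partitionRelevance`.
#' @slot partitionRelevance matrix partitions x dimensions of ARD weights, or
#'   NULL for the single-view fit.
#' @slot adaptationDim selected adaptation dimension index (NA until
#'   [selectAdaptationLV()] is applied).
#' @slot orientation +1/-1 sign applied to the adaptation dimension so the
#'   non-lymphoid pole is high.
#' @slot kernel list of kernel hyperparameters (`sf2`, `w`, `sn2`, `jitter`;
#'   per-partition lists for the partitioned fit).
#' @slot featureGenes genes the model was trained on.
#' @slot standardization list with per-gene `center` and `scale`.
#' @slot fitData internal pieces (Kinv, alpha, training Y) for projection.
#' @slot trace optimizer trace (objective value, convergence code).
#' @exportClass LatentEmbedding
setClass("LatentEmbedding", representation(
    X = "matrix",
    relevance = "numeric",
    partitionRelevance = "ANY",
    adaptationDim = "integer",
    orientation = "numeric",
    kernel = "list",
    featureGenes = "character",
    standardization = "list",
    fitData = "list",
    trace = "list"
))

setValidity("LatentEmbedding", function(object) {
    if (any(object@relevance < 0)) return("relevance weights must be >= 0")
    if (length(object@relevance) != ncol(object@X)) {
        return("one relevance weight per latent dimension required")
    }
    TRUE
})

setMethod("show", "LatentEmbedding", function(object) {
    cat("LatentEmbedding:", nrow(object@X), "cells x", ncol(object@X),
        "latent dimensions\n")
    rel <- round(object@relevance / sum(object@relevance), 3)
    cat("  relevance share:", paste(rel, collapse = " "), "\n")
    if (!is.na(object@adaptationDim)) {
        cat("  adaptation LV: dimension", object@adaptationDim,
            "(orientation", object@orientation, ")\n")
    }
    if (!is.null(object@partitionRelevance)) {
        cat("  partitions:", paste(rownames(object@partitionRelevance),
                                   collapse = ", "), "\n")
    }
})

#' L1-penalised multinomial label-transfer model
#'
#' @slot features gene space fixed at training.
#' @slot classes class labels.
#' @slot coefficients (1 + n_features) x n_classes matrix (intercept row
#'   first); predictions are softmax over the linear predictors.
#' @slot metadata training metadata (seed, regularisation, scale of input).
#' @exportClass TransferModel
setClass("TransferModel", representation(
    features = "character",
    classes = "character",
    coefficients = "matrix",
    metadata = "list"
))

setValidity("TransferModel", function(object) {
    if (length(object@classes) < 2L) return("need >= 2 classes")
    if (nrow(object@coefficients) != length(object@features) + 1L) {
        return("coefficient rows must be 1 + n_features")
    }
    if (ncol(object@coefficients) != length(object@classes)) {
        return("one coefficient column per class required")
    }
    TRUE
})

setMethod("show", "TransferModel", function(object) {
    cat("TransferModel:", length(object@classes), "classes over",
        length(object@features), "features;",
        sum(object@coefficients[-1, ] != 0), "non-zero coefficients\n")
})
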