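## Label transfer: L1-penalised multinomial logistic regression trained on a
## labelled reference, mapping query cells to reference subpopulations.

#' Train an L1-penalised multinomial classifier on labelled reference cells
#'
#' Fits a multinomial logistic regression with an L1 penalty on raw counts
#' (the convention of the reference analysis; normalised input is an
#' option). The regularisation strength uses the inverse-strength
#' convention: `l1_strength` is the analogue of C, translated to a lasso
#' penalty of `1 / (n * l1_strength)`.
#'
#' @param x `SingleCellExperiment` or genes x cells matrix (raw counts by
#'   default; pass normalised data with `input_scale = "normalized"` purely
#'   as documentation of what was supplied).
#' @param labels per-cell class labels (>= 2 classes, each >= 2 cells).
#' @param l1_strength inverse regularisation strength.
#' @param seed stored in metadata (the fit itself is deterministic).
#' @param input_scale documentation tag, "counts" or "normalized".
#' @return a [TransferModel-class].
#' @export
trainClassifier <- function(x, labels, l1_strength = 1, seed = 1,
                            input_scale = c("counts", "normalized")) {
    input_scale <- match.arg(input_scale)
    m <- if (input_scale == "counts") .getCounts(x) else .getLogcounts(x)
    labels <- as.factor(labels)
    stopifnot(length(labels) == ncol(m))
    if (nlevels(labels) < 2) stop("need at least 2 classes")
    if (any(table(labels) < 2)) stop("every class needs at least 2 cells")
    xm <- Matrix::t(m)
    n <- nrow(xm)
    lam <- 1 / (n * l1_strength)
    fit <- glmnet::glmnet(xm, labels, family = "multinomial", alpha = 1,
                          lambda = lam, standardize = FALSE)
    co <- glmnet::coef.glmnet(fit, s = lam)
    beta <- do.call(cbind, lapply(co, function(b) as.numeric(b)))
    rownames(beta) <- c("(Intercept)", rownames(m))
    colnames(beta) <- levels(labels)
    new("TransferModel", features = rownames(m),
        classes = levels(labels), coefficients = beta,
        metadata = list(seed = seed, l1_strength = l1_strength,
                        input_scale = input_scale, n_train = n))
}

#' Predict reference labels for query cells
#'
#' Softmax class probabilities from the stored coefficients; each cell gets
#' the argmax label, the full probability vector, and a low-confidence flag
#' when the top probability is below 0.5 (the flag never changes the
#' label). Query genes are matched by id; model features missing from the
#' query are imputed as zero.
#'
#' @param model a [TransferModel-class].
#' @param x query `SingleCellExperiment` or genes x cells matrix on the
#'   same scale the model was trained on.
#' @return list with `labels` (named character), `probabilities` (cells x
#'   classes matrix) and `low_confidence` (logical).
#' @export
predictLabels <- function(model, x) {
    m <- if (model@metadata$input_scale == "counts") .getCounts(x)
         else .getLogcounts(x)
    found <- intersect(model@features, rownames(m))
    if (!length(found)) stop("query shares no genes with the model")
    xm <- matrix(0, ncol(m), length(model@features),
                 dimnames = list(colnames(m), model@features))
    xm[, found] <- as.matrix(Matrix::t(m[found, , drop = FALSE]))
    eta <- cbind(1, xm) %*% model@coefficients
    eta <- eta - apply(eta, 1, max)
    pr <- exp(eta) / rowSums(exp(eta))
    lab <- model@classes[max.col(pr, ties.method = "first")]
    list(labels = setNames(lab, rownames(pr)), probabilities = pr,
         low_confidence = apply(pr, 1, max) < 0.5)
}

#' Cross-tabulate predicted reference labels against query subpopulations
#'
#' @param predicted predicted reference labels per query cell.
#' @param query_clusters the query's own subpopulation labels.
#' @return matrix of row percentages: query subpopulations x reference
#'   labels, each row summing to 100.
#' @export
compositionMatrix <- function(predicted, query_clusters) {
    stopifnot(length(predicted) == length(query_clusters))
    tab <- table(query = query_clusters, reference = predicted)
    100 * prop.table(unclass(tab), margin = 1)
}

#' Serialize / restore a transfer model as JSON
#'
#' @param model a [TransferModel-class].
#' @param path file path.
#' @return `writeTransferModel` the path, invisibly; `readTransferModel`
#'   the restored model (predictions are bit-identical to the original).
#' @export
writeTransferModel <- function(model, path) {
    jsonlite::write_json(list(
        features = model@features, classes = model@classes,
        coefficients = model@coefficients, metadata = model@metadata),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeTransferModel
#' @export
readTransferModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    beta <- as.matrix(obj$coefficients)
    rownames(beta) <- c("(Intercept)", obj$features)
    colnames(beta) <- obj$classes
    new("TransferModel", features = obj$features, classes = obj$classes,
        coefficients = beta, metadata = as.list(obj$metadata))
}
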