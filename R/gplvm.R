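## MAP Gaussian process latent variable model with ARD, plus a partitioned
## (shared-latent-space) variant in which gene partitions share the latent
## coordinates but carry partition-specific relevance weights.
##
## Model: standardized expression Y (cells x genes) is a draw from
## independent GPs over latent coordinates X (cells x Q) with an ARD
## exponentiated-quadratic kernel
##   k(x, x') = sf2 * exp(-0.5 * sum_q w_q (x_q - x'_q)^2) + sn2 * I,
## a standard-normal prior on X, and MAP optimisation of X and the kernel
## hyperparameters by L-BFGS with analytic gradients.
##
## Two regularisers keep the MAP point estimate well behaved: a log-normal
## prior centred at 1 on each ARD weight (this anchors the latent scale —
## the likelihood only depends on sqrt(w_q) * x_q, so without it X can
## collapse while w grows without bound and the latent prior never prunes
## anything) and a noise floor on sn2 (per-gene standardized scRNA-seq
## expression carries a large technical-noise share; letting sn2 collapse
## makes the GP interpolate noise through surplus latent dimensions).
##
## Reported relevance is the scale-invariant effective ARD weight
## w_q * Var(X_q) — the inverse squared lengthscale after rescaling the
## dimension to unit variance. Latent scale and sign are unidentifiable;
## the contract downstream is the cell ordering, fixed by
## selectAdaptationLV().

## squared latent distances per dimension
.latentD2 <- function(X) {
    lapply(seq_len(ncol(X)), function(q) {
        d <- outer(X[, q], X[, q], `-`)
        d * d
    })
}

## Joint objective/gradient over possibly several partitions sharing X.
## Slist: list of per-partition N x N cross-products Y_p %*% t(Y_p);
## Dlist: per-partition gene counts. Parameter vector layout:
## [X | per partition: log w (Q), log sf2, log sn2].
.gplvmEngine <- function(Slist, Dlist, N, Q, maxit = 1000, jitter = 1e-6,
                         noise_floor = 0.3, weight_prior_sd = 1.5,
                         X0 = NULL) {
    P <- length(Slist)
    nhyp <- Q + 2L
    unpack <- function(par) {
        X <- matrix(par[seq_len(N * Q)], N, Q)
        hyp <- lapply(seq_len(P), function(p) {
            off <- N * Q + (p - 1L) * nhyp
            list(w = exp(par[off + seq_len(Q)]),
                 sf2 = exp(par[off + Q + 1L]),
                 sn2 = exp(par[off + Q + 2L]))
        })
        list(X = X, hyp = hyp)
    }

    cache <- new.env(parent = emptyenv())
    evalBoth <- function(par) {
        key <- paste0(format(sum(par * seq_along(par)), digits = 17),
                      format(sum(par^2), digits = 17))
        if (!is.null(cache$key) && identical(cache$key, key)) {
            return(cache$res)
        }
        up <- unpack(par)
        X <- up$X
        D2 <- .latentD2(X)
        f <- 0.5 * sum(X^2)
        gX <- X
        ghyp <- numeric(P * nhyp)
        for (p in seq_len(P)) {
            h <- up$hyp[[p]]
            lw <- log(h$w)
            M <- matrix(0, N, N)
            for (q in seq_len(Q)) M <- M - 0.5 * h$w[q] * D2[[q]]
            Kt <- h$sf2 * exp(M)
            K <- Kt + diag(h$sn2 + jitter, N)
            ch <- tryCatch(chol(K), error = function(e) NULL)
            if (is.null(ch)) {
                res <- list(value = 1e10, grad = rep(0, length(par)))
                cache$key <- key; cache$res <- res
                return(res)
            }
            logdet <- 2 * sum(log(diag(ch)))
            Kinv <- chol2inv(ch)
            KiS <- Kinv %*% Slist[[p]]
            Dp <- Dlist[[p]]
            f <- f + Dp / 2 * logdet + 0.5 * sum(diag(KiS)) +
                0.5 * sum(lw^2) / weight_prior_sd^2
            G <- 0.5 * (Dp * Kinv - KiS %*% Kinv)
            G <- (G + t(G)) / 2
            A <- G * Kt
            rA <- rowSums(A)
            off <- (p - 1L) * nhyp
            for (q in seq_len(Q)) {
                gX[, q] <- gX[, q] -
                    2 * h$w[q] * (rA * X[, q] - A %*% X[, q])
                ghyp[off + q] <- -0.5 * h$w[q] * sum(A * D2[[q]]) +
                    lw[q] / weight_prior_sd^2
            }
            ghyp[off + Q + 1L] <- sum(A)
            ghyp[off + Q + 2L] <- h$sn2 * sum(diag(G))
        }
        res <- list(value = f, grad = c(as.numeric(gX), ghyp))
        cache$key <- key; cache$res <- res
        res
    }

    if (is.null(X0)) X0 <- matrix(rnorm(N * Q, 0, 0.1), N, Q)
    sn2_init <- max(noise_floor, 0.1)
    par0 <- c(as.numeric(X0),
              rep(c(rep(log(1), Q), log(1), log(sn2_init)), P))
    lo <- c(rep(-Inf, N * Q),
            rep(c(rep(log(1e-6), Q), log(1e-4),
                  log(max(noise_floor, 1e-6))), P))
    hi <- c(rep(Inf, N * Q),
            rep(c(rep(log(1e4), Q), log(1e3), log(10)), P))
    fit <- optim(par0, fn = function(p) evalBoth(p)$value,
                 gr = function(p) evalBoth(p)$grad,
                 method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit, factr = 1e7))
    up <- unpack(fit$par)
    list(X = up$X,
         w = do.call(rbind, lapply(up$hyp, `[[`, "w")),
         sf2 = vapply(up$hyp, `[[`, numeric(1), "sf2"),
         sn2 = vapply(up$hyp, `[[`, numeric(1), "sn2"),
         trace = list(value = fit$value, convergence = fit$convergence,
                      counts = fit$counts))
}

## cells x genes standardized expression for a gene set; drops
## zero-variance genes (errors if nothing informative remains)
.standardizeY <- function(x, genes = NULL) {
    norm <- as.matrix(.getLogcounts(x))
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(norm))
        if (length(missing)) {
            stop("genes not present in the matrix: ",
                 paste(head(missing, 5), collapse = ", "))
        }
        norm <- norm[genes, , drop = FALSE]
    }
    Y <- t(norm)
    ctr <- colMeans(Y)
    scl <- apply(Y, 2, sd)
    keep <- scl > 0
    if (sum(keep) < 2) stop("expression is (near-)constant; cannot fit")
    if (!all(keep)) {
        warning(sum(!keep), " constant gene(s) dropped before fitting")
    }
    Y <- sweep(sweep(Y[, keep, drop = FALSE], 2, ctr[keep]), 2,
               scl[keep], `/`)
    list(Y = Y, center = ctr[keep], scale = scl[keep],
         genes = colnames(Y))
}

## deterministic PCA initialisation of the latent coordinates
.pcaInit <- function(Y, Q) {
    pc <- prcomp(Y, center = FALSE, rank. = Q)
    X0 <- pc$x
    if (ncol(X0) < Q) {
        X0 <- cbind(X0, matrix(rnorm(nrow(Y) * (Q - ncol(X0)), 0, 0.01),
                               nrow(Y)))
    }
    ## deterministic sign: largest-magnitude coordinate positive
    for (q in seq_len(Q)) {
        i <- which.max(abs(X0[, q]))
        if (X0[i, q] < 0) X0[, q] <- -X0[, q]
    }
    X0 / sd(X0[, 1]) + matrix(rnorm(length(X0), 0, 1e-3),
                              nrow(X0), ncol(X0))
}

#' Fit a MAP GPLVM with ARD to normalised expression
#'
#' Genes are centred and unit-scaled before fitting; latent coordinates are
#' initialised from PCA and optimised jointly with the kernel
#' hyperparameters. Per-dimension ARD relevance weights rank the latent
#' dimensions by explanatory importance.
#'
#' @param x `SingleCellExperiment` with `logcounts` or a normalised genes x
#'   cells matrix.
#' @param genes genes to use (e.g. from [selectVariableGenes()]); default all.
#' @param q_latent number of latent dimensions.
#' @param seed RNG seed (initialisation jitter).
#' @param maxit optimizer iteration budget; non-convergence within the
#'   budget gives a warning and the trace is kept in the object.
#' @param jitter diagonal jitter added to the kernel.
#' @param noise_floor lower bound on the kernel noise variance, on the
#'   per-gene standardized scale (default 0.3: at least 30% of a
#'   standardized gene's variance is treated as noise, preventing the MAP
#'   fit from interpolating technical noise through surplus dimensions).
#' @param weight_prior_sd standard deviation of the log-normal prior
#'   anchoring the ARD weights at 1 (resolves the latent-scale/weight
#'   degeneracy of the MAP treatment).
#' @return a [LatentEmbedding-class]. Relevance is reported as the
#'   scale-invariant effective ARD weight `w_q * Var(X_q)` (the inverse
#'   squared lengthscale after unit-scaling the dimension).
#' @export
fitGPLVM <- function(x, genes = NULL, q_latent = 6, seed = 1,
                     maxit = 1000, jitter = 1e-6, noise_floor = 0.3,
                     weight_prior_sd = 1.5) {
    std <- .standardizeY(x, genes)
    Y <- std$Y
    N <- nrow(Y)
    if (N < 20) stop("need at least 20 cells")
    res <- withSeed(seed, {
        X0 <- .pcaInit(Y, q_latent)
        .gplvmEngine(list(tcrossprod(Y)), list(ncol(Y)), N, q_latent,
                     maxit = maxit, jitter = jitter,
                     noise_floor = noise_floor,
                     weight_prior_sd = weight_prior_sd, X0 = X0)
    })
    if (res$trace$convergence != 0) {
        warning("optimizer did not converge within the iteration budget ",
                "(code ", res$trace$convergence, ")")
    }
    X <- res$X
    rownames(X) <- rownames(Y)
    w <- as.numeric(res$w[1, ])
    kern <- list(w = w, sf2 = res$sf2[1], sn2 = res$sn2[1], jitter = jitter)
    M <- matrix(0, N, N)
    D2 <- .latentD2(X)
    for (q in seq_len(q_latent)) M <- M - 0.5 * w[q] * D2[[q]]
    K <- kern$sf2 * exp(M) + diag(kern$sn2 + jitter, N)
    Kinv <- chol2inv(chol(K))
    new("LatentEmbedding", X = X,
        relevance = w * apply(X, 2, var),
        partitionRelevance = NULL, adaptationDim = NA_integer_,
        orientation = 1, kernel = kern, featureGenes = std$genes,
        standardization = list(center = std$center, scale = std$scale),
        fitData = list(Kinv = Kinv, alpha = Kinv %*% Y, Ytrain = Y),
        trace = res$trace)
}

#' Fit a partitioned GPLVM (shared latent space, per-partition relevance)
#'
#' The gene space is divided into disjoint partitions (canonically
#' `cellcycle`, `tissue_markers`, `rest`); all partitions share the latent
#' coordinates but each carries its own ARD relevance weights, kernel
#' variance and noise, so confounding factors such as the cell cycle can be
#' isolated from the tissue-adaptation signal.
#'
#' @param x `SingleCellExperiment` with `logcounts` or normalised matrix.
#' @param partitions named list of disjoint, non-empty gene-id vectors.
#' @param q_latent number of latent dimensions.
#' @param seed,maxit,jitter,noise_floor,weight_prior_sd as in [fitGPLVM()].
#' @return a [LatentEmbedding-class] with `partitionRelevance` set
#'   (partitions x dimensions).
#' @export
fitPartitionedGPLVM <- function(x, partitions, q_latent = 12, seed = 1,
                                maxit = 1000, jitter = 1e-6,
                                noise_floor = 0.3, weight_prior_sd = 1.5) {
    if (is.null(names(partitions)) || any(names(partitions) == "")) {
        stop("partitions must be a named list")
    }
    if (any(lengths(partitions) == 0)) stop("empty partition")
    if (anyDuplicated(unlist(partitions))) {
        stop("partitions must be disjoint")
    }
    stds <- lapply(partitions, function(g) .standardizeY(x, g))
    N <- nrow(stds[[1]]$Y)
    if (N < 20) stop("need at least 20 cells")
    res <- withSeed(seed, {
        X0 <- .pcaInit(do.call(cbind, lapply(stds, `[[`, "Y")), q_latent)
        .gplvmEngine(lapply(stds, function(s) tcrossprod(s$Y)),
                     lapply(stds, function(s) ncol(s$Y)),
                     N, q_latent, maxit = maxit, jitter = jitter,
                     noise_floor = noise_floor,
                     weight_prior_sd = weight_prior_sd, X0 = X0)
    })
    if (res$trace$convergence != 0) {
        warning("optimizer did not converge within the iteration budget ",
                "(code ", res$trace$convergence, ")")
    }
    X <- res$X
    rownames(X) <- rownames(stds[[1]]$Y)
    rel <- sweep(res$w, 2, apply(X, 2, var), `*`)
    rownames(rel) <- names(partitions)
    new("LatentEmbedding", X = X, relevance = colSums(rel),
        partitionRelevance = rel, adaptationDim = NA_integer_,
        orientation = 1,
        kernel = list(w = res$w, sf2 = res$sf2, sn2 = res$sn2,
                      jitter = jitter),
        featureGenes = unlist(lapply(stds, `[[`, "genes"), use.names = FALSE),
        standardization = list(
            center = unlist(lapply(stds, `[[`, "center")),
            scale = unlist(lapply(stds, `[[`, "scale"))),
        fitData = list(), trace = res$trace)
}

#' Select and orient the adaptation dimension of an embedding
#'
#' Picks the latent dimension representing the lymphoid-to-non-lymphoid
#' transition: the highest-relevance dimension whose cell ordering
#' correlates with tissue identity (point-biserial |r| with the NLT
#' indicator of at least `corr_min`; if none qualifies, the dimension with
#' the largest |r|). For partitioned fits, dimensions dominated by the
#' cell-cycle partition (cell-cycle relevance at least `cycle_max_frac`
#' times that partition's maximum) are excluded first, and relevance is
#' ranked by the tissue-marker partition. Orientation is set so the
#' non-lymphoid pole is high.
#'
#' @param embedding a [LatentEmbedding-class].
#' @param tissue per-cell tissue labels.
#' @param nlt values of `tissue` counted as non-lymphoid.
#' @param corr_min minimum point-biserial |r| to qualify.
#' @param cycle_max_frac cell-cycle dominance threshold (partitioned fits).
#' @param cycle_partition,tissue_partition partition names.
#' @return the embedding with `adaptationDim` and `orientation` set.
#' @export
selectAdaptationLV <- function(embedding, tissue, nlt = "NLT",
                               corr_min = 0.3, cycle_max_frac = 0.5,
                               cycle_partition = "cellcycle",
                               tissue_partition = "tissue_markers") {
    X <- embedding@X
    stopifnot(length(tissue) == nrow(X))
    ind <- as.numeric(tissue %in% nlt)
    if (all(ind == 1) || all(ind == 0)) {
        stop("need both lymphoid and non-lymphoid cells to orient")
    }
    r <- as.numeric(cor(X, ind))
    pw <- embedding@partitionRelevance
    if (!is.null(pw) && all(c(cycle_partition, tissue_partition)
                            %in% rownames(pw))) {
        cyc <- pw[cycle_partition, ]
        share <- if (sum(cyc) > 0) cyc / sum(cyc) else cyc
        ## a dimension counts as cycle-specific only when the cycle
        ## partition is genuinely concentrated on it (more than twice the
        ## uniform share); with a factor-less cycle partition no dimension
        ## qualifies and selection reduces to plain tissue relevance
        concentrated <- max(share) > 2 / ncol(X)
        ok <- if (concentrated) share < cycle_max_frac * max(share)
              else rep(TRUE, ncol(X))
        if (!any(ok)) ok <- rep(TRUE, ncol(X))
        rel <- pw[tissue_partition, ]
        rel[!ok] <- -Inf
    } else {
        rel <- embedding@relevance
    }
    cand <- which(abs(r) >= corr_min & is.finite(rel))
    dim <- if (length(cand)) cand[which.max(rel[cand])] else which.max(abs(r))
    lv <- X[, dim]
    sgn <- if (mean(lv[ind == 1]) >= mean(lv[ind == 0])) 1 else -1
    embedding@adaptationDim <- as.integer(dim)
    embedding@orientation <- sgn
    embedding
}

#' Latent dimension most relevant to one partition
#'
#' For partitioned fits: the coordinates of the dimension with the largest
#' ARD weight in the given partition (e.g. the cell-cycle factor).
#'
#' @param embedding a partitioned [LatentEmbedding-class].
#' @param partition partition name.
#' @return named list with `dim` (index) and `lv` (coordinates).
#' @export
partitionTopLV <- function(embedding, partition) {
    pw <- embedding@partitionRelevance
    if (is.null(pw)) stop("embedding has no partitions")
    if (!partition %in% rownames(pw)) {
        stop("unknown partition: ", partition)
    }
    dim <- which.max(pw[partition, ])
    list(dim = dim, lv = setNames(embedding@X[, dim], rownames(embedding@X)))
}

#' Project new cells into a fitted latent space
#'
#' Optimises each new cell's latent coordinate against the trained model's
#' predictive objective with all kernel hyperparameters frozen: the squared
#' error between the cell's standardized expression and the GP posterior
#' mean at the candidate coordinate, plus the standard-normal latent prior
#' (so cells carrying no signal revert towards the prior mean). Each cell
#' is optimised from two deterministic starts — the latent position of its
#' nearest training cell in standardized gene space, and the prior mean —
#' keeping the better optimum. Genes missing from the query are filled with
#' zero counts (the training mean after standardization shift) and their
#' number reported.
#'
#' @param embedding a [LatentEmbedding-class] from [fitGPLVM()].
#' @param x_new `SingleCellExperiment` with `logcounts` or normalised genes
#'   x cells matrix for the new cells.
#' @param maxit per-cell optimizer budget.
#' @return matrix of latent coordinates (cells x dimensions).
#' @export
projectCells <- function(embedding, x_new, maxit = 100) {
    if (!length(embedding@fitData)) {
        stop("projection requires a single-view fit from fitGPLVM()")
    }
    norm <- as.matrix(.getLogcounts(x_new))
    genes <- embedding@featureGenes
    found <- intersect(genes, rownames(norm))
    if (!length(found)) stop("no overlap with the model's gene space")
    n_missing <- length(genes) - length(found)
    if (n_missing > 0) {
        message(n_missing, " model gene(s) absent from the query; zero-filled")
    }
    Yn <- matrix(0, ncol(norm), length(genes),
                 dimnames = list(colnames(norm), genes))
    Yn[, found] <- t(norm[found, , drop = FALSE])
    Yn <- sweep(sweep(Yn, 2, embedding@standardization$center), 2,
                embedding@standardization$scale, `/`)

    X <- embedding@X
    kern <- embedding@kernel
    alpha <- embedding@fitData$alpha
    Q <- ncol(X)

    cellObj <- function(xs, y) {
        d <- sweep(X, 2, xs)
        kv <- kern$sf2 * exp(-0.5 * as.numeric((d * d) %*% kern$w))
        m <- as.numeric(crossprod(kv, alpha))   # posterior mean per gene
        r <- m - y
        f <- 0.5 * sum(r^2) + 0.5 * sum(xs^2)
        dk <- sweep(d, 2, kern$w, `*`) * kv     # N x Q: d k / d xs
        dm <- crossprod(alpha, dk)              # D x Q
        g <- as.numeric(crossprod(dm, r)) + xs
        list(value = f, grad = g)
    }

    out <- matrix(0, nrow(Yn), Q,
                  dimnames = list(rownames(Yn), colnames(X)))
    ## nearest training cell in standardized expression space
    Ytr <- embedding@fitData$Ytrain
    for (i in seq_len(nrow(Yn))) {
        y <- Yn[i, ]
        nn <- which.min(colSums((t(Ytr) - y)^2))
        best <- NULL
        for (x0 in list(X[nn, ], rep(0, Q))) {
            f0 <- cellObj(x0, y)$value
            fit <- tryCatch(
                optim(x0, fn = function(p) cellObj(p, y)$value,
                      gr = function(p) cellObj(p, y)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit)),
                error = function(e) list(par = x0, value = f0))
            if (fit$value > f0) fit <- list(par = x0, value = f0)
            if (is.null(best) || fit$value < best$value) best <- fit
        }
        out[i, ] <- best$par
    }
    out
}

#' Genes correlated with a latent variable
#'
#' Pearson correlation of each gene's normalised expression with the latent
#' coordinate; genes with |r| above the threshold are flagged.
#'
#' @param x `SingleCellExperiment` with `logcounts` or normalised matrix.
#' @param lv latent coordinate per cell (non-constant).
#' @param min_abs_corr flagging threshold on |r|.
#' @return data.frame (`gene`, `r`, `flagged`).
#' @export
lvGeneCorrelation <- function(x, lv, min_abs_corr = 0.25) {
    norm <- as.matrix(.getLogcounts(x))
    stopifnot(length(lv) == ncol(norm))
    if (sd(lv) == 0) stop("latent variable has zero variance")
    r <- suppressWarnings(as.numeric(cor(t(norm), lv)))
    r[is.na(r)] <- 0
    data.frame(gene = rownames(norm), r = r,
               flagged = abs(r) > min_abs_corr, row.names = NULL)
}

#' Shared proportion between two flagged gene sets
#'
#' @param setA,setB character vectors of gene ids (e.g. the flagged genes of
#'   two latent variables).
#' @return list with `n_shared` and the shared proportions `frac_a` (of
#'   `setA`) and `frac_b` (of `setB`), as percentages.
#' @export
sharedCorrelatedFraction <- function(setA, setB) {
    n <- length(intersect(setA, setB))
    list(n_shared = n,
         frac_a = if (length(setA)) 100 * n / length(setA) else NA_real_,
         frac_b = if (length(setB)) 100 * n / length(setB) else NA_real_)
}
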