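## Switch-like gene kinetics along the adaptation coordinate.
##
## Each gene's normalised expression y over the latent coordinate t is
## modelled with a sigmoid mean S(t) = 2*mu0 / (1 + exp(-k*(t - t0))) under a
## Gaussian likelihood with constant (profiled) variance, and tested against
## the constant-mean model by a likelihood-ratio test with 2 degrees of
## freedom. mu0 is the mean expression between the "on" and "off" states, t0
## the point where the switch happens, and k the activation strength; the
## sign of k gives the direction (activation vs inhibition).

#' Sigmoid switch mean
#'
#' \eqn{S(t) = 2\mu_0 / (1 + e^{-k (t - t_0)})}; at `t = t0` the value is
#' `mu0`, and for large `|k|` it approaches a step between 0 and `2*mu0`.
#' Numerically safe for arbitrarily large `|k|`.
#'
#' @param t coordinate values.
#' @param mu0 mean expression between the on and off states.
#' @param k activation strength (signed; positive = activation).
#' @param t0 switch point.
#' @return numeric vector of means.
#' @export
sigmoidMean <- function(t, mu0, k, t0) {
    2 * mu0 * plogis(k * (t - t0))
}

## profiled-variance Gaussian log-likelihood from a residual sum of squares
.rssLoglik <- function(rss, n) {
    rss <- max(rss, 1e-12)
    -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Fit the sigmoid switch model to one gene
#'
#' Maximum likelihood under a Gaussian with sigmoid mean and constant
#' variance (variance profiled out), with deterministic restarts from a grid
#' of starting values: `t0` at the 20/50/80% quantiles of `t`, `k` at
#' plus/minus 1 and 10 divided by the range of `t`, `mu0` at the mean
#' expression. Box bounds keep `mu0 > 0` and `|k| <= 1e4 / range(t)`.
#' The likelihood-ratio statistic against the constant-mean model is
#' referred to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param expr normalised expression values for one gene.
#' @param t latent-coordinate values (same length, non-constant).
#' @param n_restarts number of grid starts refined by the optimizer (the
#'   best-scoring `n_restarts` of the 12 grid points).
#' @return one-row data.frame: `mu0`, `k`, `t0`, `loglik_sigmoid`,
#'   `loglik_constant`, `lrt`, `p`, `direction`, `valid`.
#' @export
fitSwitchGene <- function(expr, t, n_restarts = 3) {
    n <- length(expr)
    stopifnot(length(t) == n)
    if (n < 10) stop("need at least 10 cells")
    rng <- diff(range(t))
    if (rng == 0) stop("t is constant")

    ybar <- mean(expr)
    rss0 <- sum((expr - ybar)^2)

    kmax <- 1e4 / rng
    lower <- c(1e-8, -kmax, min(t) - rng)
    upper <- c(max(max(expr), 1e-6) * 2 + 1, kmax, max(t) + rng)

    obj <- function(par) {
        s <- sigmoidMean(t, par[1], par[2], par[3])
        sum((expr - s)^2)
    }
    grad <- function(par) {
        z <- plogis(par[2] * (t - par[3]))
        s <- 2 * par[1] * z
        r <- expr - s
        dz <- z * (1 - z)
        c(-2 * sum(r * 2 * z),
          -2 * sum(r * 2 * par[1] * dz * (t - par[3])),
          2 * sum(r * 2 * par[1] * dz * par[2]))
    }

    mu_start <- max(ybar, 1e-6)
    t0_grid <- unname(quantile(t, c(0.2, 0.5, 0.8)))
    k_grid <- c(-10, -1, 1, 10) / rng
    starts <- expand.grid(mu0 = mu_start, k = k_grid, t0 = t0_grid)
    start_rss <- apply(starts, 1, obj)
    take <- order(start_rss)[seq_len(min(n_restarts, nrow(starts)))]

    best <- list(par = c(mu_start, 0, median(t)), value = rss0)
    for (i in take) {
        fit <- tryCatch(
            optim(as.numeric(starts[i, ]), obj, grad, method = "L-BFGS-B",
                  lower = lower, upper = upper,
                  control = list(maxit = 200)),
            error = function(e) NULL)
        if (!is.null(fit) && fit$value < best$value) best <- fit
    }
    valid <- is.finite(best$value)
    ## the constant model is the k = 0 boundary of the sigmoid family, so
    ## the sigmoid fit can never be worse; clamp against optimizer slack
    rss1 <- min(best$value, rss0)
    par <- best$par
    if (best$value > rss0) par <- c(mu_start, 0, median(t))

    ll1 <- .rssLoglik(rss1, n)
    ll0 <- .rssLoglik(rss0, n)
    lrt <- max(2 * (ll1 - ll0), 0)
    data.frame(mu0 = par[1], k = par[2], t0 = par[3],
               loglik_sigmoid = ll1, loglik_constant = ll0, lrt = lrt,
               p = pchisq(lrt, df = 2, lower.tail = FALSE),
               direction = ifelse(par[2] >= 0, "activation", "inhibition"),
               valid = valid)
}

#' Fit the switch model to all genes along a latent variable
#'
#' Genes are pre-filtered to those expressed (normalised value > 0) in at
#' least `min_cells` cells and with absolute Pearson correlation with the
#' latent variable greater than `min_abs_corr`. Benjamini-Hochberg q-values
#' are computed over the fitted genes; a gene is flagged `reported` if
#' `q <= q_max` and its fitted `t0` lies within the observed range of the
#' latent variable.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or a normalised genes x
#'   cells matrix.
#' @param lv latent-coordinate vector (one value per cell).
#' @param min_cells minimum number of expressing cells.
#' @param min_abs_corr minimum |Pearson r| with `lv` (set to 0 to disable).
#' @param q_max q-value cutoff for the reported set.
#' @param exclude_genes optional gene ids to drop before testing (e.g.
#'   markers of a contaminating cell type).
#' @return data.frame with one row per fitted gene: `gene`, `mu0`, `k`,
#'   `t0`, `p`, `q`, `direction`, `n_expressing`, `corr_lv`, `reported`.
#' @export
fitAllSwitchGenes <- function(x, lv, min_cells = 30, min_abs_corr = 0.25,
                              q_max = 0.05, exclude_genes = NULL) {
    norm <- as.matrix(.getLogcounts(x))
    stopifnot(length(lv) == ncol(norm))
    if (!is.null(exclude_genes)) {
        norm <- norm[!rownames(norm) %in% exclude_genes, , drop = FALSE]
    }
    n_expr <- rowSums(norm > 0)
    r <- suppressWarnings(as.numeric(cor(t(norm), lv)))
    r[is.na(r)] <- 0
    keep <- n_expr >= min_cells & abs(r) > min_abs_corr
    if (!any(keep)) {
        warning("no genes pass the pre-filters")
        return(data.frame(gene = character(), mu0 = numeric(),
                          k = numeric(), t0 = numeric(), p = numeric(),
                          q = numeric(), direction = character(),
                          n_expressing = integer(), corr_lv = numeric(),
                          reported = logical()))
    }
    idx <- which(keep)
    fits <- lapply(idx, function(i) fitSwitchGene(norm[i, ], lv))
    tab <- do.call(rbind, fits)
    tab <- data.frame(gene = rownames(norm)[idx],
                      tab[c("mu0", "k", "t0", "p")],
                      q = p.adjust(tab$p, method = "BH"),
                      direction = tab$direction,
                      n_expressing = n_expr[idx], corr_lv = r[idx],
                      row.names = NULL)
    tab$reported <- tab$q <= q_max & tab$t0 >= min(lv) & tab$t0 <= max(lv)
    tab
}

#' Subsample-median switch fits for unbalanced subpopulations
#'
#' Runs [fitAllSwitchGenes()] `n_rounds` times, each on a subsample drawn
#' without replacement from every group matching the smallest group's size,
#' and summarises each gene by the element-wise median of its parameters
#' over the rounds in which it was fitted. A gene is `reported` if it passed
#' the filters (q-value and t0-range) in more than half of the rounds.
#'
#' @param x normalised matrix or SCE with `logcounts`.
#' @param lv latent coordinate per cell.
#' @param groups group (subpopulation) label per cell; at least 2 groups,
#'   smallest group >= 10 cells.
#' @param n_rounds subsampling rounds.
#' @param seed RNG seed.
#' @param ... passed to [fitAllSwitchGenes()].
#' @return data.frame with median `mu0`, `k`, `t0`, `q`, plus
#'   `n_rounds_fitted`, `n_rounds_passed` and `reported`.
#' @export
subsampleMedianFit <- function(x, lv, groups, n_rounds = 100, seed = 1, ...) {
    norm <- .getLogcounts(x)
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(norm), length(lv) == ncol(norm))
    sizes <- table(groups)
    if (length(sizes) < 2) stop("need at least 2 groups")
    m <- min(sizes)
    if (m < 10) stop("smallest group must have >= 10 cells")
    withSeed(seed, {
        acc <- list()
        for (r in seq_len(n_rounds)) {
            take <- unlist(lapply(split(seq_along(groups), groups),
                                  function(ii) sample(ii, m)))
            fit <- fitAllSwitchGenes(norm[, take, drop = FALSE], lv[take], ...)
            if (nrow(fit)) acc[[r]] <- cbind(fit, round = r)
        }
        all <- do.call(rbind, acc)
        if (is.null(all)) {
            warning("no genes fitted in any round")
            return(data.frame(gene = character()))
        }
        med <- function(v) median(v, na.rm = TRUE)
        agg <- aggregate(all[c("mu0", "k", "t0", "q")],
                         by = list(gene = all$gene), FUN = med)
        n_fit <- table(all$gene)
        n_pass <- tapply(all$reported, all$gene, sum)
        agg$direction <- ifelse(agg$k >= 0, "activation", "inhibition")
        agg$n_rounds_fitted <- as.integer(n_fit[agg$gene])
        agg$n_rounds_passed <- as.integer(n_pass[agg$gene])
        agg$reported <- agg$n_rounds_passed > n_rounds / 2
        attr(agg, "subsample_size") <- m
        agg
    })
}

#' Intersection of reported switch genes between two trajectories
#'
#' @param tableA,tableB switch-fit tables from [fitAllSwitchGenes()] or
#'   [subsampleMedianFit()] (same gene universe).
#' @return list with `shared` (data.frame `gene`, `t0_a`, `t0_b`),
#'   `n_a`, `n_b`, `n_shared`.
#' @export
sharedSwitchGenes <- function(tableA, tableB) {
    ra <- tableA[tableA$reported, , drop = FALSE]
    rb <- tableB[tableB$reported, , drop = FALSE]
    common <- intersect(ra$gene, rb$gene)
    list(shared = data.frame(
             gene = common,
             t0_a = ra$t0[match(common, ra$gene)],
             t0_b = rb$t0[match(common, rb$gene)]),
         n_a = nrow(ra), n_b = nrow(rb), n_shared = length(common))
}
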