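#' @importFrom methods new is validObject slot
#' @importFrom stats var sd cor median quantile rnorm runif rbinom rnbinom
#'   rlnorm rmultinom dnbinom optim prcomp pchisq phyper p.adjust wilcox.test
#'   t.test cor.test setNames plogis approxfun aggregate
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom tools md5sum
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @import SummarizedExperiment
NULL

## Run `code` under a fixed RNG seed without disturbing the caller's RNG
## state. All stochastic entry points thread their `seed` argument through
## this, so identical inputs give bitwise-identical outputs.
withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

## counts matrix (genes x cells) out of an SCE or plain/sparse matrix
.getCounts <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "counts")
    } else {
        x
    }
}

.getLogcounts <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"logcounts" %in% SummarizedExperiment::assayNames(x)) {
            stop("no 'logcounts' assay; run logNormalize() first")
        }
        SummarizedExperiment::assay(x, "logcounts")
    } else {
        x
    }
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
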