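## Readers and writers for the standard on-disk formats: Matrix Market
## triplet counts with gene/barcode label files (the 10x dialect), dense
## TSV matrices, and the tab-separated tables used throughout.

#' Write counts as Matrix Market triplet plus label files
#'
#' Produces `matrix.mtx`, `genes.tsv` and `barcodes.tsv` in `dir`, plus
#' `metadata.tsv` with the per-cell annotation when the input carries one.
#'
#' @param x `SingleCellExperiment` or genes x cells count matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts10x <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    counts <- .getCounts(x)
    Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    if (is(x, "SummarizedExperiment")) {
        .writeTSV(as.data.frame(SummarizedExperiment::colData(x)),
                  file.path(dir, "metadata.tsv"))
    }
    invisible(dir)
}

#' Read counts written by [writeCounts10x()] (or any 10x-style triplet dir)
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `metadata.tsv`.
#' @return a `SingleCellExperiment` with a `counts` assay.
#' @export
readCounts10x <- function(dir) {
    m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    rownames(m) <- readLines(file.path(dir, "genes.tsv"))
    colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
    cd <- if (file.exists(file.path(dir, "metadata.tsv"))) {
        md <- read.delim(file.path(dir, "metadata.tsv"))
        S4Vectors::DataFrame(md, row.names = md$cell_id)
    } else {
        S4Vectors::DataFrame(row.names = colnames(m))
    }
    SingleCellExperiment(assays = list(counts = m), colData = cd)
}

#' Read a dense TSV count matrix (genes in rows, cells in columns)
#'
#' @param path TSV file with gene ids in the first column and cell ids in
#'   the header.
#' @return a `SingleCellExperiment` with a `counts` assay.
#' @export
readCountsTSV <- function(path) {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    SingleCellExperiment(assays = list(
        counts = as(as.matrix(df), "CsparseMatrix")))
}

#' Read a reconstructed-TCR chain table
#'
#' @param path TSV with columns `cell_id`, `locus` (A/B/G/D), `productive`,
#'   `cdr3`.
#' @return validated data.frame.
#' @export
readTCRTable <- function(path) {
    tcr <- read.delim(path, colClasses = c(cell_id = "character",
                                           cdr3 = "character"))
    need <- c("cell_id", "locus", "productive", "cdr3")
    if (!all(need %in% names(tcr))) {
        stop("TCR table needs columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(unique(tcr$locus), c("A", "B", "G", "D"))
    if (length(bad)) stop("unknown TCR locus code(s): ",
                          paste(bad, collapse = ", "))
    tcr
}

#' Read an ortholog/paralog map
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optionally
#'   `homology_type` and `family_id`.
#' @return data.frame.
#' @export
readOrthologMap <- function(path) {
    map <- read.delim(path)
    if (!all(c("gene_a", "gene_b") %in% names(map))) {
        stop("map needs columns gene_a, gene_b")
    }
    map
}

#' Read a two-column signature table (set name, gene)
#'
#' @param path TSV with columns `set` and `gene` (header required).
#' @return named list of gene-id vectors.
#' @export
readSignatureTSV <- function(path) {
    df <- read.delim(path)
    if (!all(c("set", "gene") %in% names(df))) {
        stop("signature table needs columns set, gene")
    }
    split(df$gene, df$set)
}
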