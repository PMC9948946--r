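#' Read and write count matrices
#'
#' Counts are exchanged either as MatrixMarket sparse triplets with
#' sidecar feature/barcode TSVs (`writeCountsMtx`/`readCountsMtx`, the
#' layout of CellRanger-style exports) or as a dense TSV with genes in
#' rows (`writeCountsTsv`/`readCountsTsv`).
#'
#' @param counts gene-by-cell matrix or an experiment with a `counts`
#'   assay.
#' @param dir directory receiving `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return `readCountsMtx`/`readCountsTsv` return a gene-by-cell matrix;
#'   the writers return their destination invisibly.
#' @name countsIO
NULL

#' @rdname countsIO
#' @export
writeCountsMtx <- function(counts, dir) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname countsIO
#' @export
readCountsMtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' @rdname countsIO
#' @param path file path.
#' @export
writeCountsTsv <- function(counts, path) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  write.table(as.matrix(counts), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname countsIO
#' @export
readCountsTsv <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}

#' Read and write GMT geneset collections
#'
#' One geneset per line: name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @param sets named list of character gene vectors.
#' @return `readGmt` returns a named list of gene vectors.
#' @name gmtIO
NULL

#' @rdname gmtIO
#' @export
readGmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[`, "", 1)
  sets
}

#' @rdname gmtIO
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write network edge tables
#'
#' TSV with columns `tf`, `target`, `mi`, `support`, `p`, `fdr` (plus
#' `normMi` when present).
#'
#' @param net a [GrnNetwork-class].
#' @param path file path.
#' @return `readNetworkTsv` returns the edge data.frame.
#' @name networkIO
NULL

#' @rdname networkIO
#' @export
writeNetworkTsv <- function(net, path) {
  write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname networkIO
#' @export
readNetworkTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with a header naming the two species columns.
#' @return two-column data.frame.
#' @export
readOrthologMap <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `log2FC`, `P` and optionally `adjP`; the
#' result feeds [rankMetric()].
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a TSS table
#'
#' TSV with columns `gene`, `seqnames`, `position` (0-based), `strand`,
#' as consumed by [makePromoters()].
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readTssTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write ground truth of a simulated dataset as JSON
#'
#' @param sce a [simulateDataset()] result.
#' @param path output JSON path.
#' @export
writeGroundTruthJson <- function(sce, path) {
  jsonlite::write_json(S4Vectors::metadata(sce)$groundTruth, path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
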