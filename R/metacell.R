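#' Counts-per-million normalization
#'
#' Scales every cell (column) to one million total counts, the
#' library-size normalization applied before computing cell-cell
#' correlation distances.
#'
#' @param counts non-negative gene-by-cell matrix (base or Matrix), or a
#'   `SingleCellExperiment`/`SummarizedExperiment` with a `counts` assay.
#' @return matrix of the same shape whose columns each sum to 1e6.
#' @examples
#' cpmNormalize(matrix(c(1, 1, 2), ncol = 1))
#' @export
cpmNormalize <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("all-zero cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  out <- as.matrix(counts) %*% diag(1e6 / cs, length(cs))
  dimnames(out) <- dimnames(counts)
  out
}

#' Cell-cell correlation distance
#'
#' Distance `d(i, j) = 1 - Pearson r` between cell columns computed over
#' genes, the distance used for metacell construction.
#'
#' @param normalized gene-by-cell matrix (typically [cpmNormalize()]
#'   output) with at least 2 cells and 2 variable genes.
#' @return symmetric cell-by-cell distance matrix with zero diagonal.
#' @export
correlationDistance <- function(normalized) {
  if (ncol(normalized) < 2) stop("need at least 2 cells")
  v <- apply(normalized, 2, sd)
  if (any(v == 0)) {
    bad <- colnames(normalized)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  d <- 1 - cor(normalized)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Aggregate single cells into metacells
#'
#' Deterministic metacell construction on a precomputed distance matrix:
#' `subSize` seed cells are chosen by farthest-point sampling (the first
#' seed is the cell with minimal total distance, i.e. the most central
#' cell; each further seed maximizes its distance to the chosen set).
#' Remaining cells are then attached greedily, globally nearest
#' seed-cell pair first, each seed absorbing at most `numNeighbors`
#' cells — so a seed never reaches across a cluster gap while closer
#' pairs are available. Counts of a metacell are the sum of raw counts
#' over its members, so total counts over assigned cells are conserved;
#' cells beyond the total capacity `subSize * (numNeighbors + 1)` remain
#' unassigned.
#'
#' @param counts gene-by-cell count matrix, or an experiment object with
#'   a `counts` assay.
#' @param dist cell-by-cell distance matrix consistent with `counts`.
#' @param numNeighbors neighbors absorbed per seed (default 9, i.e.
#'   metacells of ~10 cells); must be smaller than the number of cells.
#' @param subSize number of metacells (default `ceiling(nCells / 10)`).
#' @return a [MetacellExperiment-class] with assay `counts` and the
#'   member-cell identifiers in its `membership` slot.
#' @export
buildMetacells <- function(counts, dist, numNeighbors = 9,
                           subSize = NULL) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  nC <- ncol(counts)
  if (is.null(subSize)) subSize <- ceiling(nC / 10)
  if (!all(dim(dist) == c(nC, nC)))
    stop("dist is not consistent with the cells of counts")
  if (numNeighbors >= nC) stop("numNeighbors must be smaller than n_cells")
  if (subSize < 1 || subSize > nC) stop("subSize must lie in [1, n_cells]")
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("cell%d", seq_len(nC))

  # farthest-point seed selection; ties broken by smallest index
  seeds <- integer(subSize)
  seeds[1] <- which.min(rowSums(dist))
  if (subSize > 1) {
    minDist <- dist[, seeds[1]]
    for (k in 2:subSize) {
      minDist[seeds[seq_len(k - 1)]] <- -Inf
      seeds[k] <- which.max(minDist)
      minDist <- pmin(minDist, dist[, seeds[k]])
    }
  }

  membership <- lapply(seeds, function(s) s)
  if (numNeighbors > 0) {
    cand <- setdiff(seq_len(nC), seeds)
    if (length(cand)) {
      pairDist <- dist[seeds, cand, drop = FALSE]
      ord <- order(pairDist) # column-major ties keep index order
      capacity <- rep(as.integer(numNeighbors), subSize)
      taken <- rep(FALSE, length(cand))
      for (o in ord) {
        k <- (o - 1L) %% subSize + 1L
        j <- (o - 1L) %/% subSize + 1L
        if (taken[j] || capacity[k] == 0L) next
        membership[[k]] <- c(membership[[k]], cand[j])
        taken[j] <- TRUE
        capacity[k] <- capacity[k] - 1L
        if (all(taken) || all(capacity == 0L)) break
      }
    }
  }
  membership <- lapply(membership, function(m) colnames(counts)[m])
  names(membership) <- sprintf("mc%03d", seq_len(subSize))

  agg <- vapply(membership, function(m)
    rowSums(counts[, m, drop = FALSE]), numeric(nrow(counts)))
  dimnames(agg) <- list(rownames(counts), names(membership))
  methods::new("MetacellExperiment",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = agg),
      colData = S4Vectors::DataFrame(
        seedCell = colnames(counts)[seeds],
        nMembers = lengths(membership),
        row.names = names(membership))),
    membership = membership)
}

#' Filter genes by metacell detection rate
#'
#' Retains genes with non-zero counts in at least `minNonzeroFraction` of
#' metacells (default 0.75), the detection filter applied before network
#' inference. Gene order is preserved and the operation is idempotent.
#'
#' @param mc a [MetacellExperiment-class].
#' @param minNonzeroFraction required fraction of metacells with a
#'   non-zero count, in (0, 1\]; 0 disables the filter.
#' @return the filtered [MetacellExperiment-class].
#' @export
filterGenes <- function(mc, minNonzeroFraction = 0.75) {
  stopifnot(is(mc, "MetacellExperiment"))
  cnts <- SummarizedExperiment::assay(mc, "counts")
  keep <- rowMeans(cnts > 0) >= minNonzeroFraction
  if (!any(keep))
    stop("all genes filtered out; lower minNonzeroFraction or use larger metacells")
  mc[keep, ]
}
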