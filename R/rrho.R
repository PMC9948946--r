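#' Signed significance ranking metric
#'
#' Converts a differential-expression table into per-gene signed scores
#' `-log10(P) * sign(log2FC)`, the metric used to rank signatures before
#' rank-rank overlap analysis. `p = 1` scores 0; `p = 0` is mapped to
#' the smallest positive representable double so scores stay finite.
#'
#' @param deTable data.frame with columns `gene`, `log2FC`, `P` (case
#'   insensitive; `logFC`/`pvalue` accepted).
#' @return named numeric vector of signed scores.
#' @examples
#' rankMetric(data.frame(gene = "A", log2FC = 2, P = 0.01)) # +2
#' @export
rankMetric <- function(deTable) {
  nm <- tolower(names(deTable))
  gene <- deTable[[which(nm == "gene")[1]]]
  fc <- deTable[[which(nm %in% c("log2fc", "logfc"))[1]]]
  p <- deTable[[which(nm %in% c("p", "pvalue", "p.value"))[1]]]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(!is.finite(fc))) stop("log2FC must be finite")
  p <- pmax(p, .Machine$double.xmin)
  setNames(-log10(p) * sign(fc), gene)
}

# order shared genes of a signature most-up-regulated first, ties broken
# by gene name (stable lexicographic)
.rrhoOrder <- function(scores, shared) {
  s <- scores[shared]
  shared[order(-s, shared)]
}

# stratified per-pixel test: overlap counts and sizes depend on which
# quadrant the pixel's thresholds fall in
.rrhoPixel <- function(tA, tB, kTop, N, qA, qB) {
  if (qA == "u" && qB == "u") { a <- tA;     b <- tB;     k <- kTop }
  else if (qA == "d" && qB == "d") { a <- N - tA; b <- N - tB; k <- N - tA - tB + kTop }
  else if (qA == "u" && qB == "d") { a <- tA;     b <- N - tB; k <- tA - kTop }
  else                             { a <- N - tA; b <- tB;     k <- tB - kTop }
  p <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  c(p = p, k = k)
}

#' Stratified rank-rank hypergeometric overlap grid
#'
#' Compares two ranked signatures over the grid of rank thresholds
#' `i * step` x `j * step` on their shared genes. Each pixel is a
#' hypergeometric upper-tail test of the overlap between the two lists
#' truncated at those thresholds, stratified by quadrant: concordant
#' quadrants (`uu` = both up, bottom-left; `dd` = both down, top-right)
#' test overlap of top or bottom sets, discordant quadrants test a top
#' set against a bottom set. P-values are BH-adjusted over all pixels of
#' the grid and stored as `-log10(adjusted p)`, signed positive for
#' concordant and negative for discordant pixels.
#'
#' @param sigA,sigB named numeric score vectors (e.g. [rankMetric()]
#'   output); the analysis is restricted to their shared genes (>= 10
#'   required).
#' @param step rank step size; default `ceiling(sqrt(N))` for `N` shared
#'   genes.
#' @return an [RrhoGrid-class].
#' @export
rrhoGrid <- function(sigA, sigB, step = NULL) {
  shared <- intersect(names(sigA), names(sigB))
  N <- length(shared)
  if (N < 10) stop("need at least 10 shared genes")
  if (is.null(step)) step <- ceiling(sqrt(N))
  step <- as.integer(step)
  stopifnot(step >= 1)
  ordA <- .rrhoOrder(sigA, shared)
  ordB <- .rrhoOrder(sigB, shared)
  upA <- sum(sigA[shared] > 0)
  upB <- sum(sigB[shared] > 0)
  thr <- seq_len(N %/% step) * step
  posB <- match(ordA, ordB) # B-rank of each gene, in A order

  nP <- length(thr)
  pmat <- matrix(NA_real_, nP, nP)
  kmat <- matrix(NA_real_, nP, nP)
  quad <- matrix(NA_character_, nP, nP)
  for (i in seq_len(nP)) {
    inB <- posB[seq_len(thr[i])]
    kTop <- vapply(thr, function(tB) sum(inB <= tB), 0L)
    qA <- if (thr[i] <= upA) "u" else "d"
    for (j in seq_len(nP)) {
      qB <- if (thr[j] <= upB) "u" else "d"
      px <- .rrhoPixel(thr[i], thr[j], kTop[j], N, qA, qB)
      pmat[i, j] <- px["p"]
      kmat[i, j] <- px["k"]
      quad[i, j] <- paste0(qA, qB)
    }
  }
  adj <- matrix(bhAdjust(as.vector(pmat)), nP, nP)
  sign <- ifelse(quad %in% c("uu", "dd"), 1, -1)
  logAdj <- sign * -log10(pmax(adj, .Machine$double.xmin))
  methods::new("RrhoGrid", logAdj = logAdj, pvalues = pmat, overlap = kmat,
               quadrant = quad, thresholdsA = as.integer(thr),
               thresholdsB = as.integer(thr), step = step,
               genesA = ordA, genesB = ordB,
               upA = as.integer(upA), upB = as.integer(upB))
}

#' Genes at the most significant concordant pixel
#'
#' Returns the overlapping genes at the warmest (most significant,
#' BH-adjusted) pixel of a concordant quadrant: for `uu` the
#' intersection of the two top (up-regulated) lists at the pixel's
#' thresholds, for `dd` the intersection of the two bottom
#' (down-regulated) lists. Ties between pixels are broken by the
#' smallest combined rank threshold, then the smallest A threshold.
#'
#' @param grid an [RrhoGrid-class].
#' @param quadrant `"uu"` or `"dd"`.
#' @return list with `genes`, `p` (raw pixel hypergeometric p),
#'   `thresholdA`, `thresholdB`.
#' @export
extractQuadrantGenes <- function(grid, quadrant = c("uu", "dd")) {
  quadrant <- match.arg(quadrant)
  stopifnot(is(grid, "RrhoGrid"))
  sel <- which(grid@quadrant == quadrant, arr.ind = TRUE)
  if (!nrow(sel))
    return(list(genes = character(), p = NA_real_,
                thresholdA = NA_integer_, thresholdB = NA_integer_))
  val <- grid@logAdj[sel]
  tA <- grid@thresholdsA[sel[, 1]]
  tB <- grid@thresholdsB[sel[, 2]]
  best <- order(-val, tA + tB, tA)[1]
  i <- sel[best, 1]; j <- sel[best, 2]
  N <- length(grid@genesA)
  genes <- if (quadrant == "uu") {
    intersect(head(grid@genesA, grid@thresholdsA[i]),
              head(grid@genesB, grid@thresholdsB[j]))
  } else {
    intersect(tail(grid@genesA, N - grid@thresholdsA[i]),
              tail(grid@genesB, N - grid@thresholdsB[j]))
  }
  list(genes = genes, p = grid@pvalues[i, j],
       thresholdA = grid@thresholdsA[i], thresholdB = grid@thresholdsB[j])
}

#' Hypergeometric overlap of two gene sets in a universe
#'
#' Upper-tail hypergeometric p for the overlap of two gene sets
#' restricted to a universe (e.g. RRHO quadrant genes against a LAM
#' geneset universe). Sets not contained in the universe are
#' intersected with it, with a warning.
#'
#' @param setA,setB character gene sets.
#' @param universe character gene universe.
#' @return hypergeometric upper-tail p-value.
#' @export
overlapTest <- function(setA, setB, universe) {
  hypergeometricEnrichment(setA, setB, universe)$p
}

#' Spearman correlation of two signatures with a confidence interval
#'
#' Spearman rho over shared genes (average ranks for ties), a 95%
#' confidence interval via the Fisher z transform with the
#' Fieller-Hartley-Pearson variance `1.06 / (n - 3)`, and a two-sided
#' p-value.
#'
#' @param sigA,sigB named numeric score vectors with >= 10 shared genes.
#' @return list with `rho`, `ci95` (length-2 vector), `p`, `n`.
#' @export
signatureCorrelation <- function(sigA, sigB) {
  shared <- intersect(names(sigA), names(sigB))
  if (length(shared) < 10) stop("need at least 10 shared genes")
  a <- sigA[shared]; b <- sigB[shared]
  rho <- cor(a, b, method = "spearman")
  n <- length(shared)
  p <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE)$p.value)
  if (abs(rho) >= 1) {
    ci <- c(rho, rho)
  } else {
    z <- atanh(rho)
    se <- sqrt(1.06 / (n - 3))
    ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  }
  list(rho = rho, ci95 = ci, p = p, n = n)
}
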