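#' Metacell-aggregated expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose columns are
#' metacells (pools of transcriptionally similar cells) rather than single
#' cells. The `membership` slot records, for every metacell, the
#' identifiers of the member cells whose raw counts were summed into it.
#' Memberships are disjoint: no cell contributes to two metacells, so
#' aggregation conserves total counts over the assigned cells.
#'
#' @slot membership named list, one character vector of member cell
#'   identifiers per metacell column.
#' @seealso [buildMetacells()], [filterGenes()]
#' @export
setClass("MetacellExperiment",
  contains = "SummarizedExperiment",
  slots = c(membership = "list")
)

setValidity("MetacellExperiment", function(object) {
  msg <- character()
  if (length(object@membership) != ncol(object))
    msg <- c(msg, "one membership entry per metacell column required")
  memb <- unlist(object@membership, use.names = FALSE)
  if (anyDuplicated(memb))
    msg <- c(msg, "a cell may not belong to more than one metacell")
  cnts <- SummarizedExperiment::assay(object, "counts")
  if (any(cnts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Membership of metacells
#'
#' @param x a [MetacellExperiment-class].
#' @return named list of member-cell identifier vectors.
#' @export
metacellMembership <- function(x) {
  stopifnot(is(x, "MetacellExperiment"))
  x@membership
}

#' TF-target regulatory network
#'
#' Weighted undirected TF-gene edge set produced by mutual-information
#' inference. Each edge carries the MI estimate, the number of bootstrap
#' networks supporting it, and the Poisson consolidation p-value and
#' BH-adjusted FDR (NA before consolidation). Edges between two
#' regulators are stored once, with `tf` the lexicographically smaller
#' symbol.
#'
#' @slot edges data.frame with columns `tf`, `target`, `mi`, `support`,
#'   `p`, `fdr`.
#' @slot tfs character, the regulator symbols considered.
#' @slot geneUniverse character, all genes that entered inference.
#' @slot nBootstraps integer, number of bootstrap networks consolidated
#'   (1 for a single-run network).
#' @seealso [inferRawNetwork()], [applyDpi()], [bootstrapConsolidate()],
#'   [metaConsolidate()], [extractRegulon()]
#' @export
setClass("GrnNetwork",
  slots = c(
    edges        = "data.frame",
    tfs          = "character",
    geneUniverse = "character",
    nBootstraps  = "integer"
  )
)

setValidity("GrnNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("tf", "target", "mi", "support", "p", "fdr")
  if (!all(need %in% names(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (any(ed$mi < 0, na.rm = TRUE)) msg <- c(msg, "mi must be non-negative")
    if (any(ed$tf == ed$target)) msg <- c(msg, "self-edges are not allowed")
    if (!all(ed$tf %in% object@tfs)) msg <- c(msg, "edge tf not in tf list")
    if (!all(c(ed$tf, ed$target) %in% object@geneUniverse))
      msg <- c(msg, "edge endpoints must lie in the gene universe")
    if (any(ed$support > object@nBootstraps, na.rm = TRUE))
      msg <- c(msg, "support cannot exceed the number of bootstraps")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GrnNetwork edge table accessor.
#' @param net,x a `GrnNetwork`.
#' @export
networkEdges <- function(net) { stopifnot(is(net, "GrnNetwork")); net@edges }

#' @describeIn GrnNetwork regulator symbols.
#' @export
networkTfs <- function(net) { stopifnot(is(net, "GrnNetwork")); net@tfs }

#' @describeIn GrnNetwork gene universe entering inference.
#' @export
geneUniverse <- function(net) { stopifnot(is(net, "GrnNetwork")); net@geneUniverse }

setMethod("show", "GrnNetwork", function(object) {
  cat("GrnNetwork with", nrow(object@edges), "edges |",
      length(object@tfs), "TFs |",
      length(object@geneUniverse), "genes | consolidated over",
      object@nBootstraps, "bootstrap(s)\n")
})

#' Position weight matrix with a log-odds score threshold
#'
#' Column-stochastic base-probability matrix (rows A, C, G, T) together
#' with a background distribution and the minimum log2-odds score at which
#' a window counts as a motif hit. Scores use a pseudocount of 0.001 per
#' cell; the default threshold is 80% of the maximal attainable score.
#'
#' @slot probs 4 x L base probability matrix, columns sum to 1.
#' @slot background base frequencies (A, C, G, T).
#' @slot minScore numeric log2-odds hit threshold.
#' @slot name motif name.
#' @seealso [motifPwm()], [consensusPwm()], [scanMotif()]
#' @export
setClass("MotifPwm",
  slots = c(
    probs      = "matrix",
    background = "numeric",
    minScore   = "numeric",
    name       = "character"
  )
)

setValidity("MotifPwm", function(object) {
  msg <- character()
  p <- object@probs
  if (nrow(p) != 4) msg <- c(msg, "probs must have 4 rows (A, C, G, T)")
  if (ncol(p) < 4) msg <- c(msg, "motif length must be at least 4")
  if (any(abs(colSums(p) - 1) > 1e-6))
    msg <- c(msg, "probs columns must each sum to 1")
  if (length(object@background) != 4 || abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifPwm", function(object) {
  cat("MotifPwm", object@name, "| length", ncol(object@probs),
      "| consensus", pwmConsensus(object),
      "| hit threshold", signif(object@minScore, 4), "bits\n")
})

#' Toy genome with planted motif instances
#'
#' Small synthetic genome used to exercise the promoter / proxy-cistrome
#' stage: uniform-composition chromosome(s), evenly spaced gene TSSs, one
#' open-chromatin peak per gene, and motif instances written into the
#' peaks of a chosen fraction of genes. All recorded positions are
#' 0-based (BED convention).
#'
#' @slot sequences [Biostrings::DNAStringSet] chromosome sequences.
#' @slot tss data.frame with `gene`, `seqnames`, `position` (0-based),
#'   `strand`.
#' @slot peaks [GenomicRanges::GRanges], one peak per gene, named by gene.
#' @slot motifSites data.frame with `seqnames`, `position` (0-based start
#'   of the embedded instance), `strand`, `gene`.
#' @slot plantedGenes genes whose peak carries an embedded motif instance.
#' @slot motif the [MotifPwm-class] that was planted.
#' @seealso [simulateGenome()]
#' @export
setClass("ToyGenome",
  slots = c(
    sequences    = "DNAStringSet",
    tss          = "data.frame",
    peaks        = "GRanges",
    motifSites   = "data.frame",
    plantedGenes = "character",
    motif        = "MotifPwm"
  )
)

setValidity("ToyGenome", function(object) {
  msg <- character()
  lens <- Biostrings::width(object@sequences)
  names(lens) <- names(object@sequences)
  t <- object@tss
  if (!all(c("gene", "seqnames", "position", "strand") %in% names(t)))
    msg <- c(msg, "tss needs columns gene, seqnames, position, strand")
  else if (any(t$position < 0 | t$position >= lens[t$seqnames]))
    msg <- c(msg, "TSS positions must lie within sequence bounds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ToyGenome", function(object) {
  cat("ToyGenome:", length(object@sequences), "sequence(s),",
      nrow(object@tss), "genes,", length(object@peaks), "peaks,",
      length(object@plantedGenes), "with planted", object@motif@name,
      "instances\n")
})

#' Stratified rank-rank hypergeometric overlap grid
#'
#' Grid of hypergeometric overlap tests between two ranked signatures.
#' Both gene lists are ordered from most up-regulated to most
#' down-regulated; pixel (i, j) compares the lists at rank thresholds
#' `i * step` and `j * step`. Pixels are assigned to quadrants by whether
#' each threshold falls in the up- or down-regulated part of its list
#' (`uu`, `dd` concordant; `ud`, `du` discordant), and the test at each
#' pixel is the stratified one: overlap of top sets in `uu`, of bottom
#' sets in `dd`, and of a top set with a bottom set in the discordant
#' quadrants. `logAdj` holds -log10 BH-adjusted p-values signed positive
#' for concordant and negative for discordant pixels.
#'
#' @slot logAdj signed -log10 BH-adjusted p-value matrix (A thresholds in
#'   rows, B in columns).
#' @slot pvalues raw per-pixel hypergeometric p-values.
#' @slot overlap stratified per-pixel overlap counts.
#' @slot quadrant per-pixel quadrant labels ("uu", "dd", "ud", "du").
#' @slot thresholdsA,thresholdsB rank thresholds per axis.
#' @slot step rank step size.
#' @slot genesA,genesB shared genes ordered most-up-regulated first for
#'   each signature.
#' @slot upA,upB number of genes with positive score in each list.
#' @seealso [rrhoGrid()], [extractQuadrantGenes()]
#' @export
setClass("RrhoGrid",
  slots = c(
    logAdj      = "matrix",
    pvalues     = "matrix",
    overlap     = "matrix",
    quadrant    = "matrix",
    thresholdsA = "integer",
    thresholdsB = "integer",
    step        = "integer",
    genesA      = "character",
    genesB      = "character",
    upA         = "integer",
    upB         = "integer"
  )
)

setValidity("RrhoGrid", function(object) {
  msg <- character()
  d <- dim(object@logAdj)
  if (!identical(dim(object@pvalues), d) || !identical(dim(object@quadrant), d))
    msg <- c(msg, "matrix slots must share dimensions")
  if (length(object@thresholdsA) != d[1] || length(object@thresholdsB) != d[2])
    msg <- c(msg, "threshold vectors must match matrix dimensions")
  if (!setequal(object@genesA, object@genesB))
    msg <- c(msg, "genesA and genesB must contain the same shared genes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RrhoGrid", function(object) {
  cat("RrhoGrid:", nrow(object@logAdj), "x", ncol(object@logAdj),
      "pixels | step", object@step, "|", length(object@genesA),
      "shared genes | max -log10 adj p:",
      signif(max(abs(object@logAdj)), 4), "\n")
})
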