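#' Parameters for network inference and consolidation
#'
#' @param miPvalue tail probability for the permutation-calibrated MI
#'   threshold (default 1e-8).
#' @param nBootstraps number of bootstrap networks (default 200).
#' @param dpiTolerance data-processing-inequality tolerance in \[0, 1\]
#'   (0 = strict pruning).
#' @param consolidationFdr BH-FDR cutoff on Poisson bootstrap support
#'   (default 0.05).
#' @param seed master RNG seed; per-bootstrap seeds derive from it.
#' @param nNull null draws used for threshold calibration.
#' @return validated list of class `GrnParams`.
#' @export
grnParams <- function(miPvalue = 1e-8, nBootstraps = 200, dpiTolerance = 0,
                      consolidationFdr = 0.05, seed = 1L, nNull = 1e5) {
  stopifnot(miPvalue > 0, miPvalue <= 1, consolidationFdr > 0,
            consolidationFdr <= 1, nBootstraps >= 1,
            dpiTolerance >= 0, dpiTolerance <= 1)
  structure(list(miPvalue = miPvalue, nBootstraps = as.integer(nBootstraps),
                 dpiTolerance = dpiTolerance,
                 consolidationFdr = consolidationFdr,
                 seed = as.integer(seed), nNull = nNull),
            class = "GrnParams")
}

.emptyEdges <- function() {
  data.frame(tf = character(), target = character(), mi = numeric(),
             support = integer(), p = numeric(), fdr = numeric(),
             stringsAsFactors = FALSE)
}

.newNetwork <- function(edges, tfs, universe, nBootstraps = 1L) {
  methods::new("GrnNetwork", edges = edges, tfs = sort(unique(tfs)),
               geneUniverse = sort(unique(universe)),
               nBootstraps = as.integer(nBootstraps))
}

# MI matrix between TFs and all genes of an expression matrix
# (genes x samples). Ties in the per-gene rank transform are broken at
# random with the session RNG.
.miTfGene <- function(expr, tfs) {
  genes <- rownames(expr)
  tfs <- intersect(tfs, genes)
  if (!length(tfs)) stop("no TF of tf_list is present in the expression matrix")
  ranks <- apply(expr, 1, .miRanks) # samples x genes
  storage.mode(ranks) <- "integer"
  tfIdx <- match(tfs, genes)
  mi <- cpp_mi_matrix(ranks, tfIdx - 1L)
  dimnames(mi) <- list(tfs, genes)
  mi
}

# Edge list from a TF x gene MI matrix at a fixed threshold. TF-TF pairs
# are kept once with tf the lexicographically smaller symbol.
.edgesFromMi <- function(mi, threshold) {
  hit <- which(!is.na(mi) & mi >= threshold, arr.ind = TRUE)
  if (!nrow(hit)) return(.emptyEdges())
  tf <- rownames(mi)[hit[, 1]]
  target <- colnames(mi)[hit[, 2]]
  val <- mi[hit]
  bothTf <- target %in% rownames(mi)
  a <- ifelse(bothTf & target < tf, target, tf)
  b <- ifelse(bothTf & target < tf, tf, target)
  ed <- data.frame(tf = a, target = b, mi = val, stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$tf, ed$target, sep = "\r")), , drop = FALSE]
  ed <- ed[order(ed$tf, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  ed$support <- NA_integer_; ed$p <- NA_real_; ed$fdr <- NA_real_
  ed
}

#' Infer a raw (pre-DPI) mutual-information network
#'
#' Computes adaptive-partitioning MI between every annotated regulator
#' and every other gene of a metacell matrix and keeps pairs whose MI
#' exceeds the permutation-calibrated threshold for the requested
#' p-value. No self-edges; TF-TF pairs are stored once.
#'
#' @param mc a [MetacellExperiment-class] or gene-by-sample matrix.
#' @param tfs character vector of regulator symbols; must intersect the
#'   gene names.
#' @param params a [grnParams()] object.
#' @param threshold optional precomputed MI threshold; when NULL it is
#'   calibrated at `params$miPvalue` for the matrix's sample size.
#' @return a [GrnNetwork-class] (bootstrap-support columns are NA).
#' @export
inferRawNetwork <- function(mc, tfs, params = grnParams(), threshold = NULL) {
  expr <- if (is(mc, "SummarizedExperiment"))
    SummarizedExperiment::assay(mc, "counts") else as.matrix(mc)
  if (is.null(threshold))
    threshold <- calibrateMiThreshold(ncol(expr), params$miPvalue,
                                      nNull = params$nNull)
  mi <- .miTfGene(expr, tfs)
  .newNetwork(.edgesFromMi(mi, threshold), rownames(mi), rownames(expr))
}

#' Prune indirect edges by the data processing inequality
#'
#' For every closed triangle of edges, the weakest edge is flagged when
#' its MI is below `(1 - tolerance)` times the smaller of the other two
#' MIs; all flags are evaluated against the input network simultaneously
#' and flagged edges are then removed. Edges not part of any triangle are
#' untouched, the output edge set is a subset of the input, and at
#' tolerance 0 the operation is idempotent.
#'
#' @param net a [GrnNetwork-class].
#' @param tolerance DPI tolerance in \[0, 1\]; larger values spare more
#'   near-ties.
#' @return the pruned [GrnNetwork-class].
#' @export
applyDpi <- function(net, tolerance = 0) {
  stopifnot(is(net, "GrnNetwork"), tolerance >= 0, tolerance <= 1)
  ed <- net@edges
  if (nrow(ed) < 3) return(net)
  nodes <- unique(c(ed$tf, ed$target))
  adj <- matrix(NA_real_, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(ed$tf, ed$target)] <- ed$mi
  adj[cbind(ed$target, ed$tf)] <- ed$mi
  drop <- logical(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    a <- ed$tf[e]; b <- ed$target[e]
    third <- which(!is.na(adj[a, ]) & !is.na(adj[b, ]))
    if (!length(third)) next
    lim <- (1 - tolerance) * pmin(adj[a, third], adj[b, third])
    if (any(ed$mi[e] < lim)) drop[e] <- TRUE
  }
  net@edges <- ed[!drop, , drop = FALSE]
  rownames(net@edges) <- NULL
  net
}

#' Tally DPI-pruned edges over bootstrap resamples
#'
#' Resamples metacell columns with replacement `params$nBootstraps`
#' times (per-bootstrap seeds derived deterministically from
#' `params$seed`), infers a thresholded MI network on each resample,
#' applies DPI, and tallies how often each edge appears. The MI
#' threshold is calibrated once, for the metacell sample size.
#'
#' @inheritParams inferRawNetwork
#' @return data.frame with columns `tf`, `target`, `support`, `mi` (mean
#'   MI over supporting bootstraps), plus attributes `nBootstraps`,
#'   `tfs`, `geneUniverse`.
#' @export
bootstrapEdges <- function(mc, tfs, params = grnParams()) {
  expr <- if (is(mc, "SummarizedExperiment"))
    SummarizedExperiment::assay(mc, "counts") else as.matrix(mc)
  n <- ncol(expr)
  seeds <- withr::with_seed(params$seed,
    sample.int(.Machine$integer.max - 1L, params$nBootstraps + 1L))
  threshold <- calibrateMiThreshold(n, params$miPvalue, nNull = params$nNull,
                                    seed = seeds[1])
  tally <- new.env(parent = emptyenv())
  tfsPresent <- intersect(tfs, rownames(expr))
  if (!length(tfsPresent))
    stop("no TF of tf_list is present in the expression matrix")
  for (b in seq_len(params$nBootstraps)) {
    ed <- withr::with_seed(seeds[b + 1L], {
      idx <- sample.int(n, n, replace = TRUE)
      mi <- .miTfGene(expr[, idx, drop = FALSE], tfsPresent)
      .edgesFromMi(mi, threshold)
    })
    if (!nrow(ed)) next
    net <- applyDpi(.newNetwork(ed, tfsPresent, rownames(expr)),
                    params$dpiTolerance)
    pe <- net@edges
    for (i in seq_len(nrow(pe))) {
      key <- paste(pe$tf[i], pe$target[i], sep = "\r")
      cur <- tally[[key]]
      if (is.null(cur)) cur <- c(0, 0)
      tally[[key]] <- cur + c(1, pe$mi[i])
    }
  }
  keys <- ls(tally)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    vals <- vapply(keys, function(k) tally[[k]], numeric(2))
    out <- data.frame(tf = vapply(parts, `[`, "", 1),
                      target = vapply(parts, `[`, "", 2),
                      support = as.integer(vals[1, ]),
                      mi = vals[2, ] / vals[1, ],
                      stringsAsFactors = FALSE)
    out <- out[order(out$tf, out$target), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(tf = character(), target = character(),
                      support = integer(), mi = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "nBootstraps") <- params$nBootstraps
  attr(out, "tfs") <- tfsPresent
  attr(out, "geneUniverse") <- rownames(expr)
  out
}

#' Consolidate a bootstrap edge tally into a significant network
#'
#' Tests each distinct edge's bootstrap support against a Poisson null
#' in which the total number of edge occurrences is scattered uniformly
#' over all testable TF-gene pairs (rate = total occurrences / number
#' of possible pairs), adjusts the upper-tail p-values by
#' Benjamini-Hochberg across distinct observed edges, and keeps edges
#' with FDR below the cutoff. Conditioning on the full pair universe
#' rather than the observed edges keeps the test calibrated when
#' support is uniformly high (all-true-edges regime) as well as when
#' most observed edges are one-off noise. At FDR 1 every observed edge
#' is returned.
#'
#' @param tally result of [bootstrapEdges()] (or a pooled tally).
#' @param consolidationFdr BH-FDR cutoff.
#' @return a [GrnNetwork-class]; empty tallies yield an empty network.
#' @export
consolidateEdges <- function(tally, consolidationFdr = 0.05) {
  nBoot <- attr(tally, "nBootstraps")
  tfs <- attr(tally, "tfs")
  universe <- attr(tally, "geneUniverse")
  if (!nrow(tally))
    return(.newNetwork(.emptyEdges(), tfs, universe, nBoot))
  nTf <- length(intersect(tfs, universe))
  nPossible <- nTf * (length(unique(universe)) - nTf) + choose(nTf, 2)
  lambda <- sum(tally$support) / nPossible
  p <- ppois(tally$support - 1, lambda, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  keep <- fdr < consolidationFdr | consolidationFdr >= 1
  ed <- data.frame(tf = tally$tf[keep], target = tally$target[keep],
                   mi = tally$mi[keep], support = tally$support[keep],
                   p = p[keep], fdr = fdr[keep], stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  .newNetwork(ed, tfs, universe, nBoot)
}

#' Bootstrap-consolidated network for one dataset
#'
#' Convenience wrapper: [bootstrapEdges()] followed by
#' [consolidateEdges()] at `params$consolidationFdr`.
#'
#' @inheritParams inferRawNetwork
#' @return a [GrnNetwork-class].
#' @export
bootstrapConsolidate <- function(mc, tfs, params = grnParams()) {
  consolidateEdges(bootstrapEdges(mc, tfs, params), params$consolidationFdr)
}

#' Meta-consolidate bootstrap tallies across datasets
#'
#' Pools the bootstrap edge tallies of several datasets over a shared
#' gene namespace and applies the same Poisson-support consolidation to
#' the pooled counts. Edge MI is the support-weighted mean across
#' datasets, and a min-max normalized MI column (`normMi`, in \[0, 1\])
#' is added for heatmap display.
#'
#' @param tallies list of [bootstrapEdges()] results with overlapping
#'   gene namespaces.
#' @param consolidationFdr BH-FDR cutoff.
#' @return a [GrnNetwork-class] whose edges carry `normMi`.
#' @export
metaConsolidate <- function(tallies, consolidationFdr = 0.05) {
  stopifnot(length(tallies) >= 1)
  universes <- lapply(tallies, attr, "geneUniverse")
  if (length(tallies) > 1 && length(Reduce(intersect, universes)) == 0)
    stop("datasets have disjoint gene namespaces")
  pooled <- do.call(rbind, lapply(tallies, function(t)
    t[, c("tf", "target", "support", "mi")]))
  if (nrow(pooled)) {
    key <- paste(pooled$tf, pooled$target, sep = "\r")
    supp <- tapply(pooled$support, key, sum)
    miw <- tapply(pooled$support * pooled$mi, key, sum) / supp
    parts <- strsplit(names(supp), "\r", fixed = TRUE)
    agg <- data.frame(tf = vapply(parts, `[`, "", 1),
                      target = vapply(parts, `[`, "", 2),
                      support = as.integer(supp), mi = as.numeric(miw),
                      stringsAsFactors = FALSE)
    agg <- agg[order(agg$tf, agg$target), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- pooled
  }
  attr(agg, "nBootstraps") <- sum(vapply(tallies, attr, 0L, "nBootstraps"))
  attr(agg, "tfs") <- sort(unique(unlist(lapply(tallies, attr, "tfs"))))
  attr(agg, "geneUniverse") <- sort(unique(unlist(universes)))
  net <- consolidateEdges(agg, consolidationFdr)
  if (nrow(net@edges)) {
    rng <- range(net@edges$mi)
    net@edges$normMi <- if (diff(rng) > 0)
      (net@edges$mi - rng[1]) / diff(rng) else rep(1, nrow(net@edges))
  } else {
    net@edges$normMi <- numeric()
  }
  net
}
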