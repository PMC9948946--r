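# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (enumeration / brute force) and never share code
# with the package paths they check.

tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nCells = 120, nGenes = 40, nTfs = 4, regulonSize = 6,
                   lamTfIds = c("TF01", "TF02"))
  do.call(simConfig, utils::modifyList(defaults, args))
}

# MetacellExperiment from a bare counts matrix (singleton memberships)
mcFromCounts <- function(counts) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("mc%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  memb <- as.list(colnames(counts))
  names(memb) <- colnames(counts)
  methods::new("MetacellExperiment",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts)),
    membership = memb)
}

# GrnNetwork from a plain undirected edge list (all nodes as TFs so any
# topology is expressible)
netFromEdges <- function(a, b, mi) {
  nodes <- sort(unique(c(a, b)))
  tf <- pmin(a, b); tg <- pmax(a, b)
  ed <- data.frame(tf = tf, target = tg, mi = mi,
                   support = NA_integer_, p = NA_real_, fdr = NA_real_,
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$tf, ed$target), ]
  rownames(ed) <- NULL
  methods::new("GrnNetwork", edges = ed, tfs = nodes, geneUniverse = nodes,
               nBootstraps = 1L)
}

# exhaustive-triplet DPI oracle: enumerate all node triples, flag the
# strictly weakest edge of each closed triangle
dpiOracle <- function(net, tolerance = 0) {
  ed <- networkEdges(net)
  key <- paste(ed$tf, ed$target)
  mi <- setNames(ed$mi, key)
  k <- function(x, y) paste(pmin(x, y), pmax(x, y))
  nodes <- sort(unique(c(ed$tf, ed$target)))
  drop <- rep(FALSE, nrow(ed))
  if (length(nodes) >= 3) {
    trip <- utils::combn(nodes, 3)
    for (t in seq_len(ncol(trip))) {
      e12 <- k(trip[1, t], trip[2, t])
      e13 <- k(trip[1, t], trip[3, t])
      e23 <- k(trip[2, t], trip[3, t])
      if (all(c(e12, e13, e23) %in% key)) {
        mis <- mi[c(e12, e13, e23)]
        for (i in 1:3) {
          others <- mis[-i]
          if (mis[i] < (1 - tolerance) * min(others))
            drop[key == names(mis)[i]] <- TRUE
        }
      }
    }
  }
  ed[!drop, c("tf", "target")]
}

# exact hypergeometric upper tail by direct enumeration of the pmf
hyperTailOracle <- function(N, K, n, k) {
  js <- max(0, K + n - N):min(K, n)
  pmf <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(pmf[js >= k])
}

# quadratic all-pairs interval overlap (1-based closed coordinates)
overlapOracle <- function(starts1, ends1, starts2, ends2) {
  vapply(seq_along(starts1), function(i)
    any(starts1[i] <= ends2 & starts2 <= ends1[i]), TRUE)
}

# naive consensus scan: does the string contain the consensus or its
# reverse complement as an exact substring?
naiveConsensusHit <- function(seqChar, consensus) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(consensus, "")[[1]]),
                                     collapse = ""))
  grepl(consensus, seqChar, fixed = TRUE) || grepl(rc, seqChar, fixed = TRUE)
}

# independent RRHO pixel oracle: recompute the stratified overlap test
# for one pixel directly from the two signatures
rrhoPixelOracle <- function(sigA, sigB, tA, tB) {
  shared <- intersect(names(sigA), names(sigB))
  N <- length(shared)
  ordA <- shared[order(-sigA[shared], shared)]
  ordB <- shared[order(-sigB[shared], shared)]
  upA <- sum(sigA[shared] > 0); upB <- sum(sigB[shared] > 0)
  qA <- if (tA <= upA) "u" else "d"
  qB <- if (tB <= upB) "u" else "d"
  A <- if (qA == "u") head(ordA, tA) else tail(ordA, N - tA)
  B <- if (qB == "u") head(ordB, tB) else tail(ordB, N - tB)
  k <- length(intersect(A, B))
  list(p = hyperTailOracle(N, length(A), length(B), k), k = k,
       quadrant = paste0(qA, qB))
}
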