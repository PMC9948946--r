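#' Build a position weight matrix with a hit threshold
#'
#' Wraps a column-stochastic base-probability matrix as a
#' [MotifPwm-class]. Log2-odds scores use a pseudocount of 0.001 per
#' cell against the background; the default hit threshold is 80% of the
#' maximal attainable score.
#'
#' @param probs 4 x L matrix of base probabilities (rows A, C, G, T);
#'   columns are renormalized to sum to 1.
#' @param background base frequencies (default uniform).
#' @param minScore log2-odds hit threshold; NULL for 80% of maximum.
#' @param name motif name.
#' @return a [MotifPwm-class].
#' @export
motifPwm <- function(probs, background = rep(0.25, 4), minScore = NULL,
                     name = "motif") {
  probs <- as.matrix(probs)
  rownames(probs) <- c("A", "C", "G", "T")
  probs <- sweep(probs, 2, colSums(probs), "/")
  pwm <- methods::new("MotifPwm", probs = probs,
                      background = background / sum(background),
                      minScore = 0, name = name)
  if (is.null(minScore)) minScore <- 0.8 * pwmMaxScore(pwm)
  pwm@minScore <- minScore
  pwm
}

#' @describeIn motifPwm strict-consensus PWM from a DNA string: each
#'   column puts all probability mass on the consensus base, so with the
#'   default 80% threshold only exact matches score as hits.
#' @param consensus DNA string over ACGT (length >= 4).
#' @export
consensusPwm <- function(consensus, name = consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(chars %in% c("A", "C", "G", "T")))
  m <- vapply(chars, function(b) as.numeric(c("A", "C", "G", "T") == b),
              numeric(4))
  motifPwm(m, name = name)
}

.pwmScoreMatrix <- function(pwm) {
  log2((pwm@probs + 0.001) / (1 + 0.004) / pwm@background)
}

#' @describeIn motifPwm maximal attainable log2-odds score.
#' @param pwm a [MotifPwm-class].
#' @export
pwmMaxScore <- function(pwm) sum(apply(.pwmScoreMatrix(pwm), 2, max))

#' @describeIn motifPwm consensus string (highest-probability base per
#'   column).
#' @export
pwmConsensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm@probs, 2, which.max)], collapse = "")
}

.dnaCodes <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

#' Promoter intervals around transcription start sites
#'
#' Symmetric windows of `flank` bp on each side of each TSS, clamped to
#' the sequence bounds. Positions follow the BED convention (0-based
#' TSS; the returned `GRanges` uses the usual 1-based closed
#' representation, so a TSS at 0-based 10000 with flank 2000 covers
#' 0-based \[8000, 12000)). Strand is recorded but the interval is
#' symmetric regardless of strand.
#'
#' @param tss data.frame with columns `gene`, `seqnames`, `position`
#'   (0-based TSS), `strand`.
#' @param flank bp on each side of the TSS (default 2000).
#' @param seqLengths named vector of sequence lengths (bp) used for
#'   clamping.
#' @return named [GenomicRanges::GRanges], one promoter per gene.
#' @export
makePromoters <- function(tss, flank = 2000, seqLengths) {
  stopifnot(all(c("gene", "seqnames", "position", "strand") %in% names(tss)))
  lens <- seqLengths[tss$seqnames]
  if (any(tss$position < 0 | tss$position >= lens))
    stop("TSS positions must lie within sequence bounds")
  start0 <- pmax(0, tss$position - flank)
  end0 <- pmin(lens, tss$position + flank)
  gr <- GenomicRanges::GRanges(tss$seqnames,
    IRanges::IRanges(start = start0 + 1, end = end0),
    strand = tss$strand)
  names(gr) <- tss$gene
  gr
}

#' Scan a sequence for PWM hits on both strands
#'
#' Log2-odds score against the background at every offset on both
#' strands; offsets where the score reaches the PWM's threshold are
#' reported. Windows containing an ambiguous base (N) are skipped. For
#' palindromic motifs a minus-strand hit identical to a plus-strand hit
#' at the same offset is reported once, on the plus strand.
#'
#' @param sequence DNA string ([Biostrings::DNAString] or character)
#'   over ACGTN.
#' @param pwm a [MotifPwm-class].
#' @return data.frame with `offset` (0-based start of the hit window),
#'   `strand`, `score`; empty when the sequence is shorter than the
#'   motif.
#' @export
scanMotif <- function(sequence, pwm) {
  stopifnot(is(pwm, "MotifPwm"))
  codes <- .dnaCodes(sequence)
  W <- .pwmScoreMatrix(pwm)
  L <- ncol(W)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(codes) < L) return(empty)
  fwd <- cpp_pwm_scan(codes, W)
  rev <- cpp_pwm_scan(codes, W[4:1, L:1, drop = FALSE]) # motif on - strand
  offF <- which(!is.na(fwd) & fwd >= pwm@minScore) - 1L
  offR <- which(!is.na(rev) & rev >= pwm@minScore) - 1L
  hits <- data.frame(offset = c(offF, offR),
                     strand = rep(c("+", "-"), c(length(offF), length(offR))),
                     stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  hits$score <- ifelse(hits$strand == "+", fwd[hits$offset + 1L],
                       rev[hits$offset + 1L])
  # palindrome deduplication: identical (offset, score) on both strands
  dup <- hits$strand == "-" &
    paste(hits$offset, signif(hits$score, 12)) %in%
    paste(hits$offset[hits$strand == "+"],
          signif(hits$score[hits$strand == "+"], 12))
  hits <- hits[!dup, , drop = FALSE]
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Proxy-binding sites: peaks containing motif hits
#'
#' Retains the open-chromatin peaks whose sequence contains at least one
#' PWM hit on either strand; retained peaks are annotated with their hit
#' count (`nMotifHits`). These motif-stratified peaks stand in for
#' measured TF binding (the TF's proxy cistrome).
#'
#' @param peaks [GenomicRanges::GRanges] peaks within the genome bounds.
#' @param genome named [Biostrings::DNAStringSet].
#' @param pwm a [MotifPwm-class].
#' @return the subset of `peaks` with >= 1 hit, with `nMotifHits` in
#'   `mcols`.
#' @export
proxyBindingSites <- function(peaks, genome, pwm) {
  stopifnot(is(peaks, "GRanges"), is(genome, "DNAStringSet"))
  n <- vapply(seq_along(peaks), function(i) {
    sq <- genome[[as.character(GenomicRanges::seqnames(peaks)[i])]]
    s <- subseq(sq, GenomicRanges::start(peaks)[i],
                GenomicRanges::end(peaks)[i])
    nrow(scanMotif(s, pwm))
  }, 0L)
  out <- peaks[n > 0]
  S4Vectors::mcols(out)$nMotifHits <- n[n > 0]
  out
}

#' Fraction of genes with a proxy-bound promoter
#'
#' Fraction of `lamGenes` whose promoter interval overlaps at least one
#' proxy-binding site by >= 1 bp. Genes absent from the promoter set are
#' counted as unbound, with a warning.
#'
#' @param lamGenes character gene identifiers.
#' @param promoters named [GenomicRanges::GRanges] from
#'   [makePromoters()].
#' @param proxySites [GenomicRanges::GRanges] of proxy-binding sites.
#' @return fraction in \[0, 1\].
#' @export
promoterBoundFraction <- function(lamGenes, promoters, proxySites) {
  if (!length(lamGenes)) return(0)
  known <- lamGenes %in% names(promoters)
  if (!all(known))
    warning(sum(!known), " gene(s) missing from the promoter set; counted unbound")
  if (!length(proxySites) || !any(known)) return(0)
  hit <- GenomicRanges::countOverlaps(promoters[lamGenes[known]], proxySites) > 0
  sum(hit) / length(lamGenes)
}

#' Motif position histogram around region centers
#'
#' Scans a fixed window centered on each region's midpoint and
#' accumulates motif-hit centers into bins, mirroring a
#' motif-frequency profile around peak or promoter centers (window
#' 2000 bp, bin 20 bp by default). Window parts falling outside the
#' sequence are skipped.
#'
#' @param regions [GenomicRanges::GRanges] (peaks or promoters).
#' @param genome named [Biostrings::DNAStringSet].
#' @param pwm a [MotifPwm-class].
#' @param window total window width in bp.
#' @param bin bin width in bp; must divide `window`.
#' @return data.frame with `binStart`, `binEnd` (positions relative to
#'   the region center) and `count`; counts sum to the total number of
#'   in-window hits.
#' @export
motifPositionHistogram <- function(regions, genome, pwm, window = 2000,
                                   bin = 20) {
  stopifnot(length(regions) > 0, window %% bin == 0)
  half <- window / 2
  L <- ncol(pwm@probs)
  breaks <- seq(-half, half, by = bin)
  counts <- integer(length(breaks) - 1)
  for (i in seq_along(regions)) {
    chr <- as.character(GenomicRanges::seqnames(regions)[i])
    sq <- genome[[chr]]
    center <- floor((GenomicRanges::start(regions)[i] +
                     GenomicRanges::end(regions)[i]) / 2) # 1-based
    from <- max(1, center - half)
    to <- min(length(sq), center + half - 1)
    hits <- scanMotif(subseq(sq, from, to), pwm)
    if (!nrow(hits)) next
    rel <- (from - 1 + hits$offset + L %/% 2) - (center - 1) # vs center, 0-based
    rel <- rel[rel >= -half & rel < half]
    if (length(rel))
      counts <- counts + tabulate(floor((rel + half) / bin) + 1L,
                                  nbins = length(counts))
  }
  data.frame(binStart = breaks[-length(breaks)], binEnd = breaks[-1],
             count = counts)
}

#' Export proxy-binding sites as a sorted BED6 file
#'
#' Writes peaks as BED (0-based half-open, as the format requires),
#' sorted by sequence then start, with the motif hit count as the BED
#' score when present. The file round-trips through [readPeaksBed()].
#'
#' @param peaks [GenomicRanges::GRanges]; names become the BED name
#'   column.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportStratifiedBed <- function(peaks, path) {
  ord <- order(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks))
  peaks <- peaks[ord]
  if (length(peaks) && is.null(names(peaks)))
    names(peaks) <- sprintf("peak%04d", seq_along(peaks))
  if (length(peaks)) {
    score <- S4Vectors::mcols(peaks)$nMotifHits
    S4Vectors::mcols(peaks)$score <-
      if (is.null(score)) 0 else as.numeric(score)
  }
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' @describeIn exportStratifiedBed read a BED file back as `GRanges`
#'   (1-based closed coordinates, names from the BED name column).
#' @export
readPeaksBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
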