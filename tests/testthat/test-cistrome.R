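test_that("promoters are symmetric TSS windows clamped to the sequence", {
  tss <- data.frame(gene = c("a", "b", "c"), seqnames = "chr1",
                    position = c(10000, 1000, 10000),
                    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  pr <- makePromoters(tss, flank = 2000, seqLengths = c(chr1 = 50000))
  # 0-based [8000, 12000) is 1-based [8001, 12000]
  expect_equal(start(pr["a"]), 8001)
  expect_equal(end(pr["a"]), 12000)
  expect_equal(width(pr["a"]), 4000)
  expect_equal(start(pr["b"]), 1)   # clamped at the sequence start
  expect_equal(end(pr["b"]), 3000)
  expect_equal(unname(ranges(pr["c"])), unname(ranges(pr["a"]))) # strand-symmetric
  bad <- tss; bad$position[1] <- 60000
  expect_error(makePromoters(bad, 2000, c(chr1 = 50000)), "bounds")
})

test_that("motif scanning finds consensus instances on both strands", {
  ebox <- consensusPwm("CACGTG")
  hits <- scanMotif("TTCACGTGTT", ebox)
  expect_equal(nrow(hits), 1)  # palindromic: reported once, on +
  expect_equal(hits$offset, 2)
  expect_equal(hits$strand, "+")
  # non-palindromic motif present only as its reverse complement
  m <- consensusPwm("GGATAC")
  rcHits <- scanMotif("TTGTATCCTT", m)
  expect_equal(nrow(rcHits), 1)
  expect_equal(rcHits$strand, "-")
  expect_equal(rcHits$offset, 2)
  # threshold above the attainable maximum yields nothing
  strict <- consensusPwm("CACGTG")
  strict@minScore <- pwmMaxScore(strict) + 1
  set.seed(1)
  rand <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_equal(nrow(scanMotif(rand, strict)), 0)
  # shorter than the motif, and N windows skipped
  expect_equal(nrow(scanMotif("CAC", ebox)), 0)
  expect_equal(nrow(scanMotif("CACGNG", ebox)), 0)
})

test_that("scan of the reverse complement mirrors the hit set", {
  m <- consensusPwm("GGATAC")
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  s <- paste0(substr(s, 1, 100), "GGATAC", substr(s, 107, 300), "GTATCC",
              substr(s, 307, 500))
  rc <- as.character(reverseComplement(DNAString(s)))
  h1 <- scanMotif(s, m)
  h2 <- scanMotif(rc, m)
  expect_equal(nrow(h1), nrow(h2))
  # a hit at offset o maps to the opposite strand at L - o - 6
  expect_setequal(paste(nchar(s) - h1$offset - 6, chartr("+-", "-+", h1$strand)),
                  paste(h2$offset, h2$strand))
})

test_that("proxy-binding sites agree with a naive consensus search", {
  for (seed in 1:4) {
    tg <- simulateGenome(nGenes = 25, plantedFraction = 0.5, seed = seed,
                         promoterFlank = 300, peakWidth = 100)
    hits <- proxyBindingSites(tg@peaks, tg@sequences, tg@motif)
    naive <- vapply(seq_along(tg@peaks), function(i) {
      s <- as.character(subseq(tg@sequences[["chr1"]],
                               start(tg@peaks)[i], end(tg@peaks)[i]))
      naiveConsensusHit(s, pwmConsensus(tg@motif))
    }, TRUE)
    expect_setequal(names(hits), names(tg@peaks)[naive])
    expect_setequal(names(hits), tg@plantedGenes)
    expect_true(all(mcols(hits)$nMotifHits >= 1))
  }
})

test_that("promoter-bound fraction equals the quadratic overlap oracle", {
  tg <- simulateGenome(nGenes = 50, plantedFraction = 0.4, seed = 2L)
  pr <- makePromoters(tg@tss, 2000,
                      setNames(Biostrings::width(tg@sequences),
                               names(tg@sequences)))
  sites <- proxyBindingSites(tg@peaks, tg@sequences, tg@motif)
  expect_equal(promoterBoundFraction(tg@tss$gene, pr, sites), 0.4)
  expect_equal(promoterBoundFraction(tg@tss$gene, pr, sites[0]), 0)
  # random intervals: package overlap vs brute force
  set.seed(3)
  for (rep in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    s1 <- sample(1:5000, n1); w1 <- sample(10:200, n1, TRUE)
    s2 <- sample(1:5000, n2); w2 <- sample(10:200, n2, TRUE)
    prom <- GRanges("chr1", IRanges(s1, width = w1))
    names(prom) <- sprintf("g%02d", seq_len(n1))
    pk <- GRanges("chr1", IRanges(s2, width = w2))
    got <- promoterBoundFraction(names(prom), prom, pk)
    want <- mean(overlapOracle(s1, s1 + w1 - 1, s2, s2 + w2 - 1))
    expect_equal(got, want)
  }
  # monotone in added peaks
  f1 <- promoterBoundFraction(tg@tss$gene, pr, sites[seq_len(5)])
  f2 <- promoterBoundFraction(tg@tss$gene, pr, sites)
  expect_gte(f2, f1)
  expect_warning(promoterBoundFraction(c(tg@tss$gene, "ghost"), pr, sites),
                 "missing")
})

test_that("motif position histograms center hits and conserve totals", {
  tg <- simulateGenome(nGenes = 30, plantedFraction = 1, seed = 4L)
  # instances planted at TSS = peak centers: all mass in the central bins
  h <- motifPositionHistogram(tg@peaks, tg@sequences, tg@motif,
                              window = 2000, bin = 20)
  expect_equal(sum(h$count), 30)
  expect_equal(sum(h$count[h$binStart %in% c(-20, 0)]), 30)
  # conservation against a direct scan of the same windows
  total <- 0
  for (i in seq_along(tg@peaks)) {
    ctr <- floor((start(tg@peaks)[i] + end(tg@peaks)[i]) / 2)
    s <- subseq(tg@sequences[["chr1"]], ctr - 1000, ctr + 999)
    total <- total + nrow(scanMotif(s, tg@motif))
  }
  expect_equal(sum(h$count), total)
})

test_that("uniformly planted hits give a flat histogram", {
  set.seed(5)
  cons <- "CACGTG"
  nR <- 200; win <- 400; binW <- 40
  seqs <- character(nR)
  for (i in seq_len(nR)) {
    chars <- sample(c("A", "C", "G", "T"), win, TRUE)
    s <- paste(chars, collapse = "")
    while (naiveConsensusHit(s, cons)) {
      chars <- sample(c("A", "C", "G", "T"), win, TRUE)
      s <- paste(chars, collapse = "")
    }
    at <- sample.int(win - 6, 1)
    substr(s, at, at + 5) <- cons
    seqs[i] <- s
  }
  genome <- DNAStringSet(seqs)
  names(genome) <- sprintf("r%03d", seq_len(nR))
  regions <- GRanges(names(genome), IRanges(1, win))
  h <- motifPositionHistogram(regions, genome, consensusPwm(cons),
                              window = win, bin = binW)
  expect_equal(sum(h$count), nR)
  expected <- nR / nrow(h)
  band <- 3 * sqrt(expected * (1 - 1 / nrow(h)))
  expect_true(all(abs(h$count - expected) <= band + 3))
})

test_that("stratified BED export round-trips through the reader", {
  tg <- simulateGenome(nGenes = 12, plantedFraction = 0.5, seed = 6L)
  sites <- proxyBindingSites(tg@peaks, tg@sequences, tg@motif)
  path <- tempfile(fileext = ".bed")
  exportStratifiedBed(sites, path)
  back <- readPeaksBed(path)
  expect_equal(length(back), length(sites))
  expect_equal(start(back), sort(start(sites)))
  expect_equal(end(back), end(sites)[order(start(sites))])
  expect_setequal(back$name, names(sites))
  # raw text is 0-based half-open
  first <- read.table(path, sep = "\t", nrows = 1)
  expect_equal(first$V2, min(start(sites)) - 1)
  expect_equal(first$V3, min(start(sites)) - 1 + width(sites)[1])
  # empty set: empty valid file
  p2 <- tempfile(fileext = ".bed")
  exportStratifiedBed(sites[0], p2)
  expect_true(file.exists(p2))
  expect_equal(length(readPeaksBed(p2)), 0)
})
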