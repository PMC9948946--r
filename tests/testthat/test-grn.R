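test_that("raw network inference finds a perfectly coupled pair", {
  set.seed(1)
  v <- rnorm(50, 10)
  expr <- rbind(TF01 = v, G0001 = v)
  net <- inferRawNetwork(expr, "TF01", threshold = 0.2)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$tf, "TF01")
  expect_equal(ed$target, "G0001")
  expect_error(inferRawNetwork(expr, "TF99", threshold = 0.2), "TF")
})

test_that("null matrices produce about p-value x pairs edges", {
  # 12 TFs x 188 genes + 66 TF pairs = 2322 pairs per replicate
  set.seed(11)
  thr <- calibrateMiThreshold(100, 0.001, nNull = 1e5)
  counts <- 0
  for (rep in 1:5) {
    expr <- matrix(rnorm(200 * 100), 200, 100,
                   dimnames = list(c(sprintf("TF%02d", 1:12),
                                     sprintf("G%04d", 1:188)), NULL))
    net <- inferRawNetwork(expr, sprintf("TF%02d", 1:12), threshold = thr)
    counts <- counts + nrow(networkEdges(net))
  }
  lambda <- 0.001 * 2322 * 5
  expect_lte(counts, lambda + 3 * sqrt(lambda) + 1)
})

test_that("DPI removes the weakest edge of a triangle and spares chains", {
  tri <- netFromEdges(c("A", "A", "B"), c("C", "B", "C"), c(0.9, 0.3, 0.8))
  out <- networkEdges(applyDpi(tri, 0))
  expect_equal(nrow(out), 2)
  expect_false(any(out$tf == "A" & out$target == "B"))
  chain <- netFromEdges(c("A", "B"), c("B", "C"), c(0.5, 0.4))
  expect_identical(networkEdges(applyDpi(chain, 0)),
                   networkEdges(chain))
})

test_that("DPI equals the exhaustive-triplet oracle on random graphs", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    nodes <- LETTERS[1:n]
    pairs <- utils::combn(nodes, 2)
    keep <- runif(ncol(pairs)) < 0.7
    if (sum(keep) < 3) next
    a <- pairs[1, keep]; b <- pairs[2, keep]
    mi <- round(runif(sum(keep), 0.1, 1), 2)
    tol <- sample(c(0, 0.15), 1)
    net <- netFromEdges(a, b, mi)
    got <- networkEdges(applyDpi(net, tol))[, c("tf", "target")]
    want <- dpiOracle(net, tol)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("DPI never adds edges and is idempotent at tolerance 0", {
  set.seed(6)
  for (rep in 1:20) {
    pairs <- utils::combn(LETTERS[1:5], 2)
    keep <- runif(ncol(pairs)) < 0.8
    net <- netFromEdges(pairs[1, keep], pairs[2, keep],
                        round(runif(sum(keep), 0.1, 1), 2))
    once <- applyDpi(net, 0)
    expect_true(all(paste(networkEdges(once)$tf, networkEdges(once)$target)
                    %in% paste(networkEdges(net)$tf, networkEdges(net)$target)))
    twice <- applyDpi(once, 0)
    expect_identical(networkEdges(once), networkEdges(twice))
  }
})

test_that("bootstrap tallies are deterministic and bounded by n_bootstraps", {
  co <- simulateCohort(tinyConfig(), nDatasetsPerSpecies = 1, seed = 8L)
  ds <- co$datasets$hs1
  mc <- filterGenes(buildMetacells(ds, correlationDistance(cpmNormalize(ds)),
                                   numNeighbors = 4, subSize = 24), 0.75)
  p <- grnParams(nBootstraps = 5, seed = 17, nNull = 2e4)
  t1 <- bootstrapEdges(mc, S4Vectors::metadata(ds)$tfs, p)
  t2 <- bootstrapEdges(mc, S4Vectors::metadata(ds)$tfs, p)
  expect_identical(t1, t2)
  expect_true(all(t1$support <= 5))
})

test_that("Poisson consolidation keeps recurrent edges and drops one-offs", {
  # one strong edge among many singletons: universe sized so the
  # occurrence rate is far below the strong edge's support
  mkTally <- function(df, tfs, universe, nBoot) {
    attr(df, "nBootstraps") <- nBoot
    attr(df, "tfs") <- tfs
    attr(df, "geneUniverse") <- universe
    df
  }
  universe <- c("TF1", sprintf("g%03d", 1:400))
  singles <- data.frame(tf = "TF1", target = sprintf("g%03d", 2:100),
                        support = 1L, mi = 0.3, stringsAsFactors = FALSE)
  tally <- mkTally(rbind(
    data.frame(tf = "TF1", target = "g001", support = 200L, mi = 0.9,
               stringsAsFactors = FALSE), singles),
    "TF1", universe, 200L)
  net <- consolidateEdges(tally, 0.05)
  expect_identical(networkEdges(net)$target, "g001")
  expect_equal(networkEdges(net)$support, 200L)
  expect_lt(networkEdges(net)$p, 1e-10)

  # Poisson upper-tail oracle at a checkable support level
  mid <- mkTally(rbind(
    data.frame(tf = "TF1", target = "g001", support = 4L, mi = 0.8,
               stringsAsFactors = FALSE),
    data.frame(tf = "TF1", target = sprintf("g%03d", 2:21), support = 1L,
               mi = 0.3, stringsAsFactors = FALSE)),
    "TF1", c("TF1", sprintf("g%03d", 1:100)), 50L)
  netMid <- consolidateEdges(mid, 0.05)
  lambda <- 24 / 100
  pOracle <- 1 - sum(exp(-lambda) * lambda^(0:3) / factorial(0:3))
  expect_equal(networkEdges(netMid)$p[networkEdges(netMid)$target == "g001"],
               pOracle)

  # a 1-support edge among 50-support edges is removed at FDR 0.05
  dense <- data.frame(tf = "TF1", target = sprintf("g%03d", 1:50),
                      support = 50L, mi = 0.8, stringsAsFactors = FALSE)
  tally2 <- mkTally(rbind(dense,
    data.frame(tf = "TF1", target = "g051", support = 1L, mi = 0.3,
               stringsAsFactors = FALSE)),
    "TF1", c("TF1", sprintf("g%03d", 1:51), sprintf("x%03d", 1:949)), 200L)
  net2 <- consolidateEdges(tally2, 0.05)
  expect_false("g051" %in% networkEdges(net2)$target)
  expect_setequal(networkEdges(net2)$target, sprintf("g%03d", 1:50))

  # empty tally: empty network, no error; FDR 1 keeps everything
  empty <- mkTally(data.frame(tf = character(), target = character(),
                              support = integer(), mi = numeric(),
                              stringsAsFactors = FALSE),
                   "TF1", universe, 200L)
  expect_equal(nrow(networkEdges(consolidateEdges(empty, 0.05))), 0)
  expect_equal(nrow(networkEdges(consolidateEdges(tally, 1))), 100)
})

test_that("meta-consolidation of one dataset reduces to single consolidation", {
  co <- simulateCohort(tinyConfig(), nDatasetsPerSpecies = 1, seed = 12L)
  ds <- co$datasets$hs1
  mc <- filterGenes(buildMetacells(ds, correlationDistance(cpmNormalize(ds)),
                                   numNeighbors = 4, subSize = 24), 0.75)
  p <- grnParams(nBootstraps = 5, seed = 23, nNull = 2e4)
  tal <- bootstrapEdges(mc, S4Vectors::metadata(ds)$tfs, p)
  single <- consolidateEdges(tal, p$consolidationFdr)
  meta <- metaConsolidate(list(tal), p$consolidationFdr)
  expect_identical(networkEdges(meta)[, c("tf", "target", "mi", "support")],
                   networkEdges(single)[, c("tf", "target", "mi", "support")])
  if (nrow(networkEdges(meta))) {
    expect_true(all(networkEdges(meta)$normMi >= 0 &
                    networkEdges(meta)$normMi <= 1))
  }
  expect_error(
    metaConsolidate(list(tal, structure(tal[0, ],
      nBootstraps = 5L, tfs = "zz_TF", geneUniverse = c("zz_a", "zz_b")))),
    "disjoint")
})
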