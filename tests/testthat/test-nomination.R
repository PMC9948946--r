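test_that("regulon extraction returns targets, possibly empty", {
  net <- netFromEdges(c("TF1", "TF1", "TF2"), c("g1", "g2", "TF1"),
                      c(0.5, 0.6, 0.7))
  expect_setequal(extractRegulon(net, "TF1"), c("g1", "g2", "TF2"))
  expect_true(all(extractRegulon(net, "TF1") %in% geneUniverse(net)))
  lonely <- netFromEdges("TF1", "g1", 0.5)
  lonely@tfs <- c(lonely@tfs, "TF9")
  expect_length(extractRegulon(lonely, "TF9"), 0)
  expect_error(extractRegulon(net, "nope"), "TF list")
})

test_that("hypergeometric enrichment matches closed forms", {
  u <- sprintf("g%02d", 1:20)
  r <- hypergeometricEnrichment(u[1:5], u[1:5], u)
  expect_equal(r$p, 1 / choose(20, 5))
  expect_equal(r$k, 5)
  u10 <- sprintf("g%02d", 1:10)
  r <- hypergeometricEnrichment(u10[1:5], u10[c(1:3, 6:7)], u10)
  expect_equal(r$p, 0.5) # exact tail: 126/252
  r <- hypergeometricEnrichment(u[1:5], u[6:10], u)
  expect_equal(r$p, 1) # k = 0
  expect_error(hypergeometricEnrichment("a", "a", character()), "universe")
  expect_warning(hypergeometricEnrichment(c(u[1:3], "zz"), u[1:5], u),
                 "universe")
})

test_that("hypergeometric enrichment equals tail enumeration on all small instances", {
  for (N in c(5, 8, 12)) {
    u <- sprintf("g%02d", seq_len(N))
    for (K in 0:N) for (n in 0:N) {
      kmax <- min(K, n); kmin <- max(0, K + n - N)
      for (k in kmin:kmax) {
        geneset <- c(head(u, k), head(setdiff(u, head(u, K)), n - k))
        r <- hypergeometricEnrichment(head(u, K), geneset, u)
        expect_equal(r$k, k)
        expect_equal(r$p, hyperTailOracle(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment p agrees with Monte-Carlo resampling", {
  set.seed(31)
  u <- sprintf("g%03d", 1:100)
  geneset <- u[1:30]
  regulon <- sample(u, 20)
  r <- hypergeometricEnrichment(regulon, geneset, u)
  draws <- rhyper(1e5, m = 30, n = 70, k = 20)
  mc <- mean(draws >= r$k)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(r$p - mc), 3 * se + 1e-6)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bhAdjust(c(0.5, 1.2)))
})

# small two-species enrichment fixture: 2 networks per species, 3
# genesets; `qual` gives the qualifying-network count to fabricate
mockEnrichments <- function(qualPerTf) {
  rows <- list()
  for (sp in c("hs", "mm")) for (net in 1:2) for (tf in names(qualPerTf)) {
    q <- qualPerTf[[tf]]
    hit <- net <= q[[sp]]
    for (gs in c("DAM", "LAM", "TREM2hi")) {
      rows[[length(rows) + 1]] <- data.frame(
        tf = paste0(sp, "_", tf), geneset = gs,
        network = paste0(sp, net), species = sp,
        N = 100, K = 10, n = 20, k = ifelse(hit, 9, 0),
        p = ifelse(hit, 1e-6, 1), fdr = ifelse(hit, 1e-5, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

mockOrthologs <- function(tfs) {
  data.frame(hs = paste0("hs_", tfs), mm = paste0("mm_", tfs),
             stringsAsFactors = FALSE)
}

test_that("nomination applies the cross-network, cross-species and expression rules", {
  enr <- mockEnrichments(list(
    TFa = list(hs = 2, mm = 2),   # qualifies everywhere
    TFb = list(hs = 2, mm = 0),   # human-specific
    TFc = list(hs = 2, mm = 2),   # qualifies but not expressed
    TFd = list(hs = 0, mm = 0)))  # never qualifies
  orth <- mockOrthologs(c("TFa", "TFb", "TFc", "TFd"))
  tpm <- c(hs_TFa = 5, hs_TFb = 5, hs_TFc = 0.5, hs_TFd = 5)
  nom <- nominateLamTfs(enr, orth, tpm,
                        nominationCriteria(minNetworks = 2))
  get <- function(tf) nom[nom$tf_hs == paste0("hs_", tf), ]
  expect_true(get("TFa")$nominated)
  expect_false(get("TFb")$nominated)
  expect_equal(get("TFb")$speciesSpecific, "hs")
  expect_false(get("TFc")$nominated)   # TPM 0.5 < 1
  expect_true(get("TFc")$passNetworks)
  expect_false(get("TFd")$nominated)
  # missing expression entries are flagged and treated as not expressed
  nom2 <- nominateLamTfs(enr, orth, tpm[-1],
                         nominationCriteria(minNetworks = 2))
  ra <- nom2[nom2$tf_hs == "hs_TFa", ]
  expect_true(ra$expressionMissing)
  expect_false(ra$nominated)
})

test_that("'half' rounds up and criteria changes act monotonically", {
  enr <- mockEnrichments(list(
    TFa = list(hs = 1, mm = 1),
    TFb = list(hs = 2, mm = 2)))
  orth <- mockOrthologs(c("TFa", "TFb"))
  tpm <- c(hs_TFa = 5, hs_TFb = 5)
  # half of 2 networks = 1
  nomHalf <- nominateLamTfs(enr, orth, tpm, nominationCriteria())
  expect_true(all(nomHalf$nominated))
  nom2 <- nominateLamTfs(enr, orth, tpm, nominationCriteria(minNetworks = 2))
  expect_equal(sum(nom2$nominated), 1)
  # lowering minNetworks never shrinks the nominated set
  expect_true(all(nom2$tf_hs[nom2$nominated] %in%
                  nomHalf$tf_hs[nomHalf$nominated]))
  # raising the FDR threshold never shrinks it either
  enrBorder <- mockEnrichments(list(TFa = list(hs = 2, mm = 2)))
  enrBorder$fdr[enrBorder$fdr < 1] <- 0.15
  n1 <- nominateLamTfs(enrBorder, mockOrthologs("TFa"), c(hs_TFa = 5),
                       nominationCriteria(fdrThreshold = 0.1))
  n2 <- nominateLamTfs(enrBorder, mockOrthologs("TFa"), c(hs_TFa = 5),
                       nominationCriteria(fdrThreshold = 0.2))
  expect_true(all(n1$tf_hs[n1$nominated] %in% n2$tf_hs[n2$nominated]))
  expect_true(n2$nominated[1])
})

test_that("enrichRegulons adjusts within one network across TF x geneset tests", {
  net <- netFromEdges(c("TF1", "TF1", "TF2"), c("g1", "g2", "g3"),
                      c(0.5, 0.6, 0.7))
  net@geneUniverse <- sort(c(net@geneUniverse, sprintf("x%02d", 1:20)))
  gs <- list(A = c("g1", "g2"), B = "g3")
  enr <- enrichRegulons(net, gs, networkId = "n1", species = "hs")
  expect_equal(nrow(enr), length(networkTfs(net)) * 2)
  expect_equal(enr$fdr, bhAdjust(enr$p))
})
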