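#' Extract the regulon of a transcription factor
#'
#' Targets of `tf` in a network, i.e. all genes joined to it by an edge
#' (TF-TF edges count regardless of storage orientation). May be empty.
#'
#' @param net a [GrnNetwork-class].
#' @param tf regulator symbol; must be in `networkTfs(net)`.
#' @return character vector of target genes (sorted).
#' @export
extractRegulon <- function(net, tf) {
  stopifnot(is(net, "GrnNetwork"))
  if (!tf %in% net@tfs) stop(tf, " is not in the network's TF list")
  ed <- net@edges
  sort(unique(c(ed$target[ed$tf == tf], ed$tf[ed$target == tf])))
}

#' Hypergeometric enrichment of a geneset in a regulon
#'
#' Upper-tail hypergeometric test (`phyper`) of the overlap between a
#' regulon and a geneset within a gene universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the
#' universe size, `K` the regulon size, `n` the geneset size within the
#' universe, and `k` the observed overlap. Sets not contained in the
#' universe are intersected with it, with a warning.
#'
#' @param regulon,geneset character gene sets.
#' @param universe character gene universe (non-empty).
#' @return one-row data.frame with `N`, `K`, `n`, `k`, `p`.
#' @examples
#' hypergeometricEnrichment(letters[1:5], letters[1:5], letters[1:20])
#' @export
hypergeometricEnrichment <- function(regulon, geneset, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!all(regulon %in% universe) || !all(geneset %in% universe)) {
    warning("sets restricted to the universe")
    regulon <- intersect(regulon, universe)
    geneset <- intersect(geneset, universe)
  }
  N <- length(universe)
  K <- length(unique(regulon))
  n <- length(unique(geneset))
  k <- length(intersect(regulon, geneset))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(N = N, K = K, n = n, k = k, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH-adjusted p-values (monotone, capped at 1); thin wrapper
#' over `p.adjust` so the correction family used throughout the package
#' has a single entry point.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted values of the same length.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Enrichment of every regulon of a network against genesets
#'
#' Runs [hypergeometricEnrichment()] for each TF regulon of one network
#' against each geneset and BH-adjusts the p-values across all TF x
#' geneset tests of that network (the per-network correction family used
#' for nomination).
#'
#' @param net a [GrnNetwork-class].
#' @param genesets named list of character gene sets (same species
#'   namespace as the network).
#' @param networkId identifier recorded in the result.
#' @param species species tag recorded in the result.
#' @param universe gene universe for the tests; defaults to the
#'   network's `geneUniverse` (the genes that survived the metacell
#'   filter and entered inference).
#' @return data.frame with one row per TF x geneset: `tf`, `geneset`,
#'   `network`, `species`, `N`, `K`, `n`, `k`, `p`, `fdr`.
#' @export
enrichRegulons <- function(net, genesets, networkId, species,
                           universe = geneUniverse(net)) {
  stopifnot(is(net, "GrnNetwork"), length(genesets) >= 1,
            !is.null(names(genesets)))
  rows <- list()
  for (tf in net@tfs) {
    reg <- extractRegulon(net, tf)
    for (gs in names(genesets)) {
      r <- suppressWarnings(
        hypergeometricEnrichment(reg, genesets[[gs]], universe))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(tf = tf, geneset = gs, network = networkId,
                         species = species, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Criteria for LAM-TF nomination
#'
#' @param fdrThreshold per-network enrichment FDR below which a geneset
#'   counts as enriched (default 0.2).
#' @param minNetworks `"half"` for at least half the networks of each
#'   species (rounded up), or an integer count (2 reproduces the broad
#'   list criterion).
#' @param requireAllGenesets must all genesets be enriched for a TF to
#'   qualify in a network (default TRUE)?
#' @param tpmThreshold minimum reference expression (default 1 TPM).
#' @return validated list of class `NominationCriteria`.
#' @export
nominationCriteria <- function(fdrThreshold = 0.2, minNetworks = "half",
                               requireAllGenesets = TRUE, tpmThreshold = 1) {
  stopifnot(fdrThreshold > 0,
            identical(minNetworks, "half") || minNetworks >= 1,
            tpmThreshold >= 0)
  structure(list(fdrThreshold = fdrThreshold, minNetworks = minNetworks,
                 requireAllGenesets = requireAllGenesets,
                 tpmThreshold = tpmThreshold),
            class = "NominationCriteria")
}

# match a TF symbol of species sp to its counterpart in species other
.mapOrtholog <- function(tf, sp, other, orthologs) {
  hit <- match(tf, orthologs[[sp]])
  if (!is.na(hit)) return(orthologs[[other]][hit])
  # case-insensitive symbol fallback (e.g. BHLHE40 vs Bhlhe40)
  hit <- match(toupper(tf), toupper(orthologs[[sp]]))
  if (!is.na(hit)) return(orthologs[[other]][hit])
  NA_character_
}

#' Nominate LAM transcription factors across networks and species
#'
#' Applies the cross-network, cross-species nomination logic: a TF
#' qualifies in a network if (by default) all genesets are enriched
#' there at `fdrThreshold`; it is nominated when its qualifying-network
#' count meets `minNetworks` in BOTH species (TFs matched across species
#' through the ortholog map, with a case-insensitive symbol fallback)
#' and its reference expression reaches `tpmThreshold`. TFs meeting the
#' count in exactly one species are reported as species-specific. TFs
#' missing from the expression reference are treated as not expressed
#' and flagged.
#'
#' @param enrichments row-bound [enrichRegulons()] tables over all
#'   networks of both species.
#' @param orthologs two-column data.frame named by the species tags,
#'   mapping symbols across species.
#' @param expressionTpm named numeric vector of reference expression
#'   (TPM); looked up under either species' symbol.
#' @param criteria a [nominationCriteria()] object.
#' @return data.frame with one row per cross-species TF pair: the symbol
#'   in each species, qualifying and total network counts per species,
#'   pass flags per criterion (`passNetworks`, `expressed`,
#'   `expressionMissing`), `speciesSpecific` label, and the final
#'   `nominated` call.
#' @export
nominateLamTfs <- function(enrichments, orthologs, expressionTpm,
                           criteria = nominationCriteria()) {
  stopifnot(inherits(criteria, "NominationCriteria"),
            is.data.frame(orthologs), ncol(orthologs) >= 2)
  species <- unique(enrichments$species)
  if (length(species) != 2)
    stop("enrichments must cover exactly two species")
  stopifnot(all(species %in% names(orthologs)))

  nGenesets <- length(unique(enrichments$geneset))
  nNetworks <- vapply(species, function(sp)
    length(unique(enrichments$network[enrichments$species == sp])), 0L)
  need <- vapply(species, function(sp) {
    if (identical(criteria$minNetworks, "half"))
      as.integer(ceiling(nNetworks[[sp]] / 2)) else
      as.integer(criteria$minNetworks)
  }, 0L)

  # qualifying networks per TF and species
  enr <- enrichments
  enr$hit <- enr$fdr < criteria$fdrThreshold
  qual <- lapply(species, function(sp) {
    e <- enr[enr$species == sp, , drop = FALSE]
    counts <- integer(0)
    for (tf in unique(e$tf)) {
      byNet <- split(e[e$tf == tf, , drop = FALSE], e$network[e$tf == tf])
      q <- vapply(byNet, function(d) {
        if (criteria$requireAllGenesets)
          nrow(d) == nGenesets && all(d$hit) else any(d$hit)
      }, TRUE)
      counts[tf] <- sum(q)
    }
    counts
  })
  names(qual) <- species

  sp1 <- species[1]; sp2 <- species[2]
  tfs1 <- names(qual[[sp1]])
  rows <- lapply(tfs1, function(tf1) {
    tf2 <- .mapOrtholog(tf1, sp1, sp2, orthologs)
    q1 <- qual[[sp1]][[tf1]]
    q2 <- if (!is.na(tf2) && tf2 %in% names(qual[[sp2]]))
      qual[[sp2]][[tf2]] else 0L
    missing <- !any(c(tf1, tf2) %in% names(expressionTpm))
    tpm <- if (missing) 0 else
      max(expressionTpm[stats::na.omit(c(tf1, tf2))], na.rm = TRUE)
    pass1 <- q1 >= need[[sp1]]; pass2 <- q2 >= need[[sp2]]
    data.frame(
      tf1 = tf1, tf2 = ifelse(is.na(tf2), NA_character_, tf2),
      qual1 = q1, qual2 = q2,
      nNetworks1 = nNetworks[[sp1]], nNetworks2 = nNetworks[[sp2]],
      passNetworks = pass1 && pass2,
      conserved = !is.na(tf2),
      expressed = tpm >= criteria$tpmThreshold,
      expressionMissing = missing,
      speciesSpecific = if (pass1 && !pass2) sp1
        else if (pass2 && !pass1) sp2 else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1:2] <- paste0("tf_", c(sp1, sp2))
  names(out)[3:4] <- paste0("qual_", c(sp1, sp2))
  names(out)[5:6] <- paste0("nNetworks_", c(sp1, sp2))
  out$nominated <- out$passNetworks & out$conserved & out$expressed
  rownames(out) <- NULL
  out[order(-out$nominated, out[[1]]), , drop = FALSE]
}
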