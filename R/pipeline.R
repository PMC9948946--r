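#' Run the full LAM-TF nomination pipeline on a cohort
#'
#' End-to-end orchestration over a (typically simulated) two-species
#' cohort: per dataset, CPM normalization, correlation-distance metacell
#' aggregation, gene detection filtering, bootstrap MI network inference
#' with DPI pruning and Poisson consolidation; then per-network regulon
#' enrichment against the LAM genesets and cross-network, cross-species
#' nomination. Per-species meta-networks (pooled bootstraps) are also
#' returned for regulon inspection.
#'
#' @param cohort a [simulateCohort()]-shaped list: `datasets` (named
#'   list of experiments whose names start with the species tag),
#'   `orthologs`, `species`, and for simulated cohorts `lamTfs` and
#'   `config`.
#' @param params a [grnParams()] object.
#' @param criteria a [nominationCriteria()] object.
#' @param genesets per-species named lists of genesets; default derives
#'   three overlapping LAM genesets from the cohort's ground truth.
#' @param expressionTpm named TPM reference; default marks every gene of
#'   the first species expressed at 10 TPM.
#' @param numNeighbors,subSize,minNonzeroFraction metacell parameters
#'   (see [buildMetacells()], [filterGenes()]).
#' @return list with `networks` (per dataset), `tallies` (bootstrap
#'   tallies per dataset), `metaNetworks` (per species), `enrichments`
#'   (row-bound table), and `nomination` (the [nominateLamTfs()] table).
#' @export
runLamPipeline <- function(cohort, params = grnParams(),
                           criteria = nominationCriteria(),
                           genesets = NULL, expressionTpm = NULL,
                           numNeighbors = 9, subSize = NULL,
                           minNonzeroFraction = 0.75) {
  stopifnot(length(cohort$species) == 2)
  if (is.null(genesets))
    genesets <- makeLamGenesets(cohort, seed = params$seed)
  if (is.null(expressionTpm))
    expressionTpm <- makeExpressionReference(cohort)

  dsNames <- names(cohort$datasets)
  dsSeeds <- withr::with_seed(params$seed,
    sample.int(.Machine$integer.max - 1L, length(dsNames)))

  tallies <- list(); networks <- list(); enr <- list()
  for (i in seq_along(dsNames)) {
    nm <- dsNames[i]
    sp <- cohort$species[startsWith(nm, cohort$species)][1]
    ds <- cohort$datasets[[nm]]
    norm <- cpmNormalize(ds)
    d <- correlationDistance(norm)
    mc <- buildMetacells(ds, d, numNeighbors = numNeighbors,
                         subSize = subSize)
    mc <- filterGenes(mc, minNonzeroFraction)
    tfs <- S4Vectors::metadata(ds)$tfs
    if (is.null(tfs)) tfs <- grep("TF", rownames(ds), value = TRUE)
    dsParams <- params
    dsParams$seed <- dsSeeds[i]
    tallies[[nm]] <- bootstrapEdges(mc, tfs, dsParams)
    networks[[nm]] <- consolidateEdges(tallies[[nm]],
                                       params$consolidationFdr)
    enr[[nm]] <- enrichRegulons(networks[[nm]], genesets[[sp]],
                                networkId = nm, species = sp)
  }
  metaNetworks <- lapply(cohort$species, function(sp)
    metaConsolidate(tallies[startsWith(names(tallies), sp)],
                    params$consolidationFdr))
  names(metaNetworks) <- cohort$species

  enrichments <- do.call(rbind, enr)
  rownames(enrichments) <- NULL
  nomination <- nominateLamTfs(enrichments, cohort$orthologs,
                               expressionTpm, criteria)
  list(networks = networks, tallies = tallies,
       metaNetworks = metaNetworks, enrichments = enrichments,
       nomination = nomination)
}

#' Score edge recovery of a network against planted ground truth
#'
#' Precision, recall and F1 of an inferred TF-target edge set against
#' the planted edges of a simulated dataset, both read as unordered
#' pairs.
#'
#' @param net a [GrnNetwork-class].
#' @param plantedEdges data.frame with columns `tf`, `target`.
#' @return list with `precision`, `recall`, `f1`, `nInferred`,
#'   `nPlanted`.
#' @export
scoreEdgeRecovery <- function(net, plantedEdges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ed <- networkEdges(net)
  inf <- unique(key(ed$tf, ed$target))
  pl <- unique(key(plantedEdges$tf, plantedEdges$target))
  tp <- length(intersect(inf, pl))
  precision <- if (length(inf)) tp / length(inf) else 0
  recall <- if (length(pl)) tp / length(pl) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       nInferred = length(inf), nPlanted = length(pl))
}

#' Score TF nomination against planted LAM drivers
#'
#' @param nomination a [nominateLamTfs()] table.
#' @param plantedTfs planted LAM-driver symbols of the first species.
#' @param speciesCol which TF symbol column to compare on (default the
#'   first).
#' @return list with `precision`, `recall`, `f1`, `nominated`.
#' @export
scoreNomination <- function(nomination, plantedTfs, speciesCol = 1) {
  called <- nomination[[speciesCol]][nomination$nominated]
  tp <- length(intersect(called, plantedTfs))
  precision <- if (length(called)) tp / length(called) else 0
  recall <- if (length(plantedTfs)) tp / length(plantedTfs) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       nominated = sort(called))
}
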