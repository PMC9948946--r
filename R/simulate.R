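#' Configuration for the synthetic single-cell generator
#'
#' Defines a cohort's study conditions: size, planted regulon structure,
#' negative-binomial noise, dropout, and the activated (LAM-like)
#' subpopulation. Transcription factors are named `TF01`, `TF02`, ...;
#' each regulates a disjoint block of `regulonSize` target genes
#' (`G0001`, ...), and the remaining genes are unregulated background.
#' Per cell, each TF has a log-normal activity latent that is
#' standardized across cells; activated cells receive a fixed additive
#' activity shift for the designated LAM-driver TFs. A gene's
#' negative-binomial mean is `baselineMean * (1 + effectSizeBeta * z)`
#' (floored at 5% of baseline), where `z` is the standardized activity of
#' its regulator; the TF's own transcript follows the same coupling so
#' that TF-target dependence is observable in the counts.
#'
#' @param nCells cells per dataset.
#' @param nGenes total genes (TFs included).
#' @param nTfs number of transcription factors.
#' @param regulonSize targets per TF; `regulonSize * nTfs` may not exceed
#'   `nGenes - nTfs`.
#' @param effectSizeBeta multiplier linking standardized TF activity to
#'   target mean (0 = no planted signal).
#' @param baselineMean expected counts per gene and cell at neutral
#'   activity.
#' @param dispersion negative-binomial dispersion phi; the variance is
#'   `mu * (1 + phi * mu)` (phi = 0 recovers Poisson).
#' @param dropoutRate independent probability of zeroing each count.
#' @param lamFraction fraction of cells in the activated state.
#' @param lamTfIds TF identifiers designated as LAM drivers.
#' @param lamActivityShift additive shift applied to the standardized
#'   activity of LAM-driver TFs in activated cells.
#' @param seed integer RNG seed.
#' @return validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(nCells = 200, nGenes = 60, nTfs = 4, regulonSize = 10)
#' @export
simConfig <- function(nCells = 800, nGenes = 300, nTfs = 12,
                      regulonSize = 20, effectSizeBeta = 3,
                      baselineMean = 20, dispersion = 0.1,
                      dropoutRate = 0.05, lamFraction = 0.3,
                      lamTfIds = c("TF01", "TF02", "TF03"),
                      lamActivityShift = 2, seed = 1L) {
  tfIds <- sprintf("TF%02d", seq_len(nTfs))
  if (dropoutRate < 0 || dropoutRate > 1)
    stop("dropoutRate must lie in [0, 1]")
  if (lamFraction < 0 || lamFraction > 1)
    stop("lamFraction must lie in [0, 1]")
  if (regulonSize * nTfs > nGenes - nTfs)
    stop("regulon overflow: regulonSize * nTfs exceeds nGenes - nTfs")
  if (!all(lamTfIds %in% tfIds))
    stop("lamTfIds must be a subset of the TF identifiers")
  if (dispersion < 0) stop("dispersion must be non-negative")
  structure(list(
    nCells = as.integer(nCells), nGenes = as.integer(nGenes),
    nTfs = as.integer(nTfs), regulonSize = as.integer(regulonSize),
    effectSizeBeta = effectSizeBeta, baselineMean = baselineMean,
    dispersion = dispersion, dropoutRate = dropoutRate,
    lamFraction = lamFraction, lamTfIds = lamTfIds,
    lamActivityShift = lamActivityShift, seed = as.integer(seed),
    tfIds = tfIds
  ), class = "SimConfig")
}

.simGeneTable <- function(config) {
  tfs <- config$tfIds
  targets <- sprintf("G%04d", seq_len(config$nGenes - config$nTfs))
  regulator <- rep(NA_character_, length(targets))
  idx <- seq_len(config$regulonSize * config$nTfs)
  regulator[idx] <- rep(tfs, each = config$regulonSize)
  list(tfs = tfs, targets = targets, regulator = regulator)
}

#' Simulate one single-cell dataset with planted regulons
#'
#' Draws negative-binomial counts under the generative model described in
#' [simConfig()], then injects independent dropout zeros. The returned
#' object carries the full ground truth (planted edges, LAM geneset, cell
#' states) in its metadata, so recovery by the network pipeline can be
#' scored exactly.
#'
#' @param config a [simConfig()] object.
#' @param species optional species tag; gene and TF symbols are prefixed
#'   `"<species>_"` so two pseudo-species share an ortholog structure by
#'   name.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, per-cell `cellState` ("baseline"/"activated") in
#'   `colData`, and `metadata()$groundTruth` holding `plantedEdges`
#'   (data.frame tf, target), `lamGeneset`, `lamTfs`, `cellState`.
#' @examples
#' sce <- simulateDataset(simConfig(nCells = 100, nGenes = 60, nTfs = 4,
#'                                  regulonSize = 10, lamTfIds = "TF01"))
#' @export
simulateDataset <- function(config, species = NULL, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(seed, {
    gt <- .simGeneTable(config)
    nC <- config$nCells
    pfx <- if (is.null(species)) "" else paste0(species, "_")
    genes <- paste0(pfx, c(gt$tfs, gt$targets))
    tfs <- paste0(pfx, gt$tfs)
    lamTfs <- paste0(pfx, config$lamTfIds)

    nAct <- round(config$lamFraction * nC)
    state <- rep("baseline", nC)
    if (nAct > 0) state[sample.int(nC, nAct)] <- "activated"

    # standardized log-normal activity per TF, shifted in activated cells
    act <- matrix(0, nC, config$nTfs, dimnames = list(NULL, gt$tfs))
    for (tf in gt$tfs) {
      a <- rlnorm(nC, meanlog = 0, sdlog = 0.5)
      z <- as.numeric(scale(a))
      if (paste0(pfx, tf) %in% lamTfs)
        z[state == "activated"] <- z[state == "activated"] + config$lamActivityShift
      act[, tf] <- z
    }

    mu <- matrix(config$baselineMean, length(genes), nC,
                 dimnames = list(genes, NULL))
    couple <- function(z)
      config$baselineMean * pmax(1 + config$effectSizeBeta * z, 0.05)
    for (i in seq_along(gt$tfs))
      mu[paste0(pfx, gt$tfs[i]), ] <- couple(act[, i])
    for (j in seq_along(gt$targets)) {
      reg <- gt$regulator[j]
      if (!is.na(reg)) mu[paste0(pfx, gt$targets[j]), ] <- couple(act[, reg])
    }

    counts <- matrix(0L, nrow(mu), nC, dimnames = list(genes, NULL))
    if (config$dispersion > 0) {
      counts[] <- rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      counts[] <- stats::rpois(length(mu), lambda = mu)
    }
    if (config$dropoutRate > 0) {
      drop <- matrix(runif(length(counts)) < config$dropoutRate, nrow(counts))
      counts[drop] <- 0L
    }
    colnames(counts) <- sprintf("C%04d", seq_len(nC))

    planted <- data.frame(
      tf = paste0(pfx, gt$regulator[!is.na(gt$regulator)]),
      target = paste0(pfx, gt$targets[!is.na(gt$regulator)]),
      stringsAsFactors = FALSE
    )
    lamGeneset <- planted$target[planted$tf %in% lamTfs]
    groundTruth <- list(plantedEdges = planted, lamGeneset = lamGeneset,
                        lamTfs = lamTfs, cellState = state)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(cellState = state,
                                     row.names = colnames(counts)),
      metadata = list(groundTruth = groundTruth, config = config,
                      species = species, tfs = tfs)
    )
  })
}

#' Simulate a two-pseudo-species cohort
#'
#' Generates `nDatasetsPerSpecies` datasets for each of two
#' pseudo-species from the same [simConfig()], with dataset seeds derived
#' deterministically from the master seed. Both species share the same
#' gene complement and planted LAM drivers under species-prefixed
#' symbols, and an explicit ortholog map links them, so cross-species
#' conservation logic is exercised literally.
#'
#' @param config a [simConfig()] object.
#' @param nDatasetsPerSpecies datasets per species (>= 1).
#' @param seed master seed for deriving per-dataset seeds.
#' @param species two species tags used as symbol prefixes.
#' @return list with `datasets` (named list of
#'   `SingleCellExperiment`s, names like `"hs1"`), `orthologs`
#'   (two-column data.frame named by species), `lamTfs` (list per
#'   species), `species`, and `config`.
#' @examples
#' co <- simulateCohort(simConfig(nCells = 100, nGenes = 60, nTfs = 4,
#'                                regulonSize = 10, lamTfIds = "TF01"),
#'                      nDatasetsPerSpecies = 2, seed = 7)
#' @export
simulateCohort <- function(config, nDatasetsPerSpecies = 4, seed = 1L,
                           species = c("hs", "mm")) {
  stopifnot(inherits(config, "SimConfig"), nDatasetsPerSpecies >= 1,
            length(species) == 2)
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, 2 * nDatasetsPerSpecies))
  datasets <- list()
  k <- 0
  for (sp in species) {
    for (d in seq_len(nDatasetsPerSpecies)) {
      k <- k + 1
      datasets[[paste0(sp, d)]] <-
        simulateDataset(config, species = sp, seed = seeds[k])
    }
  }
  gt <- .simGeneTable(config)
  core <- c(gt$tfs, gt$targets)
  orth <- data.frame(paste0(species[1], "_", core),
                     paste0(species[2], "_", core),
                     stringsAsFactors = FALSE)
  names(orth) <- species
  lamTfs <- lapply(species, function(sp) paste0(sp, "_", config$lamTfIds))
  names(lamTfs) <- species
  list(datasets = datasets, orthologs = orth, lamTfs = lamTfs,
       species = species, config = config)
}

#' Derive LAM genesets from a cohort's ground truth
#'
#' Builds, for each species, `nSets` overlapping genesets by sampling a
#' fraction of the planted LAM program, mimicking the three
#' independently derived LAM/DAM/TREM2hi gene collections used for
#' regulon enrichment.
#'
#' @param cohort result of [simulateCohort()].
#' @param nSets number of genesets per species.
#' @param fraction fraction of the LAM program sampled into each set.
#' @param seed RNG seed.
#' @param setNames names of the genesets.
#' @return list per species of named gene-identifier lists.
#' @export
makeLamGenesets <- function(cohort, nSets = 3, fraction = 0.8, seed = 1L,
                            setNames = c("DAM", "LAM", "TREM2hi")) {
  stopifnot(length(setNames) == nSets)
  withr::with_seed(seed, {
    out <- lapply(cohort$species, function(sp) {
      ds <- cohort$datasets[[paste0(sp, 1)]]
      lam <- S4Vectors::metadata(ds)$groundTruth$lamGeneset
      sets <- lapply(seq_len(nSets), function(i)
        sort(sample(lam, max(2, round(fraction * length(lam))))))
      names(sets) <- setNames
      sets
    })
    names(out) <- cohort$species
    out
  })
}

#' Flat TPM expression reference for a cohort
#'
#' Synthetic stand-in for a reference expression table (e.g. TPM in
#' microglia): every gene of the given species is assigned the same TPM
#' unless overridden, so the expression filter of the nomination step can
#' be exercised in both directions.
#'
#' @param cohort result of [simulateCohort()].
#' @param species which species' symbols to use (default first).
#' @param tpm default TPM per gene.
#' @param override named numeric vector of per-gene TPM overrides.
#' @return named numeric vector of TPM values.
#' @export
makeExpressionReference <- function(cohort, species = cohort$species[1],
                                    tpm = 10, override = NULL) {
  ds <- cohort$datasets[[paste0(species, 1)]]
  ref <- setNames(rep(tpm, nrow(ds)), rownames(ds))
  if (!is.null(override)) ref[names(override)] <- override
  ref
}

#' Simulate a pair of ranked signatures with controlled concordance
#'
#' Draws two per-gene signed scores from a bivariate normal whose Pearson
#' correlation is chosen (via the Gaussian rank-correlation identity
#' relating Pearson r to Spearman rho, `2 * sin(pi * rho / 6)`) so that
#' the Spearman correlation of the
#' two signatures approaches `concordance` as `nGenes` grows.
#'
#' @param nGenes number of shared genes (>= 10).
#' @param concordance target Spearman correlation in \[-1, 1\].
#' @param seed RNG seed.
#' @return list with named score vectors `a` and `b` over the same genes.
#' @examples
#' sp <- simulateSignaturePair(500, 0.3, seed = 1)
#' cor(sp$a, sp$b, method = "spearman")
#' @export
simulateSignaturePair <- function(nGenes, concordance, seed = 1L) {
  if (nGenes < 10) stop("nGenes must be at least 10")
  if (abs(concordance) > 1) stop("concordance must lie in [-1, 1]")
  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(nGenes))
    z1 <- rnorm(nGenes)
    if (concordance == 1) {
      z2 <- z1
    } else if (concordance == -1) {
      z2 <- -z1
    } else {
      r <- 2 * sin(pi * concordance / 6)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(nGenes)
    }
    list(a = setNames(z1, genes), b = setNames(z2, genes))
  })
}

#' Simulate a toy genome with planted motif instances in peaks
#'
#' Builds a single uniform-composition chromosome with `nGenes` evenly
#' spaced TSSs, one open-chromatin peak per gene centered on its TSS, and
#' a written instance of the motif consensus in the peaks of a
#' `plantedFraction` of genes (strand chosen at random). Accidental
#' occurrences of the consensus (either strand) in the background are
#' scrubbed, so with a strict consensus threshold exactly the planted
#' peaks contain hits.
#'
#' @param nGenes number of genes.
#' @param seqLength chromosome length in bp; must accommodate
#'   non-overlapping promoters (default: computed from spacing).
#' @param motif a [MotifPwm-class]; its consensus is what gets planted.
#' @param plantedFraction fraction of genes receiving a motif instance;
#'   exactly `round(plantedFraction * nGenes)` genes are planted.
#' @param seed RNG seed.
#' @param promoterFlank promoter half-width in bp (used for spacing).
#' @param peakWidth width of each peak in bp.
#' @return a [ToyGenome-class].
#' @export
simulateGenome <- function(nGenes, seqLength = NULL,
                           motif = consensusPwm("CACGTG", name = "Ebox"),
                           plantedFraction = 0.5, seed = 1L,
                           promoterFlank = 2000, peakWidth = 200) {
  stopifnot(is(motif, "MotifPwm"), plantedFraction >= 0, plantedFraction <= 1)
  spacing <- 2 * promoterFlank + 200
  minLen <- nGenes * spacing + 2 * promoterFlank
  if (is.null(seqLength)) seqLength <- minLen
  if (seqLength < minLen)
    stop("seqLength too small for ", nGenes, " non-overlapping promoters")
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqChars <- sample(bases, seqLength, replace = TRUE)
    cons <- pwmConsensus(motif)
    rcCons <- as.character(reverseComplement(DNAString(cons)))
    # scrub accidental consensus occurrences on either strand
    scrub <- function(chars) {
      s <- paste(chars, collapse = "")
      for (pat in unique(c(cons, rcCons))) {
        repeat {
          hit <- regexpr(pat, s, fixed = TRUE)
          if (hit < 0) break
          mid <- as.integer(hit) + nchar(pat) %/% 2
          cur <- substr(s, mid, mid)
          substr(s, mid, mid) <- sample(setdiff(bases, cur), 1)
        }
      }
      strsplit(s, "")[[1]]
    }
    seqChars <- scrub(seqChars)

    genes <- sprintf("gene%03d", seq_len(nGenes))
    tssPos <- promoterFlank + 100 + (seq_len(nGenes) - 1) * spacing # 0-based
    nPlant <- round(plantedFraction * nGenes)
    planted <- sort(sample(genes, nPlant))

    peakStart <- tssPos - peakWidth %/% 2 # 0-based
    sites <- data.frame(seqnames = character(), position = integer(),
                        strand = character(), gene = character(),
                        stringsAsFactors = FALSE)
    L <- nchar(cons)
    for (i in seq_len(nGenes)) {
      if (!genes[i] %in% planted) next
      pos0 <- tssPos[i] - L %/% 2 # instance centered on the TSS
      strand <- sample(c("+", "-"), 1)
      inst <- if (strand == "+") cons else rcCons
      seqChars[(pos0 + 1):(pos0 + L)] <- strsplit(inst, "")[[1]]
      sites <- rbind(sites, data.frame(seqnames = "chr1", position = pos0,
                                       strand = strand, gene = genes[i],
                                       stringsAsFactors = FALSE))
    }
    genome <- DNAStringSet(paste(seqChars, collapse = ""))
    names(genome) <- "chr1"
    peaks <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = peakStart + 1, width = peakWidth))
    names(peaks) <- genes
    tss <- data.frame(gene = genes, seqnames = "chr1", position = tssPos,
                      strand = "+", stringsAsFactors = FALSE)
    methods::new("ToyGenome", sequences = genome, tss = tss, peaks = peaks,
                 motifSites = sites, plantedGenes = planted, motif = motif)
  })
}
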