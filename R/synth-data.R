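# Seeded generators emulating the statistical structure of each pipeline
# input: DEG tables with planted shared/unique structure, peaks in
# promoter/distal compartments with planted motif instances, accessible-
# chromatin gene sets with planted baseline/unique partitions, bait x prey
# spectral-count tables with a planted prioritization outcome, and shRNA
# growth curves with planted deficit genes. Each generator seeds its own
# stream (derived from the user seed with a fixed per-generator offset) so
# adding one generator never perturbs another's output.

.seedFor <- function(seed, offset) {
  set.seed((as.integer(seed) %% 1000000L) * 1000L + offset)
}

.geneIdPool <- function(n, prefix = "gene") {
  sprintf("%s%05d", prefix, seq_len(n))
}

#' Toy genome with tiled gene models
#'
#' Random-sequence contigs carrying \code{nGenes} genes tiled at a fixed
#' spacing (alternating strands), leaving intergenic room on both sides
#' of every gene for distal peak placement. Byte-identical output under
#' the same seed.
#'
#' @param seed integer seed
#' @param nGenes number of genes (default 100)
#' @param chromLength contig length in bp (default 2e6, single contig
#'   "chr1")
#' @param geneLength gene body length (default 2000)
#' @param spacing gap between consecutive gene bodies (default 18000; must
#'   be at least twice the promoter window used downstream)
#' @param exons exons per gene (0 = no exon structure, the default)
#' @return list with \code{genome} (DNAStringSet) and \code{genes}
#'   (\linkS4class{GeneModels})
#' @export
makeToyGenome <- function(seed = 1, nGenes = 100, chromLength = 2.1e6,
                          geneLength = 2000, spacing = 18000, exons = 0) {
  .seedFor(seed, 11L)
  pitch <- geneLength + spacing
  need <- nGenes * pitch + spacing
  if (need > chromLength)
    stop("genes do not fit the contig: need ", need, " bp, have ", chromLength)
  seq <- paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
               collapse = "")
  genome <- DNAStringSet(stats::setNames(seq, "chr1"))
  txStart <- spacing + (seq_len(nGenes) - 1L) * pitch
  txEnd <- txStart + geneLength
  strand <- rep(c("+", "-"), length.out = nGenes)
  ids <- .geneIdPool(nGenes)
  exl <- NULL
  if (exons > 0) {
    exl <- lapply(seq_len(nGenes), function(i) {
      width <- floor(geneLength / (2 * exons))
      starts <- txStart[i] + (seq_len(exons) - 1L) * 2L * width
      cbind(starts, starts + width)
    })
    names(exl) <- ids
  }
  list(genome = genome,
       genes = geneModels(ids, rep("chr1", nGenes), strand, txStart, txEnd,
                          exons = exl))
}

#' Planted differential-expression panel designs
#'
#' Region structure (exclusive Venn counts for the focal fusion set
#' against its two full-length controls) for the four study panels, built
#' from the published query-in-reference overlap percentages: the fusion
#' set shares its stated fraction with the hyperactive TAZ/YAP control
#' and with the C-terminal partner control, with the stated fraction
#' unique to the fusion.
#'
#' @param panel one of "tc_nih3t3", "yt_nih3t3", "tc_sw872", "yt_sw872"
#' @return list with labels, focal set size, exclusive region counts and
#'   control set sizes
#' @export
degPanelDesign <- function(panel = c("tc_nih3t3", "yt_nih3t3",
                                     "tc_sw872", "yt_sw872")) {
  panel <- match.arg(panel)
  # fractions of the focal (fusion) gene set: in control A (TAZ4SA/YAP5SA),
  # in control B (CAMTA1/TFE3), unique to the fusion
  p <- switch(panel,
    tc_nih3t3 = list(labels = c("TC", "TAZ4SA", "CAMTA1"),
                     fracA = 0.70, fracB = 0.09, fracUnique = 0.29,
                     nFocal = 1000, nAExtra = 1400, nBExtra = 700),
    yt_nih3t3 = list(labels = c("YT", "YAP5SA", "TFE3"),
                     fracA = 0.78, fracB = 0.10, fracUnique = 0.20,
                     nFocal = 1000, nAExtra = 1200, nBExtra = 500),
    tc_sw872  = list(labels = c("TC", "TAZ4SA", "CAMTA1"),
                     fracA = 0.67, fracB = 0.09, fracUnique = 0.31,
                     nFocal = 1000, nAExtra = 1100, nBExtra = 700),
    yt_sw872  = list(labels = c("YT", "YAP5SA", "TFE3"),
                     fracA = 0.53, fracB = 0.002, fracUnique = 0.47,
                     nFocal = 1000, nAExtra = 1500, nBExtra = 400))
  both <- p$fracA + p$fracB - (1 - p$fracUnique)
  if (both < 0) stop("infeasible overlap design: fracA + fracB < 1 - fracUnique")
  counts <- round(p$nFocal * c(FA = p$fracA - both, FB = p$fracB - both,
                               FAB = both, Funique = p$fracUnique))
  c(p, list(regions = counts))
}

#' Simulate a differential-expression panel
#'
#' Draws gene identifiers from a population of \code{nPopulation} genes
#' (plus \code{nLowExpressed} genes below the count filter), plants the
#' panel's exclusive-region structure, and emits per-condition DEG tables
#' where planted genes have adjusted p below the FDR threshold and all
#' other population genes above it, with an optional misclassification
#' rate. The accompanying count matrix (3 samples per condition) is
#' consistent with the mean-count population rule, and planted DEGs carry
#' a condition-specific expression shift so replicate samples cluster by
#' condition.
#'
#' @param seed integer seed
#' @param design a \code{\link{degPanelDesign}} list
#' @param nPopulation population (gene universe) size (default 12000)
#' @param nLowExpressed genes below the mean-count filter (default 500)
#' @param noiseRate per-gene misclassification probability (default 0)
#' @param alpha FDR threshold the plant targets (default 0.05)
#' @return list with \code{tables} (per-condition DEG data.frames),
#'   \code{counts} (matrix with condition-labelled columns),
#'   \code{population}, \code{planted} (per-condition DEG id sets) and
#'   the design
#' @export
simulateDegPanel <- function(seed = 1, design = degPanelDesign("tc_nih3t3"),
                             nPopulation = 12000, nLowExpressed = 500,
                             noiseRate = 0, alpha = 0.05) {
  .seedFor(seed, 23L)
  pool <- .geneIdPool(nPopulation + nLowExpressed)
  popIds <- pool[seq_len(nPopulation)]
  lowIds <- setdiff(pool, popIds)
  r <- design$regions
  nab <- design$nAExtra + design$nBExtra
  if (sum(r) + nab > nPopulation)
    stop("infeasible design: ", sum(r) + nab,
         " planted genes exceed the population of ", nPopulation)
  draw <- sample(popIds, sum(r) + nab)
  cut <- function(k) {
    if (k == 0) return(character(0))
    out <- draw[seq_len(k)]
    draw <<- draw[-seq_len(k)]
    out
  }
  FA <- cut(r[["FA"]]); FB <- cut(r[["FB"]]); FAB <- cut(r[["FAB"]])
  Fu <- cut(r[["Funique"]])
  Aextra <- cut(design$nAExtra); Bextra <- cut(design$nBExtra)
  sets <- stats::setNames(list(c(FA, FB, FAB, Fu),
                               c(FA, FAB, Aextra),
                               c(FB, FAB, Bextra)), design$labels)
  if (noiseRate > 0) {
    sets <- lapply(sets, function(s) {
      drop <- stats::runif(length(s)) < noiseRate
      gain <- sample(setdiff(popIds, s), stats::rbinom(1, length(s), noiseRate))
      c(s[!drop], gain)
    })
  }
  tables <- lapply(sets, function(s) {
    isDeg <- popIds %in% s
    padj <- ifelse(isDeg, stats::runif(nPopulation, 1e-12, alpha * 0.98),
                   stats::runif(nPopulation, alpha * 1.04, 1))
    data.frame(gene_id = popIds,
               log2fc = ifelse(isDeg,
                               sample(c(-1, 1), nPopulation, TRUE) *
                                 stats::rnorm(nPopulation, 2, 0.5),
                               stats::rnorm(nPopulation, 0, 0.2)),
               pvalue = padj * stats::runif(nPopulation, 0.2, 1),
               padj = padj, stringsAsFactors = FALSE)
  })
  conditions <- c("EV", design$labels)
  baseMu <- stats::setNames(exp(stats::rnorm(length(pool), log(60), 0.6)), pool)
  baseMu[lowIds] <- stats::runif(nLowExpressed, 0.1, 2)
  counts <- matrix(0L, nrow = length(pool), ncol = 3 * length(conditions),
                   dimnames = list(pool, paste0(rep(conditions, each = 3),
                                                "_rep", 1:3)))
  for (ci in seq_along(conditions)) {
    mu <- baseMu
    cond <- conditions[ci]
    if (cond %in% names(sets))
      mu[sets[[cond]]] <- mu[sets[[cond]]] * 4      # planted expression shift
    for (rep in 1:3) {
      jitter <- exp(stats::rnorm(length(mu), 0, 0.1))
      counts[, (ci - 1) * 3 + rep] <-
        stats::rnbinom(length(mu), mu = mu * jitter, size = 20)
    }
  }
  list(tables = tables, counts = counts, population = popIds,
       planted = sets, design = design,
       conditionOfSample = rep(conditions, each = 3))
}

#' Simulate ChIP peak sets with planted geometry and motifs
#'
#' Places \code{nPeaks} peaks on the toy genome: a \code{promoterFraction}
#' of them centred within the promoter window of a random TSS, the rest
#' in distal intergenic space (anchor at least \code{distalMin} bp from
#' every TSS and outside every gene body). A consensus word for the
#' supplied motif is written into the genome sequence at the centre of a
#' \code{motifPlantRate} fraction of peaks. Optional replicate sets
#' jitter each peak's position for consensus-building tests.
#'
#' @param seed integer seed
#' @param toy output of \code{\link{makeToyGenome}}
#' @param nPeaks number of peaks (default 1000)
#' @param promoterFraction fraction placed in promoters (default 0.3)
#' @param peakWidth peak width in bp (default 200)
#' @param promoterWindow promoter half-width (default 1000)
#' @param distalMin minimum anchor distance from any TSS for distal
#'   placement (default 5000)
#' @param motif optional \linkS4class{MotifMatrix} whose consensus word is
#'   planted
#' @param motifPlantRate fraction of peaks receiving a planted site
#' @param replicates number of jittered replicate peak sets (default 0)
#' @param replicateJitter maximum absolute per-replicate shift in bp
#' @return list with \code{peaks} (GRanges, mcols \code{planted_promoter},
#'   \code{planted_motif}, \code{score}), \code{genome} (with planted
#'   sites written in), and \code{replicates} (list of GRanges)
#' @export
simulatePeaks <- function(seed = 1, toy, nPeaks = 1000, promoterFraction = 0.3,
                          peakWidth = 200, promoterWindow = 1000,
                          distalMin = 5000, motif = NULL, motifPlantRate = 0,
                          replicates = 0, replicateJitter = 0) {
  .seedFor(seed, 37L)
  g <- genes(toy$genes)
  tss0 <- .tss0(tssPositions(toy$genes))
  chromLength <- Biostrings::width(toy$genome)[1]
  nProm <- round(nPeaks * promoterFraction)
  nDist <- nPeaks - nProm
  half <- floor(peakWidth / 2)
  # promoter anchors: within +/- (promoterWindow - half margin) of a TSS so
  # the midpoint category is unambiguous
  promAnchor <- sample(tss0, nProm, replace = TRUE) +
    sample(seq(-(promoterWindow - 50), promoterWindow - 50), nProm, TRUE)
  # distal anchors: on a coarse grid (pitch wide enough that neighbouring
  # distal peaks cannot be clipped by one partner interval), keep
  # positions far from every gene
  grid <- seq(peakWidth, chromLength - peakWidth, by = 613)
  nearTss <- vapply(grid, function(x) min(abs(x - tss0)), numeric(1))
  inBody <- vapply(grid, function(x)
    any(x >= start(g) - 1L - distalMin & x < end(g) + distalMin), logical(1))
  distalPool <- grid[nearTss >= distalMin & !inBody]
  if (length(distalPool) < nDist)
    stop("not enough distal space on the toy genome for ", nDist, " peaks")
  distAnchor <- sample(distalPool, nDist)
  anchors <- c(promAnchor, distAnchor)
  planted_promoter <- rep(c(TRUE, FALSE), c(nProm, nDist))
  start0 <- pmax(0, anchors - half)
  peaks <- GRanges("chr1", IRanges(start0 + 1L, start0 + peakWidth),
                   name = sprintf("peak%04d", seq_len(nPeaks)),
                   score = round(stats::rexp(nPeaks, 1 / 30), 2),
                   planted_promoter = planted_promoter)
  genome <- toy$genome
  planted_motif <- rep(FALSE, nPeaks)
  if (!is.null(motif) && motifPlantRate > 0) {
    word <- paste(rownames(motif@probs)[apply(motif@probs, 2, which.max)],
                  collapse = "")
    chosen <- sample(nPeaks, round(nPeaks * motifPlantRate))
    planted_motif[chosen] <- TRUE
    seqChr <- as.character(genome[["chr1"]])
    for (i in chosen) {
      at <- anchors[i] - floor(nchar(word) / 2)       # 0-based insert position
      substr(seqChr, at + 1, at + nchar(word)) <- word
    }
    genome <- DNAStringSet(stats::setNames(seqChr, "chr1"))
  }
  mcols(peaks)$planted_motif <- planted_motif
  reps <- list()
  if (replicates > 0) {
    for (r in seq_len(replicates)) {
      shift <- if (replicateJitter > 0)
        sample(seq(-replicateJitter, replicateJitter), nPeaks, TRUE) else 0L
      reps[[paste0("rep", r)]] <- GenomicRanges::shift(
        GenomicRanges::granges(peaks), shift)
    }
  }
  list(peaks = peaks, genome = genome, replicates = reps)
}

#' Simulate a peak set overlapping a planted fraction of another
#'
#' For histone-mark co-occupancy tests: a fixed fraction of the input
#' peaks receive an overlapping partner interval; the remaining partner
#' peaks are placed far from all input peaks.
#'
#' @param seed integer seed
#' @param peaks GRanges to be overlapped
#' @param fraction fraction of \code{peaks} that get an overlapping
#'   partner
#' @param width partner peak width (default 400)
#' @param chromLength contig length for placing non-overlapping partners
#' @return GRanges of partner peaks
#' @export
simulateOverlappingPeaks <- function(seed = 1, peaks, fraction, width = 400,
                                     chromLength = NULL) {
  .seedFor(seed, 41L)
  n <- length(peaks)
  chosen <- sample(n, round(n * fraction))
  mid <- .mid0(peaks)
  partner0 <- mid[chosen] - floor(width / 2)          # centred on the peak
  if (is.null(chromLength)) chromLength <- max(end(peaks)) + 100000
  # spacer partners well away from every input peak
  grid <- seq(width, chromLength - width, by = 211)
  far <- vapply(grid, function(x) min(abs(x - mid)) > 5000, logical(1))
  nSpacer <- max(0, n - length(chosen))
  spacer0 <- sample(grid[far], min(nSpacer, sum(far)))
  start0 <- c(partner0, spacer0)
  GRanges(as.character(seqnames(peaks))[1],
          IRanges(pmax(1L, start0 + 1L), start0 + width))
}

#' Simulate accessible-chromatin gene sets with a planted partition
#'
#' Builds per-condition gene sets as (baseline shared by every
#' condition) + (per-condition planted unique genes), with an optional
#' noise rate under which a planted-unique gene is either leaked into one
#' control set (so it stops being unique) or dropped from the focal set.
#' Defaults follow the study's fusion panel scale: a baseline of 15779
#' genes and unique-set sizes 3147 (fusion), 656 and 1000 (full-length
#' controls) and 300 (empty vector).
#'
#' @param seed integer seed
#' @param focal focal condition label (default "TC")
#' @param controls control labels (default EV, TAZ4SA, CAMTA1)
#' @param baselineSize shared-gene count (default 15779)
#' @param uniqueSizes named per-condition unique-set sizes
#' @param noiseRate per-gene perturbation probability (default 0.02)
#' @return list with \code{geneSets}, \code{plantedBaseline},
#'   \code{plantedUnique}
#' @export
simulateAtacSets <- function(seed = 1, focal = "TC",
                             controls = c("EV", "TAZ4SA", "CAMTA1"),
                             baselineSize = 15779,
                             uniqueSizes = c(TC = 3147, TAZ4SA = 656,
                                             CAMTA1 = 1000, EV = 300),
                             noiseRate = 0.02) {
  .seedFor(seed, 53L)
  conditions <- c(focal, controls)
  missing <- setdiff(conditions, names(uniqueSizes))
  if (length(missing)) uniqueSizes[missing] <- 0
  total <- baselineSize + sum(uniqueSizes[conditions])
  pool <- .geneIdPool(total, prefix = "atacgene")
  baseline <- pool[seq_len(baselineSize)]
  rest <- setdiff(pool, baseline)
  plantedUnique <- list()
  for (cond in conditions) {
    k <- uniqueSizes[[cond]]
    plantedUnique[[cond]] <- rest[seq_len(k)]
    rest <- rest[-seq_len(k)]
  }
  geneSets <- lapply(conditions, function(cond)
    c(baseline, plantedUnique[[cond]]))
  names(geneSets) <- conditions
  if (noiseRate > 0) {
    fu <- plantedUnique[[focal]]
    flip <- stats::runif(length(fu)) < noiseRate
    for (gid in fu[flip]) {
      if (stats::runif(1) < 0.5) {
        ctrl <- sample(controls, 1)                  # leak into a control
        geneSets[[ctrl]] <- c(geneSets[[ctrl]], gid)
      } else {
        geneSets[[focal]] <- setdiff(geneSets[[focal]], gid)
      }
    }
  }
  list(geneSets = geneSets, plantedBaseline = baseline,
       plantedUnique = plantedUnique)
}

#' Simulate per-sample counts at consensus sites
#'
#' Negative-binomial counts at \code{nSites} sites for two or more sample
#' groups with a planted mean shift at a subset of sites, for
#' binding-affinity PCA checks.
#'
#' @param seed integer seed
#' @param nSites number of consensus sites (default 2000)
#' @param groups named integer vector: replicates per group
#' @param shiftSites number of sites carrying the group shift
#' @param shift multiplicative mean shift between successive groups
#' @return list with \code{counts} (sites x samples) and \code{group}
#' @export
simulateAffinityCounts <- function(seed = 1, nSites = 2000,
                                   groups = c(A = 3, B = 3),
                                   shiftSites = 400, shift = 4) {
  .seedFor(seed, 59L)
  mu <- exp(stats::rnorm(nSites, log(50), 0.5))
  shifted <- sample(nSites, shiftSites)
  group <- rep(names(groups), groups)
  counts <- sapply(seq_along(group), function(j) {
    m <- mu
    gi <- match(group[j], names(groups)) - 1
    m[shifted] <- m[shifted] * shift^gi
    stats::rnbinom(nSites, mu = m, size = 15)
  })
  colnames(counts) <- paste0(group, "_rep", unlist(lapply(groups, seq_len)))
  list(counts = counts, group = group)
}

.hippoDefault <- c("LATS1", "LATS2", "STK3", "STK4", "SAV1", "MOB1A",
                   "AMOT", "AMOTL1", "AMOTL2", "NF2", "TEAD1", "WWTR1", "YAP1")

#' Simulate BioID prey tables for the four baits
#'
#' Constructs spectral-count tables for the two fusion baits and their
#' full-length controls with planted prey categories chosen so the
#' prioritization cascade reproduces, by construction, the count chain
#' detected 68/47, minus-decreased 55/34, minus-Hippo 49/31,
#' increased-only 47/28, intersection 27 and, after removing weak
#' interactions, a final shared list of 18. Additional preys violating
#' the detection filters (low counts or low protein probability) are
#' included to exercise the dotplot filters.
#'
#' @param seed integer seed
#' @param sharedStrong identifiers of the planted final shared preys
#'   (default: 18 chromatin/transcription regulators)
#' @param nSharedWeak shared increased preys in the weak bins (default 9)
#' @param nTcOnly,nYtOnly fusion-specific increased preys (defaults 20, 1)
#' @param nUnchangedTc,nUnchangedYt unchanged preys per fusion (2, 3)
#' @param nDecreased decreased preys per fusion (default 13)
#' @param hippoTc,hippoYt Hippo-component preys per fusion (6 and 3 names)
#' @param nFilteredOut preys that fail the detection filters (default 20)
#' @return list with \code{preyTables} (named list TC, YT, TAZ, YAP of
#'   parsed prey data.frames), \code{hippo}, \code{planted} (category
#'   membership) and \code{categoryMap} (prey -> functional class for the
#'   YT interactome)
#' @export
simulateBioid <- function(seed = 1,
                          sharedStrong = c("YEATS2", "ZZZ3", "EP400", "KAT14",
                                           "NCOA2", "TCF20", "KAT2A", "TADA3",
                                           "DR1", "MED1", "SMARCC1", "CHD7",
                                           "BRD8", "EPC1", "KDM3B", "TRRAP",
                                           "ZNF592", "ZMYND8"),
                          nSharedWeak = 9, nTcOnly = 20, nYtOnly = 1,
                          nUnchangedTc = 2, nUnchangedYt = 3, nDecreased = 13,
                          hippoTc = .hippoDefault[1:6],
                          hippoYt = .hippoDefault[c(1, 2, 5)],
                          nFilteredOut = 20) {
  .seedFor(seed, 67L)
  syn <- function(prefix, n) if (n > 0) sprintf("%s%02d", prefix, seq_len(n))
    else character(0)
  sharedWeak <- syn("WEAKPREY", nSharedWeak)
  tcOnly <- syn("TCPREY", nTcOnly)
  ytOnly <- syn("YTPREY", nYtOnly)
  unchangedTc <- syn("EQTCPREY", nUnchangedTc)
  unchangedYt <- syn("EQYTPREY", nUnchangedYt)
  decreasedTc <- syn("CRUMBSTC", nDecreased)
  decreasedYt <- syn("CRUMBSYT", nDecreased)
  failed <- syn("BGPREY", nFilteredOut)

  strongRow <- function(bait, prey) {
    c1 <- stats::rnbinom(1, mu = 45, size = 10) + 15
    c2 <- stats::rnbinom(1, mu = 45, size = 10) + 15
    data.frame(bait = bait, prey = prey, count_r1 = c1, count_r2 = c2,
               max_count = max(c1, c2), avg_count = (c1 + c2) / 2,
               relative_abundance = stats::runif(1, 0.3, 1),
               probability = stats::runif(1, 0.97, 1),
               bfdr = stats::runif(1, 0, 0.009), stringsAsFactors = FALSE)
  }
  weakRow <- function(bait, prey) {
    c1 <- 10L; c2 <- sample(0:5, 1)
    data.frame(bait = bait, prey = prey, count_r1 = c1, count_r2 = c2,
               max_count = max(c1, c2), avg_count = (c1 + c2) / 2,
               relative_abundance = stats::runif(1, 0.01, 0.08),
               probability = stats::runif(1, 0.95, 1),
               bfdr = stats::runif(1, 0.06, 0.3), stringsAsFactors = FALSE)
  }
  midRow <- function(bait, prey, mu = 25) {
    c1 <- stats::rnbinom(1, mu = mu, size = 10) + 12
    c2 <- stats::rnbinom(1, mu = mu, size = 10) + 12
    data.frame(bait = bait, prey = prey, count_r1 = c1, count_r2 = c2,
               max_count = max(c1, c2), avg_count = (c1 + c2) / 2,
               relative_abundance = stats::runif(1, 0.15, 0.8),
               probability = stats::runif(1, 0.96, 1),
               bfdr = stats::runif(1, 0, 0.04), stringsAsFactors = FALSE)
  }
  fixedRow <- function(bait, prey, c1, c2) {
    data.frame(bait = bait, prey = prey, count_r1 = c1, count_r2 = c2,
               max_count = max(c1, c2), avg_count = (c1 + c2) / 2,
               relative_abundance = stats::runif(1, 0.1, 0.6),
               probability = stats::runif(1, 0.96, 1),
               bfdr = stats::runif(1, 0, 0.04), stringsAsFactors = FALSE)
  }
  failedRow <- function(bait, prey) {
    if (stats::runif(1) < 0.5)
      fr <- data.frame(bait = bait, prey = prey, count_r1 = sample(0:9, 1),
                       count_r2 = sample(0:9, 1), relative_abundance = 0.05,
                       probability = stats::runif(1, 0.95, 1),
                       bfdr = stats::runif(1, 0, 0.5))
    else
      fr <- data.frame(bait = bait, prey = prey, count_r1 = 30L,
                       count_r2 = 25L, relative_abundance = 0.2,
                       probability = stats::runif(1, 0.5, 0.94),
                       bfdr = stats::runif(1, 0, 0.5))
    fr$max_count <- max(fr$count_r1, fr$count_r2)
    fr$avg_count <- (fr$count_r1 + fr$count_r2) / 2
    fr[c("bait", "prey", "count_r1", "count_r2", "max_count", "avg_count",
         "relative_abundance", "probability", "bfdr")]
  }

  buildFusion <- function(bait, hippo, unchanged, decreased, only) {
    rows <- list()
    for (p in sharedStrong) rows[[length(rows) + 1]] <- strongRow(bait, p)
    for (p in sharedWeak) rows[[length(rows) + 1]] <- weakRow(bait, p)
    for (p in only) rows[[length(rows) + 1]] <- midRow(bait, p)
    for (p in hippo) rows[[length(rows) + 1]] <- midRow(bait, p)
    for (p in unchanged) rows[[length(rows) + 1]] <- fixedRow(bait, p, 20L, 20L)
    for (p in decreased) rows[[length(rows) + 1]] <- fixedRow(bait, p, 12L, 14L)
    for (p in failed) rows[[length(rows) + 1]] <- failedRow(bait, p)
    do.call(rbind, rows)
  }
  buildFull <- function(bait, unchanged, decreased) {
    rows <- list()
    # full-length baits see the decreased preys strongly and the unchanged
    # preys at the fusion level; strong/weak shared preys are absent (or
    # would be lower), making them "increased" for the fusions
    for (p in decreased) rows[[length(rows) + 1]] <- fixedRow(bait, p, 40L, 44L)
    for (p in unchanged) rows[[length(rows) + 1]] <- fixedRow(bait, p, 20L, 20L)
    for (p in failed) rows[[length(rows) + 1]] <- failedRow(bait, p)
    do.call(rbind, rows)
  }
  tables <- list(
    TC = buildFusion("TC", hippoTc, unchangedTc, decreasedTc, tcOnly),
    YT = buildFusion("YT", hippoYt, unchangedYt, decreasedYt, ytOnly),
    TAZ = buildFull("TAZ", unchangedTc, decreasedTc),
    YAP = buildFull("YAP", unchangedYt, decreasedYt))

  # functional classes over the YT post-subtraction interactome (n = 34):
  # 12/9/6/5/2 -> the rounded 35/26/18/15/6 percentage split
  ytInteractome <- c(sharedStrong, sharedWeak, ytOnly, unchangedYt, hippoYt)
  classes <- rep(c("histone modifying", "transcriptional regulation",
                   "chromatin remodeling", "transcription factor/co-activator",
                   "other"), c(12, 9, 6, 5, length(ytInteractome) - 32))
  categoryMap <- stats::setNames(classes, ytInteractome)
  list(preyTables = tables,
       hippo = union(hippoTc, hippoYt),
       planted = list(sharedStrong = sharedStrong, sharedWeak = sharedWeak,
                      tcOnly = tcOnly, ytOnly = ytOnly,
                      decreasedTc = decreasedTc, decreasedYt = decreasedYt,
                      unchangedTc = unchangedTc, unchangedYt = unchangedYt,
                      filteredOut = failed),
       categoryMap = categoryMap)
}

#' Simulate an shRNA proliferation screen
#'
#' Log-normal multiplicative growth curves (readings every other day from
#' day 0 to the endpoint) for two control constructs and five shRNAs per
#' screened gene. Effective shRNAs grow at \code{effectRatio} times the
#' control day-endpoint fold change. Defaults plant the study outcome:
#' the 18 prioritized genes with three 5/5-effective hits (YEATS2, ZZZ3,
#' EP400) and two partial hits (NCOA2, TCF20 at 3/5).
#'
#' @param seed integer seed
#' @param genes screened gene identifiers
#' @param effectiveShrnas named integer vector: number of effective
#'   shRNAs (of \code{nShrnas}) per gene; genes absent default to 0
#' @param nShrnas shRNAs per gene (default 5)
#' @param nReps biological replicates per construct (default 3)
#' @param endpointDay assay endpoint (default 10)
#' @param controlFoldChange planted control day-endpoint fold change
#'   (default 5)
#' @param effectRatio fold-change ratio of an effective shRNA vs control
#'   (default 0.4)
#' @param sigma log-scale measurement noise sd (default 0.08)
#' @return list with \code{growth} (long data.frame) and \code{planted}
#'   (the effective-shRNA design)
#' @export
simulateScreen <- function(seed = 1,
                           genes = c("YEATS2", "ZZZ3", "EP400", "KAT14",
                                     "NCOA2", "TCF20", "KAT2A", "TADA3",
                                     "DR1", "MED1", "SMARCC1", "CHD7",
                                     "BRD8", "EPC1", "KDM3B", "TRRAP",
                                     "ZNF592", "ZMYND8"),
                           effectiveShrnas = c(YEATS2 = 5, ZZZ3 = 5,
                                               EP400 = 5, NCOA2 = 3,
                                               TCF20 = 3),
                           nShrnas = 5, nReps = 3, endpointDay = 10,
                           controlFoldChange = 5, effectRatio = 0.4,
                           sigma = 0.08) {
  .seedFor(seed, 71L)
  days <- seq(0, endpointDay, by = 2)
  rate <- log(controlFoldChange) / endpointDay
  rateEff <- log(controlFoldChange * effectRatio) / endpointDay
  rows <- list()
  emit <- function(construct, gene, r) {
    for (rep in seq_len(nReps)) {
      a0 <- 0.2 * exp(stats::rnorm(1, 0, sigma))
      ab <- a0 * exp(r * days) * exp(stats::rnorm(length(days), 0, sigma))
      rows[[length(rows) + 1]] <<- data.frame(
        cell_line = "SW872_TC", construct = construct, gene = gene,
        replicate = paste0("r", rep), day = days, absorbance = ab,
        stringsAsFactors = FALSE)
    }
  }
  emit("shEV", "control", rate)
  emit("shNT", "control", rate)
  design <- list()
  for (g in genes) {
    nEff <- if (g %in% names(effectiveShrnas)) effectiveShrnas[[g]] else 0
    eff <- seq_len(nShrnas) <= nEff
    design[[g]] <- eff
    for (i in seq_len(nShrnas))
      emit(sprintf("sh%s#%d", g, i), g, if (eff[i]) rateEff else rate)
  }
  list(growth = do.call(rbind, rows), planted = design)
}

#' Simulate knockdown DEG sets nested in unique open chromatin
#'
#' Draws a DEG identifier set with a planted fraction inside a supplied
#' unique-open-chromatin gene set, emulating the knockdown-transcriptome
#' by accessibility intersection.
#'
#' @param seed integer seed
#' @param openUnique character vector of unique-open genes
#' @param otherGenes character vector of genes outside the open set
#' @param nDegs DEG set size (default 500)
#' @param fracInOpen planted fraction inside \code{openUnique}
#' @return character vector of DEG identifiers
#' @export
simulateKnockdownDegs <- function(seed = 1, openUnique, otherGenes,
                                  nDegs = 500, fracInOpen = 0.71) {
  .seedFor(seed, 79L)
  nIn <- round(nDegs * fracInOpen)
  if (nIn > length(openUnique)) stop("open-unique set smaller than planted overlap")
  if (nDegs - nIn > length(otherGenes)) stop("not enough genes outside the open set")
  c(sample(openUnique, nIn), sample(otherGenes, nDegs - nIn))
}
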