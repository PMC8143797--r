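.pipelineDefaults <- function() {
  list(seed = 1,
       outDir = NULL,
       alpha = 0.05,
       minMeanCount = 5,
       promoterWindow = 1000,
       window = 3000,
       bins = 100,
       motifPThreshold = 1e-4,
       minOverlapSamples = 2,
       tailMode = "inclusive",
       endpointDay = 10,
       screenAlpha = 0.05,
       stages = c("rna", "chip", "atac", "bioid", "screen", "integration"))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks every parameter's documented range and
#' aggregates all violations into a single error (rather than failing at
#' the first). Unknown keys are an error listing them.
#'
#' @param config named list of overrides (may be empty)
#' @return the normalized configuration list
#' @export
validateConfig <- function(config = list()) {
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  errs <- character()
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$screenAlpha > 0 && cfg$screenAlpha < 1, "screenAlpha must lie in (0, 1)")
  chk(cfg$minMeanCount >= 0, "minMeanCount must be >= 0")
  chk(cfg$promoterWindow > 0, "promoterWindow must be positive")
  chk(cfg$window > 0 && cfg$bins > 0 && (2 * cfg$window) %% cfg$bins == 0,
      "2*window must be a positive multiple of bins")
  chk(cfg$motifPThreshold > 0 && cfg$motifPThreshold < 1,
      "motifPThreshold must lie in (0, 1)")
  chk(cfg$minOverlapSamples >= 1, "minOverlapSamples must be >= 1")
  chk(cfg$tailMode %in% c("inclusive", "exclusive"),
      "tailMode must be 'inclusive' or 'exclusive'")
  chk(all(cfg$stages %in% .pipelineDefaults()$stages), "unknown stage name")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  cfg
}

# TEAD-family consensus used by the synthetic ChIP stage
.teadMotif <- function() {
  counts <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  word <- c("G", "G", "A", "A", "T", "G", "T", "G")   # MCAT-like consensus
  for (j in seq_along(word)) {
    counts[, j] <- 1
    counts[word[j], j] <- 17
  }
  motifMatrix(counts, name = "TEAD", pseudocount = 0.1)
}

#' Run the integrative pipeline on synthetic inputs
#'
#' Executes the analysis stages in dependency order on generator output
#' seeded from \code{config$seed}: differential-expression gene sets and
#' overlap statistics for the four fusion/control panels; ChIP peak
#' annotation, TSS geometry, histone-mark co-occupancy and motif
#' proportions; accessible-chromatin baseline/unique partitions,
#' consensus peaks and affinity PCA; the BioID prioritization cascade;
#' screen ranking; and the cross-modality integration fractions. Returns
#' a structured report; when \code{config$outDir} is set, per-stage TSVs
#' and a \code{report.json} are written there.
#'
#' @param config list accepted by \code{\link{validateConfig}}
#' @return nested report list with a provenance block
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  report <- list(provenance = list(
    package = "fusionomics",
    version = as.character(utils::packageVersion("fusionomics")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outDir")]))
  seed <- cfg$seed

  if ("rna" %in% cfg$stages) {
    rna <- list()
    for (panel in c("tc_nih3t3", "yt_nih3t3", "tc_sw872", "yt_sw872")) {
      sim <- simulateDegPanel(seed, degPanelDesign(panel))
      degSets <- lapply(sim$tables, filterDegs, alpha = cfg$alpha)
      population <- definePopulation(sim$counts, cfg$minMeanCount)
      focal <- names(degSets)[1]
      rep <- overlapReport(degSets[[focal]], degSets[-1], length(population),
                           mode = cfg$tailMode, queryLabel = focal)
      venn <- vennPartition(degSets)
      uniquePct <- 100 * venn$regions[[focal]] / length(degSets[[focal]])
      rna[[panel]] <- list(overlap = rep, venn = venn$regions,
                           nPopulation = length(population),
                           uniquePct = uniquePct)
    }
    # PCA on one panel's transformed counts
    sim <- simulateDegPanel(seed, degPanelDesign("tc_nih3t3"))
    vst <- vstLikeTransform(sim$counts)
    keep <- order(-apply(vst$transformed, 1, stats::var))[1:2000]
    pca <- pcaCoordinates(vst$transformed[keep, ], 2)
    rna$pca <- list(varianceFraction = pca$varianceFraction,
                    condition = sim$conditionOfSample)
    report$rna <- rna
  }

  if ("chip" %in% cfg$stages) {
    toy <- makeToyGenome(seed)
    tead <- .teadMotif()
    plantRates <- c(TC = 0.61, TAZ4SA = 0.58, YT = 0.38, YAP5SA = 0.51)
    chip <- list(motifProportion = numeric(0))
    annotated <- list()
    for (i in seq_along(plantRates)) {
      cond <- names(plantRates)[i]
      sim <- simulatePeaks(seed + i, toy, nPeaks = 400, promoterFraction = 0.3,
                           motif = tead, motifPlantRate = plantRates[[cond]])
      ann <- annotatePeaks(sim$peaks, toy$genes,
                           promoterWindow = cfg$promoterWindow)
      annotated[[cond]] <- ann
      if (cond == "TC") {
        chip$categoryDistribution <- categoryDistribution(ann)
        prof <- tssProfile(sim$peaks, toy$genes, cfg$window, cfg$bins)
        chip$tssProfileMass <- sum(prof$matrix)
        # histone-mark co-occupancy at distal fusion peaks
        distal <- sim$peaks[ann$category == "DistalIntergenic"]
        h3k27ac <- simulateOverlappingPeaks(seed + 10, distal, 0.69,
                                            chromLength =
                                              Biostrings::width(toy$genome)[1])
        chip$h3k27acDistalOverlapPct <-
          peakSetOverlapFraction(distal, h3k27ac)
      }
      if (cond == "YT") {
        distal <- sim$peaks[ann$category == "DistalIntergenic"]
        h3k27ac <- simulateOverlappingPeaks(seed + 11, distal, 0.68,
                                            chromLength =
                                              Biostrings::width(toy$genome)[1])
        chip$h3k27acDistalOverlapPctYT <-
          peakSetOverlapFraction(distal, h3k27ac)
      }
      chip$motifProportion[cond] <-
        peakMotifProportion(sim$peaks, sim$genome, tead,
                            cfg$motifPThreshold)$percent
    }
    chip$boundGenes <- lapply(annotated, function(a) assignPeaksToGenes(a))
    report$chip <- chip
  }

  if ("atac" %in% cfg$stages) {
    atac <- list()
    tcSets <- simulateAtacSets(seed, focal = "TC",
                               controls = c("EV", "TAZ4SA", "CAMTA1"))
    tcPart <- accessibilityPartition(tcSets$geneSets, "TC",
                                     c("EV", "TAZ4SA", "CAMTA1"))
    ytSets <- simulateAtacSets(seed + 1, focal = "YT",
                               controls = c("EV", "YAP5SA", "TFE3"),
                               baselineSize = 16809,
                               uniqueSizes = c(YT = 2499, YAP5SA = 1629,
                                               TFE3 = 1200, EV = 300))
    ytPart <- accessibilityPartition(ytSets$geneSets, "YT",
                                     c("EV", "YAP5SA", "TFE3"))
    atac$tc <- list(baselineSize = length(tcPart$baseline),
                    uniqueSize = length(tcPart$unique$TC),
                    overlap = tcPart$overlap)
    atac$yt <- list(baselineSize = length(ytPart$baseline),
                    uniqueSize = length(ytPart$unique$YT),
                    overlap = ytPart$overlap)
    atac$ytUniqueGenes <- ytPart$unique$YT
    atac$ytAllGenes <- unique(unlist(ytSets$geneSets, use.names = FALSE))
    # consensus + affinity PCA on simulated replicate counts
    toy <- makeToyGenome(seed)
    sim <- simulatePeaks(seed + 20, toy, nPeaks = 300, replicates = 3,
                         replicateJitter = 30)
    cons <- buildConsensus(sim$replicates, cfg$minOverlapSamples)
    aff <- simulateAffinityCounts(seed, nSites = 1000)
    pca <- pcaCoordinates(affinityMatrix(aff$counts), 2)
    atac$consensusSize <- length(consensusPeaks(cons))
    atac$affinityPca <- list(varianceFraction = pca$varianceFraction,
                             group = aff$group)
    report$atac <- atac
  }

  if ("bioid" %in% cfg$stages) {
    bio <- simulateBioid(seed)
    dots <- lapply(bio$preyTables, buildDotplot)
    cascade <- cascadeFilter(dots$TC, dots$YT, dots$TAZ, dots$YAP,
                             hippoGenes = bio$hippo)
    composition <- compositionSummary(
      dots$YT$prey[!dots$YT$prey %in% bio$planted$decreasedYt],
      bio$categoryMap)
    report$bioid <- list(cascade = cascade,
                         steps = cascadeSteps(cascade),
                         final = cascadeFinal(cascade),
                         composition = composition)
  }

  if ("screen" %in% cfg$stages) {
    scr <- simulateScreen(seed, endpointDay = cfg$endpointDay)
    res <- screenScore(scr$growth, endpointDay = cfg$endpointDay,
                       alpha = cfg$screenAlpha)
    report$screen <- list(ranking = res$perGene,
                          perShrna = res$perShrna,
                          fullHits = res$perGene$gene[res$perGene$n_deficit == 5])
  }

  if ("integration" %in% cfg$stages) {
    integ <- list()
    # fraction of fusion DEGs directly bound (planted 13% TC / 15% YT)
    for (cond in c("TC", "YT")) {
      frac <- if (cond == "TC") 0.13 else 0.15
      sim <- simulateDegPanel(seed, degPanelDesign(
        if (cond == "TC") "tc_sw872" else "yt_sw872"))
      degs <- filterDegs(sim$tables[[cond]], cfg$alpha)
      .seedFor(seed, 83L + (cond == "YT"))
      boundGenes <- sample(degs, round(length(degs) * frac))
      scores <- stats::setNames(stats::rexp(length(boundGenes), 1 / 50),
                                boundGenes)
      tab <- buildIntegrationTable(
        sim$tables[[cond]][sim$tables[[cond]]$gene_id %in% degs, ], scores)
      integ[[paste0("pctDegsBound", cond)]] <- fractionDegsBound(tab)
    }
    # knockdown DEGs nested in fusion-unique open chromatin (71% / 74%)
    if (!is.null(report$atac)) {
      openU <- report$atac$ytUniqueGenes
      others <- setdiff(report$atac$ytAllGenes, openU)
      kdFracs <- c(shYEATS2 = 0.71, shZZZ3 = 0.74)
      for (nm in names(kdFracs)) {
        degs <- simulateKnockdownDegs(seed + match(nm, names(kdFracs)),
                                      openU, others, fracInOpen = kdFracs[[nm]])
        integ[[paste0("pctDegsInOpen_", nm)]] <-
          fractionDegsInOpen(degs, openU)
      }
    }
    report$integration <- integ
  }

  if (!is.null(cfg$outDir)) .writePipelineReport(report, cfg$outDir)
  report
}

.writePipelineReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$rna))
    for (panel in intersect(names(report$rna),
                            c("tc_nih3t3", "yt_nih3t3", "tc_sw872", "yt_sw872")))
      writeReport(report$rna[[panel]]$overlap,
                  file.path(outDir, paste0("overlap_", panel, ".tsv")))
  if (!is.null(report$bioid))
    writeReport(report$bioid$steps, file.path(outDir, "cascade_steps.tsv"))
  if (!is.null(report$screen))
    writeReport(report$screen$ranking, file.path(outDir, "screen_ranking.tsv"))
  summary <- reportSummary(report)
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Flatten a pipeline report to its headline numbers
#'
#' The scalar quantities a run produces: per-panel overlap percentages
#' and HGD values, unique fractions, geometry and motif proportions,
#' partition sizes, cascade counts, screen hits and integration
#' fractions.
#'
#' @param report output of \code{\link{runPipeline}}
#' @return named list of scalars
#' @export
reportSummary <- function(report) {
  out <- list(seed = report$provenance$seed)
  if (!is.null(report$rna)) {
    for (panel in intersect(names(report$rna),
                            c("tc_nih3t3", "yt_nih3t3", "tc_sw872", "yt_sw872"))) {
      ov <- report$rna[[panel]]$overlap
      for (i in seq_len(nrow(ov))) {
        key <- paste0("pct_", panel, "_in_", ov$reference[i])
        out[[key]] <- ov$pct_of_query[i]
        out[[paste0("hgd_", panel, "_vs_", ov$reference[i])]] <- ov$hgd[i]
      }
      out[[paste0("pct_unique_", panel)]] <- report$rna[[panel]]$uniquePct
    }
  }
  if (!is.null(report$chip)) {
    for (cond in names(report$chip$motifProportion))
      out[[paste0("pct_motif_", cond)]] <- report$chip$motifProportion[[cond]]
    out$pct_h3k27ac_distal_TC <- report$chip$h3k27acDistalOverlapPct
    out$pct_h3k27ac_distal_YT <- report$chip$h3k27acDistalOverlapPctYT
    cd <- report$chip$categoryDistribution$distanceBinFraction
    out$frac_distal_TC <- unname(cd[[">=3kb"]])
  }
  if (!is.null(report$atac)) {
    out$atac_baseline_tc <- report$atac$tc$baselineSize
    out$atac_unique_tc <- report$atac$tc$uniqueSize
    out$atac_baseline_yt <- report$atac$yt$baselineSize
    out$atac_unique_yt <- report$atac$yt$uniqueSize
  }
  if (!is.null(report$bioid)) {
    st <- report$bioid$steps
    for (i in seq_len(nrow(st)))
      out[[paste0("cascade_", gsub("[^a-z]+", "_", tolower(st$step[i])),
                  "_", tolower(st$bait[i]))]] <- st$n[i]
    out$cascade_final <- length(report$bioid$final)
  }
  if (!is.null(report$screen)) {
    out$screen_n_full_hits <- length(report$screen$fullHits)
    out$screen_top_gene_deficits <- report$screen$ranking$n_deficit[1]
  }
  if (!is.null(report$integration))
    for (nm in names(report$integration)) out[[nm]] <- report$integration[[nm]]
  out
}
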