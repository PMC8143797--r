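#' @importFrom IRanges findOverlaps
NULL

.peakCategories <- c("Promoter<=1kb", "Promoter1-3kb", "Exon", "Intron",
                     "GeneBody", "Downstream<=3kb", "DistalIntergenic")

# 0-based positions used for all distance arithmetic
.mid0 <- function(gr) floor((start(gr) - 1 + end(gr)) / 2)
.tss0 <- function(tss) start(tss) - 1L

#' Annotate peaks to their nearest TSS and feature category
#'
#' Each peak is assigned the gene whose TSS is nearest to the peak anchor
#' (midpoint by default; ties broken by lexicographically smaller
#' gene_id), a signed strand-aware TSS distance (negative = upstream of
#' the TSS on the gene's strand), and exactly one category by precedence:
#' Promoter<=1kb, then Promoter 1-3 kb, then Exon/Intron (GeneBody when
#' the models carry no exon structure), then Downstream<=3kb (within
#' \code{downstreamWindow} past the gene 3' end), else DistalIntergenic.
#' The promoter windows are symmetric around the TSS. Peaks on
#' chromosomes absent from the annotation are DistalIntergenic with an NA
#' gene and are excluded from gene-set assignment.
#'
#' @param peaks GRanges of peak calls
#' @param gm a \linkS4class{GeneModels}
#' @param promoterWindow bp bound of the proximal promoter (default 1000)
#' @param proximalWindow bp bound of the 1-3 kb promoter bin (default 3000)
#' @param downstreamWindow bp past the gene 3' end still called
#'   Downstream (default 3000)
#' @param anchor "midpoint" (default) or "nearest-edge": the peak point
#'   whose distance to the TSS is measured
#' @return the input GRanges with mcols \code{nearest_gene},
#'   \code{tss_distance}, \code{category}
#' @export
annotatePeaks <- function(peaks, gm, promoterWindow = 1000,
                          proximalWindow = 3000, downstreamWindow = 3000,
                          anchor = c("midpoint", "nearest-edge")) {
  anchor <- match.arg(anchor)
  if (length(gm) == 0L) stop("gene model list is empty")
  g <- genes(gm)
  tss <- tssPositions(gm)
  hasExons <- length(exonsBy(gm)) > 0L
  n <- length(peaks)
  nearestGene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  category <- rep("DistalIntergenic", n)
  if (n == 0L) {
    mcols(peaks)$nearest_gene <- character(0)
    mcols(peaks)$tss_distance <- numeric(0)
    mcols(peaks)$category <- factor(character(0), levels = .peakCategories)
    return(peaks)
  }
  gOrd <- order(g$gene_id)         # tie-break: first hit = smaller gene_id
  g <- g[gOrd]; tss <- tss[gOrd]
  pChrom <- as.character(seqnames(peaks))
  gChrom <- as.character(seqnames(g))
  mid0 <- .mid0(peaks)
  pStart0 <- start(peaks) - 1L
  pEnd0 <- end(peaks)
  tss0 <- .tss0(tss)
  gStrand <- as.character(strand(g))
  gStart0 <- start(g) - 1L
  gEnd0 <- end(g)
  for (chr in unique(pChrom)) {
    pi <- which(pChrom == chr)
    gi <- which(gChrom == chr)
    if (!length(gi)) next                      # stays DistalIntergenic, NA gene
    anchorPos <- if (anchor == "midpoint") mid0[pi] else NA
    for (jj in seq_along(pi)) {
      p <- pi[jj]
      if (anchor == "midpoint") {
        a <- mid0[p]
        dAbs <- abs(a - tss0[gi])
      } else {
        # nearest peak edge to each TSS; 0 when the TSS falls inside the peak
        dAbs <- pmax(0, pmax(pStart0[p] - tss0[gi], tss0[gi] - (pEnd0[p] - 1L)))
        a <- NA
      }
      b <- gi[which.min(dAbs)]
      nearestGene[p] <- g$gene_id[b]
      if (anchor == "midpoint") {
        dRaw <- a - tss0[b]
      } else {
        edge <- if (tss0[b] < pStart0[p]) pStart0[p]
                else if (tss0[b] > pEnd0[p] - 1L) pEnd0[p] - 1L
                else tss0[b]
        dRaw <- edge - tss0[b]
        a <- edge
      }
      d <- if (gStrand[b] == "+") dRaw else -dRaw
      dist[p] <- d
      category[p] <- .categorize(a, d, b, gStart0, gEnd0, gStrand,
                                 g$gene_id, exonsBy(gm), hasExons,
                                 promoterWindow, proximalWindow,
                                 downstreamWindow)
    }
  }
  mcols(peaks)$nearest_gene <- nearestGene
  mcols(peaks)$tss_distance <- dist
  mcols(peaks)$category <- factor(category, levels = .peakCategories)
  peaks
}

.categorize <- function(anchor0, d, b, gStart0, gEnd0, gStrand, gids, exl,
                        hasExons, promoterWindow, proximalWindow,
                        downstreamWindow) {
  if (abs(d) <= promoterWindow) return("Promoter<=1kb")
  if (abs(d) <= proximalWindow) return("Promoter1-3kb")
  inBody <- anchor0 >= gStart0[b] && anchor0 < gEnd0[b]
  if (inBody) {
    if (!hasExons) return("GeneBody")
    ex <- exl[[gids[b]]]
    if (is.null(ex)) return("GeneBody")
    inExon <- any(anchor0 >= start(ex) - 1L & anchor0 < end(ex))
    return(if (inExon) "Exon" else "Intron")
  }
  threeEnd0 <- if (gStrand[b] == "+") gEnd0[b] - 1L else gStart0[b]
  dDown <- if (gStrand[b] == "+") anchor0 - threeEnd0 else threeEnd0 - anchor0
  if (dDown > 0 && dDown <= downstreamWindow) return("Downstream<=3kb")
  "DistalIntergenic"
}

#' Category and TSS-distance-bin distribution of annotated peaks
#'
#' Fractions per feature category (summing to 1) and per absolute TSS
#' distance bin 0-1 kb / 1-3 kb / >= 3 kb.
#'
#' @param annotated GRanges from \code{\link{annotatePeaks}}
#' @return list with \code{categoryFraction} and \code{distanceBinFraction}
#' @export
categoryDistribution <- function(annotated) {
  if (length(annotated) == 0L) stop("no annotated peaks")
  catTab <- table(annotated$category)
  d <- abs(annotated$tss_distance)
  d[is.na(d)] <- Inf                            # unannotatable peaks are distal
  bins <- cut(d, breaks = c(-1, 1000, 3000, Inf),
              labels = c("0-1kb", "1-3kb", ">=3kb"))
  list(categoryFraction = stats::setNames(as.numeric(catTab) / length(annotated),
                                          names(catTab)),
       distanceBinFraction = stats::setNames(
         as.numeric(table(bins)) / length(annotated), levels(bins)))
}

#' Binned peak occupancy around TSSs
#'
#' For every gene, the window \code{[-window, +window)} around the TSS is
#' tiled into \code{bins} equal bins oriented 5' to 3' on the gene strand
#' (an upstream peak of a minus-strand gene therefore appears on the
#' negative-x side after the flip). Each entry is the number of peak base
#' pairs overlapping the bin; the mean profile is the column mean.
#'
#' @param peaks GRanges
#' @param gm a \linkS4class{GeneModels}
#' @param window half-width in bp (default 3000)
#' @param bins number of bins tiling \code{2 * window} (must divide it)
#' @return list with \code{matrix} (genes x bins) and \code{meanProfile}
#' @export
tssProfile <- function(peaks, gm, window = 3000, bins = 100) {
  if ((2 * window) %% bins != 0) stop("2*window must be divisible by bins")
  binW <- 2 * window / bins
  tss <- tssPositions(gm)
  tss0 <- .tss0(tss)
  tStrand <- as.character(strand(tss))
  tChrom <- as.character(seqnames(tss))
  pChrom <- as.character(seqnames(peaks))
  pStart0 <- start(peaks) - 1L
  pEnd0 <- end(peaks)
  mat <- matrix(0, nrow = length(tss), ncol = bins,
                dimnames = list(names(tss), NULL))
  binEdges <- seq(-window, window, by = binW)   # gene-oriented bin edges
  for (i in seq_along(tss)) {
    pi <- which(pChrom == tChrom[i] & pEnd0 > tss0[i] - window &
                  pStart0 < tss0[i] + window)
    if (!length(pi)) next
    for (p in pi) {
      # peak in TSS-relative genomic coordinates
      rel <- c(pStart0[p], pEnd0[p]) - tss0[i]
      if (tStrand[i] == "-") rel <- sort(-rel)  # orient 5'->3'
      lo <- pmax(rel[1], binEdges[-length(binEdges)])
      hi <- pmin(rel[2], binEdges[-1])
      mat[i, ] <- mat[i, ] + pmax(0, hi - lo)
    }
  }
  list(matrix = mat, meanProfile = colMeans(mat),
       binCenters = binEdges[-1] - binW / 2)
}

#' Percentage of peaks in one set overlapping another
#'
#' \code{100 *} (number of peaks in A intersecting at least one peak in B
#' by at least \code{minOverlap} bp) \code{/ |A|}.
#'
#' @param peaksA,peaksB GRanges
#' @param minOverlap minimum overlap in bp (default 1)
#' @return percentage in [0, 100]
#' @export
peakSetOverlapFraction <- function(peaksA, peaksB, minOverlap = 1) {
  if (length(peaksA) == 0L) stop("peak set A is empty")
  hit <- GenomicRanges::countOverlaps(peaksA, peaksB,
                                      minoverlap = minOverlap) > 0
  100 * mean(hit)
}

#' Collapse annotated peaks to a gene set
#'
#' De-duplicated nearest-gene identifiers (peaks without an assigned gene
#' are dropped), with the per-gene peak count and the per-gene maximum
#' peak score retained for cross-modality integration.
#'
#' @param annotated GRanges from \code{\link{annotatePeaks}}
#' @return list with \code{genes} (character), \code{table} (data.frame
#'   gene_id, n_peaks, max_score)
#' @export
assignPeaksToGenes <- function(annotated) {
  keep <- !is.na(annotated$nearest_gene)
  ann <- annotated[keep]
  if (length(ann) == 0L)
    return(list(genes = character(0),
                table = data.frame(gene_id = character(0), n_peaks = integer(0),
                                   max_score = numeric(0))))
  score <- if (!is.null(ann$score)) ann$score else rep(0, length(ann))
  spl <- split(score, ann$nearest_gene)
  tab <- data.frame(gene_id = names(spl),
                    n_peaks = lengths(spl),
                    max_score = vapply(spl, max, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(genes = tab$gene_id, table = tab)
}
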