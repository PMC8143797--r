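#' Build a consensus peak set across replicate samples
#'
#' Union-merges all per-sample intervals, then keeps each merged interval
#' when it overlaps (>= 1 bp) a peak in at least \code{minOverlapSamples}
#' samples. The peak x sample presence matrix is retained.
#'
#' @param peakSets named list of GRanges, one per sample
#' @param minOverlapSamples support threshold (default 2)
#' @return a \linkS4class{ConsensusPeaks}
#' @export
buildConsensus <- function(peakSets, minOverlapSamples = 2) {
  if (!is.list(peakSets) || length(peakSets) < 1L)
    stop("peakSets must be a non-empty list of GRanges")
  if (minOverlapSamples > length(peakSets))
    stop("minOverlapSamples exceeds the number of samples")
  if (is.null(names(peakSets)))
    names(peakSets) <- paste0("sample", seq_along(peakSets))
  merged <- GenomicRanges::reduce(
    sort(do.call(c, lapply(unname(peakSets), GenomicRanges::granges))))
  presence <- vapply(peakSets, function(p)
    GenomicRanges::countOverlaps(merged, p) > 0, logical(length(merged)))
  if (length(merged) == 1L)
    presence <- matrix(presence, nrow = 1, dimnames = list(NULL, names(peakSets)))
  keep <- rowSums(presence) >= minOverlapSamples
  new("ConsensusPeaks", peaks = merged[keep],
      presence = presence[keep, , drop = FALSE],
      minOverlapSamples = as.integer(minOverlapSamples))
}

#' Baseline / condition-unique accessible gene sets
#'
#' From labelled per-condition gene sets (genes carrying annotated
#' accessible-chromatin peaks), the baseline is the intersection of the
#' focal condition with every control; a condition's unique set is its
#' genes absent from the union of all control sets. Pairwise overlap
#' statistics (HGD) against the focal set are emitted alongside.
#'
#' @param geneSets named list of character vectors
#' @param focal name of the focal condition
#' @param controls names of the control conditions
#' @param population population for overlap statistics (default: union of
#'   all sets)
#' @return list with \code{baseline}, \code{unique} (per non-control
#'   condition), and \code{overlap} (data.frame from
#'   \code{\link{overlapReport}})
#' @export
accessibilityPartition <- function(geneSets, focal, controls,
                                   population = NULL) {
  missing <- setdiff(c(focal, controls), names(geneSets))
  if (length(missing)) stop("unknown condition label(s): ",
                            paste(missing, collapse = ", "))
  geneSets <- lapply(geneSets, function(s) unique(as.character(s)))
  baseline <- Reduce(intersect, geneSets[c(focal, controls)])
  ctrlUnion <- unique(unlist(geneSets[controls], use.names = FALSE))
  nonControl <- setdiff(names(geneSets), controls)
  uniqueSets <- lapply(geneSets[nonControl], function(s) setdiff(s, ctrlUnion))
  if (is.null(population))
    population <- unique(unlist(geneSets, use.names = FALSE))
  rep <- overlapReport(geneSets[[focal]],
                       geneSets[setdiff(names(geneSets), focal)],
                       population, queryLabel = focal)
  list(baseline = baseline, unique = uniqueSets, overlap = rep)
}

#' Normalized binding-affinity matrix at consensus sites
#'
#' Library-size (counts-per-million) normalization of per-sample read
#' counts at the consensus intervals, then log2(x + 1). Feeds the
#' affinity PCA; differential-accessibility testing is out of scope.
#'
#' @param counts sites x samples non-negative count matrix (rows aligned
#'   to the consensus peaks)
#' @param consensus optional \linkS4class{ConsensusPeaks} for a row-count
#'   consistency check
#' @return numeric matrix of the same shape
#' @export
affinityMatrix <- function(counts, consensus = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(consensus) && nrow(counts) != length(consensusPeaks(consensus)))
    stop("count rows do not match the consensus peak set")
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("a sample has zero total counts")
  log2(sweep(counts, 2, tot / 1e6, "/") + 1)
}
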