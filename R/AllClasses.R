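#' @import methods
#' @importFrom S4Vectors metadata mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
NULL

#' Hypergeometric overlap test
#'
#' Container for one gene-set overlap configuration: \code{k} shared
#' identifiers between a query of size \code{n} and a reference of size
#' \code{K}, drawn from a population (gene universe) of size \code{N}.
#' Carries the point density P(X = k), the enrichment tail probability and
#' the HGD statistic, \eqn{-\log_{10} P(X = k)}. \code{hgd} is \code{Inf}
#' for impossible configurations (density zero).
#'
#' @slot k,K,n,N integer overlap configuration
#' @slot density numeric, P(X = k)
#' @slot tailP numeric, enrichment tail probability
#' @slot tailMode character, "inclusive" (P(X >= k)) or "exclusive" (P(X > k))
#' @slot hgd numeric, -log10 density
#' @slot query,reference labels for reporting
#' @export
setClass("OverlapTest",
  representation(
    k = "integer", K = "integer", n = "integer", N = "integer",
    density = "numeric", tailP = "numeric", tailMode = "character",
    hgd = "numeric", query = "character", reference = "character"
  )
)

setValidity("OverlapTest", function(object) {
  msg <- character()
  if (object@k < 0L) msg <- c(msg, "k must be >= 0")
  if (object@k > min(object@K, object@n)) msg <- c(msg, "k must be <= min(K, n)")
  if (object@K > object@N || object@n > object@N) msg <- c(msg, "K and n must be <= N")
  if (object@density < 0 || object@density > 1) msg <- c(msg, "density must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "OverlapTest", function(object) {
  cat(sprintf("OverlapTest: %s vs %s\n", object@query, object@reference))
  cat(sprintf("  k = %d of n = %d query genes in K = %d reference genes (N = %d)\n",
              object@k, object@n, object@K, object@N))
  cat(sprintf("  density = %.4g  tail p (%s) = %.4g  HGD = %.4g\n",
              object@density, object@tailMode, object@tailP, object@hgd))
  cat(sprintf("  %% of query shared = %.1f\n", 100 * object@k / object@n))
})

#' Gene models with strand-aware TSS
#'
#' Genes as a \linkS4class{GRanges} of gene bodies (0-based half-open
#' coordinates are converted to the 1-based closed GRanges convention on
#' construction; see \code{\link{readGeneModels}}) plus an optional
#' per-gene exon \linkS4class{GRangesList}. The TSS is derived
#' strand-aware: the 5' end of the gene body.
#'
#' @slot genes GRanges with mcols column \code{gene_id}
#' @slot exons GRangesList keyed by gene_id (may be empty)
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList")
)

setValidity("GeneModels", function(object) {
  msg <- character()
  if (is.null(object@genes$gene_id)) msg <- c(msg, "genes must carry a gene_id column")
  else if (anyDuplicated(object@genes$gene_id)) msg <- c(msg, "gene_id values must be unique")
  if (any(!as.character(strand(object@genes)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be '+' or '-'")
  if (length(object@exons) &&
      !all(names(object@exons) %in% object@genes$gene_id))
    msg <- c(msg, "exon list names must be gene_ids")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes on %d sequence(s)%s\n",
              length(object@genes),
              length(unique(as.character(seqnames(object@genes)))),
              if (length(object@exons)) sprintf("; exon structure for %d genes",
                                                length(object@exons)) else ""))
})

#' @describeIn GeneModels number of genes
#' @param x a GeneModels object
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' Accessors for GeneModels
#'
#' \code{genes()} returns the gene-body GRanges, \code{geneIds()} the
#' identifier vector, \code{exonsBy()} the exon GRangesList and
#' \code{tssPositions()} a width-1 GRanges at each strand-aware TSS.
#'
#' @param object a \linkS4class{GeneModels}
#' @return see description
#' @rdname GeneModels-accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname GeneModels-accessors
#' @export
setMethod("genes", "GeneModels", function(object) object@genes)

#' @rdname GeneModels-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname GeneModels-accessors
#' @export
setMethod("geneIds", "GeneModels", function(object) object@genes$gene_id)

#' @rdname GeneModels-accessors
#' @export
setGeneric("exonsBy", function(object) standardGeneric("exonsBy"))
#' @rdname GeneModels-accessors
#' @export
setMethod("exonsBy", "GeneModels", function(object) object@exons)

#' @rdname GeneModels-accessors
#' @export
setGeneric("tssPositions", function(object) standardGeneric("tssPositions"))
#' @rdname GeneModels-accessors
#' @export
setMethod("tssPositions", "GeneModels", function(object) {
  tss <- GenomicRanges::resize(object@genes, width = 1L, fix = "start")
  names(tss) <- tss$gene_id
  tss
})

#' Position weight matrix with background model
#'
#' A motif over {A,C,G,T}: per-position probabilities after pseudocount
#' regularization, a 0-order background, and the pseudocount used. Scores
#' are log2 odds (bits) against the background.
#'
#' @slot name motif name
#' @slot probs 4 x w probability matrix, rows A,C,G,T, columns sum to 1
#' @slot background length-4 probabilities summing to 1
#' @slot pseudocount non-negative scalar (fraction of background added per cell)
#' @export
setClass("MotifMatrix",
  representation(name = "character", probs = "matrix",
                 background = "numeric", pseudocount = "numeric")
)

setValidity("MotifMatrix", function(object) {
  msg <- character()
  if (nrow(object@probs) != 4L || is.null(rownames(object@probs)) ||
      !identical(rownames(object@probs), c("A", "C", "G", "T")))
    msg <- c(msg, "probs must be a 4 x w matrix with rows A,C,G,T")
  if (ncol(object@probs) < 1L) msg <- c(msg, "motif width must be >= 1")
  if (any(abs(colSums(object@probs) - 1) > 1e-6))
    msg <- c(msg, "each position's probabilities must sum to 1")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (any(object@background <= 0)) msg <- c(msg, "background entries must be positive")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s': width %d, pseudocount %g\n",
              object@name, ncol(object@probs), object@pseudocount))
  cat("  consensus:", paste(rownames(object@probs)[apply(object@probs, 2, which.max)],
                            collapse = ""), "\n")
})

#' @describeIn MotifMatrix motif width in bp
#' @param x a MotifMatrix
#' @export
setMethod("ncol", "MotifMatrix", function(x) ncol(x@probs))

#' Consensus peak set across replicate samples
#'
#' Union-merged intervals with a peak x sample logical presence matrix;
#' merged intervals are retained when present in at least
#' \code{minOverlapSamples} samples.
#'
#' @slot peaks merged GRanges (sorted, non-overlapping)
#' @slot presence logical matrix, rows = peaks, columns = samples
#' @slot minOverlapSamples integer support threshold used
#' @export
setClass("ConsensusPeaks",
  representation(peaks = "GRanges", presence = "matrix",
                 minOverlapSamples = "integer")
)

setValidity("ConsensusPeaks", function(object) {
  msg <- character()
  if (nrow(object@presence) != length(object@peaks))
    msg <- c(msg, "presence matrix rows must match the merged peaks")
  if (!is.logical(object@presence)) msg <- c(msg, "presence must be logical")
  if (length(object@peaks) > 1L && any(
        GenomicRanges::countOverlaps(object@peaks, object@peaks) > 1L))
    msg <- c(msg, "merged peaks must be non-overlapping")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ConsensusPeaks", function(object) {
  cat(sprintf("ConsensusPeaks: %d merged intervals across %d samples (support >= %d)\n",
              length(object@peaks), ncol(object@presence), object@minOverlapSamples))
})

#' @describeIn ConsensusPeaks the merged interval GRanges
#' @param object a ConsensusPeaks
#' @export
setGeneric("consensusPeaks", function(object) standardGeneric("consensusPeaks"))
#' @rdname ConsensusPeaks-class
#' @export
setMethod("consensusPeaks", "ConsensusPeaks", function(object) object@peaks)

#' @rdname ConsensusPeaks-class
#' @export
setGeneric("presenceMatrix", function(object) standardGeneric("presenceMatrix"))
#' @rdname ConsensusPeaks-class
#' @export
setMethod("presenceMatrix", "ConsensusPeaks", function(object) object@presence)

#' Interactome prioritization cascade report
#'
#' Audit trail for the multi-step prey prioritization: per-step labels, the
#' retained prey sets for each fusion bait after the per-bait steps, the
#' shared set after intersection, and the final list after removal of weak
#' interactions.
#'
#' @slot steps data.frame with columns step, bait, n
#' @slot retained named list of character vectors (prey ids per step/bait)
#' @slot final character vector, the prioritized shared prey list
#' @export
setClass("CascadeReport",
  representation(steps = "data.frame", retained = "list", final = "character")
)

#' @export
setMethod("show", "CascadeReport", function(object) {
  cat("Interactome prioritization cascade:\n")
  for (i in seq_len(nrow(object@steps)))
    cat(sprintf("  %-28s %-10s n = %d\n", object@steps$step[i],
                object@steps$bait[i], object@steps$n[i]))
  cat(sprintf("  final shared list: %d preys\n", length(object@final)))
})

#' @describeIn CascadeReport per-step counts table
#' @param object a CascadeReport
#' @export
setGeneric("cascadeSteps", function(object) standardGeneric("cascadeSteps"))
#' @rdname CascadeReport-class
#' @export
setMethod("cascadeSteps", "CascadeReport", function(object) object@steps)

#' @rdname CascadeReport-class
#' @export
setGeneric("cascadeFinal", function(object) standardGeneric("cascadeFinal"))
#' @rdname CascadeReport-class
#' @export
setMethod("cascadeFinal", "CascadeReport", function(object) object@final)
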