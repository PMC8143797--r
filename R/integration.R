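#' Join differential expression with binding and open-chromatin evidence
#'
#' One record per DEG-table gene: the -log10 adjusted p (underflowed
#' zeros capped at \code{padjCap} before the log), whether the gene
#' carries an assigned ChIP peak with the per-gene peak score (maximum
#' over assigned peaks; 0 when unbound), and whether it lies in the
#' condition-unique open-chromatin gene set. The join is lossless on the
#' DEG side.
#'
#' @param deg DEG data.frame (gene_id, padj, ...)
#' @param boundScores named numeric vector: per-gene peak score for bound
#'   genes (e.g. \code{max_score} from \code{\link{assignPeaksToGenes}})
#' @param openUniqueGenes character vector of unique-open genes
#' @param padjCap floor applied to padj before -log10 (default 1e-320)
#' @return data.frame with columns gene_id, deg_neglog10_padj, peak_score,
#'   bound, open_unique
#' @export
buildIntegrationTable <- function(deg, boundScores = numeric(0),
                                  openUniqueGenes = character(0),
                                  padjCap = 1e-320) {
  if (anyDuplicated(deg$gene_id)) stop("duplicate gene_id in DEG table")
  if (length(boundScores) && anyDuplicated(names(boundScores)))
    stop("duplicate gene in bound-score input")
  if (anyDuplicated(openUniqueGenes)) stop("duplicate gene in open-unique input")
  padj <- pmax(deg$padj, padjCap)
  bound <- deg$gene_id %in% names(boundScores)
  score <- rep(0, nrow(deg))
  score[bound] <- unname(boundScores[deg$gene_id[bound]])
  data.frame(gene_id = deg$gene_id,
             deg_neglog10_padj = ifelse(is.na(padj), NA_real_, -log10(padj)),
             peak_score = score,
             bound = bound,
             open_unique = deg$gene_id %in% openUniqueGenes,
             stringsAsFactors = FALSE)
}

#' Percentage of differentially expressed genes directly bound
#'
#' @param records data.frame from \code{\link{buildIntegrationTable}}
#' @return percentage in [0, 100]
#' @export
fractionDegsBound <- function(records) {
  if (nrow(records) == 0L) stop("no integration records")
  100 * mean(records$bound)
}

#' Percentage of DEGs inside condition-unique open chromatin
#'
#' Accepts either an integration table or two identifier sets.
#'
#' @param records integration data.frame, or a character vector of DEG ids
#' @param openUniqueGenes character vector (when \code{records} is a
#'   gene-id vector)
#' @return percentage in [0, 100]
#' @export
fractionDegsInOpen <- function(records, openUniqueGenes = NULL) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0L) stop("no integration records")
    return(100 * mean(records$open_unique))
  }
  degs <- unique(as.character(records))
  if (length(degs) == 0L) stop("empty DEG set")
  100 * length(intersect(degs, openUniqueGenes)) / length(degs)
}

#' Significance vs peak-score table
#'
#' The two-axis export behind the binding/expression integration plot:
#' genes sorted by peak score then significance, with the genes above
#' both thresholds flagged as the top-right quadrant.
#'
#' @param records data.frame from \code{\link{buildIntegrationTable}}
#' @param sigThreshold -log10 padj cutoff (default 2, i.e. padj 0.01)
#' @param scoreThreshold peak-score cutoff (default 50)
#' @return the records with a logical \code{quadrant} column, sorted
#' @export
significanceScoreTable <- function(records, sigThreshold = 2,
                                   scoreThreshold = 50) {
  records$quadrant <- !is.na(records$deg_neglog10_padj) &
    records$deg_neglog10_padj > sigThreshold &
    records$peak_score > scoreThreshold
  records[order(records$peak_score, records$deg_neglog10_padj), , drop = FALSE]
}
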