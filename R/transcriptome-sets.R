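#' Filter a differential-expression table to the significant gene set
#'
#' Gene identifiers with an adjusted p-value present and strictly below
#' \code{alpha} (FDR threshold). Missing adjusted p-values — the output of
#' independent filtering upstream — are treated as not significant. The
#' filter has no fold-change component and ignores direction; overlap
#' statistics downstream operate on identifiers only.
#'
#' @param deg data.frame with columns gene_id, padj (see
#'   \code{\link{readDegTable}})
#' @param alpha FDR threshold (default 0.05)
#' @return character vector of gene identifiers
#' @export
filterDegs <- function(deg, alpha = 0.05) {
  if (!is.data.frame(deg) || is.null(deg$gene_id) || is.null(deg$padj))
    stop("deg must be a data.frame with gene_id and padj columns")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  deg$gene_id[!is.na(deg$padj) & deg$padj < alpha]
}

#' Gene universe for hypergeometric testing
#'
#' The population for expression overlap tests: genes whose mean count
#' across all samples is at least \code{minMeanCount} (boundary
#' inclusive).
#'
#' @param counts genes x samples non-negative count matrix with rownames
#' @param minMeanCount inclusion threshold (default 5)
#' @return character vector of gene identifiers
#' @export
definePopulation <- function(counts, minMeanCount = 5) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("count matrix has no samples")
  if (is.null(rownames(counts))) stop("count matrix must have gene rownames")
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts)[rowMeans(counts) >= minMeanCount]
}

#' Variance-stabilizing style transform of a count matrix
#'
#' Median-of-ratios size-factor normalization (reference = geometric mean
#' over genes with all-positive counts) followed by log2(x + 1). This is
#' the package's stand-in for a fitted dispersion-based transform: the
#' only downstream consumer is PCA geometry, which is insensitive to the
#' difference at the scales used here.
#'
#' @param counts genes x samples non-negative count matrix
#' @return list with \code{transformed} (matrix) and \code{sizeFactors}
#' @export
vstLikeTransform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("a sample has all-zero counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logGeo)))
  norm <- sweep(counts, 2, sf, "/")
  list(transformed = log2(norm + 1), sizeFactors = sf)
}

#' Principal component coordinates of samples
#'
#' Samples (columns of the transformed matrix) are mean-centered across
#' genes and projected onto the top right-singular directions. The sign of
#' each component is fixed so the loading of largest magnitude is
#' positive, making coordinates reproducible across platforms.
#'
#' @param mat genes x samples numeric matrix
#' @param nComponents number of components (default 2)
#' @return list with \code{coordinates} (samples x components),
#'   \code{varianceFraction} (per component, non-increasing) and
#'   \code{loadings}
#' @export
pcaCoordinates <- function(mat, nComponents = 2) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("PCA requires at least 2 samples")
  if (nComponents > min(dim(mat))) stop("nComponents exceeds matrix rank bound")
  x <- t(mat)                      # samples x genes
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = nComponents, nv = nComponents)
  d2 <- sv$d^2
  varFrac <- (d2 / sum(d2))[seq_len(nComponents)]
  coords <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  load <- sv$v
  for (j in seq_len(nComponents)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(mat)
  colnames(coords) <- paste0("PC", seq_len(nComponents))
  list(coordinates = coords, varianceFraction = varFrac, loadings = load)
}
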