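#' Per-replicate growth fold change
#'
#' Day-\code{endpointDay} absorbance over day-0 absorbance for each
#' replicate of one construct, the proliferation readout used for all
#' deficit calls.
#'
#' @param growth long-format growth data.frame (see
#'   \code{\link{readGrowthTable}}) restricted to one construct
#' @param endpointDay assay endpoint (default 10)
#' @return named numeric vector, one fold change per replicate
#' @export
foldChange <- function(growth, endpointDay = 10) {
  spl <- split(growth, growth$replicate)
  vapply(spl, function(g) {
    d0 <- g$absorbance[g$day == 0]
    dE <- g$absorbance[g$day == endpointDay]
    if (length(d0) != 1L) stop("replicate lacks a single day-0 reading")
    if (length(dE) != 1L) stop("replicate lacks a single endpoint reading (day ",
                               endpointDay, ")")
    dE / d0
  }, numeric(1))
}

#' Deficit call for one shRNA against two controls
#'
#' An shRNA shows a growth deficit when its fold changes are
#' significantly lower than \emph{both} controls: Welch's unpaired
#' two-tailed t-test p below \code{alpha} against each control, together
#' with a lower mean fold change than each control.
#'
#' @param shrnaFC numeric fold changes for the shRNA (>= 2 replicates)
#' @param controlFCs named list of fold-change vectors, one per control
#' @param alpha significance threshold (default 0.05)
#' @param requireBoth require the criterion against every control
#'   (default TRUE; FALSE calls a deficit when any control is beaten)
#' @return list with \code{deficit} (logical), \code{pvalues} (per
#'   control) and \code{meanFC}
#' @export
deficitCall <- function(shrnaFC, controlFCs, alpha = 0.05,
                        requireBoth = TRUE) {
  if (length(shrnaFC) < 2L) stop("need >= 2 shRNA replicates")
  if (any(vapply(controlFCs, length, integer(1)) < 2L))
    stop("need >= 2 replicates per control")
  pv <- vapply(controlFCs, function(ctrl)
    stats::t.test(shrnaFC, ctrl, var.equal = FALSE)$p.value, numeric(1))
  lower <- vapply(controlFCs, function(ctrl)
    mean(shrnaFC) < mean(ctrl), logical(1))
  hit <- pv < alpha & lower
  list(deficit = if (requireBoth) all(hit) else any(hit),
       pvalues = pv, meanFC = mean(shrnaFC))
}

#' Score an RNAi proliferation screen
#'
#' For every targeting construct in a growth table, computes per-replicate
#' fold changes at the endpoint, calls a deficit against both control
#' constructs, and counts deficit-scoring shRNAs per gene.
#'
#' @param growth long-format growth data.frame
#' @param controls construct labels of the two controls
#'   (default \code{c("shEV", "shNT")})
#' @param endpointDay assay endpoint (default 10)
#' @param alpha significance threshold (default 0.05)
#' @param requireBoth see \code{\link{deficitCall}}
#' @return list with \code{perShrna} (data.frame gene, construct, mean_fc,
#'   p per control, deficit) and \code{perGene} (data.frame gene,
#'   n_deficit, mean_fc)
#' @export
screenScore <- function(growth, controls = c("shEV", "shNT"),
                        endpointDay = 10, alpha = 0.05, requireBoth = TRUE) {
  missingCtrl <- setdiff(controls, growth$construct)
  if (length(missingCtrl)) stop("control construct(s) absent: ",
                                paste(missingCtrl, collapse = ", "))
  ctrlFCs <- lapply(controls, function(cc)
    foldChange(growth[growth$construct == cc, , drop = FALSE], endpointDay))
  names(ctrlFCs) <- controls
  targets <- setdiff(unique(growth$construct), controls)
  rows <- lapply(targets, function(cons) {
    g <- growth[growth$construct == cons, , drop = FALSE]
    fc <- foldChange(g, endpointDay)
    call <- deficitCall(fc, ctrlFCs, alpha, requireBoth)
    out <- data.frame(gene = g$gene[1], construct = cons,
                      mean_fc = call$meanFC, deficit = call$deficit,
                      stringsAsFactors = FALSE)
    for (cc in controls) out[[paste0("p_vs_", cc)]] <- call$pvalues[[cc]]
    out
  })
  perShrna <- do.call(rbind, rows)
  list(perShrna = perShrna,
       perGene = rankGenes(perShrna),
       controlMeanFC = vapply(ctrlFCs, mean, numeric(1)))
}

#' Rank screen genes by number of deficit-scoring shRNAs
#'
#' Descending by \code{n_deficit}; ties broken by the stronger mean
#' fold-change deficit (smaller mean fold change first), then gene id.
#'
#' @param perShrna data.frame with columns gene, deficit, mean_fc
#' @return data.frame gene, n_shrnas, n_deficit, mean_fc, sorted
#' @export
rankGenes <- function(perShrna) {
  spl <- split(perShrna, perShrna$gene)
  tab <- do.call(rbind, lapply(spl, function(g)
    data.frame(gene = g$gene[1], n_shrnas = nrow(g),
               n_deficit = sum(g$deficit), mean_fc = mean(g$mean_fc),
               stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$n_deficit, tab$mean_fc, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
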