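#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqnames
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   reverseComplement
NULL

#' Read peak calls from a BED / narrowPeak-like file
#'
#' Accepts BED3-6 (extra narrowPeak columns are ignored). Coordinates in
#' the file are 0-based half-open and are converted to the 1-based closed
#' GRanges convention. Column 4 populates \code{name}, column 5
#' \code{score} (taken as the caller's -log10 statistic; 0 when absent —
#' peak significance is never recomputed here).
#'
#' @param path BED file
#' @return GRanges with mcols \code{name}, \code{score}
#' @export
readPeakBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GRanges(name = character(), score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineNo[which(nf < 3L)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  startTxt <- vapply(fields, `[`, "", 2L)
  endTxt <- vapply(fields, `[`, "", 3L)
  start0 <- suppressWarnings(as.numeric(startTxt))
  end0 <- suppressWarnings(as.numeric(endTxt))
  bad <- is.na(start0) | is.na(end0) | start0 != floor(start0) | end0 != floor(end0)
  if (any(bad))
    stop("malformed BED line ", lineNo[which(bad)[1]], ": non-integer coordinate")
  if (any(start0 < 0))
    stop("malformed BED line ", lineNo[which(start0 < 0)[1]], ": negative start")
  if (any(end0 <= start0))
    stop("malformed BED line ", lineNo[which(end0 <= start0)[1]], ": end <= start")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), "")
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f)
                    if (length(f) >= 5L) f[5L] else "0", ""))), 0)
  score[is.na(score)] <- 0
  GRanges(chrom, IRanges(start0 + 1L, end0), name = name, score = score)
}

#' Write a GRanges as BED
#'
#' Inverse of \code{\link{readPeakBed}}: emits 0-based half-open
#' coordinates with name and score columns.
#'
#' @param gr GRanges (mcols \code{name}, \code{score} used when present)
#' @param path output file
#' @export
writePeakBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".",
                   score = if (!is.null(gr$score)) gr$score else 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct gene models from 0-based half-open coordinates
#'
#' Builds a \linkS4class{GeneModels} from the coordinate convention used
#' for all internal distance arithmetic (0-based half-open). The TSS of a
#' gene is \code{txStart} on the + strand and \code{txEnd - 1} on the -
#' strand.
#'
#' @param gene_id character identifiers (unique)
#' @param chrom chromosome per gene
#' @param strand "+" or "-" per gene
#' @param txStart,txEnd 0-based half-open gene body
#' @param exons optional named list (by gene_id) of 2-column matrices of
#'   0-based half-open exon coordinates
#' @return a \linkS4class{GeneModels}
#' @export
geneModels <- function(gene_id, chrom, strand, txStart, txEnd, exons = NULL) {
  if (any(txEnd <= txStart)) stop("gene body end must exceed start")
  gr <- GRanges(chrom, IRanges(txStart + 1L, txEnd), strand = strand,
                gene_id = as.character(gene_id))
  exl <- GRangesList()
  if (!is.null(exons) && length(exons)) {
    exl <- GRangesList(lapply(names(exons), function(g) {
      m <- exons[[g]]
      i <- match(g, gene_id)
      GRanges(chrom[i], IRanges(m[, 1] + 1L, m[, 2]), strand = strand[i])
    }))
    names(exl) <- names(exons)
  }
  new("GeneModels", genes = gr, exons = exl)
}

#' Read gene models from a GTF file
#'
#' Imports gene and exon feature rows (1-based inclusive coordinates, the
#' GTF convention) via \code{rtracklayer} and assembles one gene model per
#' \code{gene_id}. When the file carries no \code{gene} rows, gene bodies
#' are the per-gene exon span. Rows without a \code{gene_id} attribute or
#' with strand other than +/- are an error.
#'
#' @param path GTF/GFF2 file
#' @return a \linkS4class{GeneModels}
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id) || any(gr$gene_id == ""))
    stop("GTF rows missing a gene_id attribute")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene strand must be '+' or '-' in GTF input")
  type <- as.character(gr$type)
  geneRows <- gr[type == "gene"]
  exonRows <- gr[type == "exon"]
  if (!length(geneRows)) {
    if (!length(exonRows)) stop("GTF contains neither gene nor exon rows")
    spl <- split(exonRows, exonRows$gene_id)
    geneRows <- unlist(GenomicRanges::reduce(GenomicRanges::GRangesList(
      lapply(spl, range))))
    geneRows$gene_id <- names(spl)
  }
  if (anyDuplicated(geneRows$gene_id)) stop("duplicate gene_id in GTF gene rows")
  g <- GRanges(seqnames(geneRows),
               IRanges(start(geneRows), end(geneRows)),
               strand = strand(geneRows), gene_id = geneRows$gene_id)
  exl <- GRangesList()
  if (length(exonRows)) {
    spl <- split(exonRows, exonRows$gene_id)
    exl <- GRangesList(lapply(spl, function(e)
      GRanges(seqnames(e), IRanges(start(e), end(e)), strand = strand(e))))
    names(exl) <- names(spl)
  }
  new("GeneModels", genes = g, exons = exl)
}

#' Write gene models as GTF
#'
#' Emits gene rows (and exon rows when exon structure is present) with
#' 1-based inclusive coordinates and a \code{gene_id} attribute, the
#' dialect \code{\link{readGeneModels}} reads back.
#'
#' @param gm a \linkS4class{GeneModels}
#' @param path output file
#' @export
writeGeneModels <- function(gm, path) {
  g <- genes(gm)
  fmt <- function(gr, type, ids) {
    sprintf("%s\tfusionomics\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            as.character(seqnames(gr)), type, start(gr), end(gr),
            as.character(strand(gr)), ids)
  }
  lines <- fmt(g, "gene", g$gene_id)
  exl <- exonsBy(gm)
  if (length(exl)) {
    for (gid in names(exl))
      lines <- c(lines, fmt(exl[[gid]], "exon", gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with a header; the four required columns can be renamed via
#' \code{cols}. "NA"/empty adjusted p-values become \code{NA} (treated as
#' not significant downstream). Duplicate gene identifiers are an error
#' (set membership would be ambiguous).
#'
#' @param path TSV file
#' @param cols named character vector mapping internal names
#'   (gene_id, log2fc, pvalue, padj) to file column names
#' @return data.frame with columns gene_id, log2fc, pvalue, padj
#' @export
readDegTable <- function(path,
                         cols = c(gene_id = "gene_id", log2fc = "log2fc",
                                  pvalue = "pvalue", padj = "padj")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing)) stop("DEG table missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- data.frame(gene_id = as.character(raw[[cols[["gene_id"]]]]),
                   log2fc = as.numeric(raw[[cols[["log2fc"]]]]),
                   pvalue = as.numeric(raw[[cols[["pvalue"]]]]),
                   padj = suppressWarnings(as.numeric(raw[[cols[["padj"]]]])),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in DEG table: ",
         df$gene_id[anyDuplicated(df$gene_id)])
  bad <- function(p) !is.na(p) & (p < 0 | p > 1)
  if (any(bad(df$pvalue)) || any(bad(df$padj)))
    stop("p-values must lie in [0, 1]")
  df
}

#' @rdname readDegTable
#' @param df DEG data.frame
#' @export
writeDegTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SAINT-style prey table
#'
#' TSV with columns bait, prey, counts (replicate spectral counts joined
#' by "|"), relative_abundance, probability, bfdr. Spectral counts must be
#' non-negative integers; probability and BFDR in [0, 1].
#'
#' @param path TSV file
#' @return data.frame with counts split into count_r1, count_r2 and a
#'   max_count convenience column
#' @export
readPreyTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bait", "prey", "counts", "relative_abundance", "probability", "bfdr")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("prey table missing column(s): ",
                            paste(missing, collapse = ", "))
  cts <- strsplit(as.character(raw$counts), "|", fixed = TRUE)
  if (any(lengths(cts) != 2L)) stop("counts must hold 2 replicate values joined by '|'")
  c1 <- as.numeric(vapply(cts, `[`, "", 1L))
  c2 <- as.numeric(vapply(cts, `[`, "", 2L))
  if (anyNA(c1) || anyNA(c2) || any(c(c1, c2) < 0) ||
      any(c(c1, c2) != floor(c(c1, c2))))
    stop("spectral counts must be non-negative integers")
  p <- as.numeric(raw$probability); b <- as.numeric(raw$bfdr)
  if (any(p < 0 | p > 1) || any(b < 0 | b > 1))
    stop("probability and bfdr must lie in [0, 1]")
  data.frame(bait = as.character(raw$bait), prey = as.character(raw$prey),
             count_r1 = c1, count_r2 = c2, max_count = pmax(c1, c2),
             avg_count = (c1 + c2) / 2,
             relative_abundance = as.numeric(raw$relative_abundance),
             probability = p, bfdr = b, stringsAsFactors = FALSE)
}

#' @rdname readPreyTable
#' @param df prey data.frame (as returned by \code{readPreyTable})
#' @export
writePreyTable <- function(df, path) {
  out <- data.frame(bait = df$bait, prey = df$prey,
                    counts = paste(df$count_r1, df$count_r2, sep = "|"),
                    relative_abundance = df$relative_abundance,
                    probability = df$probability, bfdr = df$bfdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an anchorage-independent growth table
#'
#' TSV with columns cell_line, construct, gene, replicate, day, absorbance.
#' Days must be non-negative integers and absorbance positive.
#'
#' @param path TSV file
#' @return data.frame in long format
#' @export
readGrowthTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "construct", "gene", "replicate", "day", "absorbance")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("growth table missing column(s): ",
                            paste(missing, collapse = ", "))
  day <- as.numeric(raw$day); ab <- as.numeric(raw$absorbance)
  if (any(is.na(day)) || any(day < 0) || any(day != floor(day)))
    stop("day must be a non-negative integer")
  if (any(is.na(ab)) || any(ab <= 0)) stop("absorbance must be positive")
  raw$day <- as.integer(day); raw$absorbance <- ab
  raw[need]
}

#' @rdname readGrowthTable
#' @param df growth data.frame
#' @export
writeGrowthTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are upper-cased and restricted to the alphabet {A,C,G,T,N}.
#'
#' @param path FASTA file
#' @return a named \code{DNAStringSet}
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- readDNAStringSet(path)
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  letters <- unique(unlist(strsplit(as.character(seqs), "")))
  bad <- setdiff(letters, c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-DNA characters in FASTA: ", paste(bad, collapse = ", "))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a tabular or list report
#'
#' Data frames are written as TSV; lists as JSON (full numeric precision).
#'
#' @param obj data.frame or list
#' @param path output file; extension selects the format when
#'   \code{format = "auto"}
#' @param format "auto", "tsv" or "json"
#' @export
writeReport <- function(obj, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!is.data.frame(obj)) stop("TSV reports require a data.frame")
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
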