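.DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' From a 4 x w count (or probability) matrix, rows A,C,G,T. Each cell is
#' regularized with \code{pseudocount * background[base]} and the column
#' renormalized: \code{p(i,b) = (count(i,b) + pc * bg(b)) / (colsum + pc)}.
#'
#' @param counts 4 x w numeric matrix (rows A,C,G,T or unnamed in that order)
#' @param name motif name
#' @param background length-4 base probabilities (default uniform)
#' @param pseudocount total pseudocount per column, split by background
#'   (default 0.1)
#' @return a \linkS4class{MotifMatrix}
#' @export
motifMatrix <- function(counts, name = "motif",
                        background = rep(0.25, 4), pseudocount = 0.1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("motif width must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(background <= 0)) stop("background entries must be positive")
  background <- background / sum(background)
  rownames(counts) <- .DNA
  probs <- apply(counts, 2, function(col)
    (col + pseudocount * background) / (sum(col) + pseudocount))
  rownames(probs) <- .DNA
  new("MotifMatrix", name = name, probs = probs,
      background = stats::setNames(background, .DNA),
      pseudocount = pseudocount)
}

#' @describeIn motifMatrix motif width in bp
#' @param pwm a MotifMatrix
#' @export
motifWidth <- function(pwm) ncol(pwm@probs)

#' Replace the background model of a PWM
#'
#' Swaps the 0-order background used for log-odds scoring (the position
#' probabilities, already regularized at construction, are unchanged).
#'
#' @param pwm a \linkS4class{MotifMatrix}
#' @param background length-4 probabilities
#' @return a \linkS4class{MotifMatrix}
#' @export
withBackground <- function(pwm, background) {
  if (any(background <= 0)) stop("background entries must be positive")
  background <- background / sum(background)
  initialize(pwm, background = stats::setNames(background, .DNA))
}

#' Log-odds score matrix of a PWM
#'
#' \code{score(b, i) = log2(p(b, i) / background(b))}, in bits.
#'
#' @param pwm a \linkS4class{MotifMatrix}
#' @return 4 x w numeric matrix
#' @export
pwmLogOdds <- function(pwm) {
  log2(pwm@probs / pwm@background)
}

# Integerized log-odds (units of eps bits) and the exact background score
# distribution of a random word, by dynamic programming.
.scoreDistribution <- function(pwm, eps = 1e-3) {
  S <- round(pwmLogOdds(pwm) / eps)
  w <- ncol(S)
  runLo <- 0                                # integer score of dist[1]
  dist <- c(1)                              # P(partial score = runLo) = 1
  for (j in seq_len(w)) {
    sj <- S[, j]
    new <- numeric(length(dist) + max(sj) - min(sj))
    for (b in 1:4) {
      idx <- seq_along(dist) + (sj[b] - min(sj))
      new[idx] <- new[idx] + pwm@background[b] * dist
    }
    dist <- new
    runLo <- runLo + min(sj)
  }
  support <- seq(runLo, by = 1, length.out = length(dist))
  tail <- rev(cumsum(rev(dist)))            # P(score_int >= support[i])
  list(support = support, prob = dist, tail = tail, eps = eps, S = S)
}

#' Exact p-value of a PWM log-odds score
#'
#' P(score of a random background word >= s), computed exactly over the
#' score distribution integerized at resolution \code{eps} bits
#' (discretization error at most \code{w * eps} in score units). Scores
#' above the maximum achievable return 0; at or below the minimum, 1.
#'
#' @param pwm a \linkS4class{MotifMatrix}
#' @param s log-odds score(s) in bits
#' @param eps integerization resolution in bits (default 1/1000)
#' @return p-value(s) in [0, 1]
#' @export
motifScorePvalue <- function(pwm, s, eps = 1e-3) {
  d <- .scoreDistribution(pwm, eps)
  si <- round(s / eps)
  vapply(si, function(t) {
    if (t > d$support[length(d$support)]) return(0)
    if (t <= d$support[1]) return(1)
    d$tail[t - d$support[1] + 1]
  }, numeric(1))
}

.encodeDNA <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, .DNA)                # N and others -> NA
  code
}

#' Scan a sequence for PWM hits on both strands
#'
#' Windows are scored on the forward sequence and on its reverse
#' complement (reported with strand "-" at the corresponding forward
#' offset); a window is a hit when its exact score p-value
#' (\code{\link{motifScorePvalue}}) is at or below \code{pThreshold}.
#' Windows containing N are skipped. Sequences shorter than the motif
#' yield no hits.
#'
#' @param seq character or DNAString
#' @param pwm a \linkS4class{MotifMatrix}
#' @param pThreshold per-window p-value threshold (default 1e-4)
#' @param eps integerization resolution (default 1/1000 bit)
#' @return data.frame with columns offset (0-based, forward strand),
#'   strand, score (bits), pvalue
#' @export
scanSequence <- function(seq, pwm, pThreshold = 1e-4, eps = 1e-3) {
  if (pThreshold <= 0 || pThreshold >= 1) stop("pThreshold must lie in (0, 1)")
  seq <- as.character(seq)
  w <- motifWidth(pwm)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0))
  if (nchar(seq) < w) return(empty)
  d <- .scoreDistribution(pwm, eps)
  scanStrand <- function(s) {
    code <- .encodeDNA(s)
    n <- nchar(s) - w + 1
    tot <- numeric(n)
    for (j in seq_len(w))
      tot <- tot + d$S[cbind(code[j:(j + n - 1)], j)]
    tot                                       # NA where the window holds an N
  }
  lookupP <- function(t) {
    ifelse(t > d$support[length(d$support)], 0,
           ifelse(t <= d$support[1], 1, d$tail[pmax(1, t - d$support[1] + 1)]))
  }
  hits <- list()
  fwd <- scanStrand(seq)
  pv <- lookupP(fwd)
  sel <- which(!is.na(fwd) & pv <= pThreshold)
  if (length(sel))
    hits[["+"]] <- data.frame(offset = sel - 1L, strand = "+",
                              score = fwd[sel] * eps, pvalue = pv[sel])
  rcSeq <- as.character(reverseComplement(DNAStringSet(seq))[[1]])
  rc <- scanStrand(rcSeq)
  pvR <- lookupP(rc)
  selR <- which(!is.na(rc) & pvR <= pThreshold)
  if (length(selR)) {
    # offset j (0-based) on the reverse complement covers forward
    # positions [L - w - j, L - j)
    hits[["-"]] <- data.frame(offset = nchar(seq) - w - (selR - 1L),
                              strand = "-", score = rc[selR] * eps,
                              pvalue = pvR[selR])
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Estimate a 0-order background from sequences
#'
#' Base frequencies over {A,C,G,T} (N ignored), the default background
#' used when scanning peak sequences.
#'
#' @param seqs character vector or DNAStringSet
#' @return length-4 probabilities (A, C, G, T)
#' @export
estimateBackground <- function(seqs) {
  chars <- unlist(strsplit(toupper(as.character(seqs)), ""), use.names = FALSE)
  counts <- table(factor(chars, levels = .DNA))
  if (sum(counts) == 0) stop("no A/C/G/T characters in sequences")
  as.numeric(counts) / sum(counts)
}

#' Proportion of peaks containing a motif
#'
#' Extracts each peak's sequence from the genome, scans both strands and
#' reports the percentage of peaks with at least one window at or below
#' the p-value threshold (multiple hits within one peak do not add
#' weight). By default the 0-order background is estimated from the
#' scanned peak sequences themselves.
#'
#' @param peaks GRanges within the genome's contig bounds
#' @param genome named DNAStringSet
#' @param pwm a \linkS4class{MotifMatrix}
#' @param pThreshold per-window p-value threshold (default 1e-4)
#' @param background "peaks" (estimate from peak sequences, default) or
#'   "uniform"
#' @return list with \code{percent} and \code{hasMotif} (logical per peak)
#' @export
peakMotifProportion <- function(peaks, genome, pwm, pThreshold = 1e-4,
                                background = c("peaks", "uniform")) {
  background <- match.arg(background)
  if (length(peaks) == 0L) stop("no peaks supplied")
  chrom <- as.character(seqnames(peaks))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing)) stop("peak chromosome(s) absent from genome: ",
                            paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  beyond <- end(peaks) > lens[chrom]
  if (any(beyond)) {
    i <- which(beyond)[1]
    stop(sprintf("peak %s:%d-%d extends beyond contig end", chrom[i],
                 start(peaks)[i] - 1L, end(peaks)[i]))
  }
  seqs <- vapply(seq_along(peaks), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    start(peaks)[i], end(peaks)[i])),
    character(1))
  pwm <- if (background == "peaks")
    withBackground(pwm, estimateBackground(seqs)) else
    withBackground(pwm, rep(0.25, 4))
  hasMotif <- vapply(seqs, function(s)
    nrow(scanSequence(s, pwm, pThreshold)) > 0, logical(1), USE.NAMES = FALSE)
  list(percent = 100 * mean(hasMotif), hasMotif = hasMotif)
}

#' Read motifs in MEME minimal format
#'
#' Parses MOTIF blocks with their letter-probability matrices; the file's
#' background line is used when present. Probability rows are treated as
#' counts for pseudocount regularization at construction.
#'
#' @param path MEME motif file
#' @param pseudocount passed to \code{\link{motifMatrix}} (default 0.1)
#' @return named list of \linkS4class{MotifMatrix}
#' @export
readMemeMotifs <- function(path, pseudocount = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)]
    if (length(bg) != 4L) stop("malformed background line in MEME file")
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks in MEME file")
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1]
    wMatch <- regmatches(lines[hdr], regexpr("w=\\s*[0-9]+", lines[hdr]))
    w <- as.integer(sub("w=\\s*", "", wMatch))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    if (anyNA(m)) stop("malformed probability row in MEME motif ", name)
    out[[name]] <- motifMatrix(t(m), name = name, background = bg,
                               pseudocount = pseudocount)
  }
  out
}

#' Read a 4-row tab-separated position frequency matrix
#'
#' Rows A, C, G, T (optionally labelled in column 1), columns = positions.
#'
#' @param path PFM file
#' @param name motif name (default: file base name)
#' @param ... passed to \code{\link{motifMatrix}}
#' @return a \linkS4class{MotifMatrix}
#' @export
readPfm <- function(path, name = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 4L) stop("PFM must have exactly 4 rows")
  labelled <- all(toupper(vapply(rows, `[`, "", 1L)) %in% .DNA)
  m <- t(vapply(rows, function(r) {
    v <- if (labelled) r[-1] else r
    as.numeric(v)
  }, numeric(length(rows[[1]]) - labelled)))
  if (anyNA(m)) stop("non-numeric entry in PFM")
  if (labelled) m <- m[match(.DNA, toupper(vapply(rows, `[`, "", 1L))), ,
                       drop = FALSE]
  motifMatrix(m, name = if (is.null(name)) basename(path) else name, ...)
}

#' Motif presence vs control association test
#'
#' Set-level enrichment reduced to a 2 x 2 association: peaks-with-motif
#' in the observed sequences against a shuffled-sequence control, with
#' odds ratio and Fisher's exact p.
#'
#' @param hasMotif logical vector for the observed peaks
#' @param hasMotifControl logical vector for control (e.g. shuffled)
#'   sequences
#' @return list with \code{oddsRatio}, \code{pvalue}, \code{table}
#' @export
motifEnrichmentTest <- function(hasMotif, hasMotifControl) {
  tab <- matrix(c(sum(hasMotif), sum(!hasMotif),
                  sum(hasMotifControl), sum(!hasMotifControl)), nrow = 2,
                dimnames = list(c("with", "without"), c("observed", "control")))
  ft <- stats::fisher.test(tab)
  list(oddsRatio = unname(ft$estimate), pvalue = ft$p.value, table = tab)
}
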