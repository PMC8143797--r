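# Independent oracles used across the suite. Each is deliberately naive:
# exact integer arithmetic, all-pairs scans and exhaustive enumeration,
# sharing no code path with the package implementations they check.

# Exact hypergeometric pmf via prime factorization of the factorials:
# every binomial coefficient is expressed through exact (integer) prime
# exponents by Legendre's formula, so the ratio is formed as an exact
# rational before a single final exponentiation.
.primesTo <- function(n) {
  if (n < 2) return(integer(0))
  sieve <- rep(TRUE, n); sieve[1] <- FALSE
  for (p in 2:floor(sqrt(n))) if (sieve[p]) sieve[seq(p * p, n, by = p)] <- FALSE
  which(sieve)
}

exactHyperPmf <- function(k, K, n, N) {
  if (k < 0 || k > min(K, n) || (n - k) > (N - K)) return(0)
  primes <- .primesTo(max(N, 2))
  legendre <- function(m, p) {
    s <- 0; q <- p
    while (q <= m) { s <- s + m %/% q; q <- q * p }
    s
  }
  factExp <- function(m) vapply(primes, function(p) legendre(m, p), numeric(1))
  e <- (factExp(K) - factExp(k) - factExp(K - k)) +
    (factExp(N - K) - factExp(n - k) - factExp(N - K - n + k)) -
    (factExp(N) - factExp(n) - factExp(N - n))
  exp(sum(e * log(primes)))
}

# All-pairs nearest-TSS scan, written from the annotation rules directly:
# no per-chromosome indexing, plain loops over every gene.
bruteAnnotate <- function(peaks, gm, promoterWindow = 1000,
                          proximalWindow = 3000, downstreamWindow = 3000) {
  g <- genes(gm)
  tssGr <- tssPositions(gm)
  ord <- order(g$gene_id)
  g <- g[ord]; tssGr <- tssGr[ord]
  gChrom <- as.character(GenomicRanges::seqnames(g))
  gStrand <- as.character(GenomicRanges::strand(g))
  gStart0 <- GenomicRanges::start(g) - 1L
  gEnd0 <- GenomicRanges::end(g)
  tss0 <- GenomicRanges::start(tssGr) - 1L
  out <- data.frame(gene = rep(NA_character_, length(peaks)),
                    dist = NA_real_, category = "DistalIntergenic",
                    stringsAsFactors = FALSE)
  for (i in seq_along(peaks)) {
    chr <- as.character(GenomicRanges::seqnames(peaks)[i])
    mid <- floor((GenomicRanges::start(peaks)[i] - 1 +
                    GenomicRanges::end(peaks)[i]) / 2)
    best <- NA; bestD <- Inf
    for (j in seq_along(g)) {
      if (gChrom[j] != chr) next
      d <- abs(mid - tss0[j])
      if (d < bestD) { bestD <- d; best <- j }
    }
    if (is.na(best)) next
    dSigned <- if (gStrand[best] == "+") mid - tss0[best] else tss0[best] - mid
    out$gene[i] <- g$gene_id[best]
    out$dist[i] <- dSigned
    cat <- if (abs(dSigned) <= promoterWindow) "Promoter<=1kb"
      else if (abs(dSigned) <= proximalWindow) "Promoter1-3kb"
      else if (mid >= gStart0[best] && mid < gEnd0[best]) "GeneBody"
      else {
        threeEnd <- if (gStrand[best] == "+") gEnd0[best] - 1 else gStart0[best]
        dd <- if (gStrand[best] == "+") mid - threeEnd else threeEnd - mid
        if (dd > 0 && dd <= downstreamWindow) "Downstream<=3kb"
        else "DistalIntergenic"
      }
    out$category[i] <- cat
  }
  out
}

# Exhaustive background score distribution of a PWM: every one of the
# 4^w words, scored directly off the log-odds matrix. With eps set, the
# per-position scores are integerized exactly as the DP does, so the two
# routes are comparable to floating-point accuracy.
enumerateMotifScores <- function(pwm, eps = NULL) {
  S <- pwmLogOdds(pwm)
  if (!is.null(eps)) S <- round(S / eps)
  w <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- rowSums(matrix(S[cbind(as.vector(words),
                                  rep(seq_len(w), each = nrow(words)))],
                          nrow = nrow(words)))
  prob <- apply(words, 1, function(idx) prod(pwm@background[idx]))
  list(score = score, prob = prob)
}

# Random non-degenerate PWM for property tests
randomPwm <- function(w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rgamma(4 * w, shape = 1) + 0.05, nrow = 4)
  bg <- stats::rgamma(4, shape = 2) + 0.2
  motifMatrix(counts, background = bg / sum(bg), pseudocount = 0.1)
}

# Minimal single-gene fixture used by several annotation tests
oneGeneFixture <- function(strand = "+", txStart = 10000, txEnd = 12000) {
  geneModels("g1", "chr1", strand, txStart, txEnd)
}

grPeak <- function(chrom, start0, end0, score = 0, name = "pk") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         name = name, score = score)
}
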