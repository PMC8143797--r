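test_that("log-odds construction matches hand arithmetic", {
  # uniform PWM against a uniform background scores zero everywhere
  uni <- motifMatrix(matrix(1, 4, 3), pseudocount = 0)
  expect_true(all(abs(pwmLogOdds(uni)) < 1e-12))
  # a certain base with no pseudocount scores log2(4) = 2 bits
  certain <- motifMatrix(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(pwmLogOdds(certain)["A", 1]), 2)
  # pseudocount 1 on counts (4,0,0,0): P(A) = 4.25/5, score log2(3.4)
  pc <- motifMatrix(matrix(c(4, 0, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(unname(pc@probs["A", 1]), 0.85)
  expect_equal(unname(pwmLogOdds(pc)["A", 1]), log2(3.4))
  expect_error(motifMatrix(matrix(1, 4, 2), background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("DP score distribution equals exhaustive enumeration", {
  eps <- 1e-3
  for (i in 1:12) {
    pwm <- randomPwm(w = sample(2:5, 1), seed = 300 + i)
    d <- fusionomics:::.scoreDistribution(pwm, eps = eps)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    # enumerate all words on the same integerized score grid as the DP
    enum <- enumerateMotifScores(pwm, eps = eps)
    for (t in unique(stats::quantile(enum$score, c(0, 0.3, 0.7, 0.95, 1),
                                     type = 1))) {
      brute <- sum(enum$prob[enum$score >= t])
      dp <- d$tail[t - d$support[1] + 1]
      expect_equal(dp, brute, tolerance = 1e-9)
    }
    # the integerized grid distorts any word's score by at most w * eps
    enumReal <- enumerateMotifScores(pwm)
    expect_lt(max(abs(enumReal$score - eps * enum$score)),
              motifWidth(pwm) * eps)
  }
})

test_that("score p-values are monotone with correct boundary behaviour", {
  pwm <- randomPwm(4, seed = 330)
  enum <- enumerateMotifScores(pwm)
  s <- seq(min(enum$score), max(enum$score), length.out = 40)
  p <- motifScorePvalue(pwm, s)
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(motifScorePvalue(pwm, min(enum$score) - 1), 1)
  expect_equal(motifScorePvalue(pwm, max(enum$score) + 1), 0)
  # p-value of the single best word is the product of its background probs
  Si <- round(pwmLogOdds(pwm) / 1e-3)
  best <- apply(Si, 2, which.max)
  expect_equal(motifScorePvalue(pwm, 1e-3 * sum(Si[cbind(best, seq_along(best))])),
               prod(pwm@background[best]), tolerance = 1e-9)
})

test_that("scanning finds a planted consensus site at its exact offset", {
  set.seed(31)
  pwm <- motifMatrix(matrix(c(20, 1, 1, 1,  1, 20, 1, 1,  1, 1, 20, 1,
                              1, 1, 1, 20,  20, 1, 1, 1,  1, 20, 1, 1,
                              1, 1, 20, 1), 4), pseudocount = 0.1) # ACGTACG
  backbone <- paste(sample(c("A", "C", "G", "T"), 40, TRUE,
                           prob = c(0.1, 0.4, 0.4, 0.1)), collapse = "")
  seq <- paste0(substr(backbone, 1, 5), "ACGTACG", substr(backbone, 13, 40))
  hits <- scanSequence(seq, pwm, pThreshold = 1e-4)
  expect_true(any(hits$offset == 5 & hits$strand == "+"))
  # an all-N sequence yields nothing, as does a too-short one
  expect_equal(nrow(scanSequence(strrep("N", 30), pwm)), 0)
  expect_equal(nrow(scanSequence("ACG", pwm)), 0)
  expect_error(scanSequence(seq, pwm, pThreshold = 0), "pThreshold")
})

test_that("strand handling is self-consistent under reverse complement", {
  set.seed(32)
  pwm <- randomPwm(5, seed = 340)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  rcSeq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scanSequence(seq, pwm, pThreshold = 0.05)
  h2 <- scanSequence(rcSeq, pwm, pThreshold = 0.05)
  # hits on the reverse complement are the mirrored hits of the original
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(seq); w <- motifWidth(pwm)
  mapped <- sort(L - w - h2$offset)
  expect_equal(sort(h1$offset), mapped)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("palindromic planted sites report both strands at one locus", {
  # GAATTC is its own reverse complement
  counts <- matrix(1, 4, 6)
  word <- c("G", "A", "A", "T", "T", "C")
  for (j in 1:6) counts[match(word[j], c("A", "C", "G", "T")), j] <- 30
  pwm <- motifMatrix(counts, pseudocount = 0.1)
  seq <- paste0(strrep("C", 10), "GAATTC", strrep("C", 10))
  hits <- scanSequence(seq, pwm, pThreshold = 1e-3)
  expect_setequal(hits$strand[hits$offset == 10], c("+", "-"))
})

test_that("peak motif proportion recovers a planted occupancy fraction", {
  toy <- makeToyGenome(33, nGenes = 20)
  pwm <- fusionomics:::.teadMotif()
  sim <- simulatePeaks(33, toy, nPeaks = 200, promoterFraction = 0.3,
                       motif = pwm, motifPlantRate = 0.58)
  res <- peakMotifProportion(sim$peaks, sim$genome, pwm, 1e-4)
  expect_true(all(res$hasMotif[sim$peaks$planted_motif]))
  expect_equal(res$percent, 58, tolerance = 5)
  # peaks past the contig end are an error naming the peak
  bad <- grPeak("chr1", Biostrings::width(toy$genome) - 50,
                Biostrings::width(toy$genome) + 50)
  expect_error(peakMotifProportion(bad, toy$genome, pwm), "beyond contig end")
})

test_that("MEME and PFM readers reconstruct the written motif", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF TEAD1", "letter-probability matrix: alength= 4 w= 3",
               " 0.97 0.01 0.01 0.01",
               " 0.01 0.01 0.97 0.01",
               " 0.25 0.25 0.25 0.25"), f)
  motifs <- readMemeMotifs(f, pseudocount = 0)
  expect_equal(names(motifs), "TEAD1")
  expect_equal(motifWidth(motifs$TEAD1), 3)
  expect_equal(unname(motifs$TEAD1@probs["A", 1]), 0.97)
  expect_equal(unname(motifs$TEAD1@background), c(0.3, 0.2, 0.2, 0.3))
  fp <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c("A\t8\t0", "C\t0\t8", "G\t2\t1", "T\t0\t1"), fp)
  pfm <- readPfm(fp, name = "toy", pseudocount = 0)
  expect_equal(unname(pfm@probs["A", 1]), 0.8)
  expect_equal(unname(pfm@probs["C", 2]), 0.8)
})

test_that("set-level enrichment reduces to the 2x2 exact test", {
  res <- motifEnrichmentTest(rep(c(TRUE, FALSE), c(58, 42)),
                             rep(c(TRUE, FALSE), c(10, 90)))
  expect_gt(res$oddsRatio, 1)
  expect_lt(res$pvalue, 1e-6)
  expect_equal(sum(res$table), 200)
})
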