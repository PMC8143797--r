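test_that("worked examples: signed distance and promoter category", {
  gm <- geneModels("g1", "chr1", "+", 1000, 3000)
  ann <- annotatePeaks(grPeak("chr1", 900, 950), gm)
  expect_equal(ann$tss_distance, -75)        # midpoint 925, TSS 1000
  expect_equal(as.character(ann$category), "Promoter<=1kb")
  # midpoint exactly at the TSS
  at <- annotatePeaks(grPeak("chr1", 990, 1010), gm)
  expect_equal(at$tss_distance, 0)
  expect_equal(as.character(at$category), "Promoter<=1kb")
  # 4.5 kb beyond the only TSS and outside the gene body
  far <- annotatePeaks(grPeak("chr1", 7400, 7600), gm)   # midpoint 7500
  expect_equal(as.character(far$category), "DistalIntergenic")
  expect_error(annotatePeaks(grPeak("chr1", 1, 10),
                             geneModels(character(0), character(0),
                                        character(0), numeric(0), numeric(0))),
               "empty")
})

test_that("signed distance is strand-aware and upstream is negative", {
  gm <- geneModels("g1", "chr1", "-", 1000, 3000)    # TSS at 2999
  up <- annotatePeaks(grPeak("chr1", 3400, 3500), gm)  # midpoint 3450, 5' side
  expect_equal(up$tss_distance, -451)
  dn <- annotatePeaks(grPeak("chr1", 2500, 2600), gm)  # midpoint 2550, inside
  expect_equal(dn$tss_distance, 449)
})

test_that("category precedence runs promoter > exon/intron > downstream > distal", {
  exons <- list(g1 = rbind(c(10000, 10400), c(14000, 14600)))
  gm <- geneModels("g1", "chr1", "+", 10000, 16000, exons = exons)
  # inside an exon, > 3 kb from the TSS
  expect_equal(as.character(annotatePeaks(grPeak("chr1", 14100, 14300),
                                          gm)$category), "Exon")
  # inside the body, outside exons, > 3 kb from the TSS
  expect_equal(as.character(annotatePeaks(grPeak("chr1", 15000, 15200),
                                          gm)$category), "Intron")
  # within 3 kb of the TSS wins over the exon category
  expect_equal(as.character(annotatePeaks(grPeak("chr1", 12000, 12200),
                                          gm)$category), "Promoter1-3kb")
  # just past the 3' end
  expect_equal(as.character(annotatePeaks(grPeak("chr1", 17000, 17200),
                                          gm)$category), "Downstream<=3kb")
  # without exon structure the body collapses to GeneBody
  gmNoEx <- geneModels("g1", "chr1", "+", 10000, 16000)
  expect_equal(as.character(annotatePeaks(grPeak("chr1", 14100, 14300),
                                          gmNoEx)$category), "GeneBody")
})

test_that("nearest-gene ties break to the smaller gene_id", {
  gm <- geneModels(c("gB", "gA"), c("chr1", "chr1"), c("+", "+"),
                   c(1000, 3000), c(2000, 4000))
  # midpoint 2000 is equidistant (1000) from both TSSs
  ann <- annotatePeaks(grPeak("chr1", 1950, 2050), gm)
  expect_equal(ann$nearest_gene, "gA")
})

test_that("peaks on chromosomes absent from the annotation stay unassigned", {
  gm <- oneGeneFixture()
  ann <- annotatePeaks(grPeak("chrUn", 100, 300), gm)
  expect_true(is.na(ann$nearest_gene))
  expect_equal(as.character(ann$category), "DistalIntergenic")
  expect_equal(length(assignPeaksToGenes(ann)$genes), 0)
})

test_that("annotation agrees with a brute-force all-pairs scan", {
  set.seed(21)
  nGenes <- 120
  chrom <- sample(c("chr1", "chr2"), nGenes, replace = TRUE)
  s <- sample(0:800000, nGenes)
  gm <- geneModels(sprintf("g%03d", seq_len(nGenes)), chrom,
                   sample(c("+", "-"), nGenes, TRUE), s, s + sample(500:8000, nGenes))
  pChrom <- sample(c("chr1", "chr2", "chr3"), 400, replace = TRUE)
  p0 <- sample(0:820000, 400)
  peaks <- grPeak(pChrom, p0, p0 + sample(50:600, 400))
  ann <- annotatePeaks(peaks, gm)
  ref <- bruteAnnotate(peaks, gm)
  expect_equal(ann$nearest_gene, ref$gene)
  expect_equal(ann$tss_distance, ref$dist)
  expect_equal(as.character(ann$category), ref$category)
})

test_that("every peak gets exactly one category and fractions sum to one", {
  set.seed(22)
  toy <- makeToyGenome(22, nGenes = 40)
  sim <- simulatePeaks(22, toy, nPeaks = 300, promoterFraction = 0.4)
  ann <- annotatePeaks(sim$peaks, toy$genes)
  expect_false(anyNA(ann$category))
  cd <- categoryDistribution(ann)
  expect_equal(sum(cd$categoryFraction), 1, tolerance = 1e-12)
  expect_equal(sum(cd$distanceBinFraction), 1, tolerance = 1e-12)
  # planted promoter/distal design is recovered within a sampling bound
  expect_equal(unname(cd$distanceBinFraction[["0-1kb"]]), 0.4, tolerance = 0.03)
})

test_that("category distribution survives coordinate reflection with strand flip", {
  set.seed(23)
  L <- 1000000
  nG <- 30
  s <- sort(sample(seq(5000, L - 15000, by = 9000), nG))
  strands <- sample(c("+", "-"), nG, TRUE)
  gm <- geneModels(sprintf("g%02d", 1:nG), rep("chr1", nG), strands, s, s + 2000)
  p0 <- sample(0:(L - 500), 250)
  peaks <- grPeak("chr1", p0, p0 + 300)
  cd <- categoryDistribution(annotatePeaks(peaks, gm))
  # reflect all coordinates about L and flip every strand; gene bodies get
  # the +1 shift that keeps midpoint-TSS distances exact under the
  # half-open convention
  flip <- c("+" = "-", "-" = "+")
  gmR <- geneModels(sprintf("g%02d", 1:nG), rep("chr1", nG),
                    unname(flip[strands]), L - (s + 2000) + 1, L - s + 1)
  peaksR <- grPeak("chr1", L - (p0 + 300), L - p0)
  cdR <- categoryDistribution(annotatePeaks(peaksR, gmR))
  expect_equal(cd$categoryFraction, cdR$categoryFraction)
  expect_equal(cd$distanceBinFraction, cdR$distanceBinFraction)
})

test_that("TSS profile geometry: central bins, orientation and conservation", {
  gm <- geneModels("g1", "chr1", "+", 50000, 52000)     # TSS at 50000
  peak <- grPeak("chr1", 50000 - 30, 50000 + 30)
  prof <- tssProfile(peak, gm, window = 3000, bins = 100)
  nz <- which(prof$matrix[1, ] > 0)
  expect_equal(nz, c(50, 51))                  # the two central 60-bp bins
  expect_equal(unname(prof$matrix[1, nz]), c(30, 30))
  # no peaks -> zero matrix
  prof0 <- tssProfile(GenomicRanges::GRanges(), gm, 3000, 100)
  expect_true(all(prof0$matrix == 0))
  # minus-strand gene: an upstream peak lands on the negative-x side
  gmM <- geneModels("g1", "chr1", "-", 50000, 52000)    # TSS at 51999
  up <- grPeak("chr1", 52500, 52700)                    # 5' of the TSS
  profM <- tssProfile(up, gmM, 3000, 100)
  expect_true(all(which(profM$matrix[1, ] > 0) < 50))
  expect_error(tssProfile(peak, gm, window = 3000, bins = 7), "divisible")
})

test_that("TSS profile mass is conserved across compatible binnings", {
  set.seed(24)
  toy <- makeToyGenome(24, nGenes = 30)
  sim <- simulatePeaks(24, toy, nPeaks = 150, promoterFraction = 0.5)
  m1 <- tssProfile(sim$peaks, toy$genes, 3000, 100)
  m2 <- tssProfile(sim$peaks, toy$genes, 3000, 60)
  expect_equal(sum(m1$matrix), sum(m2$matrix), tolerance = 1e-9)
})

test_that("peak-set overlap fraction counts A peaks hit by B", {
  a <- grPeak("chr1", 0, 100)
  b <- grPeak("chr1", 50, 150)
  expect_equal(peakSetOverlapFraction(a, b), 100)
  expect_equal(peakSetOverlapFraction(a, grPeak("chr1", 500, 600)), 0)
  set.seed(25)
  s <- seq(0, 99000, by = 1000)
  A <- grPeak("chr1", s, s + 200)
  hit <- sample(100, 69)
  B <- grPeak("chr1", s[hit] + 100, s[hit] + 400)
  expect_equal(peakSetOverlapFraction(A, B), 69)
  expect_error(peakSetOverlapFraction(GenomicRanges::GRanges(), B), "empty")
})

test_that("gene assignment de-duplicates and keeps the max peak score", {
  gm <- oneGeneFixture(txStart = 10000, txEnd = 12000)
  pk <- grPeak("chr1", c(9500, 9900, 10100), c(9700, 10100, 10300),
               score = c(10, 50, 30))
  ann <- annotatePeaks(pk, gm)
  asg <- assignPeaksToGenes(ann)
  expect_equal(asg$genes, "g1")
  expect_equal(asg$table$n_peaks, 3)
  expect_equal(asg$table$max_score, 50)
})

test_that("nearest-edge anchoring reports zero distance for TSS-covering peaks", {
  gm <- geneModels("g1", "chr1", "+", 1000, 3000)
  covering <- annotatePeaks(grPeak("chr1", 900, 1200), gm, anchor = "nearest-edge")
  expect_equal(covering$tss_distance, 0)
  before <- annotatePeaks(grPeak("chr1", 400, 600), gm, anchor = "nearest-edge")
  expect_equal(before$tss_distance, -401)     # nearest edge is end - 1 = 599
})
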