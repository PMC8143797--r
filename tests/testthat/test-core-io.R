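test_that("BED reading maps columns and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tpk1\t25", "chr2\t500\t650"), f)
  gr <- readPeakBed(f)
  expect_equal(length(gr), 2)
  expect_equal(GenomicRanges::start(gr)[1], 1)   # 0-based file -> 1-based GRanges
  expect_equal(GenomicRanges::end(gr)[1], 100)
  expect_equal(gr$name[1], "pk1")
  expect_equal(gr$score, c(25, 0))
})

test_that("BED reading rejects malformed lines with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t50"), f)
  expect_error(readPeakBed(f), "line 2.*end <= start")
  writeLines(c("chr1\tx\t100"), f)
  expect_error(readPeakBed(f), "line 1.*non-integer")
  writeLines(character(0), f)
  expect_equal(length(readPeakBed(f)), 0)
})

test_that("BED write then read is the identity on coordinates and fields", {
  f <- withr::local_tempfile(fileext = ".bed")
  gr <- grPeak("chr3", c(0, 1000, 99999), c(200, 1500, 100100),
               score = c(1.5, 0, 33), name = c("a", "b", "c"))
  writePeakBed(gr, f)
  back <- readPeakBed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$name, gr$name)
  expect_equal(back$score, gr$score)
})

test_that("GTF coordinates are converted and the strand-aware TSS derived", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gp";',
    'chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tgene_id "gm";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "gp";',
    'chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tgene_id "gp";'), f)
  gm <- readGeneModels(f)
  g <- genes(gm)
  # internal length equals GTF end - start + 1
  expect_equal(GenomicRanges::width(g), c(1000, 1000))
  tss <- tssPositions(gm)
  tss0 <- GenomicRanges::start(tss) - 1
  expect_equal(unname(tss0[match("gp", names(tss))]), 1000)
  expect_equal(unname(tss0[match("gm", names(tss))]), 1999)
  expect_equal(length(exonsBy(gm)[["gp"]]), 2)
})

test_that("gene models round-trip through the GTF writer", {
  gm <- geneModels(c("a1", "b2"), c("chr1", "chr2"), c("+", "-"),
                   c(100, 5000), c(600, 9000),
                   exons = list(a1 = rbind(c(100, 200), c(400, 600))))
  f <- withr::local_tempfile(fileext = ".gtf")
  writeGeneModels(gm, f)
  back <- readGeneModels(f)
  ord <- match(geneIds(gm), geneIds(back))
  expect_equal(GenomicRanges::start(genes(back))[ord],
               GenomicRanges::start(genes(gm)))
  expect_equal(GenomicRanges::end(genes(back))[ord],
               GenomicRanges::end(genes(gm)))
  expect_equal(as.character(GenomicRanges::strand(genes(back)))[ord],
               as.character(GenomicRanges::strand(genes(gm))))
  expect_equal(length(exonsBy(back)[["a1"]]), 2)
})

test_that("minus-strand TSS is the right body edge for random gene models", {
  set.seed(7)
  for (rep in 1:30) {
    s <- sample(0:100000, 1); e <- s + sample(100:5000, 1)
    gm <- oneGeneFixture(strand = "-", txStart = s, txEnd = e)
    expect_equal(GenomicRanges::start(tssPositions(gm)) - 1, e - 1)
  }
})

test_that("DEG tables parse, flag missing padj, and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj",
               "g1\t1.2\t0.001\t0.01", "g2\t-0.5\t0.2\tNA",
               "g3\t0.1\t0.9\t0.95"), f)
  deg <- readDegTable(f)
  expect_equal(nrow(deg), 3)
  expect_true(is.na(deg$padj[2]))
  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj",
               "g1\t1\t0.1\t0.2", "g1\t2\t0.1\t0.2"), f)
  expect_error(readDegTable(f), "duplicate gene_id")
})

test_that("DEG write then read is the identity", {
  df <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.25, -3),
                   pvalue = c(1e-5, 0.2), padj = c(1e-4, NA),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDegTable(df, f)
  expect_equal(readDegTable(f), df)
})

test_that("prey tables split replicate counts and validate ranges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("bait\tprey\tcounts\trelative_abundance\tprobability\tbfdr",
               "TC\tYEATS2\t12|3\t0.5\t0.99\t0.001"), f)
  p <- readPreyTable(f)
  expect_equal(p$count_r1, 12)
  expect_equal(p$count_r2, 3)
  expect_equal(p$max_count, 12)
  writeLines(c("bait\tprey\tcounts\trelative_abundance\tprobability\tbfdr",
               "TC\tX\t-1|3\t0.5\t0.99\t0.001"), f)
  expect_error(readPreyTable(f), "non-negative")
  writeLines(c("bait\tprey\tcounts\trelative_abundance\tprobability\tbfdr",
               "TC\tX\t1|3\t0.5\t1.99\t0.001"), f)
  expect_error(readPreyTable(f), "\\[0, 1\\]")
})

test_that("prey write then read is the identity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("bait\tprey\tcounts\trelative_abundance\tprobability\tbfdr",
               "TC\tA\t12|3\t0.5\t0.99\t0.001",
               "YT\tB\t0|44\t0.25\t0.97\t0.2"), f)
  p <- readPreyTable(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePreyTable(p, f2)
  expect_equal(readPreyTable(f2), p)
})

test_that("growth tables validate days and absorbance", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "cell_line\tconstruct\tgene\treplicate\tday\tabsorbance"
  writeLines(c(hdr, "SW\tshEV\tcontrol\tr1\t0\t0.2",
               "SW\tshEV\tcontrol\tr1\t10\t1.0"), f)
  g <- readGrowthTable(f)
  expect_equal(nrow(g), 2)
  writeLines(c(hdr, "SW\tshEV\tcontrol\tr1\t-1\t0.2"), f)
  expect_error(readGrowthTable(f), "non-negative integer")
  writeLines(c(hdr, "SW\tshEV\tcontrol\tr1\t0\t0"), f)
  expect_error(readGrowthTable(f), "positive")
})

test_that("FASTA input is upper-cased and alphabet-checked", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description", "acgtn"), f)
  g <- readGenome(f)
  expect_equal(as.character(g[["chr1"]]), "ACGTN")
  expect_equal(names(g), "chr1")
})

test_that("report writer emits TSV for tables and JSON for lists", {
  d <- withr::local_tempdir()
  df <- data.frame(x = 1:2, y = c("a", "b"))
  writeReport(df, file.path(d, "t.tsv"))
  expect_equal(utils::read.delim(file.path(d, "t.tsv"))$x, 1:2)
  writeReport(list(pct = 70.25), file.path(d, "r.json"))
  expect_equal(jsonlite::read_json(file.path(d, "r.json"))$pct, 70.25)
})
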