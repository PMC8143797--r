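test_that("pmf, tail and HGD match the enumerated toy configuration", {
  # C(10,5) = 252 draws; 120 contain exactly 2 of the 4 marked items,
  # 186 contain 2 or more
  expect_equal(hypergeomPmf(2, 4, 5, 10), 120 / 252, tolerance = 1e-12)
  expect_equal(hypergeomTail(2, 4, 5, 10), 186 / 252, tolerance = 1e-12)
  expect_equal(hgd(2, 4, 5, 10), -log10(120 / 252), tolerance = 1e-10)
})

test_that("degenerate configurations follow the support rules", {
  expect_equal(hypergeomPmf(0, 0, 5, 10), 1)
  expect_equal(hypergeomPmf(5, 4, 5, 10), 0)
  expect_equal(hypergeomTail(0, 4, 5, 10), 1)
  # single-point tail at the top of the support
  expect_equal(hypergeomTail(4, 4, 5, 10), hypergeomPmf(4, 4, 5, 10))
  expect_equal(hgd(0, 0, 5, 10), 0)         # pmf = 1 configuration
  expect_identical(hgd(5, 4, 5, 10), Inf)   # impossible -> explicit Inf
  expect_error(hypergeomPmf(2, 12, 5, 10), "K > N")
  expect_error(hypergeomPmf(2, 4, 15, 10), "n > N")
})

test_that("log-space pmf agrees with the exact prime-factorization oracle", {
  set.seed(101)
  for (rep in 1:120) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    k <- if (length(ks) == 1) ks else sample(ks, 1)
    expect_equal(hypergeomPmf(k, K, n, N), exactHyperPmf(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("pmf sums to one over the support and matches stats::dhyper", {
  set.seed(102)
  for (rep in 1:40) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    support <- max(0, n - (N - K)):min(K, n)
    p <- hypergeomPmf(support, K, n, N)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, stats::dhyper(support, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("tail telescoping and the exclusive compatibility mode hold", {
  set.seed(103)
  for (rep in 1:25) {
    N <- sample(20:80, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    ks <- max(0, n - (N - K)):(min(K, n) - 1)
    k <- if (length(ks) == 1) ks else sample(ks, 1)
    # absolute tolerance: the difference of two O(1) tails carries the
    # usual cancellation error even though the identity is exact
    expect_lt(abs(hypergeomTail(k, K, n, N) - hypergeomTail(k + 1, K, n, N) -
                    hypergeomPmf(k, K, n, N)), 1e-12)
    # exclusive mode is the upper-tail CDF that drops the boundary point
    expect_equal(hypergeomTail(k, K, n, N, mode = "exclusive"),
                 stats::phyper(k, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("HGD increases with overlap size beyond the mode", {
  K <- 400; n <- 300; N <- 2000
  mode <- floor((n + 1) * (K + 1) / (N + 2))
  ks <- mode:min(K, n)
  h <- hgd(ks, K, n, N)
  expect_true(all(diff(h) > 0))
})

test_that("extreme overlaps keep full precision far beyond double underflow", {
  # a configuration whose density underflows on the linear scale
  h <- hgd(900, 1000, 950, 20000)
  expect_true(is.finite(h) && h > 400)
  expect_equal(hypergeomPmf(900, 1000, 950, 20000), 0)  # linear scale underflows
  expect_equal(h, -stats::dhyper(900, 1000, 19000, 950, log = TRUE) / log(10),
               tolerance = 1e-10)
})

test_that("overlapTest intersects with an explicit population vector", {
  pop <- paste0("g", 1:50)
  ot <- overlapTest(c(pop[1:10], "absent1"), c(pop[6:20], "absent2"), pop)
  expect_equal(ot@k, 5L)
  expect_equal(ot@n, 10L)     # identifiers outside the population dropped
  expect_equal(ot@K, 15L)
  expect_equal(ot@N, 50L)
  expect_true(validObject(ot))
})

test_that("venn partition reproduces the hand-enumerated 3-set system", {
  v <- vennPartition(list(A = c(1, 2, 3, 4), B = c(3, 4, 5), C = c(4, 5, 6)))
  expect_equal(v$regions[["A"]], 2)
  expect_equal(v$regions[["B"]], 0)
  expect_equal(v$regions[["C"]], 1)
  expect_equal(v$regions[["A&B"]], 1)
  expect_equal(v$regions[["A&C"]], 0)
  expect_equal(v$regions[["B&C"]], 1)
  expect_equal(v$regions[["A&B&C"]], 1)
  expect_equal(sum(v$regions), v$unionSize)
  expect_equal(v$unionSize, 6)
})

test_that("venn partition handles identical and disjoint inputs", {
  same <- vennPartition(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(same$regions[["X&Y"]], 5)
  expect_equal(sum(same$regions), 5)
  disj <- vennPartition(list(X = letters[1:3], Y = letters[4:6], Z = letters[7]))
  expect_equal(unname(disj$regions[c("X", "Y", "Z")]), c(3, 3, 1))
  expect_equal(sum(disj$regions[grepl("&", names(disj$regions))]), 0)
  expect_error(vennPartition(list(A = 1, B = 2, C = 3, D = 4)), "2 or 3")
})

test_that("venn regions reconstruct every input set's cardinality", {
  set.seed(104)
  for (rep in 1:50) {
    sets <- list(A = sample(letters, sample(3:20, 1)),
                 B = sample(letters, sample(3:20, 1)),
                 C = sample(letters, sample(3:20, 1)))
    v <- vennPartition(sets)
    for (lab in names(sets)) {
      inRegions <- sum(v$regions[grepl(lab, names(v$regions), fixed = TRUE)])
      expect_equal(inRegions, length(unique(sets[[lab]])))
    }
    expect_equal(sum(v$regions), v$unionSize)
  }
})

test_that("overlap fraction is the plain query-normalized percentage", {
  expect_equal(overlapFraction(paste0("g", 1:10), paste0("g", 8:30)), 30)
  expect_equal(overlapFraction(letters[1:4], letters), 100)
  expect_error(overlapFraction(character(0), letters), "empty query")
})

test_that("overlapReport emits one row per reference with shared percents", {
  rep <- overlapReport(letters[1:10],
                       list(big = letters[1:20], small = letters[9:12]),
                       population = 100, queryLabel = "Q")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$pct_of_query, c(100, 20))
  expect_equal(rep$hgd, c(hgd(10, 20, 10, 100), hgd(2, 4, 10, 100)))
})
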