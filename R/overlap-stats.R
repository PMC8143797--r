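#' Hypergeometric point probability
#'
#' P(X = k) for the number of shared identifiers when a query set of size
#' \code{n} is drawn without replacement from a population of \code{N}
#' genes containing \code{K} reference genes:
#' \deqn{P(X=k) = \frac{{K \choose k}{N-K \choose n-k}}{{N \choose n}}.}
#' All combinatorics are evaluated in log-gamma space so extreme overlaps
#' (densities far below double underflow on the linear scale, HGD >> 300)
#' remain representable through \code{hypergeomLogPmf}.
#'
#' Impossible configurations (\code{k > min(K, n)} or more failures than the
#' population can supply) return probability 0; \code{K > N} or \code{n > N}
#' is an error.
#'
#' @param k overlap size (non-negative integer)
#' @param K reference (success) set size
#' @param n query (draw) set size
#' @param N population size
#' @return probability in [0, 1]; vectorized over \code{k}
#' @examples
#' hypergeomPmf(2, 4, 5, 10)   # 120/252
#' @export
hypergeomPmf <- function(k, K, n, N) {
  exp(hypergeomLogPmf(k, K, n, N))
}

#' @rdname hypergeomPmf
#' @return \code{hypergeomLogPmf}: natural-log probability (-Inf when impossible)
#' @export
hypergeomLogPmf <- function(k, K, n, N) {
  .checkHyperConfig(K, n, N)
  k <- as.numeric(k)
  out <- rep(-Inf, length(k))
  ok <- k >= 0 & k <= pmin(K, n) & (n - k) <= (N - K)
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  }
  out
}

.checkHyperConfig <- function(K, n, N) {
  if (any(c(K, n, N) < 0) || any(c(K, n, N) != floor(c(K, n, N))))
    stop("K, n and N must be non-negative integers")
  if (K > N) stop("reference set larger than population (K > N)")
  if (n > N) stop("query set larger than population (n > N)")
  invisible(TRUE)
}

#' Hypergeometric enrichment tail probability
#'
#' Upper-tail probability of observing the overlap \code{k} or a more
#' extreme one. The default, \code{mode = "inclusive"}, is the standard
#' enrichment p-value P(X >= k). \code{mode = "exclusive"} returns
#' P(X > k), the value produced by passing the observed overlap directly
#' to an upper-tail CDF that excludes the boundary; use it to reproduce
#' published p-values computed that way.
#'
#' @inheritParams hypergeomPmf
#' @param mode "inclusive" (P(X >= k), default) or "exclusive" (P(X > k))
#' @param log.p return the natural-log probability
#' @return probability (or log probability)
#' @examples
#' hypergeomTail(2, 4, 5, 10)   # 186/252
#' @export
hypergeomTail <- function(k, K, n, N, mode = c("inclusive", "exclusive"),
                          log.p = FALSE) {
  mode <- match.arg(mode)
  .checkHyperConfig(K, n, N)
  vapply(as.numeric(k), function(ki) {
    from <- if (mode == "inclusive") ki else ki + 1
    hi <- min(K, n)
    if (from > hi) return(if (log.p) -Inf else 0)
    lp <- hypergeomLogPmf(seq(from, hi), K, n, N)
    m <- max(lp)
    tot <- m + log(sum(exp(lp - m)))
    if (log.p) tot else min(1, exp(tot))
  }, numeric(1))
}

#' Hypergeometric density on the -log10 scale (HGD)
#'
#' The overlap-strength statistic used throughout the package:
#' \code{-log10 P(X = k)}. Computed from the log-space pmf so values far
#' beyond 300 are exact to double precision. An impossible configuration
#' (density 0) yields \code{Inf}, reported explicitly rather than as an
#' overflow.
#'
#' @inheritParams hypergeomPmf
#' @return non-negative numeric (possibly \code{Inf})
#' @examples
#' hgd(2, 4, 5, 10)
#' @export
hgd <- function(k, K, n, N) {
  -hypergeomLogPmf(k, K, n, N) / log(10)
}

#' Overlap test between two gene sets
#'
#' Convenience constructor: intersects \code{query} and \code{reference}
#' identifier sets within a population of size \code{N} (or an explicit
#' population identifier vector) and returns an \linkS4class{OverlapTest}
#' with density, enrichment tail p and HGD.
#'
#' @param query,reference character vectors of identifiers
#' @param population population size (single number) or identifier vector;
#'   when a vector, sets are intersected with it first
#' @param mode tail convention, see \code{\link{hypergeomTail}}
#' @param queryLabel,referenceLabel report labels
#' @return an \linkS4class{OverlapTest}
#' @export
overlapTest <- function(query, reference, population,
                        mode = c("inclusive", "exclusive"),
                        queryLabel = "query", referenceLabel = "reference") {
  mode <- match.arg(mode)
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  if (length(population) > 1L || is.character(population)) {
    population <- unique(as.character(population))
    query <- intersect(query, population)
    reference <- intersect(reference, population)
    N <- length(population)
  } else {
    N <- as.integer(population)
  }
  k <- length(intersect(query, reference))
  K <- length(reference)
  n <- length(query)
  new("OverlapTest",
      k = as.integer(k), K = as.integer(K), n = as.integer(n), N = as.integer(N),
      density = hypergeomPmf(k, K, n, N),
      tailP = hypergeomTail(k, K, n, N, mode = mode),
      tailMode = mode,
      hgd = hgd(k, K, n, N),
      query = queryLabel, reference = referenceLabel)
}

#' Percentage of a query gene set found in a reference set
#'
#' \code{100 * |query intersect reference| / |query|}. Full precision is
#' returned; report tables round to the nearest integer for display.
#'
#' @param query non-empty character vector
#' @param reference character vector
#' @return percentage in [0, 100]
#' @export
overlapFraction <- function(query, reference) {
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("overlap fraction is undefined for an empty query set")
  100 * length(intersect(query, unique(as.character(reference)))) / length(query)
}

#' Exclusive region counts for 2 or 3 labelled sets
#'
#' Partitions the union of the input sets into the 2^m - 1 exclusive
#' regions of the m-set Venn diagram. Region names are the sorted set
#' labels joined by "&" (e.g. "A", "A&B", "A&B&C").
#'
#' @param sets named list of 2 or 3 character vectors
#' @return list with \code{regions} (named integer vector of exclusive
#'   counts), \code{setSizes}, \code{unionSize} and \code{members}
#'   (identifiers per region)
#' @export
vennPartition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list")
  m <- length(sets)
  if (m < 2L || m > 3L) stop("vennPartition supports 2 or 3 sets")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, names(sets)))
  labs <- names(sets)
  combos <- unlist(lapply(seq_len(m), function(r)
    utils::combn(labs, r, simplify = FALSE)), recursive = FALSE)
  members <- list()
  regions <- integer(length(combos))
  names(regions) <- vapply(combos, paste, "", collapse = "&")
  for (i in seq_along(combos)) {
    inside <- combos[[i]]
    sel <- if (length(universe)) {
      rowSums(membership[, inside, drop = FALSE]) == length(inside) &
        rowSums(membership[, setdiff(labs, inside), drop = FALSE]) == 0
    } else logical(0)
    regions[i] <- sum(sel)
    members[[names(regions)[i]]] <- universe[sel]
  }
  list(regions = regions,
       setSizes = vapply(sets, length, integer(1)),
       unionSize = length(universe),
       members = members)
}

#' Overlap panel report across several gene sets
#'
#' For one focal (query) set against each reference set, assembles the
#' per-pair overlap statistics printed in the package's report tables:
#' k, K, n, N, density, tail p, HGD and the percent of the query shared.
#'
#' @param query character vector (the focal gene set)
#' @param references named list of character vectors
#' @param population population size or identifier vector
#' @param mode tail convention
#' @param queryLabel label for the query column
#' @return data.frame, one row per reference
#' @export
overlapReport <- function(query, references, population,
                          mode = c("inclusive", "exclusive"),
                          queryLabel = "query") {
  mode <- match.arg(mode)
  rows <- lapply(names(references), function(lab) {
    ot <- overlapTest(query, references[[lab]], population, mode = mode,
                      queryLabel = queryLabel, referenceLabel = lab)
    data.frame(query = queryLabel, reference = lab,
               k = ot@k, K = ot@K, n = ot@n, N = ot@N,
               density = ot@density, tail_p = ot@tailP, hgd = ot@hgd,
               pct_of_query = 100 * ot@k / ot@n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
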