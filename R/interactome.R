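.defaultContaminants <- c("TRYPSIN", "BIOTIN", "STREPTAVIDIN")

#' Dotplot-ready filtered prey entries
#'
#' Applies the detection filters used for the proximity-interactome dot
#' plot: iProphet protein probability at least \code{minProbability},
#' maximum replicate spectral count at least \code{minCount}, and removal
#' of affinity-purification contaminants (trypsin, biotin, streptavidin).
#' BFDR values are tiered (<= 0.01, <= 0.05, > 0.05), the encoding used
#' downstream by the weak-interaction filter.
#'
#' @param preys data.frame from \code{\link{readPreyTable}}
#' @param minCount minimum spectral counts in at least one replicate
#'   (default 10)
#' @param minProbability protein-probability floor (default 0.95)
#' @param contaminants identifiers to exclude (case-insensitive match)
#' @return the retained rows with added \code{bfdr_tier} factor
#' @export
buildDotplot <- function(preys, minCount = 10, minProbability = 0.95,
                         contaminants = .defaultContaminants) {
  if (any(preys$count_r1 < 0 | preys$count_r2 < 0))
    stop("spectral counts must be non-negative")
  keep <- preys$probability >= minProbability &
    pmax(preys$count_r1, preys$count_r2) >= minCount &
    !(toupper(preys$prey) %in% toupper(contaminants))
  out <- preys[keep, , drop = FALSE]
  out$bfdr_tier <- cut(out$bfdr, breaks = c(-Inf, 0.01, 0.05, Inf),
                       labels = c("<=0.01", "<=0.05", ">0.05"))
  rownames(out) <- NULL
  out
}

#' Classify preys by fusion vs full-length interaction change
#'
#' Per prey, compares average spectral counts between a fusion bait's
#' dotplot and its cognate full-length control: increased when the ratio
#' exceeds \code{1 + delta}, decreased when below \code{1 - delta}, else
#' unchanged. A prey absent from the full-length table counts as
#' increased; absent from the fusion table, decreased. Preys in neither
#' table are not reported.
#'
#' @param fusionEntries,fullLengthEntries dotplot data.frames (one bait
#'   each)
#' @param delta relative dead-band around ratio 1 (default 0)
#' @return data.frame with columns prey, class
#' @export
compareToFullLength <- function(fusionEntries, fullLengthEntries, delta = 0) {
  f <- stats::setNames(fusionEntries$avg_count, fusionEntries$prey)
  l <- stats::setNames(fullLengthEntries$avg_count, fullLengthEntries$prey)
  preys <- union(names(f), names(l))
  cls <- vapply(preys, function(p) {
    inF <- p %in% names(f); inL <- p %in% names(l)
    if (inF && !inL) return("increased")
    if (!inF && inL) return("decreased")
    r <- f[[p]] / l[[p]]
    if (r > 1 + delta) "increased" else if (r < 1 - delta) "decreased"
    else "unchanged"
  }, character(1))
  data.frame(prey = preys, class = unname(cls), stringsAsFactors = FALSE)
}

#' Interactome prioritization cascade
#'
#' The ordered prioritization of the two fusion interactomes:
#' \enumerate{
#'   \item per fusion, drop preys with a decreased interaction relative
#'     to the cognate full-length bait;
#'   \item drop known Hippo pathway components;
#'   \item keep only preys with an increased interaction;
#'   \item intersect the two fusions' retained sets;
#'   \item drop weak interactions — preys in the lowest spectral-count
#'     and relative-abundance bins with BFDR > 0.05 in both fusion
#'     dotplots.
#' }
#' Counts at every step are reported; steps 1 and 3 are kept distinct so
#' the fate of unchanged preys is auditable.
#'
#' @param tc,yt dotplot data.frames for the two fusion baits
#' @param tcFull,ytFull dotplot data.frames for the cognate full-length
#'   baits
#' @param hippoGenes character vector of Hippo pathway components
#' @param delta dead-band for \code{\link{compareToFullLength}}
#' @param weakCountMax,weakAbundanceMax upper edges of the lowest
#'   dotplot bins (defaults 10 average counts, 0.1 relative abundance)
#' @return a \linkS4class{CascadeReport}
#' @export
cascadeFilter <- function(tc, yt, tcFull, ytFull, hippoGenes = character(0),
                          delta = 0, weakCountMax = 10,
                          weakAbundanceMax = 0.1) {
  for (nm in c("tc", "yt", "tcFull", "ytFull")) {
    tab <- get(nm)
    if (!is.data.frame(tab)) stop("missing bait table: ", nm)
  }
  steps <- list(); retained <- list()
  note <- function(step, bait, set) {
    steps[[length(steps) + 1]] <<- data.frame(step = step, bait = bait,
                                              n = length(set))
    retained[[paste(step, bait, sep = ":")]] <<- set
  }
  run <- function(fusion, full, bait) {
    cls <- compareToFullLength(fusion, full, delta)
    clsMap <- stats::setNames(cls$class, cls$prey)
    s0 <- fusion$prey
    note("detected", bait, s0)
    s1 <- s0[clsMap[s0] != "decreased"]
    note("minus decreased", bait, s1)
    s2 <- setdiff(s1, hippoGenes)
    note("minus Hippo", bait, s2)
    s3 <- s2[clsMap[s2] == "increased"]
    note("increased only", bait, s3)
    s3
  }
  tcSet <- run(tc, tcFull, "TC")
  ytSet <- run(yt, ytFull, "YT")
  shared <- sort(intersect(tcSet, ytSet))
  note("intersection", "shared", shared)
  isWeak <- function(tab, prey) {
    i <- match(prey, tab$prey)
    tier <- cut(tab$bfdr[i], breaks = c(-Inf, 0.01, 0.05, Inf),
                labels = c("<=0.01", "<=0.05", ">0.05"))
    tab$avg_count[i] < weakCountMax &
      tab$relative_abundance[i] < weakAbundanceMax & tier == ">0.05"
  }
  weak <- isWeak(tc, shared) & isWeak(yt, shared)
  final <- shared[!weak]
  note("minus weak", "shared", final)
  new("CascadeReport",
      steps = do.call(rbind, steps),
      retained = retained,
      final = final)
}

#' Functional composition of a prey set
#'
#' Percentage of preys per functional class under a user-supplied
#' prey-to-class map; unmapped preys fall into "other".
#'
#' @param preySet character vector of prey identifiers
#' @param categoryMap named character vector, prey -> class
#' @return named numeric percentages, descending, summing to 100
#' @export
compositionSummary <- function(preySet, categoryMap) {
  preySet <- unique(as.character(preySet))
  if (length(preySet) == 0L) stop("empty prey set")
  cls <- categoryMap[preySet]
  cls[is.na(cls)] <- "other"
  pct <- 100 * table(cls) / length(preySet)
  sort(stats::setNames(as.numeric(pct), names(pct)), decreasing = TRUE)
}
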