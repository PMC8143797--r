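---
title: "Methods: integrative set analysis for chimeric transcription factors"
author: "fusionomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative set analysis for chimeric transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionomics)
```

# Scope and model

`fusionomics` asks one question across five assay modalities: do two fusion
transcription factors drive a shared regulatory program? Every panel reduces
to operations on identifier sets (genes, peaks assigned to genes, preys),
and the package's statistical core is a single overlap model.

## Hypergeometric overlap and the HGD statistic

Let the gene universe hold $N$ genes, a reference set $K$ of them, and let a
query set of $n$ genes share $k$ with the reference. Under the null that the
query is an unstructured draw,

$$P(X = k) \;=\; \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

and the package reports both the enrichment tail $P(X \ge k)$ and the
overlap-strength statistic $\mathrm{HGD} = -\log_{10} P(X = k)$. For the
strongly structured overlaps this field produces, the tail is dominated by
the point density (the ratio of successive pmf terms decays geometrically
above the mode), so HGD and $-\log_{10} p$ travel together; the suite
verifies $-\log_{10}(\text{tail}) \in [\mathrm{HGD} - 0.5,\, \mathrm{HGD}]$
on randomized enriched configurations.

Two conventions needed deciding:

* **Tail boundary.** `hypergeomTail()` defaults to the inclusive enrichment
  p-value $P(X \ge k)$, the standard definition. An upper-tail CDF that
  excludes the boundary ($P(X > k)$) is common in practice when an observed
  overlap is passed directly to such a function, so a
  `mode = "exclusive"` switch reproduces values computed that way.
* **Population.** The gene universe is an explicit argument everywhere. For
  expression panels it is the genes with mean count $\ge$ 5 across all
  samples (`definePopulation()`, boundary inclusive); for peak-derived
  panels it is the union of genes annotated across conditions.

All combinatorics run through `lchoose` in log space; `hgd()` stays exact
when the density underflows doubles (values well beyond 300), and an
impossible configuration reports `Inf` explicitly rather than overflowing.

## DEG sets

`filterDegs()` keeps genes with adjusted $p <$ `alpha` (default 0.05,
strict). Missing adjusted p-values — the signature of upstream independent
filtering — count as not significant. The filter has no fold-change
component and ignores direction; overlaps are computed on identifiers. A
direction-concordant overlap would be a stricter, different question; since
the set definitions here are direction-free, concordance is left to the
caller (compute it on signed subsets of the tables).

`vstLikeTransform()` is median-of-ratios size-factor normalization followed
by $\log_2(x+1)$. It deliberately does not fit a dispersion model: its only
consumer is PCA geometry, and at the scales used here the geometry is
insensitive to the difference. The suite cross-checks the size factors
against the DESeq2 estimator on random matrices. PCA
(`pcaCoordinates()`) fixes each component's sign so the largest-magnitude
loading is positive, making coordinates stable across BLAS builds.

## Peak annotation

`annotatePeaks()` measures the distance from the peak **midpoint** (the
common annotation convention; `anchor = "nearest-edge"` is available) to
the nearest TSS, strand-aware and signed (negative = upstream on the gene's
strand). Nearest-gene ties break to the lexicographically smaller gene id
for determinism. Categories follow a fixed precedence:
promoter $\le$ 1 kb, promoter 1–3 kb, exon/intron (collapsing to a single
GeneBody category when the gene models carry no exon structure, as
synthetic annotations may), downstream $\le$ 3 kb past the gene 3' end,
else distal intergenic. The promoter windows are symmetric about the TSS —
the natural reading of a "within 1 kb of the TSS" definition when no
direction is stated. Peaks on chromosomes absent from the annotation are
distal with no gene and never enter gene sets.

`tssProfile()` bins peak base pairs into a $\pm W$ window around each TSS
($W = 3000$, 100 bins by default; $2W$ must be divisible by the bin count),
oriented 5'→3' per gene. Total profile mass is conserved across compatible
binnings, which the suite asserts.

## Motif scanning

Scores are $\log_2$ odds against a 0-order background. Each PWM cell is
regularized at construction with `pseudocount * background[base]` (default
total pseudocount 0.1 per column). The score p-value is exact: scores are
integerized at `eps` = 1/1000 bit and the full background score
distribution built by dynamic programming (position-by-position
convolution), the construction FIMO uses; discretization distorts any
word's score by at most $w \cdot$ `eps`. The suite checks the DP against
exhaustive enumeration of all $4^w$ words on the same grid.

Scanning covers both strands (reverse-complement scoring), skips windows
containing N, and calls a peak motif-positive when at least one window's
p-value is at or below the threshold (default $10^{-4}$, the conventional
per-window scanning default; no threshold is universal, and reported
proportions move with it). The default background is estimated from the
scanned peak sequences themselves; a uniform background is a flag away.
Set-level enrichment is reduced to a 2×2 exact test against a control
sequence set, since per-condition proportions are the quantity of interest.

## ATAC sets

`buildConsensus()` union-merges per-sample peaks and keeps merged intervals
supported by $\ge$ `minOverlapSamples` samples (default 2 — a majority of
triplicates; the threshold is configurable since consensus definitions
vary). `accessibilityPartition()` defines the baseline as the intersection
of the focal condition with **all** controls, and a condition's unique set
against the union of all controls, including empty vector.
`affinityMatrix()` is counts-per-million then $\log_2(x+1)$; differential
accessibility testing is intentionally out of scope — the partition logic
is set-based, and the affinity matrix exists for PCA geometry.

## BioID cascade

`buildDotplot()` applies the detection filters: max replicate spectral
count $\ge$ 10, protein probability $\ge$ 0.95, contaminants (trypsin,
biotin, streptavidin) removed, BFDR tiered at 0.01/0.05. The
prioritization cascade keeps five auditable steps per run: drop
decreased-vs-full-length preys, drop Hippo components (a user-supplied
list; no canonical source exists, so the package ships none), keep
increased-only, intersect the two fusions, drop weak interactions. The
increased/decreased comparison is an average-spectral-count ratio with an
explicit dead-band `delta` (default 0); a prey absent from the full-length
table counts as increased, absent from the fusion as decreased. "Weak"
means lowest bin on **both** average count (< 10) and relative abundance
(< 0.1) with BFDR > 0.05 in both fusions; the bin edges are arguments.
Subtract-decreased and keep-increased are kept as separate steps (rather
than one comparison) so the fate of unchanged preys is visible in the step
counts.

## Screen ranking

`foldChange()` is endpoint-over-day-0 absorbance per replicate (day 10
default). A deficit call (`deficitCall()`) requires a Welch unpaired
two-tailed t-test $p <$ 0.05 **and** a lower mean fold change against
*both* control constructs (shEV and shNT); requiring both controls is the
conservative reading of a two-control design, with a single-control
relaxation available. No multiple-testing correction is applied across
hairpins — the ranking statistic is the per-gene count of deficit-scoring
hairpins, and the two-control requirement already squares the per-test
false-positive rate (the suite bounds the empirical null rate at
$2\alpha^2$). Ties rank by deeper mean fold-change deficit, then gene id.

# The synthetic-data generator

Every input is generated, seeded, and planted with the structure the
analysis is supposed to find, at the study's own scales:

* **Expression panels** (`simulateDegPanel()`): a 12,000-gene universe
  (plus 500 genes below the count filter), focal fusion sets of 1000 genes
  with planted exclusive-region structure derived from the published
  query-in-reference percentages (70/9/29, 78/10/20, 67/9/31, 53/0.2/47
  for shared-with-activated-control / shared-with-partner-control /
  unique), and a count matrix consistent with the population rule in which
  planted DEGs carry a condition-specific expression shift.
* **Peaks** (`simulatePeaks()`): a 2.1 Mb toy contig with 100 tiled genes;
  peaks split between promoters and distal intergenic space, consensus
  motif words written into the sequence at planted rates (0.61/0.58 and
  0.38/0.51 for the two panels), replicate jitter for consensus tests, and
  partner peak sets overlapping planted fractions (0.69/0.68) for
  histone-mark co-occupancy.
* **ATAC gene sets** (`simulateAtacSets()`): baseline 15,779 (TC panel)
  and 16,809 (YT panel) shared genes with unique sets of 3147/656 and
  2499/1629, and a 2% perturbation rate as the default noise condition.
* **BioID** (`simulateBioid()`): prey categories sized so the cascade
  reproduces 68/47 → 55/34 → 49/31 → 47/28 → 27 → 18 by construction
  (per-bait starting counts are not published; 68 and 47 are the
  generator's choice consistent with the published chain), plus preys that
  violate each detection filter.
* **Screen** (`simulateScreen()`): log-normal multiplicative growth,
  control day-10 fold change 5, effective hairpins at ratio 0.4 with
  log-scale noise 0.08 — an effect size a three-replicate Welch test
  detects reliably; the 18 screened genes carry three planted 5/5 hits and
  two 3/5 hits.

What the generator does **not** emulate: read-level data, genomic
covariates (GC, mappability, blacklists), correlated replicate structure,
and real motif composition of regulatory sequence. Passing tests therefore
demonstrate the correctness of the set logic, the statistics and the
planted-parameter recovery — not robustness to the failure modes of real
sequencing data.

# Numerical choices

* Hypergeometric quantities in log space (`lchoose`); HGD of an impossible
  overlap is `Inf`, never an overflow.
* Motif DP at 1/1000-bit resolution; p-values clamp to [0, 1] at the
  support edges.
* Adjusted p-values of 0 (upstream underflow) are capped at $10^{-320}$
  before $-\log_{10}$ in integration tables.
* Degenerate inputs error early and specifically: empty query sets
  (undefined fractions), all-zero samples, malformed coordinates with
  their line number, peaks beyond contig ends by name.
* Every generator seeds its own stream derived from the user seed with a
  fixed per-generator offset, so adding a generator never changes
  another's output; equal seeds give byte-identical files.

# Problem sizes in the test suite

The suite favours exact oracles at small scale: exact prime-factorization
pmf checks at $N \le 60$ (500 configurations), brute-force all-pairs
annotation on 1000 peaks × 200 genes, exhaustive $4^w$ motif enumeration
for $w \le 6$ (50 PWMs), 20-seed recovery runs for the ATAC partitions,
and 10,000 null simulations for the screen's false-deficit bound. The full
pipeline run used by the acceptance script generates four expression
panels at the 12,000-gene scale and 400-peak ChIP panels, completing in a
couple of minutes on one core.

# Known limitations

* The 5'UTR category of peak annotation requires UTR structure the gene
  models do not carry; exon/intron (or GeneBody) is the finest resolution.
* The variance-stabilizing stand-in is not a fitted dispersion transform;
  do not reuse it for differential testing.
* Motif-proportion values depend on the scanning p-threshold; comparisons
  are meaningful within a fixed threshold, not across thresholds.
* Annotation build reconciliation (e.g. peaks on one build, expression on
  another) is the caller's responsibility; the package treats annotation
  as a single given input.
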