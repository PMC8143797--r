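# fusionomics

Integrative multi-omic set analysis for chimeric transcription factors.

## The problem

Fusion oncoproteins such as TAZ-CAMTA1 and YAP-TFE3 — the defining drivers of
epithelioid hemangioendothelioma (EHE) — are chimeric transcription factors:
the N-terminus of a Hippo pathway effector (TAZ or YAP) fused in frame to the
C-terminus of an unrelated transcription factor (CAMTA1 or TFE3). Deciding
whether two such fusions converge on a shared regulatory program requires
joining evidence across assays: differential expression (RNA-seq),
chromatin binding (ChIP-seq), chromatin accessibility (ATAC-seq),
proximity-labeling interactomes (BioID) and functional shRNA screens.

`fusionomics` implements that integration as a tested R pipeline for
computational biologists working on fusion-driven cancers:

- **Gene-set overlap statistics on the HGD scale.** For a query set of size
  *n* sharing *k* genes with a reference set of size *K* inside a gene
  universe of size *N*, the overlap strength is the negative log density of
  the hypergeometric distribution,

  HGD = −log₁₀ P(X = k),  P(X = k) = C(K, k) C(N−K, n−k) / C(N, n),

  with the enrichment tail p-value P(X ≥ k) alongside (an exclusive-tail
  compatibility mode, P(X > k), is available). All combinatorics run in
  log-gamma space, so overlaps whose densities underflow doubles (HGD ≫ 300)
  are exact.
- **Peak-to-TSS annotation.** Strand-aware nearest-TSS assignment with signed
  distances, promoter/gene-body/downstream/distal-intergenic categories,
  distance-bin distributions and binned TSS occupancy profiles.
- **PWM motif scanning with exact p-values.** Log-odds scoring against a
  0-order background with the exact score distribution computed by dynamic
  programming over an integerized score grid (the FIMO-style construction),
  and per-peak motif occupancy proportions.
- **ATAC set construction.** Consensus peak sets across replicates,
  baseline vs condition-unique accessible gene partitions, and CPM/log2
  binding-affinity matrices for PCA.
- **BioID prioritization cascade.** SAINT-style dotplot filters (≥ 10
  spectral counts in one replicate, protein probability ≥ 0.95, BFDR tiers),
  fusion-vs-full-length interaction comparison, Hippo-component subtraction,
  intersection of the two fusion interactomes and removal of weak
  interactions — with a per-step audit trail.
- **shRNA screen ranking.** Day-10 growth fold changes, Welch-test deficit
  calls against both control constructs, and per-gene ranking by the number
  of deficit-scoring hairpins.
- **A seeded synthetic-data generator** that emulates the statistical
  structure of every input (planted overlap fractions, peak geometry, motif
  occupancy, prey categories, screen effect sizes), so the full pipeline
  runs and is tested with no external data.

## Worked example

Overlap of a fusion transcriptome with its full-length control on synthetic
data planted at a 70% / 9% overlap design:

```r
library(fusionomics)

sim        <- simulateDegPanel(1, degPanelDesign("tc_nih3t3"))
degSets    <- lapply(sim$tables, filterDegs)          # FDR < 0.05
population <- definePopulation(sim$counts)            # mean counts >= 5

overlapReport(degSets$TC, degSets[c("TAZ4SA", "CAMTA1")],
              length(population), queryLabel = "TC")
#>   query reference   k    K    n     N  density   tail_p     hgd pct_of_query
#> 1    TC    TAZ4SA 700 2100 1000 12000 0.000000 0.000000 331.979           70
#> 2    TC    CAMTA1  90  790 1000 12000 0.000414 0.001229   3.383            9
```

Reading the first row: 700 of the 1000 fusion DEGs are shared with the
hyperactive full-length control (70% of the query), an overlap whose
hypergeometric density is far below double precision on the linear scale —
the HGD of 332 is the usable statistic. The 9% overlap with the C-terminal
partner control is far weaker (HGD 3.4). The whole analysis — all four
expression panels, ChIP geometry and motifs, ATAC partitions, the BioID
cascade, the screen and the cross-modality fractions — runs with

```r
report <- runPipeline(list(seed = 1, outDir = "results"))
reportSummary(report)   # the headline numbers as a flat named list
```

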