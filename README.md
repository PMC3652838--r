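# barcodegap

Distance-based species delimitation for DNA barcode data.

Cryptic species complexes — sets of morphologically indistinguishable
lineages historically treated as one species, such as the whitefly *Bemisia
tabaci* — are delimited in practice from the distribution of pairwise
genetic distances in a standardized marker (typically a ~650-bp 3' window of
mitochondrial *COI*). Within-species and between-species distances form two
distributions separated by an empty interval, the **barcode gap**, and the
gap's position sets the delimitation threshold. `barcodegap` implements the
full analysis:

* **Distances.** Kimura 2-parameter and uncorrected p-distances with
  pairwise deletion of gap/ambiguous sites. With transition and transversion
  proportions *P* and *Q* among compared sites,

  d<sub>K2P</sub> = −½ ln[(1 − 2P − Q) √(1 − 2Q)],  d<sub>p</sub> = P + Q.

  Saturated pairs (log argument ≤ 0) are undefined and tracked, never
  silently zeroed.
* **Input handling.** Aligned FASTA + taxonomy TSV, trimming to the 3'
  barcode window of a reference record, and exact-match collapse of
  duplicate haplotypes.
* **Divergence profiles.** Per-level (conspecific / congeneric /
  confamilial) and per-species summaries, and divergence histograms.
* **Barcode-gap detection and threshold clustering.** Bin-free sorted-gap or
  histogram gap detection; delimitation as connected components of the
  "distance < t" graph (single linkage), with threshold profiles and
  partition comparison (adjusted Rand index).
* **Discriminant validation.** Principal-coordinates embedding of the
  distance matrix, canonical discriminant analysis on the leading axes, and
  leave-one-out cross-validated nearest-centroid classification (confusion
  matrix, % correct).
* **Cross-locus comparison.** Paired Wilcoxon signed-rank tests (exact
  p-values under midranks for n ≤ 25) and per-pair regressions of each
  mitochondrial locus against *COI*.
* **Simulator.** A K2P sequence simulator generating species complexes and
  multi-gene panels with known truth, so every stage is testable without
  downloads.

## Worked example

Simulate a 31-species complex with the package defaults (three members per
species, 650 sites, expected within-species divergence 1.2%, between-species
15.7%), and run the delimitation analysis:

```r
library(barcodegap)

cx <- simulate_complex(seed = 42)
m  <- distance_matrix(cx$alignment, model = "k2p")
m
#> Pairwise K2P distances: 93 sequences, 4278 pairs
#>   range 0.3% - 22.2%, mean 15.3%

summarize_levels(partition_pairs_by_level(m))
#> Divergence profile (values in %):
#>                         level avg_pct     range n_comparisons
#>                within_species     1.3   0.3-2.5            93
#>  within_genus_between_species    15.6 10.7-22.2          4185

find_barcode_gap(m)
#> Barcode gap: 2.50% - 10.00% (width 7.50%), method sorted_gap, window [1%, 10%]

del <- delimit_at_threshold(m, 4)
del
#> Species delimitation at 4% (single linkage): 31 putative species from 93 sequences
compare_delimitations(del, cx$truth)$adjusted_rand_index
#> [1] 1

co <- distances_to_coordinates(m)
loocv_classify(co, cx$truth[m$ids])
#> Leave-one-out cross-validation: 93 samples, 31 groups
#>   overall correct: 100.0%
```

Reading the output: the 93 within-species distances average 1.3% and never
exceed 2.5%, while all 4 185 between-species distances are ≥ 10.7% — so the
gap finder reports an empty interval starting at 2.50% (clipped to its 1–10%
search window), clustering at a 4% threshold recovers exactly the 31
simulated species (adjusted Rand index 1 against the truth), and the
cross-validated discriminant analysis reclassifies every sequence correctly.

The same functions run on real data via `read_alignment("aln.fasta",
"taxonomy.tsv")`, `trim_to_reference_window()`, and `dedup_haplotypes()`, or
end to end with `run_pipeline(pipeline_config(...))`. A thin command-line
wrapper lives at `inst/scripts/barcodegap.R`
(`Rscript barcodegap.R run --fasta aln.fasta --taxonomy tax.tsv --out-dir out`).

See the vignette (`vignettes/barcode-gap-delimitation.Rmd`) for the model,
the design decisions, and the simulator's scope.

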