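# coitiler

Tiled-amplicon COI barcode recovery and taxonomic assignment for museum
specimens.

## The problem

Natural-history collections hold millions of expertly identified voucher
specimens whose DNA is too fragmented for a single-amplicon 658-bp COI
barcode. The tiled-amplicon strategy rescues them: amplify several
short, overlapping fragments spanning the barcode region, tag each
specimen's amplicons with sample-specific indices (96 forward × 96
reverse, asymmetric dual tagging), pool 95 specimens plus a negative
control per 96-well array, and sequence the pool on a high-accuracy
circular-consensus platform. `coitiler` provides the informatics for
that workflow — for collection staff and barcoding labs who need to turn
pooled reads into per-specimen barcodes and use them to identify
unidentified material.

## What the package does

* **Plate data model** — 8×12 arrays, canonical sample IDs
  (`CCDB-31120-A01`), specimen metadata TSV I/O with a reserved
  negative-control well.
* **Panels and tag sets** — 0-based half-open amplicon coordinates on
  the 658-bp frame (presets: `sanger2`, two amplicons of 307/407 bp;
  `ngs_tiled`, six tiling amplicons), and validated UMI tag sets whose
  pairwise Hamming distance guarantees unambiguous decoding at the
  configured mismatch tolerance (≥ 2t + 1 for tolerance t).
* **Assembly pipeline** (`run_pipeline()`), six stages: mean-QV/length
  filter (QV ≥ 20, ≥ 100 bp), UMI demultiplexing on both strands,
  order-level taxonomy screen against a reference library, primer-based
  amplicon assignment (≤ 10 % of primer length in mismatches),
  alignment-free positioning (fragments anchored at their amplicon's
  frame start), and per-column majority consensus with N filling any
  internal uncovered interval. A barcode is *recovered* with > 0 non-N
  bp and *acceptable* with > 300 non-N bp.
* **Classifier** — p-distance (mismatches / compared sites on an
  ends-free global alignment, ambiguous sites excluded), a
  single-linkage cluster proxy for Barcode Index Numbers at 2.2 %
  (documented stand-in, not RESL), and two assignment routes in strict
  order: cluster taxonomy match first, then nearest-match thresholds —
  species below 2 %, genus below 5 %, always the lowest rank without
  conflict among the top matches.
* **Simulator** — synthetic true barcodes with controlled intra-species
  (< 2 %) and inter-genus (> 5 %) divergence, exponential per-amplicon
  survival `2^(−age / half-life)`, substitution/indel read noise, and
  negative-control contamination scenarios, so the whole pipeline is
  testable with no downloads.
* **Reporting** — recovery/compliance percentages (half-up, one
  decimal), failure-tracking combination with enforced count
  conservation, genus-level success, OLS regression of recovered length
  on specimen age, and the method × rank assignment table.

## Worked example

Simulate one plate of 95 degraded specimens, assemble it, and assign two
new queries against a library built from the first 40 barcodes:

```r
library(coitiler)

panel    <- load_panel("ngs_tiled")
tags     <- make_tagset()
barcodes <- simulate_barcodes(95, seed = 7)
plate    <- plate_array("CCDB-31120", barcode_records(barcodes))
model    <- degradation_model(half_life_years = 30,
                              base_error_rate = 0.005, indel_rate = 0)
sim <- simulate_reads(barcodes, panel, tags, model, depth = 3, seed = 8)

res <- run_pipeline(sim$reads, plate, panel, tags)
res$report
#>               stage reads
#> 1             input   687
#> 2          filtered   687
#> 3     demultiplexed   687
#> 4          screened   687
#> 5 amplicon_assigned   687

success_summary(res$barcodes, plate$specimens)
#> <success_summary> 95 specimens: 81 recovered (85.3%), 42 acceptable (44.2%); 23/24 genera (95.8%)

age_length_regression(plate$specimens, res$barcodes)
#> <regression_result> n = 95: length = 538.20 -4.787 * age, R^2 = 0.701, p = 4.32e-26

lib <- reference_from_barcodes(barcodes[1:40, ])
queries <- data.frame(id = c("q1", "q2"),
                      sequence = barcodes$sequence[c(41, 90)])
asg <- assign_all(queries, lib)
asg$results[["q1"]]
#> <assignment_result> q1: bin_match -> species = Genus17 sp01 (d = 0.0152)
```

Reading the output: 687 reads survive every stage (the simulated errors
are below all thresholds); 81 of 95 specimens recover some sequence but
only 42 exceed the 300-bp compliance bar, because older specimens lose
amplicons at the simulated 30-year half-life — which is exactly what the
regression shows (recovered length falls by ≈ 4.8 bp per year of
specimen age, R² = 0.70). Query `q1`, a conspecific of a library
member, inherits its species through the cluster-match route at 1.5 %
divergence.

The same operations are scriptable from a shell via `exec/coitiler`
(`simulate`, `assemble`, `assign`, `report` subcommands).

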