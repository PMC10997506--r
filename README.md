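# mbrobust

Host-derived sequence hiding inside microbial reference databases is a major
source of false positives in metagenomics: reads from the host that survive
computational host depletion can map to "microbial" genomes that are really
carrying fragments of the host genome, and taxon tables built on such
databases inherit those phantom signals. `mbrobust` is a toolkit for
auditing and hardening this part of a metagenomic pipeline, aimed at
researchers building or validating cancer-microbiome (or any
host-associated-microbiome) analyses. It provides four pieces of machinery:

1. **Exhaustive database masking** (`run_exhaustive()` and its stages).
   Every window of a host reference — 150 bp windows at 75 bp steps by
   default, windows shorter than 75 bp or with ≥ 100 N's dropped — is
   located exactly in a target database (built-in matcher on both strands,
   or SAM from any external aligner). Hits are converted to 0-based
   half-open intervals (`end = pos − 1 + length(seq)`, clipped to the
   contig), deduplicated, merged at distance 0 (book-ended intervals fuse,
   bedtools-merge semantics) and the merged spans are replaced with N's.
   The report gives per-genome cumulative masked lengths, and an
   `awk_compat` mode reproduces the one-base coordinate shift of pipelines
   that print the 1-based SAM position directly into a BED context.

2. **False-positive leakage simulation** (`run_fp_simulation()`).
   Paired-end reads (2 × 150 bp, normal fragment lengths, mean 270 sd 27,
   seeds 42, 43, ... per sample) are simulated from a host genome, optionally
   subsampled, sequentially depleted against host references (a pair
   survives only if neither mate matches), and the survivors mapped against
   a database; the output is the mapped fraction and the set of
   false-positive taxa, with mean ± sd over replicate samples.
   `expected_fp_fraction()` gives the exact enumeration expectation for a
   planted shared segment, so the simulator can be validated end to end.

3. **Conservative taxon filtering**: human-association whitelist
   intersection with an optional viral bypass (`intersect_whitelist()`),
   KrakenUniq-style read ≥ 10 AND unique-k-mer ≥ 1000 thresholds
   (`filter_krakenuniq()`), and aggregate genome coverage — the union of
   covered intervals across samples — with inclusive thresholds of 50/75/90%
   and an any-genome-per-species keep rule (`aggregate_coverage()`,
   `filter_by_coverage()`).

4. **Feature-concordance statistics** for comparing two classifiers trained
   on variants of the same data (`per_batch_compare()` and its parts):
   2×2 Fisher exact tests on used/unused feature sets (a feature is used
   iff its importance is > 0), Kendall tau-b on importance ranks with every
   unused feature tied at rank k + 1, Fisher's method across batches
   computed in log space with underflow clamped at 2.2 × 10⁻³⁰⁸,
   Benjamini–Hochberg across classes, and AUROC/AUPR with 99%
   confidence-interval overlap as the equivalence criterion.

A synthetic-fixture module (`make_planted_database()`,
`make_importance_pair()`, `make_taxon_table()`) generates every input with
known ground truth, so the whole toolkit is testable offline, and a
`mbrobust` umbrella CLI (under `exec/`) exposes the pipeline stages with
JSON run manifests for byte-identical reruns.

## Worked example

Plant two 300 bp host segments into a three-genome database, mask them, and
measure how many host reads would leak through as false positives:

```r
library(mbrobust)

fx <- make_planted_database(n_segments = 2, segment_length = 300,
                            grid_aligned = TRUE, seed = 11)
fx$db
#> genome_set: 3 contig(s), 3 genome(s), 15000 bp total

report <- run_exhaustive(fx$host, fx$db)
report
#> mask_report: 2 interval(s), 600 base(s) masked across 2 of 3 genome(s)
report$intervals
#>   contig start  end support
#> 1    g02  3316 3616       3
#> 2    g03  4074 4374       3
```

The two merged intervals coincide exactly with the planted contamination
(`fx$truth`), each supported by the 3 overlapping windows that tile a
300 bp span at 150/75 geometry. Before masking, host-only reads map to the
contaminated genomes:

```r
taxa <- setNames(c("Fusobacterium", "Prevotella", "Bacteroides"),
                 unique(fx$db$genome))
est <- run_fp_simulation(fx$host, fx$db, taxa,
                         cfg = read_sim_config(fold_coverage = 10),
                         replicates = 5, seed_start = 42)
est
#> fp_estimate: 5.76577% of 1,665 mapped (5 replicate(s)); 2 +/- 0 taxa
est$taxa_hit
#> [1] "Bacteroides" "Prevotella"
```

About 5.8% of purely host-derived read pairs are reported as microbial, all
attributed to the two genomes carrying planted host sequence; running the
same simulation against `report$masked_db` drops the mapped fraction to
zero. The statistics layer is equally direct:

```r
fisher_exact(c(a = 2, b = 0, c = 0, d = 2))$p  # 1/6
combine_fisher(c(0.5, 0.5))                    # 0.5966 (chi-square, 4 df)
bh_adjust(c(0.01, 0.02, 0.03, 0.04))           # 0.04 0.04 0.04 0.04
```

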