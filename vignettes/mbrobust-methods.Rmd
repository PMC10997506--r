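---
title: "Methods: database decontamination, leakage simulation, and concordance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: database decontamination, leakage simulation, and concordance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrobust)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and why their defaults
are what they are, what the synthetic fixtures do and do not emulate, and
the design decisions taken where more than one reasonable choice existed.

## 1. The problem

Microbial reference databases assembled from public genome repositories
contain stretches of host (e.g. human) sequence, deposited through
contaminated assemblies or genuine integrations. When a metagenomic
pipeline maps host-depleted reads against such a database, residual host
reads can align to these stretches and appear as microbial signal. The
package addresses three questions: *where* is the host sequence inside a
database (masking), *how much* host signal leaks through a given
depletion-plus-mapping pipeline (simulation), and *are downstream models
robust* to choices such as batch correction or the host reference used for
depletion (filtering and concordance statistics).

## 2. Window-based masking

### Model

The host reference is tiled into overlapping windows of `window_len = 150`
bases at `step = 75`, so every position (except within `step` of a contig
start) is covered by two windows. Trailing windows keep shrinking down to
`min_len = 75` bases; windows with `max_n = 100` or more N's are dropped.
Each window is searched for exactly — both strands, all occurrences, no
hit cap — in every database contig. The 150/75 geometry means a shared
segment that is window-aligned and at least one window long is tiled
completely; an arbitrarily placed shared segment is recovered up to
`step - 1` bases at each edge, a deliberate trade of edge sensitivity for
a dense, enumerable query set.

Hits are converted to 0-based half-open intervals with
`start = pos − 1`, `end = start + nchar(seq)`. The end position is derived
from the alignment record's sequence length without consulting the CIGAR,
so it can overrun the contig and is clipped to the contig length; this
mirrors widely used awk-based interval extraction, and a CIGAR-unaware end
is exact for the built-in ungapped matcher anyway. Sorted, deduplicated
intervals are merged at distance 0 — overlapping *or book-ended* spans
fuse, matching bedtools-merge defaults — with the number of constituent
records kept as `support`. Merged spans are replaced by N's; masking is
idempotent, preserves contig lengths, and reduces the non-N base count by
exactly the reported masked total.

### Coordinate conventions

Internal and BED coordinates are 0-based half-open; SAM positions are
converted by −1. Pipelines that print the 1-based SAM position directly
into a BED-like file introduce a one-base shift; `awk_compat = TRUE`
reproduces that shifted output exactly (every interval equals the standard
one shifted +1 before clipping), so results produced either way can be
replicated. The standards-correct conversion is the default. Whether the
shifted behaviour in existing pipelines was intentional is unknowable from
the outside; both are provided and neither is guessed to be "intended".

Secondary alignments (flag 0x100) in ingested SAM are **kept** by default,
because the awk-style extraction this stage models does not filter them;
`exclude_secondary = TRUE` is available. Unmapped records (flag 0x4 or
reference `*`) are always skipped.

### The built-in matcher versus a real aligner

The built-in matcher is exact-match only. Real short-read aligners at
sensitive settings tolerate a handful of mismatches per 150 bp window and
may cap reported hits; an exact matcher therefore under-reports diverged
contamination but is fully deterministic and oracle-checkable. Externally
produced SAM is accepted at the same interface for fidelity runs. This is
a documented divergence, not an approximation error: every test oracle in
the package defines truth at the exact-match level.

## 3. Leakage simulation

### Read model

`simulate_read_pairs()` draws, per contig,
`floor(fold_coverage · len / (2 · read_len))` fragments: start uniform on
the positions admitting at least `read_len` bases, length a rounded normal
(`frag_mean = 270`, `frag_sd = 27`) clamped to
`[read_len, contig_len − start]`. The forward mate is the fragment prefix,
the reverse mate the reverse complement of the fragment suffix; with
`frag_mean < 2 · read_len` mates overlap, as they do on real short-insert
libraries. The error model is substitution-only at `base_error_rate`
(default 0): quality-profile machinery and indels are intentionally out of
scope, because the quantity of interest — exact-substring leakage — is
defined on error-free sequence, and the error rate is exposed as a
parameter for sensitivity analyses. Defaults mirror a 2 × 150 bp Illumina
paired-end run at 1× coverage; replicate samples use seeds
`seed_start, seed_start + 1, ...` with `seed_start = 42`.

### Depletion and mapping contracts

Sequential depletion applies each host reference in turn; a pair survives
a reference only if *neither* mate matches it (the both-mates-unmapped
retention rule). Real pipelines sometimes add a single-end re-pass with
re-pairing; under an exact matcher that collapses to the both-mates rule,
so only the latter is implemented — a divergence that matters only for
gapped aligners. Mapping counts a pair as a false positive if either mate
matches any database contig; the denominator is pairs by default
(`per_read = TRUE` switches to mates), because "percent of reads mapped"
is genuinely ambiguous between the two conventions and the package refuses
to guess. Taxon labels come from a genome→taxon map, defaulting to
genus-level labels in the examples, the granularity at which false-positive
taxa are usually counted.

### Exact expectation

For a single planted segment, `expected_fp_fraction()` enumerates every
fragment start and integrates the clamped rounded-normal fragment-length
distribution in closed form (its CDF is piecewise normal), giving the exact
probability that at least one sampled mate lies wholly inside the segment.
The acceptance suite requires the simulated fraction, pooled over 20
replicate seeds of 2,500 pairs each (50,000 pairs), to fall inside the
99% binomial interval around this expectation — a statement about the
whole simulate→map chain, not about any single stage.

## 4. Taxon filtering

The two-step filter encodes a conservative stance: first restrict to taxa
with documented human association (whitelist intersection after label
normalisation — case and whitespace only; no fuzzy matching, since silent
synonym resolution would be invisible curation), then require quantitative
support. Viruses and phages are usually absent from human-association
catalogues, so a `bypass_viral` flag lets them through step (i) explicitly
flagged, shifting the burden entirely onto step (ii).

Step (ii) comes in two forms. For classifier-style counts, a taxon passes
with read count ≥ 10 **and** unique-k-mer count ≥ 1000, boundaries
inclusive. The aggregation over samples defaults to *any-sample* (some one
sample meets both thresholds) with a *summed* mode available, because
"applied among samples" is ambiguous between the two; any-sample is the
stricter reading in the sense that it demands co-occurrence of read and
k-mer support within one sample. For alignment-derived data, aggregate
genome coverage is the fraction of a genome covered by at least one read
in at least one sample of the set — a union, not a mean, so ten samples
covering the same 5% contribute 5%, not 50%. Thresholds (default 0.50,
alternatives 0.75/0.90) are inclusive. A species with several genomes is
kept if *any* constituent genome passes; pooling intervals across a
species' genomes is the other defensible rule, but coordinates are not
portable across assemblies, so best-single-genome is the default. Manual
exclusions are a configuration list applied after filtering, never code.

## 5. Concordance statistics

Two models trained on variants of the same data are compared within a
shared feature universe. A feature is *used* iff its importance score is
strictly positive. The 2×2 table (both / A-only / B-only / neither) is
tested with Fisher's exact test, one-sided `greater` by default: the
scientific question is enrichment of joint usage, and the one-sided test
is the sharper instrument for it; two-sided (summing tables no more
probable than observed) is a flag. Degenerate margins return p = 1 with a
warning rather than an error, since a model that used no features is an
empirical outcome, not a caller bug.

For rank agreement, each model's nonzero features are ranked by descending
importance (midranks for tied scores) and every zero-importance feature is
assigned the tied rank k + 1, k being that model's nonzero count. This
rule creates a large tie block by construction, which dictates the
variant: tau-b with tie-corrected variance and a normal-approximation
p-value. Vectors with fewer than two nonzero entries are rejected
(degenerate variance). Per-class evidence across batches is combined with
Fisher's method, computed in log space (`pchisq(..., log.p = TRUE)`), with
a single-batch class passing its raw p-value through; reported p-values
are clamped below at the smallest normalised double (2.2 × 10⁻³⁰⁸) with
the exact log10 value retained, and plotting columns floor q at twice that
constant before taking −log10. Benjamini–Hochberg is applied across
classes. AUROC is the tie-aware rank statistic U/(n₁n₀); AUPR uses
non-interpolated stepwise summation by default (trapezoid available);
confidence intervals are normal-approximation mean ± z·sd/√n (z = 2.576
at the default 99%) truncated to [0, 1], and two metric series are
*equivalent* when their intervals overlap. The CI construction is the
plainest available; per-fold metric distributions are not normal in the
tails, which is a known limitation shared with the practice this mirrors.

## 6. Synthetic fixtures: what they do and do not show

`make_planted_database()` builds uniform-random host and database
sequences and copies host segments into the database at recorded
positions. Generation verifies that database sequence wholly outside the
planted segments shares no ≥ 75-mer with the host (regenerating on
collision), so a null fixture guarantees zero matches and every masked
base in a planted fixture is attributable to a segment. Directly at the
junctions a planted match chance-extends by a few bases (each flank base
continues the host with probability 1/4); such extensions sit far below
the 75-base window scale and cannot create or move window-level matches,
so they are permitted rather than rejected — rejecting them would discard
most multi-segment fixtures for a property with no observable effect.

`make_importance_pair()` builds two importance vectors over a shared
universe with a controlled number of jointly used features; `overlap =
NULL` draws the two used sets independently, making the joint-usage count
exactly hypergeometric. The defaults — a universe of 428 features with 50
used per model — reflect a genus-level cancer-microbiome feature space in
which per-batch models typically use 50–150 features; at the low end of
that range the one-sided Fisher test attains a level of 0.0496 at nominal
0.05 (computed from the exact hypergeometric null), so the type-I
acceptance property tests the statistic rather than the discreteness of
the support. At k = 100 on the same universe the attainable level drops to
0.029 — a property of exact tests on discrete data worth knowing when
interpreting "significant" feature overlap on real tables. Replicate
fixtures in the type-I experiment are seeded from a master RNG: consecutive
integer seeds produce correlated Mersenne–Twister first draws and a
measurably biased null.

Fixtures are uniform-random by design: they have no GC skew, no repeats,
no homopolymers, and no quality structure. Passing tests therefore
demonstrate the *algorithmic* correctness of masking, simulation and
statistics — coordinate arithmetic, merge semantics, rank and tail
computations — not robustness to the compositional pathologies of real
genomes (repetitive contamination, low-complexity regions, diverged
homologs), which additionally require a mismatch-tolerant aligner
upstream.

## 7. Numerical choices and degenerate inputs

* Interval merging refuses unsorted input instead of silently re-sorting:
  an unsorted stream at that stage means the upstream sort/dedup contract
  was broken, and hiding it would mask bugs.
* Sequence validation is strict: any character outside `{A,C,G,T,N}` is a
  hard error naming the contig and offset; lowercase is accepted and
  uppercased.
* Fisher exact p-values are computed from hypergeometric tail sums with
  the conventional `(1 + 1e-7)` relative slack when collecting "no more
  probable" tables two-sided.
* All meta-analysis is done in log space; clamping happens only at the
  reporting boundary, and the unclamped log10 value always travels with
  the clamped number.
* Zero p-values entering Fisher's method are treated as the clamp value
  with a warning; empty inputs are errors.
* Ties in AUROC receive half credit via midranks; all-tied scores give
  exactly 0.5.
* Empty host-reference lists in depletion warn and return the input
  unchanged; contigs shorter than the read length are skipped with a
  warning, and simulation errors only when no contig is usable.

## 8. Problem sizes used by the automated checks

The test and acceptance runs use deliberately small instances — databases
of a few kilobases across 2–3 genomes, hosts of 3–20 kb, 30–100 fixture
replicates, 50,000 simulated pairs, 1000-replicate null experiments —
chosen so every check has either an exact oracle (brute-force scan,
enumeration, closed form) or a known sampling distribution at sizes where
those oracles are computable. Scaling the same code to real databases is
a matter of the external aligner and I/O, not of the algorithms, whose
costs are linear in windows × hits.

## 9. Known limitations

* The built-in matcher's exact-match semantics under-reports diverged
  contamination relative to a sensitive aligner; use external SAM for
  fidelity.
* Contamination is not distinguished from biological integration; a
  flagged region is a mapping ambiguity by definition, and deciding its
  origin is out of scope.
* The CLI's `compare-masks` comparison operates on in-memory reports via
  `compare_mask_reports()`; a serialised mask-report interchange format is
  not defined.
* The whitelist matcher is exact after normalisation; taxonomic synonym
  resolution is the caller's responsibility.
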