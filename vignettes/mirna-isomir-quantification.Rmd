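---
title: "Quantifying miRNAs and isomiRs with mirtally: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNAs and isomiRs with mirtally}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtally)
```

## The problem

Mature microRNAs are ~22 nt products excised from hairpin precursors. Counting
them from small-RNA sequencing is harder than it looks for four reasons that
drive every design choice in this package:

1. **Redundant annotation.** Registries such as miRBase contain matures with
   byte-identical sequences under different names (paralog expansions), matures
   produced by several precursors, and distinct matures overlapping on one
   hairpin. Quantifying against the raw registry double-counts or
   arbitrarily splits such reads.
2. **isomiRs.** The dominant isoform of a locus in a given sample is often not
   the annotated one: 5' ends vary little (the seed, nucleotides 2–8, is
   functionally constrained) while 3' ends vary by a few nucleotides through
   imprecise processing, exonucleolytic trimming, and non-templated additions.
   A reference holding only annotated matures cannot represent these reads.
3. **Strandedness.** Small-RNA protocols ligate adapters to the RNA itself, so
   reads are sense-strand by construction. Some 5p/3p arm pairs are mutual
   reverse complements; an aligner that searches both strands cross-assigns
   their reads.
4. **Chance alignments.** Once mismatches are allowed, short genomic fragments
   can hit a miRNA by accident, and sporadic background reads inflate the
   number of "detected" miRNAs.

`mirtally` addresses these with, respectively: a deduplicated, clustered,
flank-extended reference with delimiter-encoded entries; offset-based isomiR
counting; sense-only alignment; and genome remap invalidation plus a
cross-sample noise filter.

## Reference construction

`build_reference()` parses mature and hairpin FASTA (RNA alphabet accepted,
`U` mapped to `T`), collapses identical sequences into groups represented by
the lexicographically smallest member id (all members are preserved in the
annotation), and locates every exact sense-strand occurrence of each mature in
each hairpin. Matures that occur nowhere are excluded with a warning rather
than an error, since registries contain such records depending on release.
Overlapping matures on a shared hairpin are clustered by connected components
of the overlap graph (computed with igraph).

Each occurrence is extended by up to `extension` nucleotides of precursor
sequence per side, clipped at hairpin boundaries, with flanks in lower case and
the mature in upper case. The default `extension = 4` covers the offset ranges
the package is designed to count (5' within ±1, 3' within ±3) with one spare
base; it is configurable for libraries with wider end variation.

Entries are assembled in one of two modes. In the default **per-mature** mode
each deduplicated mature becomes one entry whose segments (one per precursor
occurrence) are joined by a single `N`. In **per-cluster** mode each overlap
cluster becomes one entry, with `NN` between segments of different matures.
Both modes are offered because deduplication motivates per-mature entries while
the clustering motivates per-cluster ones; per-mature is the default because it
keeps feature identities interpretable, and the cluster table is emitted either
way. `N` never matches any base and no alignment may span one, so the
delimiters make concatenation safe. Coordinates are 0-based half-open
internally and 1-based inclusive in the emitted TSV (stated in its header).

## Preprocessing

Every genuine miRNA read runs into the 3' adapter, so trimming is mandatory.
The trimmer is 3'-anchored prefix matching under Hamming distance (no indels):
the leftmost read position where an adapter prefix of length `k >= min_overlap`
(default 3) aligns with at most `floor(max_error_rate * k)` mismatches (default
rate 0.1) marks the cut. Reads without an adapter hit are kept by default —
the adapter fraction is a QC metric, not a drop rule — and
`discard_untrimmed = TRUE` is available. Trimmed reads shorter than
`min_len = 16` nt are discarded. No maximum-length cap is applied; over-long
reads simply fail to align within the extended-reference geometry. Base
qualities are read and ignored.

Identical reads are collapsed within each sample and then joined across
samples into one unique-read × sample count matrix, so the alignment runs once
over the union of unique reads instead of once per read. Because trimming is a
pure function of the sequence, the implementation collapses raw reads first and
trims each distinct sequence once; per-read semantics are unchanged. With the
noise filter disabled, joint processing and per-sample processing give
identical count tables — joint collapsing is an efficiency device, and the
test suite asserts this equivalence.

## Alignment and annotation

Alignment is sense-only Hamming matching with a per-stage mismatch bound
(default `max_mm = 1` per stage — one substitution in a ~22 nt read is the
error mode these libraries actually show, and indels are not part of the read
model). An `N` in a read is an unconditional mismatch; a placement covering a
reference `N` is rejected outright. All placements at the minimum mismatch
count of a read are retained, leftmost first.

The search itself is an exhaustive compiled (C++) scan over the concatenated
reference. miRNA references are a few kilobases, so exhaustive scanning is both
fast and exactly equal to the brute-force definition of the hit set; the
contract verified by the tests is the hit set, not the search strategy, and
the suite checks equality against an independent R-level oracle across random
instances with 0–2 mismatches.

Unique reads are annotated sequentially: miRNA → hairpin → small RNA → mRNA,
each read taking the first tier in which it has a hit, else `unaligned`.
Categories are therefore mutually exclusive and exhaustive, and the per-sample
category totals sum to the surviving read count. A read whose minimum-mismatch
miRNA hits span several entries is counted once, attributed to the
lexicographically smallest entry id, and tallied in a `multi_entry_reads`
counter: the reference grouping eliminates most such reads, and the residue
must not be double-counted but should remain auditable.

### Remap invalidation

A read that aligns to a miRNA only with mismatches, yet occurs verbatim
somewhere in the genome (either strand), most plausibly originates from that
locus; its miRNA assignment is invalidated. Perfect miRNA hits are never
candidates, so reads matching their own locus are untouched. The miRNA loci
themselves are not masked from the genome: only exact occurrence matters, and
an error read never matches its own locus exactly. One consequence, verified
deliberately in the tests: a sequencing error can recreate another genomic
sequence verbatim (for instance the planted single-substitution decoy, or the
mirrored context of a reverse-complementary arm pair), and such a read is
invalidated *by definition of the rule* — it is indistinguishable from a
genomic read. The validation therefore audits invalidations against verbatim
genome occurrence rather than against read provenance alone.

## Noise filtering and counting

The cross-sample noise filter flags a unique read from its count pattern:
zero fraction (share of samples with zero count, threshold 0.60, strict `>`)
and mean count (threshold 2, strict `<`). The default combines them with OR
(a read is removed if *either* condition holds); AND is also available because
descriptions of this rule appear in both forms, and the mode in force is
logged at run time. The filter operates on unique reads before any table is
built, so miRNA and isomiR tables stay consistent by construction.

Counting sums the per-sample counts of kept, valid unique reads per entry.
isomiR features are `(entry, offset5, offset3)` keys, where
`offset5 = read start − mature start` and `offset3 = read end − mature end`
within the segment containing the placement; `(0, 0)` is the canonical form,
negative 5' offsets mean a longer 5' end, positive 3' offsets a longer 3' end.
Distinct sequences sharing a key are summed, and per entry the isomiR rows sum
exactly to the miRNA cell. Nucleotide substitutions are deliberately *not*
part of the isomiR key — isomiRs are defined here purely by end offsets — and
surface instead through the **mismatch-only companion tables**, which count
only mismatch-carrying reads. Standard minus companion is the perfect-only
table, so users can switch between including and excluding mismatch reads
without re-running anything. Reads valid for several segments of one entry
take their offsets from the first containing segment; when the extended
contexts are identical the offsets coincide anyway.

RPM normalization defaults to the miRNA-mapped denominator (columns sum to
exactly 10^6); a library-size denominator (`all_reads`) is available. Samples
with a zero denominator yield `NA` columns with a warning.

## QC metrics

Per sample: raw/adapter/surviving read counts, surviving-length histogram,
total and unique reads per category, redundancy (total/unique, `NA` when
unique is zero — high miRNA redundancy with low redundancy elsewhere is the
signature of a healthy library, and deviations flag problems such as primer
dimers), the count-weighted fraction of miRNA reads carrying mismatches, and
detected miRNAs (count ≥ 1, configurable) before and after filtering. The
offset distribution (marginals, joint, and the no-variation / 5'-varying /
3'-varying fractions) is computed over valid unique miRNA reads, i.e.
unweighted by abundance. Every number in the QC summary is re-derivable from
the per-read artifacts emitted alongside it; `emit_reports()` writes
byte-deterministic TSV/JSON, with static plots optional.

## The synthetic-data generator

`synth_params()` / `synth_experiment()` define a deterministic study with
known ground truth, used by the test suite and the acceptance script. The
reference plants, by construction: an identical mature on two hairpins, a
hairpin with three mutually overlapping matures, a reverse-complementary
5p/3p arm pair, and an identical hairpin pair. The genome holds each hairpin
in random flanks, plain decoy contigs, and one decoy carrying a
single-substitution variant of a planted mature — reads from it align to the
miRNA with exactly one mismatch while matching the genome perfectly, the case
remap invalidation exists for.

Default study conditions, chosen once:

* **8 samples × 50,000 reads** — a desk-scale multi-sample study, large
  enough for the cross-sample filter to have meaningful zero fractions.
* **Offsets**: 5' in {−1, 0, +1} with probabilities (0.1, 0.8, 0.1); 3' in
  {−3..+3} with (0.045, 0.08, 0.2, 0.35, 0.2, 0.08, 0.045) — the 3' end much
  more variable than the seed-anchored 5' end, the qualitative pattern real
  libraries show; not fitted to any dataset.
* **Overlap stagger 8 nt**: with extension 4 and the offset supports above, no
  read of one mature can lie entirely inside an overlapping mature's extended
  segment, so per-mature attribution is unambiguous and exact truth recovery
  is well-defined.
* **Substitution rate 0.001 per base**, iid — the typical Illumina
  substitution rate. This is the one place the generator is knowingly
  unrealistic in structure: iid errors make essentially every mismatch read a
  sporadic singleton, whereas real libraries also contain *recurrent* mismatch
  reads (SNPs, editing, systematic cross-mapping) that survive cross-sample
  filtering. Raising the iid rate does not emulate that; it only shifts count
  mass into singletons that the filter then removes.
* **Trace entries**: a quarter of the ordinary arms are expressed sporadically
  (present in a sample with probability 0.3 at Poisson mean 1.5) — the sparse
  low-count features the noise filter targets.
* **5% background noise reads** from decoy contigs (either strand), 25
  error-free planted decoy reads per sample, adapter
  `TGGAATTCTCGGGTGCCAAGG`, read length 50 with dummy qualities (the pipeline
  ignores quality), `A`-padding after the adapter.

Read ids encode provenance (`mir|entry|o5|o3|sample|serial|e<n>`, ...) purely
as a test convenience; the pipeline never reads them. Everything is a
deterministic function of the seed, and outputs are byte-identical across
reruns.

What passing tests on this generator do and do not show: exact recovery with
zero errors demonstrates that reference construction, trimming, collapsing,
alignment, attribution and offset arithmetic are lossless under the planted
structures; it does not show robustness to ligation bias, indel errors,
non-templated 3' additions, quality artifacts, or recurrent mismatch reads,
none of which the generator models.

## Numerical and tie-breaking choices

* Representative ids (groups, clusters, multi-entry attribution) always use
  the lexicographically smallest identifier — deterministic and
  registry-agnostic.
* Equal-mismatch placements within an entry are reported leftmost-first; the
  first containing segment supplies isomiR offsets.
* The noise-filter thresholds are strict inequalities (`> 0.60`, `< 2`), so a
  read present in exactly 40% of samples, or with mean exactly 2, survives.
* All randomness in the generator flows from a single integer seed; the
  pipeline itself is deterministic.
* Degenerate inputs: empty FASTA parses to an empty table; an empty reference
  is an error at index construction; a zero-read sample yields empty outputs;
  zero RPM denominators yield `NA` columns with a warning.

## Scale of the validation runs

The test suite exercises module-level properties on studies of 2–4 samples ×
a few thousand reads, and the end-to-end checks (exact recovery, decoy
invalidation, joint/per-sample equivalence, filter direction) on the default
8 × 50,000 study; the aligner is additionally checked against a brute-force
oracle on 100 random reference/read instances with 0–2 mismatches. These sizes
were chosen as the smallest that exercise every planted structure with
comfortable margins.

## Limitations

* No indel-aware alignment; a read with an insertion or deletion relative to
  its locus is counted as unaligned or mismatch-aligned.
* isomiR identity ignores internal substitutions and non-templated additions
  as sequence events; they appear only via the mismatch companion.
* Novel miRNA discovery and differential expression are out of scope; the
  count tables are designed to feed standard downstream tools.
* The remap rule is unconditional: a mismatch read exactly matching a
  SNP-bearing genomic locus is invalidated even if it truly is a miRNA read
  with that SNP.
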