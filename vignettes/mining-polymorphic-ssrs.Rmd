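---
title: "Mining potentially polymorphic SSR loci from multiple transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining potentially polymorphic SSR loci from multiple transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## The idea

A microsatellite locus is polymorphic when individuals carry different
repeat counts. De novo transcriptome assemblies of *different* individuals
or populations of one species are, in effect, a free resequencing panel:
if the same locus assembles with 7 repeat copies in one sample and 9 in
another, the locus is very likely polymorphic, and no PCR is needed to
discover that. `ssrmine` operationalizes this in three stages — detect SSR
runs in the merged transcript dataset, aggregate repeat-count observations
under exact flanking-sequence keys, and extract/verify primer-ready
candidate sequences — followed by the statistics used to validate a marker
panel after genotyping.

This vignette documents the model assumptions, the tunable parameters, the
numerical conventions, and the limits of what the synthetic fixtures can
show.

## Detection model

`find_ssrs()` reports **maximal runs of full tandem copies** of a
**primitive** unit (1–6 bp) that reach a per-unit-length minimum repeat
count. The defaults follow the MISA convention:

| unit length | 1 | 2 | 3 | 4 | 5 | 6 |
|---|---|---|---|---|---|---|
| min repeats | 10 | 6 | 5 | 5 | 5 | 5 |

All six are configurable through `ssr_thresholds()`; raising a threshold
can only remove hits (a property the test suite checks).

Conventions that pin down edge cases:

* **Full copies only.** A run of `(AT)x7` followed by a lone `A` is 7
  repeats; the trailing partial copy belongs to the flank. Repeat number is
  the quantity compared across samples, so it must be an integer.
* **Region anchoring.** A maximal tandem region (e.g. `CGCGCGC`, 3.5 copies)
  yields one run anchored at the region start (`CGCGCG`), not one run per
  phase. The scan uses a zero-width lookahead so that an adjacent upstream
  region can never consume the first base of the next region and shift its
  phase.
* **Primitivity.** `ATATAT` is a dinucleotide run, never additionally an
  `ATAT` tetranucleotide run: units that are powers of a shorter unit are
  rejected, which prevents double counting. Overlapping runs of *different*
  primitive unit lengths that each pass their threshold are all reported;
  in the degenerate identical-span case the shorter unit wins.
* **Interrupted repeats.** An imperfect SSR (`(AT)x6 C (AT)x5`) is reported
  as separate maximal runs, each thresholded on its own. The method makes
  no perfect/imperfect distinction; thresholds alone decide.
* **Ambiguity.** `N` terminates extension and a run containing `N` is never
  reported — assembly ambiguity must not fabricate repeats. Any character
  outside `ACGTN` is an input error naming the offending position.
* **Coordinates** are 0-based half-open in tibbles (so
  `end - start = repeats * unit length` exactly); report files are
  1-based inclusive where applicable.

Motif tallies use the canonical class under cyclic rotation and reverse
complementation (`TA` → `AT/AT`, `CT` → `AG/CT`, `TTA` → `AAT/ATT`), the
standard grouping for motif-type abundance summaries.

The detector is validated against an independent brute-force finder that
locates maximal tandem regions by run-length-encoding the lag-u
self-comparison of the sequence; the two agree exactly on 1000 random 2-kb
sequences with planted runs of every unit length.

## Locus identity: exact flank keys

A hit's locus key is the string `left flank (k bp) + motif + right flank
(k bp)`. Identical keys across the merged dataset are treated as one locus;
the repeat counts observed under a key are its polymorphism evidence, and a
key with ≥ 2 distinct repeat counts is flagged potentially polymorphic.

* **k (flank length per side), default 10.** Short flanks risk key
  collisions between unrelated loci (a 2k-mer must be effectively unique in
  the dataset); long flanks discard hits near transcript ends and are more
  likely to overlap a neighboring polymorphism. Values ≥ 8 are sensible for
  transcriptome-scale data; 10 is the default working value.
* **Exact matching is deliberate.** A SNP or assembly error inside a flank
  splits a locus into two keys — observations are lost, never wrongly
  merged. The test suite asserts this splitting behavior as documented
  behavior. Consequence: some real polymorphic loci are missed; no
  similarity-based clustering is attempted.
* **Strands.** Transcripts from one locus may assemble on either strand.
  By default keys are *not* merged with their reverse complements (exact
  string identity, matching the splitting semantics above);
  `merge_revcomp = TRUE` canonicalizes each key against the reverse
  complement of its key string and merges the observations.
* **min_obs (default off).** With few input transcriptomes (roughly five or
  fewer) a key collects too few repeat-count values for the polymorphic
  flag to mean much. An optional `min_obs` filter gates the flag on
  observation count; the detail file always retains every record.
* **Counting.** Observations are counted per occurrence, not per sample: a
  locus detected twice in one assembly contributes two values, since the
  reported count is the total number of SSRs assigned to the locus.

Aggregation is a single pass over hits grouped by key, independent of input
record order (records sort by key; each record's repeat list follows the
deterministic transcript-id/position sort of the dataset). The two report
files are three tab-separated columns — key string, observation count,
comma-separated repeat numbers — with no header by default, and round-trip
losslessly through `read_locus_report()`.

## Extraction and verification

Primer design needs context. For each selected locus key,
`locate_key()` re-finds exact occurrences of *left flank + ≥ threshold
copies of the motif + right flank* within single transcripts (never across
record boundaries), and `extract_window()` cuts a candidate amplicon:

* window length 100–300 bp containing the run, ≥ 50 bp of context per side;
* the window grows symmetrically from the run and then extends toward the
  300 bp cap only as the transcript allows, deterministically;
* a transcript that cannot supply 50 bp on each side (or a run longer than
  200 bp, which cannot fit both flanks under the cap) yields a skip reason
  instead of a window.

`verify_locus()` then checks, across a locus's windows: every occurrence
passed the flank rule, and the non-repeat context agrees wherever two
windows both cover a position (left contexts compared right-aligned at the
run start, right contexts left-aligned after the run end). The repeat run
itself is excluded from the comparison — a repeat-count difference is the
signal, not an inconsistency. A locus whose windows disagree in covered
context is two different loci sharing a key neighborhood, not one marker.
The comparison span is the formalization of the manual text-editor check
the workflow replaces: with conserved flanks the decision does not depend
on how far beyond the key the windows happen to extend.

## Marker statistics

After genotyping a panel, each locus is summarized by N (individuals
successfully genotyped), Na (distinct alleles), F~M~ (major-allele
frequency) and PIC:

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2$$

computed from allele frequencies $p$ counted over the $2N$ gene copies of
diploid fragment-length calls. Conventions, fixed because genotype exports
underdetermine them:

* an individual with a single detected peak is recorded as homozygous;
  an empty allele pair is a failed call and contributes nothing to N;
* informativeness thresholds are strict: "exceeds 0.25 / 0.5" means
  `pic > 0.25` / `pic > 0.5`;
* frequencies must sum to 1 within 1e-9; the implementation evaluates the
  cross term as $(\sum p_i^2)^2 - \sum p_i^4$ and is tested against a
  direct double-loop evaluation to 1e-12;
* reported tables round to 4 decimals, the convention of published
  validation panels.

Useful identities the tests exercise: PIC ≤ expected heterozygosity
$1-\sum p_i^2$ always; PIC = 0 iff the locus is monomorphic; equal
frequencies maximize PIC for fixed Na. A 52-locus published pea aphid
validation panel ships in `inst/extdata/` as a worked reference input; its
summary reproduces the published mean row to 4 decimals.

## What the synthetic generator emulates — and what it does not

`make_transcript_set()` builds per-sample assemblies containing planted
loci: per locus one motif, one left and one right context generated once
and reused verbatim in every sample, and a per-sample repeat-count vector.
Background transcripts and contexts are rejection-sampled to contain no
run above threshold, every planted run is verified to be detected exactly
as planted, and every key is verified to occur exactly once per sample —
the truth table is therefore exact by construction.

Default conditions: 6 samples (one more than the data volume at which the
approach starts to be informative), 20 loci of which 12 vary across
samples, 30 background transcripts of 300–800 bp per sample, contexts of
60–120 bp per side with 6 loci given a 25–45 bp context on one side so the
flank-length check has true negatives. Repeat counts sit 2–10 copies above
threshold, the range where transcriptome SSRs concentrate.

`make_genotype_table()` draws independent diploid genotypes from stated
allele-frequency vectors with optional per-call dropout; frequency
re-estimation at n = 500 recovers the truth within binomial error, which is
the calibration check on the statistics path.

What the fixtures deliberately do **not** model: assembly errors and flank
SNPs (except as explicit mutations in tests that assert the splitting
behavior), read-level noise or coverage-dependent assembly dropout,
imperfect/compound repeats, paralogous loci sharing flanks, and
non-uniform base composition. Passing the planted-recovery tests therefore
shows the bookkeeping is exact under clean conditions — it does not bound
the false-negative rate on real assemblies, which is dominated by flank
mutations and assembly quality.

## Determinism and problem sizes

Every stochastic component takes an explicit seed and restores the
caller's RNG state; identical seeds and configuration give byte-identical
FASTA, report, and statistics outputs (fixed sort orders, fixed 4-decimal
formatting). The test suite runs the detector-vs-oracle comparison on
1000 random 2-kb sequences and the end-to-end planted-recovery analysis on
the default 6 x 20 locus configuration; both finish in well under five
minutes on a single core, and the sizes are stated here as the package's
reference validation conditions.

## Known limitations

* Exact key matching undercounts polymorphic loci in the presence of flank
  variation (by design; see above).
* Mononucleotide runs near homopolymer-error-prone positions of real
  assemblies will inflate the detail file; thresholds are the only guard.
* The polymorphic flag is evidence, not proof: repeat-count differences
  between assemblies can still reflect assembly artifacts, which is why
  the extraction stage re-verifies context and the final arbiter remains
  genotyping.
* No primer design is attempted; the extraction stage only guarantees the
  sequence context such a design needs.
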