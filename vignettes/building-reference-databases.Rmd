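---
title: "Building curated metabarcoding reference databases with ampliref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building curated metabarcoding reference databases with ampliref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliref)
```

## The problem

Taxonomic classification of metabarcoding reads is only as good as the
reference database behind it. For most loci no professionally curated
reference exists, and assembling one by hand — finding every sequence a
primer pair can amplify, pulling in homologs whose deposited records do
not include the primer-binding regions, and resolving conflicting or
missing taxonomy — does not scale. `ampliref` automates this as a
three-stage pipeline over a local sequence collection:

1. **Seed discovery (in silico PCR).** Every non-degenerate variant of the
   forward and reverse primers is placed on both strands of every corpus
   sequence; convergent, non-overlapping placements within the product
   length bounds become *seed amplicons*, annotated with a seven-rank
   lineage (superkingdom, phylum, class, order, family, genus, species).
2. **Iterative stratified expansion.** Seeds are grouped at a taxonomic
   rank (genus by default) and one seed per stratum is similarity-searched
   against the corpus per round. Hits are accumulated per accession
   (longest hit wins); recovered seeds leave the pool, so each round
   shrinks the work. This recovers homologous records that lack the primer
   regions entirely.
3. **Dereplication and curation.** Records with uninformative lineages are
   set aside, byte-identical sequences are collapsed under a joined
   representative accession, and each collapsed entry's taxonomy is
   reconciled to the lowest common agreement across its members.

A fourth component compares any two databases in the emitted format
(shared/unique accessions and species, and a per-rank table of lineage
paths unique to each side).

## Primer model and matching semantics

Primers may contain IUPAC ambiguity codes; `expand_degenerate()` produces
the full Cartesian set of A/C/G/T variants (the pipeline searches variants,
not degenerate strings, mirroring how primer pools physically anneal).
When a primer is highly degenerate, `enumerate_primers()` caps the pool at
`n_max_variants` per role (default 25) by uniform subsampling under the run
seed; the cap bounds search cost and 25 is ample for the 2–8-fold
degeneracies typical of published barcode primers.

Mismatch counting is IUPAC-aware **on the primer side**: a subject base
matching any base in the primer position's degeneracy set counts as zero
mismatches. An ambiguous subject base (N) matches any primer base by
default — ambiguity in the deposited sequence should not inflate mismatch
counts — and `subject_n_matches = FALSE` flips this to strict counting.
When several variants place on the same amplicon span, the span is
reported once with the per-role minimum mismatch count, as a PCR with the
full primer pool would behave.

Placements are full-length and ungapped (a primer-annealing model; an
indel in the binding site generally kills amplification), and a pair is
only amplifiable when the two placements are convergent, on the same
accession, non-overlapping, and the primer-to-primer product (inclusive of
both footprints) lies within the length bounds.

## Search backends

All searching goes through one contract with two implementations.

The **internal backend** is exhaustive and has no external dependencies:
primer placement enumerates every qualifying window (via
`Biostrings::vmatchPattern`), and seed expansion computes the best
affine-gap Smith–Waterman local alignment for every query/subject pair on
both strands, using blastn's default nucleotide scoring (match +2,
mismatch −3, gap open 5, gap extend 2; implemented in C++). Its e-value is
the deterministic surrogate `e = 0.1 * m * n * 2^(-score/2)` (m, n: total
query and corpus lengths). The surrogate is monotone in alignment score,
so `max_evalue` behaves correctly as a filter knob, but the values are
**not** comparable to BLAST e-values — filter primarily on
`min_percent_identity` and `min_query_coverage` when using this backend.
Percent identity is matches over alignment columns; query coverage is the
aligned query span over query length. Where the published similarity
filter speaks of "query length" we expose a coverage fraction, which is
scale-free across loci of different lengths.

The **external backend** shells out to `makeblastdb`/`blastn`
(`-task blastn-short` for primers) and parses fixed tabular column lists
into the same record types. It exists for production-scale corpora; every
test and the whole acceptance suite run on the internal backend, so
nothing in the package's correctness story depends on an external binary.
The blastn-short word-size/reward defaults of the external tool are
inherited, not overridden.

Hit coordinates are 1-based inclusive on the subject plus strand with
`start <= end` regardless of strand, everywhere.

## Why expansion results do not depend on the sampling

Stratified sampling is an efficiency device: only a few seeds are searched
per round, and any seed recovered as a hit of an earlier round is removed
unsearched. The final accession set is therefore invariant to the RNG seed
and the stratification rank whenever similarity is transitive across the
seed set — i.e. when sequences form clusters (congeneric barcode
sequences) such that any one member's hits cover the whole cluster. Real
barcode loci approximate this well; the synthetic fixtures are built to
have exactly this structure, which is what lets the tests demand *exact*
set equality across seeds and ranks rather than a tolerance. On a corpus
with borderline similarity ties (pairs sitting exactly at the identity or
coverage threshold) the guarantee weakens to approximate invariance.

Termination is structural: sampled seeds always leave the pool, so the
pool strictly shrinks; when fewer than `max_to_blast` seeds remain, all of
them are searched in one final round. A `max_iterations` cap (default 100)
guards against configuration errors.

## Taxonomy reconciliation

Lineages are fixed seven-rank paths with an explicit missing sentinel
(`NA`). The lowest common agreed taxonomy walks ranks from superkingdom
downward: missing values never veto agreement (members "Chordata" and
missing at phylum resolve to "Chordata"); a rank with two or more distinct
names becomes missing, and so does everything below it, even if lower
ranks coincidentally agree — a shared species epithet under conflicting
genera is a homonym, not agreement. So members *Badis assamensis* and
*Badis badis* reconcile to genus *Badis* with species missing.

One subtlety: because "missing does not veto", collapsing a conflict to
`NA` and then meeting the result with a third lineage can resurrect a name
the conflict should have killed. A pairwise-folded implementation would
therefore depend on fold order. `lowest_common_lineage()` instead computes
the meet over **all** members at once (per-rank distinct-value sets), which
is invariant to member order and duplication; binary folding agrees with it
exactly when no rank conflicts, and the tests check precisely these
properties rather than an associativity that the collapsed representation
cannot have.

Representative accessions whose membership map lists several member
taxids, and subjects reporting several taxids, are resolved through the
same meet. The NA-lineage filter discards an entry only when **all five**
of phylum, class, order, family and genus are missing (the signature of
environmental records with no classification value); `na_mode = "any"`
gives the strict alternative. Discarded entries are written to a side
file, never deleted. Species missing alone never routes an entry aside.

## Dereplication

"Identical" means exact uppercase string identity — equal length and
composition follow from it, while composition alone would merge different
sequences. Reverse-complement duplicates are deliberately not merged: the
emitted database preserves deposited orientation. Representative ids join
the sorted member accessions with `"|"`, entries are emitted in
representative-id order, FASTA wraps at 80 columns with LF endings, and
missing ranks print as `"NA"` in the tab + semicolon taxonomy dialect.
These conventions make `build_reference()` a byte-level fixpoint on its
own output, which is the property the tests pin.

## Determinism

All randomness (variant subsampling, stratified draws, fixture generation)
flows from the single configured seed through `withr::with_seed`, so no
call disturbs the caller's RNG stream and identical configuration
reproduces the final FASTA and taxonomy files byte for byte. Ordering
tie-breaks are explicit everywhere (hits by accession/start/query;
longest-hit dedup ties by lexicographic sequence then query accession).

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds a small taxonomy (two genera per family, one
order), plants one amplicon per accession with primer-site mismatches
drawn from a configurable profile (default 60/30/10% for 0/1/2
mismatches), and derives the accessions of a genus from a shared template
at ~2% point divergence outside the primer footprints — the within-genus
cluster structure of real barcode loci. A quarter of accessions are stored
reverse-complemented. Decoys (wrong orientation, single primer,
out-of-bounds product), byte-identical duplicates (same or congeneric
taxon), and uninformative-lineage records exercise each filter, and every
planted site is re-scanned before the truth file is written, so generation
fails loudly rather than emit wrong ground truth. Background sequence is
i.i.d. uniform ACGT, with rejection of chance primer matches.

Deliberately absent: indels and rate heterogeneity, read-level error,
chimeras, taxonomic mislabeling beyond taxid conflicts, and realistic
base composition. Passing tests therefore demonstrate the pipeline's
logic — recovery, closure, accounting, reconciliation, reproducibility —
not classifier-level performance on real NCBI data.

## Problem sizes and defaults

The test and acceptance fixtures use 12–60 accessions of 400–600 bp with
120–180 bp products, sizes at which the internal backend's all-pairs
alignment is exact and fast; the oracle checks (independent sliding-window
scan, `Biostrings::pairwiseAlignment`, set arithmetic) run at the same
scale. Defaults a user should know: `max_mismatch = 3` per primer,
product length 50–2000 bp, `rank = "genus"`, `max_to_blast = 1000`,
`sample_size_per_stratum = 1`, `min_percent_identity = 70`,
`min_query_coverage = 0.5`, wildcard drop threshold 0.5 N-fraction, and
`na_mode = "all"`. Parameters named in the underlying method but without
published defaults were fixed once to these values and documented here
rather than tuned per run.

## Known limitations

* The internal backend is quadratic in corpus size; beyond roughly 10^6
  total bases use the BLAST+ adapter.
* E-values from the internal backend are surrogates (see above).
* Primer placement is ungapped; a true indel-tolerant annealing model is
  out of scope.
* Name-based synonym resolution and chimera detection are not attempted;
  curation is limited to the taxid-conflict and NA rules described.
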