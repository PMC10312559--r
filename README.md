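# ampliref

Build curated, locus-specific reference barcode databases for
metabarcoding from a local sequence collection — no web services, fully
reproducible under a single seed.

Classifying environmental amplicon reads requires a reference database of
sequences the study's primer pair can amplify, each with reliable
taxonomy. For most loci no curated database exists. `ampliref` builds one
in three stages:

1. **Seed discovery (in silico PCR)** — `find_seeds()` expands degenerate
   primers into their IUPAC variants, places every variant on both strands
   of every corpus sequence (≤ *k* mismatches, IUPAC-aware on the primer
   side), and keeps convergent, non-overlapping placements whose
   primer-to-primer product length is within bounds. Seeds carry a
   seven-rank lineage (superkingdom…species) resolved from an NCBI
   taxdump-dialect store.
2. **Iterative stratified expansion** — `expand_seeds()` repeatedly draws
   one seed per taxonomic stratum (genus by default), similarity-searches
   the sample against the corpus, keeps the longest hit per accession, and
   removes every sampled or recovered seed from the pool until fewer than
   `max_to_blast` remain (then searches them all). This pulls in
   homologous records that lack the primer regions.
3. **Dereplication and curation** — `build_reference()` sets aside entries
   whose phylum–genus ranks are all missing, collapses byte-identical
   sequences under a joined representative accession, and reconciles each
   entry's taxonomy to the lowest common agreement: missing values never
   veto ("Chordata" + missing → "Chordata"), conflicting names become
   missing along with every rank below them (*Badis assamensis* +
   *Badis badis* → genus *Badis*, species missing).

`compare_ref_db()` quantifies overlap between two databases (shared and
unique accessions and species, plus a per-rank table of lineage paths
unique to each side). `generate_fixture()` creates self-verified synthetic
corpora — planted amplicons with known mismatch counts, labeled decoys,
duplicates, uninformative lineages — so the entire pipeline is testable
offline. Searching runs on an internal exhaustive backend (C++
Smith–Waterman, blastn default scoring) or through external BLAST+ when
available.

## Worked example

```r
library(ampliref)

# 1. a small self-verified corpus with known ground truth
truth <- generate_fixture(
  fixture_spec(n_genera = 4, species_per_genus = 2, accessions_per_species = 2,
               decoy_fraction = 0.2, duplicate_fraction = 0.1,
               na_lineage_fraction = 0.1, rng_seed = 7),
  "fixture_demo")
truth
#> fixture_truth: 20 accessions (13 planted, 3 decoys, 2 duplicates, 2 NA-lineage)

corpus  <- read_fasta(truth$paths$corpus)
store   <- fixture_store(truth)
primers <- primer_set("ACGTTCGAWCTGCAGGTCAT", "TGCATCGRAGTCCTAGGACT")

# 2. in silico PCR
seeds <- find_seeds(primers, corpus, store, truth$seed_params)
seeds
#> seed_result: 17 seeds on 17 accessions (4 primer variants, 75 raw hits)

# 3. iterative stratified expansion
ex <- expand_seeds(seeds$seeds, corpus, store,
                   expansion_params(max_to_blast = 3,
                                    sim = similarity_params(85, 10, 0.8),
                                    rng_seed = 1))
ex$iteration_log[, 1:6]
#>   iteration sampled hits_returned new_accessions seeds_removed seeds_remaining
#> 1         1       5            23             17            17               0

# 4. dereplication + curation
db <- build_reference(ex$hits, out_dir = "refdb_demo")
db
#> ref_database: 13 entries (2 discarded by NA-lineage filter)
head(db$entries[, c("representative_id", "genus", "species")], 3)
#>     representative_id         genus                  species
#> 1 SYN0001.1|SYN0017.1 Synthogenus01 Synthogenus01 specimen01
#> 2 SYN0003.1|SYN0018.1 Synthogenus01                     <NA>
#> 3           SYN0004.1 Synthogenus01 Synthogenus01 specimen02
```

Reading the numbers: the 4 enumerated primer variants produce 75 raw
placements, which pair into 17 plausible amplicons — exactly the 13
planted accessions plus 2 duplicates and 2 uninformative-lineage records;
the 3 decoys (wrong orientation, single primer, out-of-bounds length)
yield none. One stratified round (5 seeds, one per genus and one for the
missing-genus stratum) recovers all 17 amplicon-bearing accessions, so the
pool empties immediately. Dereplication discards the 2 uninformative
records and collapses the 2 duplicates into their sources' entries —
13 entries from 15 kept accessions. `SYN0001.1|SYN0017.1` is a same-species
duplicate pair; `SYN0003.1|SYN0018.1` collapsed two congeneric species, so
its species rank is reconciled to missing while the genus survives.

Final outputs in `refdb_demo/`: `reference_derep.fasta`,
`reference_taxonomy.txt` (id + semicolon-joined 7-rank lineage),
`reference_discarded_na.{fasta,txt}`, `provenance.json`.

The whole pipeline also runs as one call (`run_pipeline(run_config(...))`)
or from the shell via the thin CLI in `inst/cli/ampliref.R`
(`get-seeds`, `expand`, `derep`, `compare`, `fixture`, `run-all`
subcommands; flags mirror `run_config()`, YAML config supported).

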