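make_hit <- function(role, acc, start, end, strand, mm = 0L) {
  data.frame(query_id = "Q", role = role, subject_accession = acc,
             subject_gi = NA_character_, mismatches = mm,
             subject_start = start, subject_end = end, strand = strand,
             taxid = NA_character_, stringsAsFactors = FALSE)
}

test_that("convergent hit pairs become amplicons with inclusive coordinates", {
  withr::with_seed(1, corpus <- c(ACC1 = random_dna_string(200),
                                  ACC2 = random_dna_string(200)))
  hits <- rbind(make_hit("forward", "ACC1", 10L, 30L, "plus"),
                make_hit("reverse", "ACC1", 110L, 130L, "minus"))
  seeds <- pair_hits_to_amplicons(hits, corpus,
                                  seed_params(min_product_length = 50,
                                              max_product_length = 500))
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$amplicon_start, 10L)
  expect_identical(seeds$amplicon_end, 130L)
  expect_identical(seeds$product_length, 121L)
  expect_identical(seeds$orientation, "plus")
  expect_identical(seeds$amplicon_sequence,
                   substr(corpus[["ACC1"]], 10, 130))

  # the same two hits on different accessions pair to nothing
  hits2 <- rbind(make_hit("forward", "ACC1", 10L, 30L, "plus"),
                 make_hit("reverse", "ACC2", 110L, 130L, "minus"))
  expect_identical(nrow(pair_hits_to_amplicons(hits2, corpus)), 0L)
})

test_that("orientation, overlap and length rules reject implausible pairs", {
  withr::with_seed(2, corpus <- c(A = random_dna_string(400)))
  p <- seed_params(min_product_length = 50, max_product_length = 200)
  # same strand (divergent primers): no product
  same <- rbind(make_hit("forward", "A", 10L, 30L, "plus"),
                make_hit("reverse", "A", 110L, 130L, "plus"))
  expect_identical(nrow(pair_hits_to_amplicons(same, corpus, p)), 0L)
  # reverse hit upstream of a plus forward hit: facing away
  away <- rbind(make_hit("forward", "A", 210L, 230L, "plus"),
                make_hit("reverse", "A", 110L, 130L, "minus"))
  expect_identical(nrow(pair_hits_to_amplicons(away, corpus, p)), 0L)
  # overlapping footprints are non-amplifiable
  ovl <- rbind(make_hit("forward", "A", 10L, 30L, "plus"),
               make_hit("reverse", "A", 25L, 45L, "minus"))
  expect_identical(nrow(pair_hits_to_amplicons(ovl, corpus, p)), 0L)
  # product outside the length bounds
  long <- rbind(make_hit("forward", "A", 10L, 30L, "plus"),
                make_hit("reverse", "A", 350L, 370L, "minus"))
  expect_identical(nrow(pair_hits_to_amplicons(long, corpus, p)), 0L)
  # minus-orientation product is reverse-complemented
  minus <- rbind(make_hit("forward", "A", 110L, 130L, "minus"),
                 make_hit("reverse", "A", 10L, 30L, "plus"))
  s <- pair_hits_to_amplicons(minus, corpus, p)
  expect_identical(s$orientation, "minus")
  expect_identical(s$amplicon_sequence,
                   reverse_complement(substr(corpus[["A"]], 10, 130)))
  # hits naming an accession missing from the corpus are an error
  bad <- make_hit("forward", "GHOST", 1L, 20L, "plus")
  expect_error(pair_hits_to_amplicons(bad, corpus, p), "GHOST")
})

test_that("find_seeds recovers exactly the planted amplicons with true mismatch counts", {
  truth <- small_fixture(rng_seed = 31, decoy_fraction = 0.2)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  res <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)

  tr <- truth$accessions
  planted <- tr[tr$has_planted_amplicon, ]
  expect_identical(sort(res$seeds$accession), sort(planted$accession))
  m <- merge(res$seeds, planted, by = "accession")
  expect_identical(nrow(m), nrow(planted))
  expect_identical(m$amplicon_start.x, m$amplicon_start.y)
  expect_identical(m$amplicon_end.x, m$amplicon_end.y)
  expect_identical(m$forward_mismatches.x, m$forward_mismatches.y)
  expect_identical(m$reverse_mismatches.x, m$reverse_mismatches.y)
  # decoys never yield seeds
  expect_false(any(tr$accession[tr$is_decoy] %in% res$seeds$accession))
  # lineage annotation matches fixture ground truth
  lin <- merge(res$seeds, truth$lineages, by = "accession",
               suffixes = c("", ".truth"))
  for (r in LINEAGE_RANKS) {
    expect_identical(lin[[r]], lin[[paste0(r, ".truth")]])
  }
})

test_that("seed summaries count per-rank seeds as the fixture records them", {
  truth <- small_fixture(rng_seed = 32)
  res <- find_seeds(FIXTURE_PRIMERS, fixture_corpus(truth),
                    fixture_store(truth), truth$seed_params)
  s <- res$summary
  expect_identical(s$seeds_passing, nrow(res$seeds))
  expect_identical(s$summary_rank, "genus")
  tr <- truth$accessions
  want <- table(tr$genus[tr$has_planted_amplicon], useNA = "no")
  got <- unlist(s$seeds_per_rank_value)
  got <- got[names(got) != "NA"]
  expect_identical(sort(names(got)), sort(names(want)))
  expect_identical(as.integer(got[names(want)]), as.integer(want))
})

test_that("every emitted amplicon starts and ends with a primer match", {
  truth <- small_fixture(rng_seed = 33)
  res <- find_seeds(FIXTURE_PRIMERS, fixture_corpus(truth),
                    fixture_store(truth), truth$seed_params)
  max_mm <- truth$seed_params$max_mismatch_per_primer
  fvars <- expand_degenerate(FIXTURE_PRIMERS$forward)
  rvars <- expand_degenerate(FIXTURE_PRIMERS$reverse)
  flen <- nchar(FIXTURE_PRIMERS$forward)
  rlen <- nchar(FIXTURE_PRIMERS$reverse)
  for (i in seq_len(nrow(res$seeds))) {
    amp <- res$seeds$amplicon_sequence[i]
    head_ <- substr(amp, 1, flen)
    tail_ <- substr(amp, nchar(amp) - rlen + 1, nchar(amp))
    head_mm <- min(vapply(fvars, function(v)
      sum(!iupac_match(strsplit(v, "")[[1]], strsplit(head_, "")[[1]])),
      numeric(1)))
    tail_mm <- min(vapply(rvars, function(v)
      sum(!iupac_match(strsplit(reverse_complement(v), "")[[1]],
                       strsplit(tail_, "")[[1]])), numeric(1)))
    expect_lte(head_mm, res$seeds$forward_mismatches[i])
    expect_lte(tail_mm, max_mm)
  }
})

test_that("loosening thresholds never removes a previously found seed", {
  truth <- small_fixture(rng_seed = 34)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  tight <- truth$seed_params
  loose <- seed_params(
    min_product_length = tight$min_product_length - 10L,
    max_product_length = tight$max_product_length + 60L,
    max_mismatch_per_primer = tight$max_mismatch_per_primer + 1L,
    n_max_variants = tight$n_max_variants, rng_seed = tight$rng_seed)
  s_tight <- find_seeds(FIXTURE_PRIMERS, corpus, store, tight)$seeds
  s_loose <- find_seeds(FIXTURE_PRIMERS, corpus, store, loose)$seeds
  expect_true(all(s_tight$seed_id %in% s_loose$seed_id))
  # no seed violates its subject bounds
  w <- Biostrings::width(corpus)[match(s_loose$accession, names(corpus))]
  expect_true(all(s_loose$amplicon_start >= 1L))
  expect_true(all(s_loose$amplicon_end <= w))
})

test_that("find_seeds is bit-reproducible for a fixed seed and writes its outputs", {
  truth <- small_fixture(rng_seed = 35)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  r1 <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)
  r2 <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)
  expect_identical(r1$seeds, r2$seeds)

  out <- tempfile()
  write_seeds(r1, out, params = truth$seed_params)
  expect_true(all(file.exists(file.path(out, c(
    "seeds.fasta", "seeds_taxonomy.txt", "seed_summary.tsv",
    "provenance.json")))))
  fa <- read_fasta(file.path(out, "seeds.fasta"))
  expect_identical(length(fa), nrow(r1$seeds))
  expect_identical(unname(as.character(fa)), r1$seeds$amplicon_sequence)

  # an empty corpus yields an empty result with zeroed summary
  suppressWarnings(
    empty <- find_seeds(FIXTURE_PRIMERS,
                        Biostrings::DNAStringSet(), store,
                        truth$seed_params))
  expect_identical(nrow(empty$seeds), 0L)
  expect_identical(empty$summary$raw_hits, 0L)
  expect_identical(empty$summary$seeds_passing, 0L)
})
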