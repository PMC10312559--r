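fake_seed_table <- function(genera, ids = seq_along(genera)) {
  df <- data.frame(seed_id = paste0("S", ids),
                   accession = paste0("ACC", ids, ".1"),
                   amplicon_sequence = vapply(ids, function(i)
                     random_dna_string(60), character(1)),
                   stringsAsFactors = FALSE)
  for (r in LINEAGE_RANKS) df[[r]] <- NA_character_
  df$genus <- genera
  df$family <- paste0("F", toupper(substr(genera, 1, 1)))
  df
}

test_that("stratified sampling takes one seed per rank value", {
  withr::with_seed(9, {
    seeds <- fake_seed_table(rep(c("ga", "gb", "gc"), each = 3))
  })
  s <- stratified_sample(seeds, "genus", 1L, rng_seed = 4)
  expect_identical(nrow(s), 3L)
  expect_setequal(s$genus, c("ga", "gb", "gc"))
  # a singleton stratum is always drawn
  withr::with_seed(9, single <- fake_seed_table(c("ga", "ga", "gb")))
  for (seed in 1:10) {
    expect_true("gb" %in% stratified_sample(single, "genus", 1L, seed)$genus)
  }
  # missing rank values form their own stratum
  withr::with_seed(9, nas <- fake_seed_table(c("ga", NA, NA)))
  s2 <- stratified_sample(nas, "genus", 1L, rng_seed = 1)
  expect_identical(nrow(s2), 2L)
  expect_true(any(is.na(s2$genus)))
})

test_that("stratified draws are uniform within a stratum and deterministic", {
  withr::with_seed(10, seeds <- fake_seed_table(rep("g", 5)))
  expect_identical(stratified_sample(seeds, "genus", 2L, 77),
                   stratified_sample(seeds, "genus", 2L, 77))
  picks <- vapply(1:1000, function(s)
    stratified_sample(seeds, "genus", 1L, s)$seed_id, character(1))
  freqs <- as.numeric(table(picks)) / 1000
  expect_length(freqs, 5L)
  expect_true(all(abs(freqs - 0.2) < 0.05))
})

test_that("per-accession dedup keeps the longest hit with stable tie-breaks", {
  h <- empty_similarity_hits()
  hit <- function(q, s, seq) data.frame(
    query_accession = q, subject_accession = s, percent_identity = 99,
    evalue = 1e-10, alignment_length = nchar(seq), subject_start = 1L,
    subject_end = nchar(seq), taxids = "1", subject_sequence = seq,
    stringsAsFactors = FALSE)
  h <- rbind(hit("q1", "X", strrep("A", 100)), hit("q2", "X", strrep("A", 150)),
             hit("q1", "Y", "ACGT"))
  d <- dedupe_longest(h)
  expect_identical(nrow(d), 2L)
  expect_identical(nchar(d$subject_sequence[d$subject_accession == "X"]), 150L)
  # equal length: lexicographically smallest sequence, then smallest query
  tie <- rbind(hit("q2", "Z", "TTTT"), hit("q1", "Z", "AAAA"),
               hit("q0", "Z", "TTTT"))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    w <- dedupe_longest(tie[perm, ])
    expect_identical(w$subject_sequence, "AAAA")
    expect_identical(w$query_accession, "q1")
  }
})

test_that("hit-table cleaning strips gaps, drops wildcard floods, unpacks taxids", {
  store <- toy_store(
    acc2taxid = c(R1.1 = "15", S1.1 = "16", W1.1 = "15"),
    membership = data.frame(rep = c("R1.1", "R1.1"),
                            member = c("R1.1", "R1b.1"),
                            taxid = c("15", "16")))
  hit <- function(acc, seq, taxids) data.frame(
    query_accession = "q", subject_accession = acc, percent_identity = 99,
    evalue = 1e-10, alignment_length = nchar(seq), subject_start = 1L,
    subject_end = nchar(seq), taxids = taxids, subject_sequence = seq,
    stringsAsFactors = FALSE)
  hits <- rbind(
    hit("R1.1", "AC-GT", "15"),                  # rep with 2 member taxids
    hit("S1.1", "ACGTACGT", "16"),               # single taxid: untouched
    hit("M1.1", "ACGTACGT", "15;16"),            # multiple blast taxids
    hit("W1.1", "ANNNNNNT", "15"))               # 6/8 N: dropped
  expect_message(clean <- clean_hit_table(hits, store), "ambiguous")
  expect_identical(sort(clean$subject_accession), c("M1.1", "R1.1", "S1.1"))
  expect_identical(attr(clean, "dropped_wildcards")$subject_accession, "W1.1")
  # gap stripped
  expect_identical(clean$subject_sequence[clean$subject_accession == "R1.1"],
                   "ACGT")
  # representative unpacked to the lowest common agreed taxonomy
  r1 <- clean[clean$subject_accession == "R1.1", ]
  expect_identical(r1$genus, "Badis")
  expect_true(is.na(r1$species))
  expect_identical(r1$taxids, "15;16")
  # multi-taxid subject likewise
  m1 <- clean[clean$subject_accession == "M1.1", ]
  expect_true(is.na(m1$species))
  # single-taxid entry keeps its full species path
  s1 <- clean[clean$subject_accession == "S1.1", ]
  expect_identical(s1$species, "Badis badis")
})

test_that("expansion terminates, removes recovered seeds, and matches the all-pairs oracle", {
  truth <- small_fixture(rng_seed = 41, na_lineage_fraction = 0.1)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  seeds <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)$seeds
  ep <- expansion_params(max_to_blast = 3L, sim = STRICT_SIM, rng_seed = 5)
  ex <- expand_seeds(seeds, corpus, store, ep)

  log <- ex$iteration_log
  expect_true(all(log$seeds_removed >= log$sampled | log$final_round))
  expect_identical(log$seeds_remaining[nrow(log)], 0L)
  expect_false(anyDuplicated(ex$hits$subject_accession) > 0)

  queries <- setNames(seeds$amplicon_sequence, seeds$accession)
  oracle <- oracle_qualifying_accessions(
    as.list(queries), corpus, STRICT_SIM$min_percent_identity,
    STRICT_SIM$min_query_coverage)
  expect_identical(sort(ex$hits$subject_accession), oracle)
})

test_that("the recovered accession set is invariant to rng seed and rank", {
  truth <- small_fixture(rng_seed = 42)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  seeds <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)$seeds
  runs <- list(
    expand_seeds(seeds, corpus, store,
                 expansion_params(max_to_blast = 3L, sim = STRICT_SIM,
                                  rng_seed = 1)),
    expand_seeds(seeds, corpus, store,
                 expansion_params(max_to_blast = 3L, sim = STRICT_SIM,
                                  rng_seed = 2)),
    expand_seeds(seeds, corpus, store,
                 expansion_params(rank = "family", max_to_blast = 3L,
                                  sim = STRICT_SIM, rng_seed = 3)))
  sets <- lapply(runs, function(r) sort(r$hits$subject_accession))
  expect_identical(sets[[2]], sets[[1]])
  expect_identical(sets[[3]], sets[[1]])
})

test_that("a single round suffices when round-1 hits cover every seed", {
  truth <- small_fixture(rng_seed = 43)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  seeds <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)$seeds
  # one seed per genus sampled; within-genus hits recover all other seeds,
  # so the pool empties after the first stratified round plus final flush
  ex <- expand_seeds(seeds, corpus, store,
                     expansion_params(max_to_blast = 1L, sim = STRICT_SIM,
                                      rng_seed = 6))
  expect_lte(nrow(ex$iteration_log), 2L)
  # default max_to_blast larger than the pool: exactly one (final) round
  ex2 <- expand_seeds(seeds, corpus, store,
                      expansion_params(sim = STRICT_SIM, rng_seed = 6))
  expect_identical(nrow(ex2$iteration_log), 1L)
  expect_true(ex2$iteration_log$final_round)
  expect_identical(sort(ex2$hits$subject_accession),
                   sort(ex$hits$subject_accession))
})

test_that("expansion writes its outputs and honours the iteration cap", {
  truth <- small_fixture(rng_seed = 44)
  corpus <- fixture_corpus(truth)
  store <- fixture_store(truth)
  seeds <- find_seeds(FIXTURE_PRIMERS, corpus, store, truth$seed_params)$seeds
  ep <- expansion_params(max_to_blast = 2L, sim = STRICT_SIM, rng_seed = 7)
  ex <- expand_seeds(seeds, corpus, store, ep)
  out <- tempfile()
  write_expansion(ex, out, params = ep)
  expect_true(all(file.exists(file.path(out, c(
    "expanded_hits.tsv", "iteration_log.tsv", "provenance.json")))))
  tab <- utils::read.delim(file.path(out, "expanded_hits.tsv"),
                           stringsAsFactors = FALSE)
  expect_identical(nrow(tab), nrow(ex$hits))

  # unrelated seeds recover nothing but themselves: one stratum per round,
  # so a low iteration cap must trip the non-termination guard
  withr::with_seed(70, lone <- fake_seed_table(rep("g1", 8)))
  lone_corpus <- setNames(lone$amplicon_sequence, lone$accession)
  expect_error(
    expand_seeds(lone, as_dna_set(lone_corpus), store,
                 expansion_params(max_to_blast = 1L, sim = STRICT_SIM,
                                  max_iterations = 2L, rng_seed = 7)),
    "did not terminate")
})
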