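test_that("short-match search places primers with BLAST-style coordinates", {
  corpus <- c(s1 = "TTACGTTT")
  h <- short_match_search("ACGT", corpus, short_match_params(max_mismatch = 0))
  expect_identical(nrow(h), 2L)  # ACGT is its own reverse complement
  plus <- h[h$strand == "plus", ]
  expect_identical(plus$subject_start, 3L)
  expect_identical(plus$subject_end, 6L)
  expect_identical(plus$mismatches, 0L)

  h1 <- short_match_search("ACGT", c(s1 = "TTACGATT"),
                           short_match_params(max_mismatch = 1))
  h1 <- h1[h1$strand == "plus" & h1$subject_start == 3L, ]
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$mismatches, 1L)

  expect_warning(empty <- short_match_search("ACGT", Biostrings::DNAStringSet()),
                 "empty corpus")
  expect_identical(nrow(empty), 0L)
})

test_that("subject ambiguity handling is switchable", {
  corpus <- c(s1 = "GGGACGNACGG")
  lenient <- short_match_search("ACGT", corpus,
                                short_match_params(max_mismatch = 0))
  expect_true(any(lenient$subject_start == 4 & lenient$strand == "plus"))
  strict <- short_match_search("ACGT", corpus,
                               short_match_params(max_mismatch = 0,
                                                  subject_n_matches = FALSE))
  expect_false(any(strict$subject_start == 4 & strict$strand == "plus"))
})

test_that("short-match search equals the exhaustive sliding-window oracle", {
  withr::with_seed(101, {
    for (inst in 1:30) {
      primers <- vapply(seq_len(sample(2:4, 1)),
                        function(i) random_dna_string(sample(8:25, 1)),
                        character(1))
      n_subj <- sample(5:12, 1)
      corpus <- setNames(
        vapply(seq_len(n_subj), function(i) random_dna_string(sample(80:300, 1)),
               character(1)),
        sprintf("ACC%03d.1", seq_len(n_subj)))
      max_mm <- sample(0:3, 1)
      got <- short_match_search(primers, as_dna_set(corpus),
                                short_match_params(max_mismatch = max_mm))
      want <- oracle_primer_hits(primers, as_dna_set(corpus), max_mm)
      cols <- c("query_id", "subject_accession", "subject_start",
                "subject_end", "strand", "mismatches")
      got <- got[do.call(order, got[cols]), cols]
      want <- want[do.call(order, want[cols]), cols]
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
    }
  })
})

test_that("strand symmetry: a reverse-complemented corpus mirrors coordinates", {
  withr::with_seed(55, {
    corpus <- setNames(vapply(1:5, function(i) random_dna_string(150),
                              character(1)), paste0("S", 1:5))
    rc <- setNames(vapply(corpus, reverse_complement, character(1),
                          USE.NAMES = FALSE), names(corpus))
    p <- random_dna_string(12)
    h <- short_match_search(p, as_dna_set(corpus),
                            short_match_params(max_mismatch = 2))
    h_rc <- short_match_search(p, as_dna_set(rc),
                               short_match_params(max_mismatch = 2))
    expect_identical(nrow(h), nrow(h_rc))
    if (nrow(h)) {
      L <- nchar(corpus)[h$subject_accession]
      mirrored <- data.frame(
        subject_accession = h$subject_accession,
        subject_start = unname(L) - h$subject_end + 1L,
        subject_end = unname(L) - h$subject_start + 1L,
        strand = ifelse(h$strand == "plus", "minus", "plus"),
        mismatches = h$mismatches, stringsAsFactors = FALSE)
      cols <- names(mirrored)
      a <- mirrored[do.call(order, mirrored[cols]), ]
      b <- h_rc[do.call(order, h_rc[cols]), cols]
      rownames(a) <- rownames(b) <- NULL
      expect_identical(a, b)
    }
  })
})

test_that("similarity search finds identical sequences at full identity", {
  withr::with_seed(77, {
    seqs <- setNames(vapply(1:4, function(i) random_dna_string(200),
                            character(1)), paste0("A", 1:4, ".1"))
  })
  hits <- similarity_search(seqs[1], as_dna_set(seqs),
                            similarity_params(min_percent_identity = 90,
                                              min_query_coverage = 0.9,
                                              max_evalue = 10))
  self <- hits[hits$subject_accession == "A1.1", ]
  expect_identical(nrow(self), 1L)
  expect_equal(self$percent_identity, 100)
  expect_identical(self$alignment_length, 200L)
  expect_identical(self$subject_sequence, unname(seqs[1]))
  # unrelated random sequences do not qualify at these thresholds
  expect_false(any(hits$subject_accession != "A1.1"))
})

test_that("similarity search recovers minus-strand and mutated homologs", {
  withr::with_seed(78, {
    base <- random_dna_string(300)
    mut <- strsplit(base, "")[[1]]
    at <- sample(300, 9)  # 3% divergence
    mut[at] <- vapply(mut[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                      character(1))
    corpus <- c(plus = base, minus = reverse_complement(base),
                mutated = paste(mut, collapse = ""),
                noise = random_dna_string(300))
  })
  hits <- similarity_search(c(q = base), as_dna_set(corpus), STRICT_SIM)
  expect_setequal(hits$subject_accession, c("plus", "minus", "mutated"))
  expect_equal(hits$percent_identity[hits$subject_accession == "plus"], 100)
  expect_gte(hits$percent_identity[hits$subject_accession == "mutated"], 96)
})

test_that("internal alignments agree with the Biostrings local-alignment oracle", {
  withr::with_seed(202, {
    for (inst in 1:8) {
      # clusters of related sequences so qualifying hits exist
      seed <- random_dna_string(sample(150:250, 1))
      seqs <- c(seed, vapply(1:3, function(i) {
        ch <- strsplit(seed, "")[[1]]
        at <- sample(length(ch), round(length(ch) * 0.04))
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        paste(ch, collapse = "")
      }, character(1)), random_dna_string(200))
      names(seqs) <- sprintf("S%d.1", seq_along(seqs))
      queries <- seqs[1:2]
      names(queries) <- paste0("Q", 1:2)

      got <- similarity_search(queries, as_dna_set(seqs), STRICT_SIM)
      want <- oracle_qualifying_accessions(
        queries, as_dna_set(seqs),
        STRICT_SIM$min_percent_identity, STRICT_SIM$min_query_coverage)
      # implementation hit set covers the oracle's qualifying set
      expect_true(all(want %in% got$subject_accession))
      # and per-pair identities agree within one point
      for (k in seq_len(nrow(got))) {
        a <- oracle_local_align(queries[[got$query_accession[k]]],
                                seqs[[got$subject_accession[k]]])
        oracle_pid <- 100 * a$matches / a$align_length
        expect_lt(abs(got$percent_identity[k] - oracle_pid), 1 + 1e-9)
      }
    }
  })
})

test_that("tabular parsers round-trip fixture files into hit records", {
  primer_tab <- c(
    "forward_ACGTACGTACGT\t12345\tAB123456.1\t1\t10\t21\t15",
    "reverse_TTGGCCAATTGG\tN/A\tAB123456.1\t0\t110\t99\tN/A",
    "forward_ACGTACGTACGT\t777\tXY000001.2\t2\t5\t16\t15;16")
  f <- tempfile()
  writeLines(primer_tab, f)
  ph <- parse_primer_blast(f)
  expect_identical(nrow(ph), 3L)
  expect_identical(ph$role, c("forward", "reverse", "forward"))
  expect_identical(ph$query_id[1], "ACGTACGTACGT")
  expect_identical(ph$subject_start[2], 99L)  # reversed pair normalized
  expect_identical(ph$subject_end[2], 110L)
  expect_identical(ph$strand, c("plus", "minus", "plus"))
  expect_true(is.na(ph$subject_gi[2]))
  expect_identical(ph$taxid[3], "15;16")

  sim_tab <- c(
    "SEED1.1\tAB123456.1\t98.500\t1e-50\t200\t1\t200\t15\tACGT-ACGT",
    "SEED1.1\tXY000001.2\t91.000\t2e-20\t180\t250\t71\t16\tGGGGCCCC")
  writeLines(sim_tab, f)
  sh <- parse_similarity_blast(f)
  expect_identical(nrow(sh), 2L)
  expect_equal(sh$percent_identity, c(98.5, 91))
  expect_identical(sh$subject_start[2], 71L)
  expect_identical(sh$subject_end[2], 250L)
  expect_identical(sh$subject_sequence[1], "ACGT-ACGT")

  writeLines("only\tthree\tcols", f)
  expect_error(parse_similarity_blast(f), "expected 9")
  file.create(f)
  expect_identical(nrow(parse_primer_blast(f)), 0L)
})

test_that("the external BLAST+ adapter matches the internal backend when present", {
  skip_if(!blast_available(), "BLAST+ executables not on PATH")
  withr::with_seed(99, {
    truth <- small_fixture(rng_seed = 21)
  })
  corpus <- fixture_corpus(truth)
  variants <- rbind(
    enumerate_primers(FIXTURE_PRIMERS$forward, role = "forward"),
    enumerate_primers(FIXTURE_PRIMERS$reverse, role = "reverse"))
  internal <- short_match_search(variants, corpus,
                                 short_match_params(max_mismatch = 2))
  external <- short_match_search_blast(variants, corpus,
                                       short_match_params(max_mismatch = 2))
  # blastn-short trims or misses some near-threshold placements; every
  # external placement must exist internally with identical coordinates
  key <- function(d) paste(d$query_id, d$subject_accession, d$subject_start,
                           d$subject_end, d$strand)
  full_len <- external[external$subject_end - external$subject_start + 1L ==
                         nchar(external$query_id), ]
  expect_true(all(key(full_len) %in% key(internal)))
})
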