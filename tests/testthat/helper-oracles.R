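# Independent oracles, deliberately coded apart from the package internals:
# the primer-scan oracle builds its own IUPAC tables and slides its own
# windows; the alignment oracle is Biostrings::pairwiseAlignment; the
# lineage-meet oracle walks ranks one by one.

# --- IUPAC tables (own definition, not the package's) --------------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# does subject char `sc` satisfy primer char `pc`? (subject ambiguity
# matches when the two sets overlap, the package's default semantics)
oracle_base_ok <- function(pc, sc) {
  length(intersect(ORACLE_IUPAC[[pc]], ORACLE_IUPAC[[sc]])) > 0L
}

# the same relation tabulated once, so the sliding-window scan stays fast
ORACLE_OK <- local({
  l <- names(ORACLE_IUPAC)
  m <- matrix(FALSE, length(l), length(l), dimnames = list(l, l))
  for (p in l) for (s in l) m[p, s] <- oracle_base_ok(p, s)
  m
})

# Exhaustive sliding-window scan of one primer over both strands of one
# subject. Returns plus-strand coordinates, start <= end.
oracle_scan_one <- function(primer, subject, max_mm) {
  sc <- strsplit(toupper(subject), "")[[1]]
  hits <- list()
  for (strand in c("plus", "minus")) {
    pat <- if (strand == "plus") primer else oracle_revcomp(primer)
    pc <- strsplit(toupper(pat), "")[[1]]
    k <- length(pc)
    if (k > length(sc)) next
    for (off in 1:(length(sc) - k + 1L)) {
      mm <- 0L
      for (j in 1:k) {
        if (!ORACLE_OK[pc[j], sc[off + j - 1L]]) mm <- mm + 1L
        if (mm > max_mm) break
      }
      if (mm <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          subject_start = off, subject_end = off + k - 1L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(subject_start = integer(0), subject_end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# Full oracle hit table over a primer set and corpus, in the same
# (query_id, accession, start, end, strand, mismatches) vocabulary as
# short_match_search.
oracle_primer_hits <- function(primers, corpus, max_mm) {
  out <- list()
  for (p in primers) {
    for (acc in names(corpus)) {
      h <- oracle_scan_one(p, as.character(corpus[[acc]]), max_mm)
      if (nrow(h)) {
        h$query_id <- p
        h$subject_accession <- acc
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), subject_accession = character(0),
                      subject_start = integer(0), subject_end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$subject_accession, df$subject_start, df$query_id,
                 df$strand), c("query_id", "subject_accession",
                               "subject_start", "subject_end", "strand",
                               "mismatches")]
  rownames(df) <- NULL
  df
}

# --- local-alignment oracle (Biostrings, blastn default scoring) ---------
oracle_local_align <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  best <- NULL
  for (strand in c("plus", "minus")) {
    subj <- if (strand == "plus") subject else oracle_revcomp(subject)
    aln <- Biostrings::pairwiseAlignment(query, subj, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    cand <- list(score = Biostrings::score(aln),
                 matches = Biostrings::nmatch(aln),
                 align_length = Biostrings::nchar(aln),
                 qstart = IRanges::start(Biostrings::pattern(aln)),
                 qend = IRanges::end(Biostrings::pattern(aln)),
                 strand = strand)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# Accessions in `corpus` with at least one qualifying alignment to at least
# one of the `queries` (named character vectors), at the given thresholds.
oracle_qualifying_accessions <- function(queries, corpus, min_pident,
                                         min_coverage) {
  qualifying <- character(0)
  for (acc in names(corpus)) {
    for (q in names(queries)) {
      a <- oracle_local_align(queries[[q]], as.character(corpus[[acc]]))
      if (a$align_length == 0) next
      pident <- 100 * a$matches / a$align_length
      coverage <- (a$qend - a$qstart + 1) / nchar(queries[[q]])
      if (pident >= min_pident && coverage >= min_coverage) {
        qualifying <- c(qualifying, acc)
        break
      }
    }
  }
  sort(qualifying)
}

# --- lineage meet oracle -------------------------------------------------
RANKS7 <- c("superkingdom", "phylum", "class", "order", "family", "genus",
            "species")

# n-ary rank-walk: top-down, keep a rank's value when the non-missing
# entries agree; the first rank holding two or more distinct names nulls
# itself and everything below it.
oracle_meet <- function(lineages) {
  out <- setNames(rep(NA_character_, 7), RANKS7)
  for (i in 1:7) {
    vals <- character(0)
    for (l in lineages) {
      v <- l[[i]]
      if (!is.na(v) && !v %in% vals) vals <- c(vals, v)
    }
    if (length(vals) > 1) break
    if (length(vals) == 1) out[[i]] <- vals
  }
  out
}

random_lineage <- function(p_missing = 0.25, pool = 3L) {
  l <- setNames(paste0(substr(RANKS7, 1, 2), sample.int(pool, 7, TRUE)),
                RANKS7)
  miss <- runif(7) < p_missing
  l[miss] <- NA_character_
  l
}

random_iupac_string <- function(len, degenerate_weight = 0.15) {
  letters15 <- names(ORACLE_IUPAC)
  w <- ifelse(letters15 %in% c("A", "C", "G", "T"),
              (1 - degenerate_weight) / 4, degenerate_weight / 11)
  paste(sample(letters15, len, TRUE, prob = w), collapse = "")
}

random_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}
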