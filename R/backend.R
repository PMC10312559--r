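# Sequence-similarity search behind a uniform contract, with two
# implementations: an exhaustive internal backend (pure R/Rcpp, fully
# reproducible offline) and an adapter shelling out to external BLAST+
# (makeblastdb / blastn) for production-scale corpora.

#' Parameters for short (primer-length) matching
#'
#' Emulates a `blastn -task blastn-short` primer placement: full-length,
#' ungapped placement of each primer variant on either strand of the
#' subject, with at most `max_mismatch` mismatches.
#'
#' @param max_mismatch Maximum mismatches per primer placement.
#' @param search_both_strands Search the minus strand too (default `TRUE`).
#' @param subject_n_matches Treat ambiguous subject bases (N etc.) as
#'   matching any primer base (default `TRUE`); `FALSE` makes a subject N a
#'   literal mismatch.
#' @return A `short_match_params` list.
#' @export
short_match_params <- function(max_mismatch = 3L, search_both_strands = TRUE,
                               subject_n_matches = TRUE) {
  stopifnot(max_mismatch >= 0L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 search_both_strands = isTRUE(search_both_strands),
                 subject_n_matches = isTRUE(subject_n_matches)),
            class = "short_match_params")
}

#' Parameters for seed similarity search
#'
#' @param min_percent_identity Minimum percent identity of the local
#'   alignment, in `(0, 100]`.
#' @param max_evalue Maximum e-value. The internal backend computes a
#'   deterministic surrogate (see [similarity_search()]) honoured
#'   monotonically; it is not comparable to BLAST e-values.
#' @param min_query_coverage Minimum fraction of the query covered by the
#'   alignment, in `(0, 1]`.
#' @param align_limit Maximum hits retained per query (by score).
#' @return A `similarity_params` list.
#' @export
similarity_params <- function(min_percent_identity = 70, max_evalue = 10,
                              min_query_coverage = 0.5, align_limit = Inf) {
  stopifnot(min_percent_identity > 0, min_percent_identity <= 100,
            max_evalue > 0, min_query_coverage > 0, min_query_coverage <= 1)
  structure(list(min_percent_identity = min_percent_identity,
                 max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage,
                 align_limit = align_limit),
            class = "similarity_params")
}

empty_primer_hits <- function() {
  data.frame(query_id = character(0), role = character(0),
             subject_accession = character(0), subject_gi = character(0),
             mismatches = integer(0), subject_start = integer(0),
             subject_end = integer(0), strand = character(0),
             taxid = character(0), stringsAsFactors = FALSE)
}

as_dna_set <- function(corpus) {
  if (methods::is(corpus, "DNAStringSet")) return(corpus)
  if (is.character(corpus)) {
    if (is.null(names(corpus))) stop("corpus must be named", call. = FALSE)
    return(Biostrings::DNAStringSet(corpus))
  }
  stop("corpus must be a named character vector or DNAStringSet", call. = FALSE)
}

#' Place primer variants on a corpus (blastn-short analogue)
#'
#' The internal backend reports every full-length ungapped placement of
#' every primer variant on either strand of every corpus sequence with at
#' most `params$max_mismatch` mismatches, IUPAC-aware on the primer side.
#' Coordinates are 1-based inclusive on the subject plus strand with
#' `subject_start <= subject_end` regardless of strand (BLAST convention).
#' Output rows are ordered by (accession, start, query_id) so runs are
#' deterministic.
#'
#' @param variants A data.frame from [enumerate_primers()] (columns
#'   `variant`, `source`, `role`), or a character vector of non-degenerate
#'   primers (then `role` applies to all).
#' @param corpus Named `DNAStringSet` (names are accession.version) or
#'   named character vector.
#' @param params A [short_match_params()] object.
#' @param role Role label used when `variants` is a plain character vector.
#' @return data.frame of primer hits: `query_id`, `role`,
#'   `subject_accession`, `subject_gi`, `mismatches`, `subject_start`,
#'   `subject_end`, `strand`, `taxid`.
#' @export
short_match_search <- function(variants, corpus,
                               params = short_match_params(),
                               role = "forward") {
  if (is.character(variants)) {
    variants <- data.frame(variant = variants, source = variants, role = role,
                           stringsAsFactors = FALSE)
  }
  corpus <- as_dna_set(corpus)
  if (length(corpus) == 0L) {
    warning("empty corpus: no primer hits possible")
    return(empty_primer_hits())
  }
  if (is.null(names(corpus)) || anyDuplicated(names(corpus))) {
    stop("corpus sequences must carry unique accession names", call. = FALSE)
  }
  fixed <- c(pattern = FALSE, subject = params$subject_n_matches == FALSE)

  res <- vector("list", 2L * nrow(variants))
  k <- 0L
  strands <- if (params$search_both_strands) c("plus", "minus") else "plus"
  for (vi in seq_len(nrow(variants))) {
    v <- variants$variant[vi]
    for (strand in strands) {
      pat <- if (strand == "plus") v else reverse_complement(v)
      dpat <- Biostrings::DNAString(pat)
      m <- Biostrings::vmatchPattern(dpat, corpus,
                                     max.mismatch = params$max_mismatch,
                                     with.indels = FALSE, fixed = fixed)
      starts <- IRanges::start(m)
      nhit <- lengths(starts)
      if (sum(nhit) == 0L) next
      acc <- rep(names(corpus), nhit)
      st <- unlist(starts, use.names = FALSE)
      en <- st + nchar(v) - 1L
      # drop out-of-bounds placements (vmatchPattern can report partial
      # overhangs when max.mismatch > 0)
      w <- rep(Biostrings::width(corpus), nhit)
      ok <- st >= 1L & en <= w
      if (!any(ok)) next
      acc <- acc[ok]; st <- st[ok]; en <- en[ok]
      mm <- integer(length(st))
      for (a in unique(acc)) {
        sel <- acc == a
        mm[sel] <- Biostrings::neditStartingAt(
          dpat, corpus[[a]], starting.at = st[sel],
          with.indels = FALSE, fixed = fixed)
      }
      keep <- mm <= params$max_mismatch
      if (!any(keep)) next
      k <- k + 1L
      res[[k]] <- data.frame(
        query_id = v, role = variants$role[vi],
        subject_accession = acc[keep], subject_gi = NA_character_,
        mismatches = mm[keep], subject_start = st[keep],
        subject_end = en[keep], strand = strand, taxid = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty_primer_hits())
  out <- do.call(rbind, res[seq_len(k)])
  out <- unique(out)
  out <- out[order(out$subject_accession, out$subject_start, out$query_id,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_similarity_hits <- function() {
  data.frame(query_accession = character(0), subject_accession = character(0),
             percent_identity = numeric(0), evalue = numeric(0),
             alignment_length = integer(0), subject_start = integer(0),
             subject_end = integer(0), taxids = character(0),
             subject_sequence = character(0), stringsAsFactors = FALSE)
}

#' Similarity search of seed sequences against a corpus (blastn analogue)
#'
#' The internal backend computes, for every query/subject pair, the best
#' affine-gap Smith-Waterman local alignment under blastn's default
#' nucleotide scoring (reward 2, penalty -3, gap open 5, gap extend 2) and
#' filters hits by percent identity, query coverage and e-value. Its
#' e-value is the deterministic surrogate `e = 0.1 * m * n * 2^(-score/2)`
#' (m, n = query and corpus lengths): monotone in alignment score, so the
#' `max_evalue` threshold behaves as a filter knob, but the values are NOT
#' comparable to BLAST e-values.
#'
#' The `"blast"` method shells out to `makeblastdb`/`blastn` and parses the
#' tabular output into the same record type.
#'
#' @param queries Named `DNAStringSet` (or named character vector) of seed
#'   sequences; names are query accessions.
#' @param corpus Named `DNAStringSet` or named character vector.
#' @param params A [similarity_params()] object.
#' @param method `"internal"` (exhaustive, default) or `"blast"`.
#' @param store Optional [load_taxdump()] store used to fill the `taxids`
#'   column for the internal backend.
#' @return data.frame of similarity hits: `query_accession`,
#'   `subject_accession`, `percent_identity`, `evalue`, `alignment_length`,
#'   `subject_start`, `subject_end`, `taxids` (";"-joined when multiple),
#'   `subject_sequence` (aligned subject span).
#' @export
similarity_search <- function(queries, corpus, params = similarity_params(),
                              method = c("internal", "blast"), store = NULL) {
  method <- match.arg(method)
  queries <- as_dna_set(queries)
  corpus <- as_dna_set(corpus)
  if (length(queries) == 0L) return(empty_similarity_hits())
  if (method == "blast") {
    return(similarity_search_blast(queries, corpus, params))
  }

  qs <- as.character(queries)
  ss <- as.character(corpus)
  # Both strands, like blastn: align against the subject and its reverse
  # complement, keep the better placement per pair (ties favour plus).
  ss_rc <- vapply(ss, reverse_complement, character(1L), USE.NAMES = FALSE)
  tab_p <- .sw_align_pairs(unname(qs), unname(ss))
  tab_m <- .sw_align_pairs(unname(qs), ss_rc)
  minus_better <- tab_m$score > tab_p$score
  tab <- tab_p
  tab[minus_better, ] <- tab_m[minus_better, ]
  tab$strand <- ifelse(minus_better, "minus", "plus")
  # minus-strand subject coordinates back onto the plus strand
  L <- nchar(ss)[tab$subject_index]
  sel <- tab$strand == "minus" & tab$align_length > 0L
  s0 <- tab$sstart[sel]; e0 <- tab$send[sel]
  tab$sstart[sel] <- L[sel] - e0 + 1L
  tab$send[sel] <- L[sel] - s0 + 1L
  tab$query_accession <- names(qs)[tab$query_index]
  tab$subject_accession <- names(ss)[tab$subject_index]
  tab <- tab[tab$align_length > 0L, , drop = FALSE]
  if (!nrow(tab)) return(empty_similarity_hits())

  qlen <- nchar(qs)[tab$query_index]
  tab$percent_identity <- 100 * tab$matches / tab$align_length
  coverage <- (tab$qend - tab$qstart + 1L) / qlen
  m_total <- sum(nchar(qs))
  n_total <- sum(nchar(ss))
  tab$evalue <- 0.1 * m_total * n_total * 2^(-tab$score / 2)

  keep <- tab$percent_identity >= params$min_percent_identity &
    coverage >= params$min_query_coverage &
    tab$evalue <= params$max_evalue
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(empty_similarity_hits())

  if (is.finite(params$align_limit)) {
    tab <- do.call(rbind, lapply(split(tab, tab$query_accession), function(d) {
      d[order(-d$score, d$subject_accession), , drop = FALSE][
        seq_len(min(nrow(d), params$align_limit)), , drop = FALSE]
    }))
  }

  # aligned subject span, reported in alignment orientation (BLAST sseq
  # convention): minus-strand hits are reverse-complemented
  span <- substr(as.character(corpus[tab$subject_accession]),
                 tab$sstart, tab$send)
  is_minus <- tab$strand == "minus"
  span[is_minus] <- vapply(span[is_minus], reverse_complement, character(1L),
                           USE.NAMES = FALSE)
  tab$subject_sequence <- span
  taxids <- if (!is.null(store)) {
    accession_taxid(store, tab$subject_accession)
  } else NA_character_
  out <- data.frame(
    query_accession = tab$query_accession,
    subject_accession = tab$subject_accession,
    percent_identity = tab$percent_identity,
    evalue = tab$evalue,
    alignment_length = tab$align_length,
    subject_start = tab$sstart, subject_end = tab$send,
    taxids = taxids,
    subject_sequence = tab$subject_sequence,
    stringsAsFactors = FALSE)
  out <- out[order(out$query_accession, out$subject_accession,
                   -out$percent_identity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- external BLAST+ adapter -------------------------------------------

#' Is the external BLAST+ toolchain available?
#' @return `TRUE` when both `makeblastdb` and `blastn` resolve on PATH.
#' @export
blast_available <- function() {
  nzchar(Sys.which("makeblastdb")) && nzchar(Sys.which("blastn"))
}

require_blast <- function() {
  for (exe in c("makeblastdb", "blastn")) {
    if (!nzchar(Sys.which(exe))) {
      stop(sprintf(
        "external backend requested but '%s' was not found on PATH", exe),
        call. = FALSE)
    }
  }
}

make_blast_db <- function(corpus, dir = tempfile("blastdb")) {
  require_blast()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "corpus.fasta")
  write_fasta(corpus, fa)
  db <- file.path(dir, "corpus")
  status <- system2("makeblastdb",
                    c("-in", fa, "-dbtype", "nucl", "-out", db),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed", call. = FALSE)
  db
}

PRIMER_BLAST_COLS <- c("qseqid", "sgi", "saccver", "mismatch", "sstart",
                       "send", "staxids")
SIM_BLAST_COLS <- c("qaccver", "saccver", "pident", "evalue", "length",
                    "sstart", "send", "staxids", "sseq")

similarity_search_blast <- function(queries, corpus, params) {
  db <- make_blast_db(corpus)
  qfa <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfa), add = TRUE)
  write_fasta(queries, qfa)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c("-query", qfa, "-db", db,
            "-perc_identity", params$min_percent_identity,
            "-evalue", params$max_evalue,
            "-qcov_hsp_perc", 100 * params$min_query_coverage,
            "-outfmt", shQuote(paste("6", paste(SIM_BLAST_COLS, collapse = " "))),
            "-out", out)
  status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn failed", call. = FALSE)
  parse_similarity_blast(out)
}

#' Run primer placement through external blastn -task blastn-short
#'
#' @inheritParams short_match_search
#' @return Same primer-hit data.frame as [short_match_search()].
#' @export
short_match_search_blast <- function(variants, corpus,
                                     params = short_match_params(),
                                     role = "forward") {
  if (is.character(variants)) {
    variants <- data.frame(variant = variants, source = variants, role = role,
                           stringsAsFactors = FALSE)
  }
  corpus <- as_dna_set(corpus)
  db <- make_blast_db(corpus)
  qfa <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfa), add = TRUE)
  ids <- paste0(variants$role, "_", variants$variant)
  write_fasta(stats::setNames(variants$variant, ids), qfa)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c("-query", qfa, "-db", db, "-task", "blastn-short",
            "-evalue", 1000, "-ungapped",
            "-outfmt", shQuote(paste("6", paste(PRIMER_BLAST_COLS, collapse = " "))),
            "-out", out)
  status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn failed", call. = FALSE)
  hits <- parse_primer_blast(out)
  hits <- hits[hits$mismatches <= params$max_mismatch, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Parse a blastn-short tabular file into primer-hit records
#'
#' Expects `-outfmt "6 qseqid sgi saccver mismatch sstart send staxids"`.
#' Coordinates are normalized so `subject_start <= subject_end` and a
#' reversed pair is reported as a minus-strand hit.
#'
#' @param path Tabular file path.
#' @return Primer-hit data.frame (see [short_match_search()]).
#' @export
parse_primer_blast <- function(path) {
  if (file.size(path) == 0L) return(empty_primer_hits())
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != length(PRIMER_BLAST_COLS)) {
    stop(sprintf("expected %d tab-separated columns (%s), found %d",
                 length(PRIMER_BLAST_COLS),
                 paste(PRIMER_BLAST_COLS, collapse = ","), ncol(df)),
         call. = FALSE)
  }
  names(df) <- PRIMER_BLAST_COLS
  sstart <- as.integer(df$sstart)
  send <- as.integer(df$send)
  role <- ifelse(grepl("^reverse", df$qseqid), "reverse", "forward")
  data.frame(
    query_id = sub("^(forward|reverse)_", "", df$qseqid), role = role,
    subject_accession = df$saccver,
    subject_gi = ifelse(df$sgi %in% c("N/A", ""), NA_character_, df$sgi),
    mismatches = as.integer(df$mismatch),
    subject_start = pmin(sstart, send), subject_end = pmax(sstart, send),
    strand = ifelse(sstart <= send, "plus", "minus"),
    taxid = ifelse(df$staxids %in% c("N/A", ""), NA_character_, df$staxids),
    stringsAsFactors = FALSE)
}

#' Parse a blastn tabular file into similarity-hit records
#'
#' Expects `-outfmt "6 qaccver saccver pident evalue length sstart send
#' staxids sseq"`.
#'
#' @param path Tabular file path.
#' @return Similarity-hit data.frame (see [similarity_search()]).
#' @export
parse_similarity_blast <- function(path) {
  if (file.size(path) == 0L) return(empty_similarity_hits())
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != length(SIM_BLAST_COLS)) {
    stop(sprintf("expected %d tab-separated columns (%s), found %d",
                 length(SIM_BLAST_COLS),
                 paste(SIM_BLAST_COLS, collapse = ","), ncol(df)),
         call. = FALSE)
  }
  names(df) <- SIM_BLAST_COLS
  sstart <- as.integer(df$sstart)
  send <- as.integer(df$send)
  data.frame(
    query_accession = df$qaccver, subject_accession = df$saccver,
    percent_identity = as.numeric(df$pident),
    evalue = as.numeric(df$evalue),
    alignment_length = as.integer(df$length),
    subject_start = pmin(sstart, send), subject_end = pmax(sstart, send),
    taxids = df$staxids, subject_sequence = df$sseq,
    stringsAsFactors = FALSE)
}
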