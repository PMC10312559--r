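# In silico PCR: turn primer placements into plausible amplicon seed
# records with taxonomy and summary statistics.

#' Parameters for seed (amplicon) discovery
#'
#' @param min_product_length,max_product_length Allowed amplicon length in
#'   bp, primer-to-primer inclusive of both primer footprints.
#' @param max_mismatch_per_primer Maximum mismatches allowed for each primer
#'   placement.
#' @param n_max_variants Maximum non-degenerate variants retained per primer
#'   role after degenerate expansion (see [enumerate_primers()]).
#' @param rng_seed Seed controlling variant subsampling.
#' @return A `seed_params` list.
#' @export
seed_params <- function(min_product_length = 50L, max_product_length = 2000L,
                        max_mismatch_per_primer = 3L, n_max_variants = 25L,
                        rng_seed = 1L) {
  stopifnot(min_product_length > 0L,
            min_product_length <= max_product_length,
            max_mismatch_per_primer >= 0L, n_max_variants >= 1L)
  structure(list(min_product_length = as.integer(min_product_length),
                 max_product_length = as.integer(max_product_length),
                 max_mismatch_per_primer = as.integer(max_mismatch_per_primer),
                 n_max_variants = as.integer(n_max_variants),
                 rng_seed = as.integer(rng_seed)),
            class = "seed_params")
}

empty_seeds <- function() {
  df <- data.frame(seed_id = character(0), accession = character(0),
                   amplicon_start = integer(0), amplicon_end = integer(0),
                   orientation = character(0), product_length = integer(0),
                   forward_mismatches = integer(0),
                   reverse_mismatches = integer(0),
                   amplicon_sequence = character(0), taxid = character(0),
                   stringsAsFactors = FALSE)
  for (r in LINEAGE_RANKS) df[[r]] <- character(0)
  df
}

#' Pair forward and reverse primer hits into candidate amplicons
#'
#' A (forward hit, reverse hit) pair on the same accession yields an
#' amplicon when the two hits sit on opposite strands in convergent
#' orientation (each primer's 3' end pointing toward the other), their
#' footprints do not overlap, and the plus-strand span from the upstream
#' hit's start to the downstream hit's end is within the length bounds.
#' The amplicon sequence is extracted primer-to-primer from the corpus and
#' reported 5'->3' in the orientation defined by the forward primer
#' (reverse-complemented when the forward primer sits on the minus strand).
#'
#' @param hits Primer-hit data.frame from [short_match_search()] with both
#'   roles present.
#' @param corpus Named `DNAStringSet` or named character vector.
#' @param params A [seed_params()] object.
#' @return Seed data.frame: `seed_id`, `accession`, `amplicon_start`,
#'   `amplicon_end` (1-based inclusive, plus strand), `orientation` (strand
#'   of the forward primer), `product_length`, `forward_mismatches`,
#'   `reverse_mismatches`, `amplicon_sequence`, `taxid` (unannotated).
#' @export
pair_hits_to_amplicons <- function(hits, corpus, params = seed_params()) {
  corpus <- as_dna_set(corpus)
  if (!nrow(hits)) return(empty_seeds()[, 1:10])
  missing_acc <- setdiff(unique(hits$subject_accession), names(corpus))
  if (length(missing_acc)) {
    stop(sprintf("hit accession(s) absent from corpus: %s",
                 paste(missing_acc, collapse = ", ")), call. = FALSE)
  }
  hits <- hits[hits$mismatches <= params$max_mismatch_per_primer, , drop = FALSE]
  fwd <- hits[hits$role == "forward", , drop = FALSE]
  rev <- hits[hits$role == "reverse", , drop = FALSE]
  out <- list(); k <- 0L
  for (acc in intersect(unique(fwd$subject_accession),
                        unique(rev$subject_accession))) {
    f <- fwd[fwd$subject_accession == acc, , drop = FALSE]
    r <- rev[rev$subject_accession == acc, , drop = FALSE]
    subject <- as.character(corpus[[acc]])
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      fs <- f$subject_start[i]; fe <- f$subject_end[i]
      rs <- r$subject_start[j]; re <- r$subject_end[j]
      if (f$strand[i] == "plus" && r$strand[j] == "minus" && fe < rs) {
        start <- fs; end <- re; orient <- "plus"
      } else if (f$strand[i] == "minus" && r$strand[j] == "plus" && re < fs) {
        start <- rs; end <- fe; orient <- "minus"
      } else {
        next  # same strand, divergent, or overlapping footprints
      }
      len <- end - start + 1L
      if (len < params$min_product_length || len > params$max_product_length) next
      seq <- substr(subject, start, end)
      if (orient == "minus") seq <- reverse_complement(seq)
      k <- k + 1L
      out[[k]] <- data.frame(
        seed_id = sprintf("%s_%d_%d", acc, start, end), accession = acc,
        amplicon_start = start, amplicon_end = end, orientation = orient,
        product_length = len, forward_mismatches = f$mismatches[i],
        reverse_mismatches = r$mismatches[j], amplicon_sequence = seq,
        taxid = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!k) return(empty_seeds()[, 1:10])
  out <- do.call(rbind, out)
  # Several enumerated variants can place on one amplicon span with
  # different mismatch counts; report the span once with the best-matching
  # forward and reverse variant (minimum mismatches), as a PCR would.
  key <- paste(out$seed_id, out$orientation)
  out$forward_mismatches <- stats::ave(out$forward_mismatches, key,
                                       FUN = min)
  out$reverse_mismatches <- stats::ave(out$reverse_mismatches, key,
                                       FUN = min)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$accession, out$amplicon_start, out$amplicon_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discover seed amplicons for a primer set (in silico PCR)
#'
#' Runs the full seed stage: degenerate expansion and (optional)
#' subsampling of primer variants, short-match placement of every variant on
#' both strands of the corpus, convergent pairing into candidate amplicons,
#' length/mismatch filtering, and lineage annotation. Accessions with no
#' resolvable taxid receive an all-missing lineage and are counted in the
#' summary rather than dropped (the dereplication stage removes
#' uninformative lineages later).
#'
#' @param primers A [primer_set()].
#' @param corpus Named `DNAStringSet` or named character vector.
#' @param store A [load_taxdump()] taxonomy store.
#' @param params A [seed_params()] object.
#' @param method Search backend: `"internal"` or `"blast"`.
#' @param summary_rank Rank whose per-value seed counts are reported in the
#'   summary (default `"genus"`, matching the expansion stage default).
#' @return A list of class `seed_result`: `seeds` (data.frame with lineage
#'   columns appended) and `summary` (list of counters).
#' @export
find_seeds <- function(primers, corpus, store, params = seed_params(),
                       method = c("internal", "blast"),
                       summary_rank = "genus") {
  method <- match.arg(method)
  stopifnot(inherits(primers, "primer_set"), summary_rank %in% LINEAGE_RANKS)
  corpus <- as_dna_set(corpus)
  fwd <- enumerate_primers(primers$forward, n_max = params$n_max_variants,
                           seed = params$rng_seed, role = "forward")
  rev <- enumerate_primers(primers$reverse, n_max = params$n_max_variants,
                           seed = params$rng_seed + 1L, role = "reverse")
  variants <- rbind(fwd, rev)
  sm <- short_match_params(max_mismatch = params$max_mismatch_per_primer)
  hits <- if (method == "internal") {
    short_match_search(variants, corpus, sm)
  } else {
    short_match_search_blast(variants, corpus, sm)
  }
  seeds <- pair_hits_to_amplicons(hits, corpus, params)
  seeds$taxid <- accession_taxid(store, seeds$accession)
  lin <- get_lineages(store, seeds$taxid, permissive = TRUE)
  seeds <- cbind(seeds, lin)

  per_rank <- if (nrow(seeds)) {
    vals <- seeds[[summary_rank]]
    vals[is.na(vals)] <- "NA"
    as.list(table(vals))
  } else list()
  summary <- list(
    primers_searched = nrow(variants),
    raw_hits = nrow(hits),
    accessions_with_hits = length(unique(hits$subject_accession)),
    seeds_passing = nrow(seeds),
    accessions_with_seeds = length(unique(seeds$accession)),
    unresolved_taxids = sum(is.na(seeds$taxid)),
    summary_rank = summary_rank,
    seeds_per_rank_value = per_rank)
  structure(list(seeds = seeds, summary = summary), class = "seed_result")
}

#' @export
print.seed_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "seed_result: %d seeds on %d accessions (%d primer variants, %d raw hits)\n",
    s$seeds_passing, s$accessions_with_seeds, s$primers_searched, s$raw_hits))
  invisible(x)
}

#' Write seed-stage outputs
#'
#' Emits `seeds.fasta` (headers are `accession_start_end`),
#' `seeds_taxonomy.txt`, `seed_summary.tsv` and `provenance.json` under
#' `out_dir`.
#'
#' @param result A `seed_result` from [find_seeds()].
#' @param out_dir Output directory (created if needed).
#' @param params The [seed_params()] used (recorded in provenance).
#' @return `out_dir`, invisibly.
#' @export
write_seeds <- function(result, out_dir, params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- result$seeds
  write_fasta(stats::setNames(seeds$amplicon_sequence, seeds$seed_id),
              file.path(out_dir, "seeds.fasta"))
  write_taxonomy_table(seeds$seed_id, seeds[, LINEAGE_RANKS, drop = FALSE],
                       file.path(out_dir, "seeds_taxonomy.txt"))
  s <- result$summary
  flat <- data.frame(
    statistic = c("primers_searched", "raw_hits", "accessions_with_hits",
                  "seeds_passing", "accessions_with_seeds",
                  "unresolved_taxids",
                  paste0("seeds_", s$summary_rank, "_",
                         names(s$seeds_per_rank_value))),
    value = c(s$primers_searched, s$raw_hits, s$accessions_with_hits,
              s$seeds_passing, s$accessions_with_seeds, s$unresolved_taxids,
              unlist(s$seeds_per_rank_value, use.names = FALSE)),
    stringsAsFactors = FALSE)
  utils::write.table(flat, file.path(out_dir, "seed_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(file.path(out_dir, "provenance.json"), "find_seeds",
                   params = unclass(params) %||% list(),
                   extra = list(summary = s[names(s) != "seeds_per_rank_value"]))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
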