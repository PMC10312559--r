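# Iterative, taxonomically stratified expansion of the seed set into a
# comprehensive accession-keyed hit table.

#' Parameters for iterative seed expansion
#'
#' @param rank Stratification rank (one of the 7 canonical ranks; default
#'   `"genus"`). Seeds missing a value at this rank form their own stratum.
#' @param max_to_blast When fewer seeds than this remain, all of them are
#'   searched in one final round and the loop stops (default 1000).
#' @param sample_size_per_stratum Seeds drawn per stratum per round
#'   (default 1, guaranteeing at least one representative of every rank
#'   value enters each round).
#' @param sim A [similarity_params()] object.
#' @param rng_seed Seed controlling the stratified draws.
#' @param max_iterations Safety cap on rounds.
#' @param max_n_fraction Hits whose sequence exceeds this fraction of
#'   ambiguous (N) bases are dropped during cleaning (default 0.5).
#' @return An `expansion_params` list.
#' @export
expansion_params <- function(rank = "genus", max_to_blast = 1000L,
                             sample_size_per_stratum = 1L,
                             sim = similarity_params(), rng_seed = 1L,
                             max_iterations = 100L, max_n_fraction = 0.5) {
  stopifnot(rank %in% LINEAGE_RANKS, max_to_blast >= 1L,
            sample_size_per_stratum >= 1L, max_iterations >= 1L,
            max_n_fraction >= 0, max_n_fraction <= 1)
  structure(list(rank = rank, max_to_blast = as.integer(max_to_blast),
                 sample_size_per_stratum = as.integer(sample_size_per_stratum),
                 sim = sim, rng_seed = as.integer(rng_seed),
                 max_iterations = as.integer(max_iterations),
                 max_n_fraction = max_n_fraction),
            class = "expansion_params")
}

#' Stratified random sample of seeds at a taxonomic rank
#'
#' Groups seeds by their lineage value at `rank` (missing values form a
#' single stratum) and draws `min(size_per_stratum, stratum size)` seeds
#' uniformly without replacement from each stratum. Deterministic for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param seeds Seed data.frame (must carry the lineage columns).
#' @param rank Stratification rank.
#' @param size_per_stratum Seeds per stratum.
#' @param rng_seed RNG seed.
#' @return Subset of `seeds` (row order: stratum name, then seed_id).
#' @export
stratified_sample <- function(seeds, rank = "genus", size_per_stratum = 1L,
                              rng_seed = 1L) {
  stopifnot(nrow(seeds) > 0L, rank %in% names(seeds))
  strata <- seeds[[rank]]
  strata[is.na(strata)] <- "MISSING"
  idx <- withr::with_seed(rng_seed, {
    unlist(lapply(split(seq_len(nrow(seeds)), strata), function(ix) {
      if (length(ix) <= size_per_stratum) ix
      else sort(ix[sample.int(length(ix), size_per_stratum)])
    }), use.names = FALSE)
  })
  out <- seeds[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only the longest hit per subject accession
#'
#' Ties on sequence length are broken by lexicographically smallest
#' sequence, then smallest query accession, so the winner is stable across
#' runs.
#'
#' @param hits Similarity-hit data.frame.
#' @return Deduplicated hits, one row per `subject_accession`, ordered by
#'   accession.
#' @export
dedupe_longest <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$subject_accession, -nchar(hits$subject_sequence),
             hits$subject_sequence, hits$query_accession)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$subject_accession), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Clean an accumulated hit table
#'
#' Three cleaning rules: (a) alignment gap characters (`-`) are stripped
#' from hit sequences; (b) hits whose ambiguous-base (N) fraction exceeds
#' `max_n_fraction` are dropped and reported in the `dropped_wildcards`
#' attribute; (c) taxonomy is resolved — subjects reporting multiple
#' taxids, and representative accessions whose membership map lists
#' multiple member taxids, get the lowest common agreed taxonomy across all
#' member lineages, while single-taxid subjects keep their lineage
#' unchanged.
#'
#' @param hits Accession-keyed similarity-hit data.frame.
#' @param store A [load_taxdump()] taxonomy store.
#' @param max_n_fraction Wildcard threshold (default 0.5).
#' @return Cleaned hits with the 7 lineage columns appended and a
#'   `taxids` column of ";"-joined member taxids; attribute
#'   `dropped_wildcards` holds the removed rows.
#' @export
clean_hit_table <- function(hits, store, max_n_fraction = 0.5) {
  if (!nrow(hits)) {
    out <- cbind(hits, get_lineages(store, character(0)))
    attr(out, "dropped_wildcards") <- hits
    return(out)
  }
  hits$subject_sequence <- toupper(gsub("-", "", hits$subject_sequence,
                                        fixed = TRUE))
  n_frac <- vapply(hits$subject_sequence, function(s) {
    if (!nzchar(s)) return(1)
    sum(strsplit(s, "", fixed = TRUE)[[1L]] == "N") / nchar(s)
  }, numeric(1L), USE.NAMES = FALSE)
  dropped <- hits[n_frac > max_n_fraction, , drop = FALSE]
  if (nrow(dropped)) {
    message(sprintf("dropping %d hit(s) with > %.0f%% ambiguous bases",
                    nrow(dropped), 100 * max_n_fraction))
  }
  hits <- hits[n_frac <= max_n_fraction, , drop = FALSE]

  member_taxids <- function(i) {
    acc <- hits$subject_accession[i]
    tx <- hits$taxids[i]
    tx <- if (is.na(tx) || !nzchar(tx)) character(0) else
      strsplit(tx, ";", fixed = TRUE)[[1L]]
    mem <- store$membership[store$membership$representative == acc, , drop = FALSE]
    tx <- unique(c(tx, mem$taxid))
    if (!length(tx)) {
      direct <- accession_taxid(store, acc)
      tx <- direct[!is.na(direct)]
    }
    sort(tx)
  }
  tax_list <- lapply(seq_len(nrow(hits)), member_taxids)
  lin <- lapply(tax_list, function(tx) {
    if (!length(tx)) return(empty_lineage())
    if (length(tx) == 1L) return(get_lineage(store, tx, permissive = TRUE))
    lowest_common_lineage(get_lineages(store, tx, permissive = TRUE))
  })
  lin <- as.data.frame(do.call(rbind, lin), stringsAsFactors = FALSE)
  names(lin) <- LINEAGE_RANKS
  hits$taxids <- vapply(tax_list, paste, character(1L), collapse = ";")
  hits$taxids[!nzchar(hits$taxids)] <- NA_character_
  out <- cbind(hits, lin)
  rownames(out) <- NULL
  attr(out, "dropped_wildcards") <- dropped
  out
}

#' Iteratively expand seeds into a comprehensive hit table
#'
#' Each round: draw a stratified sample of the remaining seeds at
#' `params$rank`, similarity-search the sampled amplicons against the
#' corpus, merge hits into the accumulated table keeping only the longest
#' hit per accession, then remove from the seed pool every sampled seed and
#' every seed whose accession was recovered as a hit. When fewer than
#' `params$max_to_blast` seeds remain, all of them are searched in a final
#' round and the loop stops. The accumulated table is then cleaned
#' ([clean_hit_table()]) and lineage-annotated.
#'
#' With the exhaustive internal backend the final accession set does not
#' depend on the RNG seed or the stratification rank on corpora whose
#' similarity structure is transitive (e.g. per-taxon sequence clusters):
#' the stratification is an efficiency device, not a result-changing one.
#'
#' @param seeds Seed data.frame from [find_seeds()] (lineage columns
#'   required).
#' @param corpus Named `DNAStringSet` or named character vector.
#' @param store A [load_taxdump()] taxonomy store.
#' @param params An [expansion_params()] object.
#' @param method `"internal"` or `"blast"`.
#' @param checkpoint_dir Optional directory; when given, the accumulated
#'   hit table and remaining-seed ids are written there after every round
#'   so an interrupted run can be resumed by hand.
#' @return A list of class `expansion_result`: `hits` (cleaned, annotated,
#'   one row per accession) and `iteration_log` (data.frame of per-round
#'   counters).
#' @export
expand_seeds <- function(seeds, corpus, store, params = expansion_params(),
                         method = c("internal", "blast"),
                         checkpoint_dir = NULL) {
  method <- match.arg(method)
  stopifnot(nrow(seeds) > 0L)
  corpus <- as_dna_set(corpus)
  remaining <- seeds
  accumulated <- empty_similarity_hits()
  log_rows <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > params$max_iterations) {
      stop(sprintf(
        "expansion did not terminate after %d iterations (%d seeds remaining)",
        params$max_iterations, nrow(remaining)), call. = FALSE)
    }
    final_round <- nrow(remaining) < params$max_to_blast
    batch <- if (final_round) remaining else {
      stratified_sample(remaining, params$rank,
                        params$sample_size_per_stratum,
                        rng_seed = params$rng_seed + iter)
    }
    queries <- stats::setNames(batch$amplicon_sequence, batch$accession)
    queries <- queries[!duplicated(names(queries))]
    new_hits <- similarity_search(queries, corpus, params$sim,
                                  method = method, store = store)
    before <- nrow(accumulated)
    accumulated <- dedupe_longest(rbind(accumulated, new_hits))
    recovered <- unique(strip_version(new_hits$subject_accession))
    drop <- strip_version(remaining$accession) %in% recovered |
      remaining$seed_id %in% batch$seed_id
    log_rows[[iter]] <- data.frame(
      iteration = iter, sampled = nrow(batch), hits_returned = nrow(new_hits),
      new_accessions = nrow(accumulated) - before,
      seeds_removed = sum(drop), seeds_remaining = sum(!drop),
      final_round = final_round, stringsAsFactors = FALSE)
    remaining <- remaining[!drop, , drop = FALSE]
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(accumulated,
                         file.path(checkpoint_dir, "accumulated_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(remaining$seed_id,
                 file.path(checkpoint_dir, "remaining_seeds.txt"))
    }
    if (final_round || nrow(remaining) == 0L) break
  }
  hits <- clean_hit_table(accumulated, store, params$max_n_fraction)
  hits <- hits[order(hits$subject_accession), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits,
                 iteration_log = do.call(rbind, log_rows)),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("expansion_result: %d accessions after %d round(s)\n",
              nrow(x$hits), nrow(x$iteration_log)))
  invisible(x)
}

#' Write expansion-stage outputs
#'
#' Emits `expanded_hits.tsv` (accession, identity, evalue, length, taxids,
#' lineage, sequence), `iteration_log.tsv` and `provenance.json`.
#'
#' @param result An `expansion_result`.
#' @param out_dir Output directory.
#' @param params The [expansion_params()] used.
#' @return `out_dir`, invisibly.
#' @export
write_expansion <- function(result, out_dir, params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$hits, file.path(out_dir, "expanded_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$iteration_log,
                     file.path(out_dir, "iteration_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- if (is.null(params)) list() else {
    p <- unclass(params); p$sim <- unclass(p$sim); p
  }
  write_provenance(file.path(out_dir, "provenance.json"), "expand_seeds",
                   params = p,
                   extra = list(accessions = nrow(result$hits),
                                rounds = nrow(result$iteration_log)))
  invisible(out_dir)
}
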